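#' Augmentation configuration
#'
#' Random augmentations applied to training batches: rotation, width/height
#' shift, zoom, and horizontal flipping, with nearest-edge fill for pixels
#' created by the transform. Bound semantics: rotation is drawn uniformly in
#' \code{[-rotationDegMax, rotationDegMax]} degrees; shifts uniformly in
#' \code{[-frac, frac]} of the image extent; zoom factors uniformly in
#' \code{[1 - zoomFrac, 1 + zoomFrac]} per axis; flips with probability 0.5.
#'
#' @slot rotationDegMax maximum absolute rotation in degrees (default 1).
#' @slot widthShiftFrac maximum horizontal shift fraction (default 0.10).
#' @slot heightShiftFrac maximum vertical shift fraction (default 0.20).
#' @slot zoomFrac zoom half-range (default 0.20).
#' @slot horizontalFlip allow horizontal flips (default TRUE)?
#' @slot fillMode fill strategy; only \code{"nearest"} is implemented.
#' @export
setClass("AugmentationConfig",
  representation(rotationDegMax = "numeric", widthShiftFrac = "numeric",
                 heightShiftFrac = "numeric", zoomFrac = "numeric",
                 horizontalFlip = "logical", fillMode = "character"),
  prototype(rotationDegMax = 1, widthShiftFrac = 0.10,
            heightShiftFrac = 0.20, zoomFrac = 0.20,
            horizontalFlip = TRUE, fillMode = "nearest"))

setValidity("AugmentationConfig", function(object) {
  msgs <- character(0)
  if (object@widthShiftFrac < 0 || object@widthShiftFrac > 1 ||
      object@heightShiftFrac < 0 || object@heightShiftFrac > 1 ||
      object@zoomFrac < 0 || object@zoomFrac > 1)
    msgs <- c(msgs, "shift/zoom fractions must lie in [0, 1]")
  if (object@fillMode != "nearest")
    msgs <- c(msgs, "only nearest fill is implemented")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AugmentationConfig-class
#' @param rotationDegMax,widthShiftFrac,heightShiftFrac see slots.
#' @param zoomFrac,horizontalFlip,fillMode see slots.
#' @return An \code{AugmentationConfig}.
#' @export
AugmentationConfig <- function(rotationDegMax = 1, widthShiftFrac = 0.10,
                               heightShiftFrac = 0.20, zoomFrac = 0.20,
                               horizontalFlip = TRUE,
                               fillMode = "nearest") {
  new("AugmentationConfig", rotationDegMax = rotationDegMax,
      widthShiftFrac = widthShiftFrac, heightShiftFrac = heightShiftFrac,
      zoomFrac = zoomFrac, horizontalFlip = horizontalFlip,
      fillMode = fillMode)
}

#' Training plan
#'
#' @slot epochs number of training epochs (the full-scale reference run
#'   uses 2500; desk-scale profiles use far fewer).
#' @slot valFraction fraction held out for validation (default 0.2,
#'   i.e. an 80/20 split).
#' @slot reshufflePeriod every this many epochs the training and validation
#'   partitions are each reshuffled internally; no sample ever migrates
#'   between partitions (default 10).
#' @slot seed integer seed governing the split, shuffling, dropout and
#'   augmentation.
#' @slot initOutputBias start the linear output unit's bias at the mean
#'   training age (default TRUE). The optimization then starts from the
#'   best constant predictor and spends its updates on age-dependent
#'   structure — important for short desk-scale runs, harmless for long
#'   ones.
#' @export
setClass("TrainPlan",
  representation(epochs = "integer", valFraction = "numeric",
                 reshufflePeriod = "integer", seed = "integer",
                 initOutputBias = "logical"),
  prototype(epochs = 2500L, valFraction = 0.2, reshufflePeriod = 10L,
            seed = 1L, initOutputBias = TRUE))

setValidity("TrainPlan", function(object) {
  msgs <- character(0)
  if (object@epochs < 1) msgs <- c(msgs, "epochs must be >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msgs <- c(msgs, "valFraction must lie in (0, 1)")
  if (object@reshufflePeriod < 1)
    msgs <- c(msgs, "reshufflePeriod must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TrainPlan-class
#' @param epochs,valFraction,reshufflePeriod,seed,initOutputBias see slots.
#' @return A \code{TrainPlan}.
#' @export
TrainPlan <- function(epochs = 2500L, valFraction = 0.2,
                      reshufflePeriod = 10L, seed = 1L,
                      initOutputBias = TRUE) {
  new("TrainPlan", epochs = as.integer(epochs), valFraction = valFraction,
      reshufflePeriod = as.integer(reshufflePeriod), seed = as.integer(seed),
      initOutputBias = initOutputBias)
}

# ---- batch geometry ------------------------------------------------------

# build the inverse-map 2x3 affine for one augmented image
.augAffine <- function(h, w, theta, dx, dy, zx, zy, flip) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  tr <- function(x, y) matrix(c(1, 0, 0, 0, 1, 0, x, y, 1), 3, 3)
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  zoom <- diag(c(zx, zy, 1))
  fl <- diag(c(if (flip) -1 else 1, 1, 1))
  fwd <- tr(cx + dx, cy + dy) %*% rot %*% zoom %*% fl %*% tr(-cx, -cy)
  solve(fwd)[1:2, , drop = FALSE]
}

#' Randomly augment a batch of images
#'
#' Each image receives an independent random rotation, shift, zoom and
#' (optionally) horizontal flip within the configured bounds; newly exposed
#' pixels take the nearest edge value. Seeded and reproducible.
#'
#' @param x numeric array \code{(h, w, c, n)} or \code{(h, w, n)}.
#' @param acfg an [AugmentationConfig-class].
#' @param seed integer seed.
#' @return Array of the same shape.
#' @export
augmentBatch <- function(x, acfg = AugmentationConfig(), seed = 1L) {
  stopifnot(is(acfg, "AugmentationConfig"))
  d <- dim(x)
  three <- length(d) == 3L
  if (three) dim(x) <- c(d[1], d[2], 1L, d[3])
  dd <- dim(x)
  h <- dd[1]; w <- dd[2]; nc <- dd[3]; n <- dd[4]
  set.seed(seed)
  out <- x
  for (i in seq_len(n)) {
    theta <- stats::runif(1, -acfg@rotationDegMax, acfg@rotationDegMax) *
      pi / 180
    dx <- stats::runif(1, -acfg@widthShiftFrac, acfg@widthShiftFrac) * w
    dy <- stats::runif(1, -acfg@heightShiftFrac, acfg@heightShiftFrac) * h
    zx <- stats::runif(1, 1 - acfg@zoomFrac, 1 + acfg@zoomFrac)
    zy <- stats::runif(1, 1 - acfg@zoomFrac, 1 + acfg@zoomFrac)
    flip <- acfg@horizontalFlip && stats::runif(1) < 0.5
    A <- .augAffine(h, w, theta, dx, dy, zx, zy, flip)
    for (ch in seq_len(nc))
      out[, , ch, i] <- .affine_sample(x[, , ch, i], h, w, A, 1L)
  }
  if (three) dim(out) <- d
  out
}

# ---- forward / backward engine ------------------------------------------

# per-channel batch statistics of a (h, w, c, n) array
.bnSpatialStats <- function(x) {
  d <- dim(x); hw <- d[1] * d[2]; cc <- d[3]; n <- d[4]
  m <- x; dim(m) <- c(hw, cc * n)
  cm <- matrix(.colMeans(m, hw, cc * n), cc, n)
  sq <- matrix(.colMeans(m * m, hw, cc * n), cc, n)
  mu <- rowMeans(cm)
  list(mu = mu, var = pmax(rowMeans(sq) - mu^2, 0), hw = hw, cc = cc, n = n)
}

# per-channel sums of a (h, w, c, n) array
.bnSpatialSums <- function(x, hw, cc, n) {
  m <- x; dim(m) <- c(hw, cc * n)
  rowSums(matrix(.colSums(m, hw, cc * n), cc, n))
}

.forwardCnn <- function(layers, x, cfg, train = FALSE) {
  caches <- vector("list", length(layers))
  eps <- cfg@bnEpsilon
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    cache <- NULL
    if (L$type == "conv") {
      cache <- list(x = x)
      x <- .conv3_forward(x, L$W, L$b)
    } else if (L$type == "bn" && L$kind == "spatial") {
      d <- dim(x); hw <- d[1] * d[2]
      if (train) {
        st <- .bnSpatialStats(x)
        mu <- st$mu; v <- st$var
      } else {
        mu <- L$runMean; v <- L$runVar
      }
      invstd <- 1 / sqrt(v + eps)
      xhat <- (x - rep(mu, each = hw)) * rep(invstd, each = hw)
      x <- xhat * rep(L$gamma, each = hw) + rep(L$beta, each = hw)
      cache <- list(xhat = xhat, invstd = invstd, mu = mu, var = v, hw = hw,
                    cc = d[3], n = d[4])
    } else if (L$type == "bn" && L$kind == "dense") {
      if (train) {
        mu <- colMeans(x)
        v <- pmax(colMeans(x * x) - mu^2, 0)
      } else {
        mu <- L$runMean; v <- L$runVar
      }
      invstd <- 1 / sqrt(v + eps)
      xhat <- sweep(x, 2, mu) * rep(invstd, each = nrow(x))
      x <- sweep(xhat * rep(L$gamma, each = nrow(x)), 2, L$beta, `+`)
      cache <- list(xhat = xhat, invstd = invstd, mu = mu, var = v,
                    n = nrow(x))
    } else if (L$type == "relu") {
      mask <- x > 0
      x <- x * mask
      cache <- list(mask = mask)
    } else if (L$type == "pool") {
      res <- .maxpool2_forward(x)
      cache <- list(idx = res$idx, xdim = dim(x))
      x <- res$y
    } else if (L$type == "dropout") {
      if (train && L$rate > 0) {
        mask <- (stats::runif(length(x)) >= L$rate) / (1 - L$rate)
        if (!is.null(dim(x))) dim(mask) <- dim(x)
        x <- x * mask
        cache <- list(mask = mask)
      }
    } else if (L$type == "flatten") {
      d <- dim(x)
      cache <- list(d = d)
      dim(x) <- c(prod(d[1:3]), d[4])
      x <- t(x)
    } else if (L$type == "dense") {
      cache <- list(x = x)
      x <- sweep(x %*% L$W, 2, L$b, `+`)
    } else stop("unknown layer type: ", L$type)
    caches[[li]] <- cache
  }
  list(out = x, caches = caches)
}

.backwardCnn <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    cache <- caches[[li]]
    if (L$type == "conv") {
      res <- .conv3_backward(cache$x, L$W, gy)
      grads[[li]] <- list(W = res$gW, b = as.vector(res$gb))
      gy <- res$gx
    } else if (L$type == "bn" && L$kind == "spatial") {
      hw <- cache$hw; cc <- cache$cc; n <- cache$n
      N <- hw * n
      sum_gy <- .bnSpatialSums(gy, hw, cc, n)
      sum_gyx <- .bnSpatialSums(gy * cache$xhat, hw, cc, n)
      grads[[li]] <- list(gamma = sum_gyx, beta = sum_gy)
      coef <- rep(L$gamma * cache$invstd / N, each = hw)
      gy <- coef * (N * gy - rep(sum_gy, each = hw) -
                      cache$xhat * rep(sum_gyx, each = hw))
    } else if (L$type == "bn" && L$kind == "dense") {
      n <- cache$n
      sum_gy <- colSums(gy)
      sum_gyx <- colSums(gy * cache$xhat)
      grads[[li]] <- list(gamma = sum_gyx, beta = sum_gy)
      coef <- rep(L$gamma * cache$invstd / n, each = n)
      gy <- coef * (n * gy - rep(sum_gy, each = n) -
                      cache$xhat * rep(sum_gyx, each = n))
    } else if (L$type == "relu") {
      gy <- gy * cache$mask
    } else if (L$type == "pool") {
      gy <- .maxpool2_backward(cache$idx, gy, as.integer(cache$xdim))
    } else if (L$type == "dropout") {
      if (!is.null(cache)) gy <- gy * cache$mask
    } else if (L$type == "flatten") {
      gy <- t(gy)
      dim(gy) <- cache$d
    } else if (L$type == "dense") {
      grads[[li]] <- list(W = crossprod(cache$x, gy), b = colSums(gy))
      gy <- tcrossprod(gy, L$W)
    }
  }
  grads
}

# update batch-norm running statistics from one training batch
.updateRunningStats <- function(layers, caches, momentum) {
  for (li in seq_along(layers)) {
    if (layers[[li]]$type == "bn") {
      cache <- caches[[li]]
      layers[[li]]$runMean <-
        momentum * layers[[li]]$runMean + (1 - momentum) * cache$mu
      layers[[li]]$runVar <-
        momentum * layers[[li]]$runVar + (1 - momentum) * cache$var
    }
  }
  layers
}

.adamInit <- function(layers) {
  lapply(layers, function(L) {
    nm <- intersect(names(L), c("W", "b", "gamma", "beta"))
    if (!length(nm)) return(NULL)
    st <- lapply(L[nm], function(p) list(m = p * 0, v = p * 0))
    st
  })
}

.adamStep <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[li]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      state[[li]][[nm]] <- st
      layers[[li]][[nm]] <- layers[[li]][[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}

# ---- input preparation ---------------------------------------------------

#' Convert radiographs to a CNN input array
#'
#' Scales intensities to \code{[0, 1]} by the declared bit depth and
#' resizes (bilinear) to the model input size. Accepts a single
#' [Radiograph-class], a list of them, or a numeric array already shaped
#' \code{(h, w, n)} / \code{(h, w, c, n)} in \code{[0, 1]}.
#'
#' @param x input image(s).
#' @param inputSize integer(2) target rows, cols.
#' @return numeric array \code{(rows, cols, 1, n)} in \code{[0, 1]}.
#' @export
cnnInputArray <- function(x, inputSize = c(256L, 256L)) {
  if (is(x, "Radiograph")) x <- list(x)
  if (is.list(x)) {
    n <- length(x)
    out <- array(0, c(inputSize[1], inputSize[2], 1L, n))
    for (i in seq_len(n)) {
      rg <- x[[i]]
      stopifnot(is(rg, "Radiograph"))
      sc <- rg@pixels / (2^rg@bitDepth - 1)
      out[, , 1L, i] <- .resize_bilinear(sc, inputSize[1], inputSize[2])
    }
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
  d <- dim(x)
  if (d[1] == inputSize[1] && d[2] == inputSize[2]) return(x)
  out <- array(0, c(inputSize[1], inputSize[2], d[3], d[4]))
  for (i in seq_len(d[4]))
    for (ch in seq_len(d[3]))
      out[, , ch, i] <- .resize_bilinear(x[, , ch, i],
                                         inputSize[1], inputSize[2])
  out
}

# ---- training ------------------------------------------------------------

#' Train the CNN age-regression model
#'
#' Splits the dataset into training and validation partitions (the split is
#' fixed for the whole run; each partition is reshuffled internally every
#' \code{reshufflePeriod} epochs), optimizes the mean-squared-error loss
#' with Adam, optionally augmenting every training batch, and keeps the
#' checkpoint with the lowest validation mean absolute error.
#'
#' @param model an [AgeCnnModel-class] (freshly built or pre-trained).
#' @param images input array accepted by [cnnInputArray()].
#' @param ages numeric vector of chronological ages (years), one per image.
#' @param plan a [TrainPlan-class].
#' @param augCfg an [AugmentationConfig-class], or \code{NULL} to train
#'   without augmentation.
#' @param verbose print per-epoch progress?
#' @return A list with elements \code{model} (best checkpoint,
#'   [AgeCnnModel-class]), \code{history} (per-epoch data.frame with
#'   columns epoch, loss, mae, val_loss, val_mae), and \code{bestEpoch}.
#' @export
trainAgeModel <- function(model, images, ages, plan = TrainPlan(),
                          augCfg = AugmentationConfig(), verbose = FALSE) {
  stopifnot(is(model, "AgeCnnModel"), is(plan, "TrainPlan"))
  cfg <- model@cfg
  x <- cnnInputArray(images, cfg@inputSize)
  n <- dim(x)[4]
  if (n == 0L || length(ages) != n)
    stop("need a non-empty dataset with one age per image")
  if (length(unique(ages)) < 2L)
    warning("all training ages are identical; fitting a constant")
  ages <- as.numeric(ages)

  set.seed(plan@seed)
  perm <- sample.int(n)
  nval <- max(1L, round(plan@valFraction * n))
  valIdx <- perm[seq_len(nval)]
  trainIdx <- perm[-seq_len(nval)]
  xval <- x[, , , valIdx, drop = FALSE]
  yval <- ages[valIdx]

  layers <- model@layers
  if (plan@initOutputBias)
    layers[[length(layers)]]$b <- mean(ages[trainIdx])
  state <- .adamInit(layers)
  t <- 0L
  best <- list(valMae = Inf, layers = layers, epoch = 0L)
  hist <- vector("list", plan@epochs)

  for (epoch in seq_len(plan@epochs)) {
    if ((epoch - 1L) %% plan@reshufflePeriod == 0L) {
      trainIdx <- trainIdx[sample.int(length(trainIdx))]
      valIdx <- valIdx[sample.int(length(valIdx))]
    }
    bstarts <- seq(1L, length(trainIdx), by = cfg@batchSize)
    eloss <- 0; emae <- 0; eseen <- 0
    for (bs in bstarts) {
      idx <- trainIdx[bs:min(bs + cfg@batchSize - 1L, length(trainIdx))]
      xb <- x[, , , idx, drop = FALSE]
      if (!is.null(augCfg))
        xb <- augmentBatch(xb, augCfg,
                           seed = .deriveSeed(plan@seed, epoch * 100003 + bs))
      yb <- ages[idx]
      fw <- .forwardCnn(layers, xb, cfg, train = TRUE)
      pred <- as.vector(fw$out)
      resid <- pred - yb
      m <- length(yb)
      eloss <- eloss + sum(resid^2); emae <- emae + sum(abs(resid))
      eseen <- eseen + m
      gy <- matrix(2 * resid / m, ncol = 1)
      grads <- .backwardCnn(layers, fw$caches, gy)
      layers <- .updateRunningStats(layers, fw$caches, cfg@bnMomentum)
      t <- t + 1L
      upd <- .adamStep(layers, grads, state, cfg@learningRate, t)
      layers <- upd$layers
      state <- upd$state
    }
    vp <- .predictArray(layers, xval, cfg)
    vloss <- mean((vp - yval)^2)
    vmae <- mean(abs(vp - yval))
    hist[[epoch]] <- data.frame(epoch = epoch, loss = eloss / eseen,
                                mae = emae / eseen, val_loss = vloss,
                                val_mae = vmae)
    if (vmae < best$valMae)
      best <- list(valMae = vmae, layers = layers, epoch = epoch)
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %8.2f  mae %6.2f  val_loss %8.2f  val_mae %6.2f",
        epoch, eloss / eseen, emae / eseen, vloss, vmae))
  }
  bestModel <- new("AgeCnnModel", cfg = cfg, layers = best$layers,
                   manifest = model@manifest, version = model@version)
  list(model = bestModel, history = do.call(rbind, hist),
       bestEpoch = best$epoch,
       split = list(train = sort(trainIdx), val = sort(valIdx)))
}

# inference forward pass in batches (running BN statistics, no dropout)
.predictArray <- function(layers, x, cfg, batchSize = 64L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (bs in seq(1L, n, by = batchSize)) {
    idx <- bs:min(bs + batchSize - 1L, n)
    fw <- .forwardCnn(layers, x[, , , idx, drop = FALSE], cfg,
                      train = FALSE)
    out[idx] <- as.vector(fw$out)
  }
  out
}

#' Predict age from radiographs
#'
#' Deterministic inference (dropout inactive, batch normalization using its
#' running statistics). Input images are intensity-scaled to \code{[0, 1]}
#' and resized to the model's input size.
#'
#' @param model a trained [AgeCnnModel-class].
#' @param x a [Radiograph-class], list of them, or image array accepted by
#'   [cnnInputArray()].
#' @return Numeric vector of estimated ages in years, with the model
#'   version in \code{attr(, "model_version")}.
#' @export
predictAge <- function(model, x) {
  stopifnot(is(model, "AgeCnnModel"))
  arr <- cnnInputArray(x, model@cfg@inputSize)
  est <- .predictArray(model@layers, arr, model@cfg)
  attr(est, "model_version") <- model@version
  est
}
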