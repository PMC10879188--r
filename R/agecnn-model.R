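#' CNN age-regression configuration
#'
#' Architecture and optimization hyperparameters of the dental-age
#' regression network. The default configuration is the full-size model:
#' 256 x 256 single-channel input; four blocks of three convolution +
#' batch-normalization pairs (3x3 kernels; 32, 64, 128, 256 filters) each
#' followed by 2x2 max pooling and dropout; a 1024-unit dense layer with
#' batch normalization and dropout; and a single linear output unit. Adam
#' with mean-squared-error loss, learning rate 1e-4, batch size 64,
#' dropout 0.25. ReLU activations follow every batch-normalization except
#' the linear output.
#'
#' @slot inputSize integer(2): input rows, cols; must be divisible by
#'   \code{2^length(blocks)}.
#' @slot channels input channels (1 for grayscale radiographs).
#' @slot blocks filter counts per convolutional block.
#' @slot convsPerBlock convolution+BN pairs per block (default 3).
#' @slot denseUnits width of the fully connected layer (default 1024).
#' @slot dropoutRate dropout probability (default 0.25).
#' @slot learningRate Adam learning rate (default 1e-4).
#' @slot batchSize minibatch size (default 64).
#' @slot bnMomentum momentum of the batch-norm running statistics
#'   (default 0.99).
#' @slot bnEpsilon batch-norm variance floor (default 1e-3).
#' @seealso [buildAgeModel()], [ageCnnTestProfile()]
#' @export
setClass("AgeCnnConfig",
  representation(
    inputSize = "integer", channels = "integer", blocks = "integer",
    convsPerBlock = "integer", denseUnits = "integer",
    dropoutRate = "numeric", learningRate = "numeric",
    batchSize = "integer", bnMomentum = "numeric", bnEpsilon = "numeric"
  ),
  prototype(
    inputSize = c(256L, 256L), channels = 1L,
    blocks = c(32L, 64L, 128L, 256L), convsPerBlock = 3L,
    denseUnits = 1024L, dropoutRate = 0.25, learningRate = 1e-4,
    batchSize = 64L, bnMomentum = 0.99, bnEpsilon = 1e-3
  )
)

setValidity("AgeCnnConfig", function(object) {
  msgs <- character(0)
  if (length(object@blocks) < 1) msgs <- c(msgs, "blocks must be non-empty")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msgs <- c(msgs, "dropoutRate must lie in [0, 1)")
  if (any(object@inputSize < 1) || object@denseUnits < 1 ||
      object@convsPerBlock < 1 || any(object@blocks < 1))
    msgs <- c(msgs, "all sizes must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AgeCnnConfig-class
#' @param inputSize,channels,blocks,convsPerBlock,denseUnits see slots.
#' @param dropoutRate,learningRate,batchSize,bnMomentum,bnEpsilon see slots.
#' @return An \code{AgeCnnConfig}.
#' @export
AgeCnnConfig <- function(inputSize = c(256L, 256L), channels = 1L,
                         blocks = c(32L, 64L, 128L, 256L),
                         convsPerBlock = 3L, denseUnits = 1024L,
                         dropoutRate = 0.25, learningRate = 1e-4,
                         batchSize = 64L, bnMomentum = 0.99,
                         bnEpsilon = 1e-3) {
  new("AgeCnnConfig", inputSize = as.integer(inputSize),
      channels = as.integer(channels), blocks = as.integer(blocks),
      convsPerBlock = as.integer(convsPerBlock),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      bnMomentum = bnMomentum, bnEpsilon = bnEpsilon)
}

#' Reduced configuration for desk-scale experiments
#'
#' A small profile of the same architecture family — 64 x 64 input, blocks
#' of 8/16/32/64 filters, a 64-unit dense layer, a larger learning rate and
#' faster-adapting batch-norm statistics — suited to training on synthetic
#' cohorts of a few hundred images in minutes on one CPU. The layer
#' structure (three conv+BN pairs per block, pooling, dropout, single
#' linear output) is unchanged.
#'
#' @return An [AgeCnnConfig-class].
#' @export
ageCnnTestProfile <- function() {
  AgeCnnConfig(inputSize = c(64L, 64L), blocks = c(8L, 16L, 32L, 64L),
               denseUnits = 64L, learningRate = 1e-3, batchSize = 16L,
               bnMomentum = 0.9)
}

#' Fitted/initialized CNN age-regression model
#'
#' Holds the layer sequence (weights included), the machine-readable layer
#' manifest, and the architecture configuration.
#'
#' @slot cfg the [AgeCnnConfig-class] used to build the model.
#' @slot layers list of layer objects in forward order.
#' @slot manifest data.frame describing every layer (type, output shape,
#'   trainable parameter count).
#' @slot version model version string.
#' @export
setClass("AgeCnnModel",
  representation(cfg = "AgeCnnConfig", layers = "list",
                 manifest = "data.frame", version = "character"))

setMethod("show", "AgeCnnModel", function(object) {
  cat(sprintf(
    "AgeCnnModel (%s): input %d x %d x %d, %d layers, %s trainable parameters\n",
    object@version, object@cfg@inputSize[1], object@cfg@inputSize[2],
    object@cfg@channels, nrow(object@manifest),
    format(parameterCount(object), big.mark = ",")))
})

# glorot-uniform initialisation
.glorot <- function(fanIn, fanOut, n) {
  lim <- sqrt(6 / (fanIn + fanOut))
  stats::runif(n, -lim, lim)
}

#' Build the CNN age-regression model
#'
#' Constructs the layer sequence: for each block, \code{convsPerBlock}
#' convolution (3x3, same padding) + batch-normalization + ReLU triplets,
#' then 2x2 max pooling and dropout; then flatten, dense, batch
#' normalization, ReLU, dropout, and a single-unit linear output. Weights
#' are glorot-uniform initialized from the given seed. A machine-readable
#' layer manifest with per-layer output shapes and trainable parameter
#' counts is attached.
#'
#' @param cfg an [AgeCnnConfig-class].
#' @param seed integer seed for weight initialization.
#' @return An [AgeCnnModel-class].
#' @examples
#' m <- buildAgeModel(ageCnnTestProfile(), seed = 1)
#' head(layerManifest(m))
#' @export
buildAgeModel <- function(cfg = AgeCnnConfig(), seed = 1L) {
  stopifnot(is(cfg, "AgeCnnConfig"))
  nb <- length(cfg@blocks)
  if (any(cfg@inputSize %% 2^nb != 0))
    stop("input size must be divisible by 2^", nb,
         " (one 2x2 pooling per block)")
  set.seed(seed)
  layers <- list()
  man <- list()
  h <- cfg@inputSize[1]; w <- cfg@inputSize[2]; cin <- cfg@channels
  addman <- function(type, shape, params, note = "") {
    man[[length(man) + 1]] <<- data.frame(
      index = length(man) + 1L, type = type, output_shape = shape,
      params = params, note = note, stringsAsFactors = FALSE)
  }
  for (b in seq_len(nb)) {
    f <- cfg@blocks[b]
    for (k in seq_len(cfg@convsPerBlock)) {
      W <- matrix(.glorot(9 * cin, 9 * f, 9 * cin * f), 9 * cin, f)
      layers[[length(layers) + 1]] <-
        list(type = "conv", W = W, b = numeric(f))
      addman("conv2d", sprintf("%d x %d x %d", h, w, f),
             9 * cin * f + f, sprintf("3x3, block %d", b))
      layers[[length(layers) + 1]] <-
        list(type = "bn", kind = "spatial", gamma = rep(1, f),
             beta = numeric(f), runMean = numeric(f), runVar = rep(1, f))
      addman("batch_norm", sprintf("%d x %d x %d", h, w, f), 2 * f)
      layers[[length(layers) + 1]] <- list(type = "relu")
      addman("relu", sprintf("%d x %d x %d", h, w, f), 0,
             "activation")
      cin <- f
    }
    h <- h %/% 2L; w <- w %/% 2L
    layers[[length(layers) + 1]] <- list(type = "pool")
    addman("max_pool", sprintf("%d x %d x %d", h, w, cin), 0, "2x2")
    layers[[length(layers) + 1]] <-
      list(type = "dropout", rate = cfg@dropoutRate)
    addman("dropout", sprintf("%d x %d x %d", h, w, cin), 0,
           sprintf("rate %.2f", cfg@dropoutRate))
  }
  flat <- h * w * cin
  layers[[length(layers) + 1]] <- list(type = "flatten")
  addman("flatten", sprintf("%d", flat), 0)
  W <- matrix(.glorot(flat, cfg@denseUnits, flat * cfg@denseUnits),
              flat, cfg@denseUnits)
  layers[[length(layers) + 1]] <-
    list(type = "dense", W = W, b = numeric(cfg@denseUnits))
  addman("dense", sprintf("%d", cfg@denseUnits),
         flat * cfg@denseUnits + cfg@denseUnits)
  layers[[length(layers) + 1]] <-
    list(type = "bn", kind = "dense", gamma = rep(1, cfg@denseUnits),
         beta = numeric(cfg@denseUnits), runMean = numeric(cfg@denseUnits),
         runVar = rep(1, cfg@denseUnits))
  addman("batch_norm", sprintf("%d", cfg@denseUnits), 2 * cfg@denseUnits)
  layers[[length(layers) + 1]] <- list(type = "relu")
  addman("relu", sprintf("%d", cfg@denseUnits), 0, "activation")
  layers[[length(layers) + 1]] <-
    list(type = "dropout", rate = cfg@dropoutRate)
  addman("dropout", sprintf("%d", cfg@denseUnits), 0,
         sprintf("rate %.2f", cfg@dropoutRate))
  W <- matrix(.glorot(cfg@denseUnits, 1L, cfg@denseUnits), cfg@denseUnits, 1)
  layers[[length(layers) + 1]] <- list(type = "dense", W = W, b = 0)
  addman("dense", "1", cfg@denseUnits + 1L, "linear output")
  new("AgeCnnModel", cfg = cfg, layers = layers,
      manifest = do.call(rbind, man), version = "odontoid-agecnn-1")
}

#' @describeIn buildAgeModel machine-readable layer manifest.
#' @param model an [AgeCnnModel-class].
#' @export
setMethod("layerManifest", "AgeCnnModel", function(model) model@manifest)

#' @describeIn buildAgeModel total count of trainable parameters
#'   (convolution and dense weights/biases plus batch-norm scale/offset;
#'   running statistics are not trainable).
#' @export
setMethod("parameterCount", "AgeCnnModel",
          function(model) sum(model@manifest$params))

#' Write the layer manifest as JSON
#'
#' Framework-independent description of the architecture, one record per
#' layer.
#'
#' @param model an [AgeCnnModel-class].
#' @param path optional output file.
#' @return JSON string (invisibly when \code{path} is given).
#' @export
manifestToJSON <- function(model, path = NULL) {
  stopifnot(is(model, "AgeCnnModel"))
  js <- jsonlite::toJSON(layerManifest(model), digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Save or load a model checkpoint
#'
#' Checkpoints store the configuration, all layer weights and running
#' statistics, and the manifest in a single file.
#'
#' @param model an [AgeCnnModel-class].
#' @param path checkpoint file path.
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the restored [AgeCnnModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "AgeCnnModel"))
  saveRDS(list(format = "odontoid-checkpoint-1",
               cfg = model@cfg, layers = model@layers,
               manifest = model@manifest, version = model@version), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable checkpoint: ", conditionMessage(e)))
  if (!identical(obj$format, "odontoid-checkpoint-1"))
    stop("not an age-model checkpoint: ", path)
  new("AgeCnnModel", cfg = obj$cfg, layers = obj$layers,
      manifest = obj$manifest, version = obj$version)
}
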