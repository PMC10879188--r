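#' Acquisition parameters for synthetic radiographs
#'
#' Concrete acquisition settings for one synthetic exposure: additive noise,
#' small rotation and shift (patient positioning), a gamma contrast change
#' (exposure variation), and optional occlusion rectangles emulating
#' postmortem-style artifacts. The renderer applies these after the
#' identity- and age-determined anatomy is drawn.
#'
#' @slot noiseSD additive Gaussian noise standard deviation, in 8-bit
#'   intensity units.
#' @slot rotationDeg in-plane rotation in degrees.
#' @slot shiftPx numeric(2): horizontal and vertical shift in pixels.
#' @slot contrastGamma gamma applied to normalized intensities.
#' @slot occlusionFraction approximate fraction of the image covered by
#'   dark occlusion rectangles, in \code{[0, 1]}.
#' @slot renderSize integer(2): rows, cols of the rendered image.
#' @slot bitDepth 8 or 16.
#' @slot spacingMM numeric(2): mm per pixel recorded in the output.
#' @export
setClass("AcquisitionParams",
  representation(noiseSD = "numeric", rotationDeg = "numeric",
                 shiftPx = "numeric", contrastGamma = "numeric",
                 occlusionFraction = "numeric", renderSize = "integer",
                 bitDepth = "integer", spacingMM = "numeric"),
  prototype(noiseSD = 2, rotationDeg = 0, shiftPx = c(0, 0),
            contrastGamma = 1, occlusionFraction = 0,
            renderSize = c(220L, 400L), bitDepth = 8L,
            spacingMM = c(0.5, 0.5)))

setValidity("AcquisitionParams", function(object) {
  msgs <- character(0)
  if (object@noiseSD < 0) msgs <- c(msgs, "noiseSD must be >= 0")
  if (object@occlusionFraction < 0 || object@occlusionFraction > 1)
    msgs <- c(msgs, "occlusionFraction must lie in [0, 1]")
  if (!object@bitDepth %in% c(8L, 16L))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (length(msgs)) msgs else TRUE
})

#' @rdname AcquisitionParams-class
#' @param noiseSD,rotationDeg,shiftPx,contrastGamma see slots.
#' @param occlusionFraction,renderSize,bitDepth,spacingMM see slots.
#' @return An \code{AcquisitionParams}.
#' @export
AcquisitionParams <- function(noiseSD = 2, rotationDeg = 0,
                              shiftPx = c(0, 0), contrastGamma = 1,
                              occlusionFraction = 0,
                              renderSize = c(220L, 400L), bitDepth = 8L,
                              spacingMM = c(0.5, 0.5)) {
  new("AcquisitionParams", noiseSD = noiseSD, rotationDeg = rotationDeg,
      shiftPx = as.numeric(shiftPx), contrastGamma = contrastGamma,
      occlusionFraction = occlusionFraction,
      renderSize = as.integer(renderSize), bitDepth = as.integer(bitDepth),
      spacingMM = as.numeric(spacingMM))
}

#' Generate a synthetic cohort
#'
#' Each individual carries an identifier, a chronological age drawn from
#' \code{ageDistribution} on the supported range 2-89 years, and a
#' structure seed that fixes the per-individual anatomy (dental-arch
#' geometry, tooth placement and widths, intra-tooth texture). Reproducible
#' under \code{masterSeed}.
#'
#' @param n number of individuals.
#' @param ageDistribution \code{"uniform"} (default: uniform on [2, 89]) or
#'   a function \code{f(n)} returning \code{n} ages within [2, 89].
#' @param masterSeed integer seed.
#' @return data.frame with columns \code{individual_id}, \code{age_years},
#'   \code{structure_seed}.
#' @examples
#' cohort <- makeCohort(5, masterSeed = 7)
#' cohort$age_years
#' @export
makeCohort <- function(n, ageDistribution = "uniform", masterSeed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(masterSeed)
  ages <- if (is.function(ageDistribution)) ageDistribution(n)
          else if (identical(ageDistribution, "uniform"))
            stats::runif(n, 2, 89)
          else stop("unknown age distribution")
  if (any(ages < 2 - 1e-9) || any(ages > 89 + 1e-9))
    stop("ages must lie within [2, 89]")
  data.frame(
    individual_id = sprintf("IND%05d", seq_len(n)),
    age_years = as.numeric(ages),
    structure_seed = .deriveSeed(masterSeed, seq_len(n) * 131),
    stringsAsFactors = FALSE)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Identity- and age-determined render geometry of a synthetic individual
#'
#' Deterministically derives, from the individual's structure seed and age,
#' the generative parameters the renderer draws: dental-arch curve, the
#' per-tooth slots present at that age (tooth count ramps from the
#' deciduous 20 to the full 32 over ages 2-21, an eruption analogue), crown
#' heights (shrinking linearly through adulthood), pulp-core brightness
#' (fading with adult age), and per-tooth identity texture spots.
#'
#' @param individual one-row data.frame or list with
#'   \code{individual_id}, \code{age_years}, \code{structure_seed}.
#' @param renderSize integer(2) rows, cols the geometry is laid out for.
#' @return A list with elements \code{teeth} (data.frame: row, slot, x, y,
#'   width, crownHeight, brightness, pulpAmp), \code{arch} (curve
#'   parameters), and \code{textureSeed}.
#' @export
toothGeometry <- function(individual, renderSize = c(220L, 400L)) {
  age <- as.numeric(individual$age_years)
  R <- renderSize[1]; C <- renderSize[2]
  set.seed(as.integer(individual$structure_seed))
  archCurv <- stats::runif(1, 0.0009, 0.0016)
  archSep <- stats::runif(1, 36, 46)
  rowY <- 0.5 * R + stats::runif(1, -8, 8)
  span <- stats::runif(1, 0.62, 0.72) * C
  nslots <- 16L
  # per-slot identity parameters (drawn for all slots so geometry is stable
  # across ages; eruption only selects which slots are rendered)
  slotJitter <- stats::rnorm(2 * nslots, 0, 2.6)
  widths <- stats::runif(2 * nslots, 6.5, 9.5)
  hscale <- stats::runif(2 * nslots, 0.9, 1.1)
  bright <- stats::runif(2 * nslots, 175, 215)
  texU <- stats::runif(4 * nslots, -0.35, 0.35)
  texV <- stats::runif(4 * nslots, -0.45, 0.45)
  texA <- stats::runif(4 * nslots, 35, 80) *
    sample(c(-1, 1), 4 * nslots, replace = TRUE)
  texR <- stats::runif(4 * nslots, 1.3, 2.4)
  textureSeed <- .deriveSeed(individual$structure_seed, 977)

  eruption <- .clamp01((age - 2) / 19)          # 2 -> 21 years
  adult <- .clamp01((age - 21) / 68)            # 21 -> 89 years
  perRow <- as.integer(round(10 + 6 * eruption))
  crownBase <- 17 * (1 - 0.30 * adult)
  pulpAmp <- 55 * (1 - 0.60 * adult)

  cx <- (C - 1) / 2
  teeth <- list()
  for (row in 1:2) {                            # 1 = upper, 2 = lower
    keep <- seq_len(nslots)
    # symmetric eruption: the outermost slots appear last
    drop <- nslots - perRow
    if (drop > 0) {
      outer_first <- order(abs(keep - (nslots + 1) / 2), decreasing = TRUE)
      keep <- sort(setdiff(keep, outer_first[seq_len(drop)]))
    }
    for (s in keep) {
      gi <- (row - 1L) * nslots + s
      x <- cx + span * ((s - 1) / (nslots - 1) - 0.5) + slotJitter[gi]
      curve <- archCurv * (x - cx)^2
      y <- if (row == 1) rowY - archSep / 2 - curve
           else rowY + archSep / 2 - curve + archSep * 0.1
      teeth[[length(teeth) + 1]] <- data.frame(
        row = row, slot = s, x = x, y = y, width = widths[gi],
        crownHeight = crownBase * hscale[gi], brightness = bright[gi],
        pulpAmp = pulpAmp,
        texU = I(list(texU[c(2 * gi - 1, 2 * gi)])),
        texV = I(list(texV[c(2 * gi - 1, 2 * gi)])),
        texA = I(list(texA[c(2 * gi - 1, 2 * gi)])),
        texR = I(list(texR[c(2 * gi - 1, 2 * gi)])))
    }
  }
  list(teeth = do.call(rbind, teeth),
       arch = list(curv = archCurv, sep = archSep, rowY = rowY,
                   span = span, cx = cx),
       textureSeed = textureSeed,
       age = age, eruption = eruption, adult = adult)
}

# draw the noise-free anatomy (float matrix, 0-255 scale)
.renderIdeal <- function(geom, renderSize) {
  R <- renderSize[1]; C <- renderSize[2]
  img <- matrix(22, R, C)
  arch <- geom$arch
  # jaw-bone glow along both tooth rows
  xs <- seq_len(C) - 1
  curve <- arch$curv * (xs - arch$cx)^2
  for (rowSign in c(-1, 1)) {
    yc <- arch$rowY + rowSign * arch$sep / 2 - curve
    for (j in seq_len(C)) {
      dy <- (seq_len(R) - 1) - yc[j]
      img[, j] <- img[, j] + 30 * exp(-(dy / 26)^2)
    }
  }
  # mandible border: bright curved line near the lower jaw
  yb <- arch$rowY + arch$sep * 1.9 - 0.6 * curve
  for (j in seq_len(C)) {
    dy <- (seq_len(R) - 1) - yb[j]
    img[, j] <- img[, j] + 55 * exp(-(dy / 2.5)^2)
  }
  # age-coarsened trabecular texture (identity-stable)
  set.seed(geom$textureSeed)
  tex <- matrix(stats::rnorm(R * C), R, C)
  tex <- .box_mean_replicate(tex, 2L + as.integer(round(3 * geom$adult)))
  img <- img + 9 * tex / stats::sd(tex)
  # teeth
  th <- geom$teeth
  for (i in seq_len(nrow(th))) {
    t <- th[i, ]
    hw <- ceiling(t$width * 2.2)
    hh <- ceiling(t$crownHeight * 1.6)
    jr <- max(1, round(t$y) - hh + 1):min(R, round(t$y) + hh + 1)
    jc <- max(1, round(t$x) - hw + 1):min(C, round(t$x) + hw + 1)
    dx <- outer(rep(1, length(jr)), (jc - 1) - t$x)
    dy <- outer((jr - 1) - t$y, rep(1, length(jc)))
    # flat-topped crown blob
    crown <- t$brightness *
      exp(-((dx / t$width)^2 + (dy / t$crownHeight)^2)^2)
    # pulp core: brighter, narrower, fades with adult age
    pulp <- t$pulpAmp *
      exp(-((dx / (0.35 * t$width))^2 + (dy / (0.45 * t$crownHeight))^2))
    patch <- crown + pulp
    # identity texture spots inside the crown
    for (q in 1:2) {
      u <- t$texU[[1]][q] * t$width * 2
      v <- t$texV[[1]][q] * t$crownHeight * 1.4
      patch <- patch + t$texA[[1]][q] *
        exp(-(((dx - u)^2 + (dy - v)^2) / t$texR[[1]][q]^2))
    }
    img[jr, jc] <- pmax(img[jr, jc], pmin(pmax(patch, 0), 245))
  }
  img
}

#' Render a synthetic panoramic radiograph
#'
#' Draws the individual's identity-stable anatomy (dental arch, per-tooth
#' blobs with pulp cores and texture spots, mandible border, trabecular
#' background) at the individual's age, then applies the acquisition
#' transform: rotation/shift, gamma, additive noise, occlusion rectangles,
#' and quantization to the requested bit depth. Deterministic under
#' \code{(structure_seed, acqSeed)}.
#'
#' The generator is deliberately not anatomically realistic; it reproduces
#' the statistical structure the identification pipeline relies on —
#' keypoints that are stable within an individual and distinct between
#' individuals, plus age-monotone global features.
#'
#' @param individual one-row data.frame or list from [makeCohort()].
#' @param acq an [AcquisitionParams-class].
#' @param acqSeed integer seed for the acquisition randomness (noise,
#'   occlusion placement).
#' @return A [Radiograph-class] carrying the individual id, age and pixel
#'   spacing.
#' @examples
#' co <- makeCohort(1, masterSeed = 3)
#' rg <- renderOpg(co[1, ], AcquisitionParams(), acqSeed = 11)
#' @export
renderOpg <- function(individual, acq = AcquisitionParams(), acqSeed = 1L) {
  stopifnot(is(acq, "AcquisitionParams"))
  geom <- toothGeometry(individual, acq@renderSize)
  img <- .renderIdeal(geom, acq@renderSize)
  R <- acq@renderSize[1]; C <- acq@renderSize[2]
  if (acq@rotationDeg != 0 || any(acq@shiftPx != 0)) {
    A <- .augAffine(R, C, acq@rotationDeg * pi / 180,
                    acq@shiftPx[1], acq@shiftPx[2], 1, 1, FALSE)
    img <- .affine_sample(img, R, C, A, 1L)
  }
  if (acq@contrastGamma != 1)
    img <- 255 * .clamp01(img / 255)^acq@contrastGamma
  set.seed(acqSeed)
  if (acq@noiseSD > 0)
    img <- img + stats::rnorm(length(img), 0, acq@noiseSD)
  if (acq@occlusionFraction > 0) {
    total <- R * C
    covered <- 0
    tries <- 0L
    while (covered < acq@occlusionFraction * total && tries < 20L) {
      tries <- tries + 1L
      rh <- max(2L, round(stats::runif(1, 0.05, 0.15) * R))
      rw <- max(2L, round(stats::runif(1, 0.05, 0.15) * C))
      r0 <- sample.int(R - rh + 1L, 1L)
      c0 <- sample.int(C - rw + 1L, 1L)
      img[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)] <- 4
      covered <- covered + rh * rw
    }
  }
  img <- pmin(pmax(img, 0), 255)
  if (acq@bitDepth == 16L) img <- img * 257
  px <- .roundHalfUp(img)
  Radiograph(px, bitDepth = acq@bitDepth, spacingMM = acq@spacingMM,
             individualId = individual$individual_id,
             ageYears = individual$age_years)
}

#' Default acquisition jitter ranges for fixtures
#'
#' The range set used by [makeFixtureDb()] to draw per-exposure acquisition
#' parameters: positioning rotation within ±0.7 degrees, shifts within
#' ±2.5 px per axis, gamma in [0.95, 1.05], noise SD 2, and postmortem-style
#' occlusion (fraction 0.05) on query images only.
#'
#' @return A named list of ranges.
#' @export
defaultAcquisitionRanges <- function() {
  list(noiseSD = 2, rotationDegMax = 0.7, shiftPxMax = 2.5,
       gammaRange = c(0.95, 1.05), queryOcclusion = 0.05)
}

.drawAcq <- function(ranges, occlusion = 0) {
  AcquisitionParams(
    noiseSD = ranges$noiseSD,
    rotationDeg = stats::runif(1, -ranges$rotationDegMax,
                               ranges$rotationDegMax),
    shiftPx = stats::runif(2, -ranges$shiftPxMax, ranges$shiftPxMax),
    contrastGamma = stats::runif(1, ranges$gammaRange[1],
                                 ranges$gammaRange[2]),
    occlusionFraction = occlusion)
}

#' Render one exposure per cohort member with drawn acquisition jitter
#'
#' Renders a single radiograph for every individual in the cohort, drawing
#' the acquisition parameters from \code{acqRanges}. Occlusion fractions
#' are drawn uniformly in \code{[0, acqRanges$queryOcclusion]}, so a cohort
#' rendered this way spans the full acquisition distribution — including
#' postmortem-style degradation — and is suitable for training the age
#' model that will later face degraded query images. (The reference
#' workflow deliberately trains on diverse, unfiltered images for the same
#' reason.)
#'
#' @param cohort data.frame from [makeCohort()].
#' @param seed integer master seed.
#' @param acqRanges acquisition jitter ranges
#'   (see [defaultAcquisitionRanges()]).
#' @return list of [Radiograph-class], one per cohort row.
#' @export
renderCohortImages <- function(cohort, seed = 1L,
                               acqRanges = defaultAcquisitionRanges()) {
  imgs <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    s <- .deriveSeed(seed, i * 1000 + 1)
    set.seed(s)
    occ <- stats::runif(1, 0, acqRanges$queryOcclusion)
    acq <- .drawAcq(acqRanges, occlusion = occ)
    imgs[[i]] <- renderOpg(cohort[i, ], acq, acqSeed = .deriveSeed(s, 1))
  }
  imgs
}

#' Build a synthetic fixture database with held-out queries
#'
#' Renders \code{imagesPerIndividual} exposures per cohort member with
#' randomly drawn acquisition jitter, enrolls the preprocessed and
#' feature-extracted first \code{imagesPerIndividual - 1} exposures in a
#' [FeatureDatabase-class] under the individual's true age, and returns the
#' final exposure of each individual as a held-out query together with the
#' ground-truth identity map.
#'
#' @param cohort data.frame from [makeCohort()].
#' @param imagesPerIndividual at least 2 (>= 1 enrolled + 1 query).
#' @param acqRanges acquisition jitter ranges
#'   (see [defaultAcquisitionRanges()]).
#' @param seed integer master seed.
#' @param preCfg a [PreprocessConfig-class].
#' @param featCfg a [FeatureConfig-class].
#' @return A list with elements \code{db} ([FeatureDatabase-class]),
#'   \code{queries} (named list of [Radiograph-class]; names are query
#'   ids), \code{truth} (named character: query id -> individual id), and
#'   \code{queryAges} (named numeric).
#' @export
makeFixtureDb <- function(cohort, imagesPerIndividual = 2L,
                          acqRanges = defaultAcquisitionRanges(),
                          seed = 1L, preCfg = PreprocessConfig(),
                          featCfg = FeatureConfig()) {
  if (imagesPerIndividual < 2L)
    stop("imagesPerIndividual must be >= 2 (enrolled + held-out query)")
  db <- FeatureDatabase()
  queries <- list()
  truth <- character(0)
  queryAges <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    ind <- cohort[i, ]
    for (k in seq_len(imagesPerIndividual)) {
      isQuery <- k == imagesPerIndividual
      s <- .deriveSeed(seed, i * 1000 + k)
      set.seed(s)
      acq <- .drawAcq(acqRanges,
                      occlusion = if (isQuery) acqRanges$queryOcclusion else 0)
      rg <- renderOpg(ind, acq, acqSeed = .deriveSeed(s, 1))
      if (isQuery) {
        qid <- paste0("Q_", ind$individual_id)
        queries[[qid]] <- rg
        truth[qid] <- ind$individual_id
        queryAges[qid] <- ind$age_years
      } else {
        feats <- extractFeatures(preprocessRadiograph(rg, preCfg), featCfg)
        addEntry(db, ind$individual_id, ind$age_years, feats,
                 sourceTag = "synthetic")
      }
    }
  }
  list(db = db, queries = queries, truth = truth, queryAges = queryAges)
}
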