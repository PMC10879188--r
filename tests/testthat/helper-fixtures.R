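# Shared fixtures, memoized across test files within one run. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a random KeypointSet with i.i.d. uniform descriptors at random positions
randomKeypointSet <- function(n, seed, shape = c(100L, 150L), dlen = 64L) {
  set.seed(seed)
  kp <- data.frame(x = runif(n, 0, shape[2] - 1),
                   y = runif(n, 0, shape[1] - 1),
                   scale = runif(n, 1.5, 6), response = runif(n))
  KeypointSet(kp, matrix(runif(n * dlen), n, dlen), shape)
}

emptyKeypointSet <- function(shape = c(100L, 150L), dlen = 64L) {
  KeypointSet(data.frame(x = numeric(0), y = numeric(0),
                         scale = numeric(0), response = numeric(0)),
              matrix(numeric(0), 0, dlen), shape)
}

# features of two independent renders (same vs different individual)
renderedFeaturePair <- function() {
  memoFixture("featPair", function() {
    co <- makeCohort(2, masterSeed = 303)
    ex <- function(ind, acqSeed, rot = 0.4, shift = c(1.5, -1)) {
      acq <- AcquisitionParams(rotationDeg = rot, shiftPx = shift,
                               contrastGamma = 1.03)
      extractFeatures(preprocessRadiograph(renderOpg(ind, acq, acqSeed)))
    }
    list(a1 = ex(co[1, ], 11, rot = 0),
         a2 = ex(co[1, ], 12),
         b1 = ex(co[2, ], 13, rot = -0.3, shift = c(-2, 0.5)))
  })
}

# small identification fixture: 12 individuals, 1 enrolled + 1 query each
smallFixture <- function() {
  memoFixture("smallFixture", function() {
    cohort <- makeCohort(12, masterSeed = 505)
    makeFixtureDb(cohort, imagesPerIndividual = 2L, seed = 505)
  })
}

# 200-entry age-spread database with held-out queries (acceptance scale);
# capped keypoint budget keeps the exhaustive-search oracle tractable
bigFixtureFeatCfg <- function() FeatureConfig(maxKeypoints = 200L)

bigFixture <- function() {
  memoFixture("bigFixture", function() {
    cohort <- makeCohort(200, masterSeed = 808)
    fx <- makeFixtureDb(cohort, imagesPerIndividual = 2L, seed = 808,
                        featCfg = bigFixtureFeatCfg())
    qids <- names(fx$queries)[1:50]
    fx$queryFeatures <- lapply(fx$queries[qids], function(rg)
      extractFeatures(preprocessRadiograph(rg), bigFixtureFeatCfg()))
    fx$qids <- qids
    fx
  })
}

# test-profile CNN trained once on a synthetic age cohort; shared by the
# parameter-recovery and end-to-end gating checks
ageCohortImages <- function(n, masterSeed) {
  cohort <- makeCohort(n, masterSeed = masterSeed)
  list(cohort = cohort,
       images = renderCohortImages(cohort, seed = masterSeed))
}

trainedAgeModel <- function() {
  memoFixture("trainedAgeModel", function() {
    cfg <- ageCnnTestProfile()
    train <- ageCohortImages(600, masterSeed = 2024)
    held <- ageCohortImages(120, masterSeed = 4048)
    model <- buildAgeModel(cfg, seed = 77)
    res <- trainAgeModel(model, train$images, train$cohort$age_years,
                         TrainPlan(epochs = 30L, seed = 77))
    heldPred <- as.numeric(predictAge(res$model, held$images))
    list(model = res$model, history = res$history, res = res,
         trainAges = train$cohort$age_years,
         heldAges = held$cohort$age_years, heldPred = heldPred)
  })
}

# fixed-radius gated search over precomputed features (test shorthand)
.gatedSearchForTest <- function(qf, est, db, radius, seed) {
  pol <- SearchPolicy(mode = "fixed", radiusYears = radius)
  OdontoID:::.gatedSearch(qf, est, db, radius, pol, MatchConfig(), seed)
}

# independent closed-form parameter count: conv k^2*cin*f + f, BN 2f
# (trainable scale/offset only), dense in*out + out
closedFormParams <- function(inputSize, channels, blocks, convsPerBlock,
                             denseUnits) {
  total <- 0
  cin <- channels
  for (f in blocks) {
    for (k in seq_len(convsPerBlock)) {
      total <- total + 9 * cin * f + f + 2 * f
      cin <- f
    }
  }
  flat <- prod(inputSize %/% 2^length(blocks)) * cin
  total + flat * denseUnits + denseUnits + 2 * denseUnits +
    denseUnits * 1 + 1
}

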