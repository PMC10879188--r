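test_that("layer manifest matches the architecture contract", {
  m <- buildAgeModel(AgeCnnConfig(), seed = 1)
  man <- layerManifest(m)
  convs <- man[man$type == "conv2d", ]
  expect_equal(nrow(convs), 12L)
  expect_true(all(grepl("x 32$", convs$output_shape[1:3])))
  expect_true(all(grepl("x 256$", convs$output_shape[10:12])))
  # every conv is paired with a batch norm
  expect_equal(sum(man$type == "batch_norm"), 13L)  # 12 conv + 1 dense
  expect_equal(sum(man$type == "max_pool"), 4L)
  # last layer is the single linear output
  expect_equal(man$output_shape[nrow(man)], "1")
  expect_equal(man$note[nrow(man)], "linear output")

  expect_error(buildAgeModel(AgeCnnConfig(inputSize = c(100L, 100L))),
               "divisible")
})

test_that("a single scalar is emitted per input image", {
  cfg <- AgeCnnConfig(inputSize = c(16L, 16L), blocks = c(4L, 8L),
                      convsPerBlock = 1L, denseUnits = 8L)
  m <- buildAgeModel(cfg, seed = 2)
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  out <- predictAge(m, x)
  expect_length(out, 3L)
  expect_true(all(is.finite(out)))
})

test_that("trainable parameter counts equal the closed-form summation", {
  # reference configuration
  m <- buildAgeModel(AgeCnnConfig(), seed = 1)
  expect_equal(parameterCount(m),
               closedFormParams(c(256L, 256L), 1L, c(32L, 64L, 128L, 256L),
                                3L, 1024L))
  # five random configurations
  set.seed(99)
  for (i in 1:5) {
    nb <- sample(1:3, 1)
    blocks <- sample(c(2L, 4L, 8L, 16L), nb, replace = TRUE)
    cpb <- sample(1:3, 1)
    du <- sample(c(8L, 16L, 32L), 1)
    side <- 8L * 2L^nb
    cfg <- AgeCnnConfig(inputSize = c(side, side), blocks = blocks,
                        convsPerBlock = cpb, denseUnits = du)
    mm <- buildAgeModel(cfg, seed = i)
    expect_equal(parameterCount(mm),
                 closedFormParams(c(side, side), 1L, blocks, cpb, du))
  }
})

test_that("augmentation respects its bounds and its seed", {
  set.seed(3)
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  idcfg <- AugmentationConfig(rotationDegMax = 0, widthShiftFrac = 0,
                              heightShiftFrac = 0, zoomFrac = 0,
                              horizontalFlip = FALSE)
  expect_equal(augmentBatch(x, idcfg, seed = 1), x, tolerance = 1e-12)

  acfg <- AugmentationConfig()
  a1 <- augmentBatch(x, acfg, seed = 7)
  a2 <- augmentBatch(x, acfg, seed = 7)
  expect_identical(a1, a2)
  expect_false(identical(a1, augmentBatch(x, acfg, seed = 8)))

  # zoom-only: the area of a centered bright square stays within the
  # [0.8, 1.2]^2 scale bounds (nearest-edge fill keeps the border dark)
  sq <- array(0, c(64, 64, 1, 1)); sq[25:40, 25:40, 1, 1] <- 1
  zcfg <- AugmentationConfig(rotationDegMax = 0, widthShiftFrac = 0,
                             heightShiftFrac = 0, zoomFrac = 0.2,
                             horizontalFlip = FALSE)
  for (s in 1:40) {
    az <- augmentBatch(sq, zcfg, seed = s)
    ratio <- sum(az > 0.5) / sum(sq > 0.5)
    expect_gte(ratio, 0.8^2 * 0.9)   # discretization slack
    expect_lte(ratio, 1.2^2 * 1.1)
  }
})

test_that("training learns a constant target and splits 80/20", {
  cfg <- AgeCnnConfig(inputSize = c(8L, 8L), blocks = c(4L),
                      convsPerBlock = 1L, denseUnits = 8L,
                      dropoutRate = 0, learningRate = 1e-2,
                      batchSize = 5L, bnMomentum = 0.8)
  set.seed(10)
  img <- array(rep(runif(64), 20), c(8, 8, 1, 20))
  ages <- rep(40, 20)
  m <- buildAgeModel(cfg, seed = 4)
  res <- suppressWarnings(
    trainAgeModel(m, img, ages, TrainPlan(epochs = 5L, seed = 4),
                  augCfg = NULL))
  expect_lt(utils::tail(res$history$mae, 1), 1)

  # split sizes: 80/20
  expect_equal(length(res$split$val), 4L)
  expect_equal(length(res$split$train), 16L)

  # checkpoint selection = argmin validation MAE
  expect_equal(res$bestEpoch, which.min(res$history$val_mae))

  expect_error(trainAgeModel(m, img[, , , 0, drop = FALSE], numeric(0)),
               "non-empty")
})

test_that("inference is deterministic and honours a forced output bias", {
  cfg <- AgeCnnConfig(inputSize = c(16L, 16L), blocks = c(4L),
                      convsPerBlock = 1L, denseUnits = 8L)
  m <- buildAgeModel(cfg, seed = 6)
  set.seed(6)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  p1 <- predictAge(m, x)
  p2 <- predictAge(m, x)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_equal(attr(p1, "model_version"), m@version)

  # zero final dense weights, bias beta -> every estimate equals beta
  m2 <- m
  last <- length(m2@layers)
  m2@layers[[last]]$W[] <- 0
  m2@layers[[last]]$b <- 12.5
  expect_equal(as.numeric(predictAge(m2, x)), c(12.5, 12.5))
})

test_that("checkpoints round-trip through disk", {
  cfg <- AgeCnnConfig(inputSize = c(16L, 16L), blocks = c(4L),
                      convsPerBlock = 1L, denseUnits = 8L)
  m <- buildAgeModel(cfg, seed = 8)
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  set.seed(1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  expect_identical(as.numeric(predictAge(m, x)),
                   as.numeric(predictAge(m2, x)))
  # integrity: arbitrary files are rejected
  bad <- tempfile(); saveRDS(list(a = 1), bad)
  expect_error(loadCheckpoint(bad), "checkpoint")
  unlink(c(path, bad))
})
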