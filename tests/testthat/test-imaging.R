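test_that("depth normalization rescales the declared full range", {
  rg16 <- Radiograph(matrix(65535, 5, 5), bitDepth = 16)
  expect_true(all(pixelData(normalizeDepth(rg16, 8)) == 255))
  expect_equal(bitDepth(normalizeDepth(rg16, 8)), 8L)

  rg8 <- Radiograph(matrix(37, 5, 5), bitDepth = 8)
  expect_identical(pixelData(normalizeDepth(rg8, 8)), pixelData(rg8))

  # scalar oracle: round(2048 * 255 / 4095) = 128
  rg12 <- Radiograph(matrix(2048, 4, 4), bitDepth = 12)
  expect_true(all(pixelData(normalizeDepth(rg12, 8)) ==
                    round(2048 * 255 / 4095)))

  expect_error(normalizeDepth(rg8, 12), "exceeds")

  # idempotence and output range
  set.seed(1)
  rg <- Radiograph(matrix(sample(0:1023, 60, TRUE), 6, 10), bitDepth = 10)
  once <- normalizeDepth(rg, 8)
  expect_identical(pixelData(normalizeDepth(once, 8)), pixelData(once))
  expect_true(all(pixelData(once) >= 0 & pixelData(once) <= 255))

  # metadata preserved
  rgm <- Radiograph(matrix(100, 5, 5), bitDepth = 12, spacingMM = 0.25,
                    individualId = "A", ageYears = 31)
  out <- normalizeDepth(rgm, 8)
  expect_equal(individualId(out), "A")
  expect_equal(ageYears(out), 31)
  expect_equal(spacingMM(out), c(0.25, 0.25))
})

test_that("margin crop honours physical spacing and the fallback path", {
  cfg <- PreprocessConfig()
  # exactly 180 x 100 mm: nothing to remove
  rg <- Radiograph(matrix(0, 200, 360), bitDepth = 8, spacingMM = 0.5)
  expect_identical(dim(pixelData(cropMargins(rg, cfg))), c(200L, 360L))

  # 200 x 120 mm at 0.5 mm/px: 10 mm (20 px) off each side, top and bottom
  rg2 <- Radiograph(matrix(seq_len(240 * 400) %% 60000, 240, 400), bitDepth = 16,
                    spacingMM = 0.5)
  out <- cropMargins(rg2, cfg)
  expect_identical(dim(pixelData(out)), c(200L, 360L))
  expect_identical(pixelData(out), pixelData(rg2)[21:220, 21:380])

  # no spacing + zero fallback fraction: unchanged
  rg3 <- Radiograph(matrix(0, 50, 70), bitDepth = 8)
  cfg0 <- PreprocessConfig(fallbackCropFraction = c(0, 0))
  expect_identical(dim(pixelData(cropMargins(rg3, cfg0))), c(50L, 70L))

  # default fallback removes 5% per side
  out3 <- cropMargins(rg3, cfg)
  expect_identical(dim(pixelData(out3)),
                   as.integer(c(50 - 2 * floor(50 * 0.05), 70 - 2 * floor(70 * 0.05))))

  # physically too small
  rg4 <- Radiograph(matrix(0, 100, 100), bitDepth = 8, spacingMM = 0.5)
  expect_error(cropMargins(rg4, cfg), "smaller")
})

test_that("compass Sobel kernels are the rotated standard family", {
  expect_identical(compassSobelKernel(0),
                   matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  expect_identical(compassSobelKernel(45),
                   matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3))
  # 90-degree kernel = transpose-flip of the 0-degree one
  expect_identical(compassSobelKernel(90),
                   matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))
  # the family is closed: rotating any member 360 degrees returns it
  expect_identical(compassSobelKernel(315 + 45), compassSobelKernel(0))
  expect_error(compassSobelKernel(30), "multiple of 45")
})

test_that("edge enhancement: zero on constants, step oracle, equivariance", {
  cfg <- PreprocessConfig()
  const <- Radiograph(matrix(180, 20, 30), bitDepth = 8)
  expect_true(all(pixelData(enhanceEdges(const, cfg)) == 0))

  # unit vertical step: interior edge columns respond 4 under the
  # 0-degree kernel, which attains the max; value = round(1.8 * 4) = 7
  step <- matrix(0, 20, 30); step[, 16:30] <- 1
  out <- pixelData(enhanceEdges(Radiograph(step, bitDepth = 8), cfg))
  expect_true(all(out[5:15, 15] == round(cfg@edgeGain * 4)))
  expect_true(all(out[5:15, 16] == round(cfg@edgeGain * 4)))
  expect_true(all(out[, 1:13] == 0))

  # invariance to constant offsets
  set.seed(4)
  base <- matrix(sample(0:200, 400, TRUE), 20, 20)
  a <- pixelData(enhanceEdges(Radiograph(base, bitDepth = 8), cfg))
  b <- pixelData(enhanceEdges(Radiograph(base + 30, bitDepth = 8), cfg))
  expect_identical(a, b)

  # 90-degree rotation equivariance of the compass stage
  rot90 <- function(m) t(apply(m, 2, rev))
  r1 <- pixelData(enhanceEdges(Radiograph(rot90(base), bitDepth = 8), cfg))
  expect_identical(r1, rot90(a))

  expect_error(enhanceEdges(Radiograph(matrix(0, 5, 5), bitDepth = 12), cfg),
               "8-bit")
})

test_that("averaging filter: impulse response, anchoring, linearity", {
  cfg <- PreprocessConfig()
  const <- Radiograph(matrix(42, 15, 15), bitDepth = 8)
  expect_true(all(pixelData(smoothImage(const, cfg)) == 42))

  # impulse of 36 spreads to value 1 over the 6x6 support; with the window
  # anchored at the top-left of its center 2x2 block, an impulse at (8, 8)
  # lights rows/cols 5..10
  imp <- matrix(0, 15, 15); imp[8, 8] <- 36
  out <- pixelData(smoothImage(Radiograph(imp, bitDepth = 8), cfg))
  expect_equal(sum(out), 36)
  expect_true(all(out[5:10, 5:10] == 1))
  expect_true(all(out[-(5:10), ] == 0) && all(out[, -(5:10)] == 0))

  # linearity before rounding
  set.seed(5)
  a <- matrix(sample(0:100, 144, TRUE), 12, 12)
  b <- matrix(sample(0:100, 144, TRUE), 12, 12)
  sa <- OdontoID:::.box_mean_replicate(a, 6L)
  sb <- OdontoID:::.box_mean_replicate(b, 6L)
  sab <- OdontoID:::.box_mean_replicate(a + b, 6L)
  expect_equal(sa + sb, sab, tolerance = 1e-12)
})

test_that("full preprocessing is deterministic and logs its parameters", {
  co <- makeCohort(1, masterSeed = 99)
  rg <- renderOpg(co[1, ], AcquisitionParams(bitDepth = 16L), acqSeed = 2)
  p1 <- preprocessRadiograph(rg)
  p2 <- preprocessRadiograph(rg)
  expect_identical(pixelData(p1), pixelData(p2))
  expect_equal(bitDepth(p1), 8L)

  # constant 16-bit image -> constant zero edge image
  flat <- Radiograph(matrix(30000, 60, 80), bitDepth = 16, spacingMM = 4)
  expect_true(all(pixelData(preprocessRadiograph(flat)) == 0))

  # stage parameters recorded in the processing log
  log <- processingLog(p1)
  stages <- vapply(log, `[[`, "", "stage")
  expect_identical(stages, c("normalize_depth", "crop_margins",
                             "edge_enhance", "smooth"))
  expect_equal(log[[3]]$params$edge_gain, 1.8)
  expect_equal(log[[4]]$params$mean_filter_size, 6L)
  expect_equal(log[[2]]$params$crop_mm, c(180, 100))
})
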