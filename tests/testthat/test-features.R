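test_that("structureless images yield an empty KeypointSet with a warning", {
  flat <- Radiograph(matrix(0, 64, 96), bitDepth = 8)
  expect_warning(ks <- extractFeatures(flat), "no keypoints")
  expect_equal(nKeypoints(ks), 0L)
  expect_identical(imageShape(ks), c(64L, 96L))
})

test_that("extraction is deterministic down to serialized bytes", {
  co <- makeCohort(1, masterSeed = 21)
  rg <- preprocessRadiograph(renderOpg(co[1, ], AcquisitionParams(),
                                       acqSeed = 5))
  k1 <- extractFeatures(rg)
  k2 <- extractFeatures(rg)
  expect_identical(serializeKeypointSet(k1), serializeKeypointSet(k2))
})

test_that("synthetic renders yield structured, consistent keypoint sets", {
  co <- makeCohort(3, masterSeed = 33)
  for (i in 1:3) {
    rg <- preprocessRadiograph(renderOpg(co[i, ], AcquisitionParams(),
                                         acqSeed = i))
    ks <- extractFeatures(rg)
    expect_gt(nKeypoints(ks), 0L)
    expect_equal(descriptorLength(ks), 64L)
    expect_equal(nrow(descriptors(ks)), nKeypoints(ks))
    kp <- keypoints(ks)
    expect_true(all(kp$x >= 0 & kp$x <= imageShape(ks)[2] - 1))
    expect_true(all(kp$y >= 0 & kp$y <= imageShape(ks)[1] - 1))
    expect_true(all(abs(sqrt(rowSums(descriptors(ks)^2)) - 1) < 1e-6))
  }
})

test_that("the keypoint cap keeps the strongest detections", {
  co <- makeCohort(1, masterSeed = 41)
  rg <- preprocessRadiograph(renderOpg(co[1, ], AcquisitionParams(),
                                       acqSeed = 1))
  full <- extractFeatures(rg, FeatureConfig(maxKeypoints = 0L))
  capped <- extractFeatures(rg, FeatureConfig(maxKeypoints = 50L))
  expect_equal(nKeypoints(capped), 50L)
  expect_gte(min(keypoints(capped)$response),
             sort(keypoints(full)$response, decreasing = TRUE)[50])
})

test_that("serialization round-trips bit-exactly and rejects corruption", {
  ks <- randomKeypointSet(40, seed = 8)
  ks@descriptors <- OdontoID:::.f32(ks@descriptors)  # stored precision
  blob <- serializeKeypointSet(ks)
  back <- deserializeKeypointSet(blob)
  expect_identical(keypoints(back), keypoints(ks))
  expect_identical(descriptors(back), descriptors(ks))
  expect_identical(imageShape(back), imageShape(ks))

  # empty set round trip
  e <- emptyKeypointSet()
  expect_equal(nKeypoints(deserializeKeypointSet(serializeKeypointSet(e))),
               0L)

  bad <- blob; bad[1] <- as.raw(0)
  expect_error(deserializeKeypointSet(bad), "magic")
  expect_error(deserializeKeypointSet(blob[1:30]), "truncated|corrupt")

  js <- jsonlite::fromJSON(keypointSetToJSON(ks))
  expect_equal(nrow(js$keypoints), 40)
})

test_that("invalid feature configurations are rejected", {
  expect_error(FeatureConfig(octaves = 0), "octaves")
  expect_error(FeatureConfig(upright = FALSE), "upright")
  expect_error(FeatureConfig(diffusivity = "TV"), "diffusivity")
  expect_error(extractFeatures(Radiograph(matrix(0, 32, 32),
                                          bitDepth = 16)), "8-bit")
})
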