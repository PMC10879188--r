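test_that("cohort generation is seeded, bounded and unique", {
  c1 <- makeCohort(10, masterSeed = 5)
  c2 <- makeCohort(10, masterSeed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1, makeCohort(10, masterSeed = 6)))
  expect_equal(anyDuplicated(c1$individual_id), 0L)
  expect_equal(nrow(makeCohort(1, masterSeed = 1)), 1L)

  # uniform ages: empirical mean within 3 SE of (2 + 89) / 2
  big <- makeCohort(10000, masterSeed = 31)
  se <- (89 - 2) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big$age_years) - 45.5), 3 * se)
  expect_true(all(big$age_years >= 2 & big$age_years <= 89))
})

test_that("noise-free identical acquisitions render bit-identically", {
  co <- makeCohort(1, masterSeed = 17)
  acq <- AcquisitionParams(noiseSD = 0, occlusionFraction = 0)
  r1 <- renderOpg(co[1, ], acq, acqSeed = 3)
  r2 <- renderOpg(co[1, ], acq, acqSeed = 99)  # seed only drives noise
  expect_identical(pixelData(r1), pixelData(r2))
  expect_equal(individualId(r1), co$individual_id[1])
  expect_equal(ageYears(r1), co$age_years[1])
})

test_that("age drives monotone generative features", {
  co <- makeCohort(1, masterSeed = 23)
  young <- co[1, ]; young$age_years <- 10
  old <- co[1, ]; old$age_years <- 80
  gy <- toothGeometry(young)
  go <- toothGeometry(old)
  # crown height shrinks with adult age
  expect_gt(mean(gy$teeth$crownHeight), mean(go$teeth$crownHeight))
  # pulp brightness fades with adult age
  expect_gt(mean(gy$teeth$pulpAmp), mean(go$teeth$pulpAmp))
  # eruption analogue: fewer teeth at age 4 than at 30
  child <- co[1, ]; child$age_years <- 4
  expect_lt(nrow(toothGeometry(child)$teeth),
            nrow(toothGeometry(old)$teeth))

  # recoverability: crown height regressed on age has a strongly negative
  # slope across a cohort of adults
  cohort <- makeCohort(200, masterSeed = 29,
                       ageDistribution = function(n) runif(n, 21, 89))
  ch <- vapply(seq_len(200), function(i)
    mean(toothGeometry(cohort[i, ])$teeth$crownHeight), numeric(1))
  fit <- summary(lm(ch ~ cohort$age_years))
  expect_lt(fit$coefficients[2, 1], 0)
  expect_gt(abs(fit$coefficients[2, 3]), 10)  # |t| of the slope
})

test_that("fixture databases enroll and hold out the right counts", {
  fx <- smallFixture()
  expect_equal(dbSize(fx$db), 12L)
  expect_equal(length(fx$queries), 12L)
  expect_identical(sort(names(fx$truth)), sort(names(fx$queries)))
  expect_true(all(fx$truth %in% dbEntries(fx$db)$individual_id))
  expect_error(makeFixtureDb(makeCohort(2, masterSeed = 1),
                             imagesPerIndividual = 1L), ">= 2")
})

test_that("render geometry is identity-stable across repeat acquisitions", {
  co <- makeCohort(2, masterSeed = 53)
  g1 <- toothGeometry(co[1, ])
  g2 <- toothGeometry(co[1, ])
  expect_identical(g1$teeth, g2$teeth)
  g3 <- toothGeometry(co[2, ])
  expect_false(isTRUE(all.equal(g1$teeth$x, g3$teeth$x)))
})
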