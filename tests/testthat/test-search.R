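test_that("an infinite radius reproduces the exhaustive ranking", {
  fx <- smallFixture()
  q <- fx$queries[[3]]
  rep <- identify(q, fx$db, SearchPolicy(mode = "fixed", radiusYears = Inf),
                  seed = 21)
  expect_equal(rowsEvaluated(rep), dbSize(fx$db))
  expect_equal(fractionEvaluated(rep), 1)
  expect_equal(stopReason(rep), "full_scan")

  qf <- extractFeatures(preprocessRadiograph(q))
  oracle <- rankCandidates(qf, fx$db, seed = 21)
  got <- rankedCandidates(rep)
  expect_equal(got$entry_id, head(oracle$entry_id, 10))
  expect_equal(got$average, head(oracle$average, 10))
  # the enrolled render of the same individual ranks first
  expect_equal(got$individual_id[1], fx$truth[[names(fx$queries)[3]]])
})

test_that("early stopping boundaries behave as specified", {
  fx <- smallFixture()
  qf <- extractFeatures(preprocessRadiograph(fx$queries[[1]]))
  est <- 45

  # threshold Inf: stop reason is never early_stop
  r1 <- expandingSearch(qf, est, fx$db,
                        SearchPolicy(mode = "expanding",
                                     earlyStopThreshold = Inf), seed = 3)
  expect_equal(stopReason(r1), "full_scan")
  expect_equal(rowsEvaluated(r1), dbSize(fx$db))

  # zero threshold: the very first scored entry stops the stream
  r2 <- expandingSearch(qf, est, fx$db,
                        SearchPolicy(mode = "expanding",
                                     earlyStopThreshold = 0), seed = 3)
  expect_equal(rowsEvaluated(r2), 1L)
  expect_equal(stopReason(r2), "early_stop")
})

test_that("a hand-traced schedule stops at the second candidate", {
  fx <- smallFixture()
  qf <- extractFeatures(preprocessRadiograph(fx$queries[[2]]))
  est <- 50
  db <- FeatureDatabase()
  addEntry(db, "near_empty", est + 1, emptyKeypointSet())  # scores 0
  addEntry(db, "genuine", est - 3, qf)                     # self-match
  addEntry(db, "far", est + 8, emptyKeypointSet())
  rep <- expandingSearch(qf, est, db,
                         SearchPolicy(mode = "expanding",
                                      earlyStopThreshold = 5), seed = 5)
  expect_equal(rowsEvaluated(rep), 2L)
  expect_equal(stopReason(rep), "early_stop")
  expect_equal(rankedCandidates(rep)$individual_id[1], "genuine")
})

test_that("no entry is ever scored twice in any mode", {
  fx <- smallFixture()
  qf <- extractFeatures(preprocessRadiograph(fx$queries[[4]]))
  matchCallCount(reset = TRUE)
  rep <- expandingSearch(qf, 40, fx$db,
                         SearchPolicy(mode = "expanding"), seed = 7)
  calls <- matchCallCount(reset = TRUE)
  expect_lte(calls, 2L * dbSize(fx$db))
  expect_equal(calls, 2L * rowsEvaluated(rep))
})

test_that("fixed(Inf) and expanding(threshold Inf) rankings coincide", {
  fx <- smallFixture()
  q <- fx$queries[[5]]
  qf <- extractFeatures(preprocessRadiograph(q))
  a <- identify(q, fx$db, SearchPolicy(mode = "fixed", radiusYears = Inf),
                seed = 11)
  # same seed stream: expanding over the same features
  b <- expandingSearch(qf, 40, fx$db,
                       SearchPolicy(mode = "expanding",
                                    radiusSchedule = c(5, 10, 15, Inf),
                                    earlyStopThreshold = Inf), seed = 11)
  expect_equal(rankedCandidates(a)$entry_id, rankedCandidates(b)$entry_id)
  expect_equal(rankedCandidates(a)$average, rankedCandidates(b)$average)
})

test_that("gate soundness: covered rank-1 entries survive gating", {
  fx <- smallFixture()
  ages <- dbEntries(fx$db)$age_years
  for (qi in c(1L, 6L, 9L)) {
    set.seed(qi)
    q <- fx$queries[[qi]]
    qf <- extractFeatures(preprocessRadiograph(q))
    full <- rankCandidates(qf, fx$db, seed = 31)
    est <- ageYears(q) + runif(1, -3, 3)  # stand-in age estimate
    for (radius in c(5, 10, 20)) {
      top <- full[1, ]
      gated <- .gatedSearchForTest(qf, est, fx$db, radius, seed = 31)
      if (abs(top$age_years - est) <= radius) {
        expect_equal(rankedCandidates(gated)$entry_id[1], top$entry_id)
      }
      # monotonicity of evaluated rows in the radius
      expect_lte(rowsEvaluated(gated), dbSize(fx$db))
    }
  }
})

test_that("degenerate searches fail loudly or return empty reports", {
  fx <- smallFixture()
  empty <- FeatureDatabase()
  expect_error(identify(fx$queries[[1]], empty), "empty")
  expect_error(identify(fx$queries[[1]], fx$db,
                        SearchPolicy(mode = "fixed", radiusYears = 5),
                        model = NULL), "requires an age")
  # zero candidates in the window: empty ranking, schedule exhausted
  qf <- extractFeatures(preprocessRadiograph(fx$queries[[1]]))
  rep <- .gatedSearchForTest(qf, 200, fx$db, 3, seed = 1)
  expect_equal(nrow(rankedCandidates(rep)), 0L)
  expect_equal(stopReason(rep), "schedule_exhausted")
})

test_that("the younger-side widening flag expands the right boundary", {
  db <- FeatureDatabase()
  for (a in c(58, 62, 78, 83)) addEntry(db, paste0("I", a), a,
                                        emptyKeypointSet())
  pol <- SearchPolicy(mode = "fixed", radiusYears = 10,
                      widenYounger = TRUE)
  qf <- emptyKeypointSet()
  rep <- OdontoID:::.gatedSearch(qf, 75, db, 10, pol, MatchConfig(), 1)
  # widened younger radius 15: age 62 included; 58 and 83 excluded... 83 is
  # within +10 -> included; 58 is below 75 - 15 -> excluded
  got <- rankedCandidates(rep)$age_years
  expect_true(62 %in% got)
  expect_true(83 %in% got)
  expect_false(58 %in% got)
})

test_that("the impostor-calibrated threshold separates genuine matches", {
  fx <- smallFixture()
  thr <- calibrateEarlyStop(fx$db, nPairs = 30L, seed = 17)
  imp <- attr(thr, "impostor_scores")
  expect_true(all(imp <= thr))
  # a genuine comparison crosses the threshold
  q <- fx$queries[[1]]
  qf <- extractFeatures(preprocessRadiograph(q))
  tab <- dbEntries(fx$db)
  ownId <- tab$entry_id[tab$individual_id == fx$truth[[names(fx$queries)[1]]]]
  g <- averagePoints(scorePair(qf, entryFeatures(fx$db, ownId[1]), seed = 2))
  expect_gt(g, thr)
})
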