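test_that("hand-computed prediction metrics are reproduced exactly", {
  m <- evaluatePredictions(c(3, 5), c(1, 5))
  expect_equal(m@mae, 1.0)
  expect_equal(m@signedMeanError, 1.0)
  expect_equal(m@successRate[["5"]], 100)
  expect_equal(m@rmse, sqrt(2))
  expect_equal(m@n, 2L)

  # perfect prediction
  p <- evaluatePredictions(c(10, 20, 30), c(10, 20, 30))
  expect_equal(p@mae, 0)
  expect_equal(p@rmse, 0)
  expect_true(all(p@successRate == 100))
  expect_equal(p@rSquared, 1)

  # constant prediction at the mean of the actuals: R^2 = 0
  act <- c(10, 20, 30, 40)
  cm <- evaluatePredictions(rep(mean(act), 4), act)
  expect_equal(cm@rSquared, 0)

  expect_error(evaluatePredictions(1:3, 1:4), "equal")
  expect_error(evaluatePredictions(numeric(0), numeric(0)), "non-zero")
})

test_that("success rates are monotone and rmse dominates mae", {
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    pred <- runif(n, 0, 90); act <- runif(n, 0, 90)
    m <- evaluatePredictions(pred, act, tolerances = c(2, 5, 10, 20))
    expect_true(all(diff(m@successRate) >= 0))
    expect_gte(m@rmse, m@mae - 1e-12)
    expect_lte(m@ci95[1], m@ci95[2])
  }
})

test_that("age stratification partitions every pair exactly once", {
  # one pair per bin
  act <- c(5, 15, 25)
  s <- stratifyByAge(act + 1, act, binEdges = c(2, 10, 20, 30))
  expect_equal(s$n, c(1L, 1L, 1L))
  expect_equal(s$group, c("2-9", "10-19", "20-29"))

  # the decade groups 2-9 and 10-19 split ages 5 and 15
  s2 <- stratifyByAge(c(6, 14), c(5, 15), binEdges = c(2, 10, 20))
  expect_equal(s2$n, c(1L, 1L))

  # conservation on random data, including the overflow bin
  set.seed(8)
  act <- runif(500, 0, 100)
  pred <- act + rnorm(500, 0, 4)
  s3 <- stratifyByAge(pred, act)
  expect_equal(sum(s3$n), 500L)
  expect_true("overflow" %in% s3$group)  # ages outside [2, 90)
})

test_that("identification summaries tally rank-1 successes", {
  mkrep <- function(top_individual, frac, n = 2L) {
    ranked <- if (is.na(top_individual))
      data.frame(entry_id = integer(0), individual_id = character(0),
                 age_years = numeric(0), forward = integer(0),
                 reverse = integer(0), average = numeric(0),
                 rank = integer(0))
    else data.frame(entry_id = 1L, individual_id = top_individual,
                    age_years = 30, forward = 5L, reverse = 7L,
                    average = 6, rank = 1L)
    new("SearchReport", ranked = ranked, rowsEvaluated = 1L,
        dbSize = n, fractionEvaluated = frac, estimatedAge = 30,
        stopReason = "full_scan", queryId = NA_character_)
  }
  reports <- list(q1 = mkrep("A", 0.2), q2 = mkrep("B", 0.4),
                  q3 = mkrep("X", 0.6), q4 = mkrep(NA, 1.0))
  truth <- c(q1 = "A", q2 = "B", q3 = "C", q4 = "D")
  s <- identificationSummary(reports, truth)
  expect_equal(s$n, 4L)
  expect_equal(s$successes, 2L)  # q3 wrong, q4 degenerate -> failures
  expect_equal(s$success_rate, 50)
  expect_equal(s$mean_fraction_evaluated, mean(c(0.2, 0.4, 0.6, 1.0)))

  # all correct
  allok <- identificationSummary(list(q1 = mkrep("A", 0.1)),
                                 c(q1 = "A"))
  expect_equal(allok$successes, 1L)

  expect_error(identificationSummary(reports, truth[1:2]), "missing truth")
})
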