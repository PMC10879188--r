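test_that("self-match recovers every uniquely matched keypoint", {
  ks <- randomKeypointSet(60, seed = 14)
  expect_equal(matchDirected(ks, ks, seed = 1), 60L)
  s <- scorePair(ks, ks, seed = 1)
  expect_equal(averagePoints(s), 60)
})

test_that("degenerate inputs score zero or error as specified", {
  ks <- randomKeypointSet(20, seed = 15)
  e <- emptyKeypointSet()
  expect_equal(matchDirected(e, ks, seed = 1), 0L)
  expect_equal(matchDirected(ks, e, seed = 1), 0L)
  short <- randomKeypointSet(10, seed = 16, dlen = 32L)
  expect_error(matchDirected(ks, short, seed = 1), "descriptor lengths")
})

test_that("match scores are deterministic and symmetric with paired seeds", {
  fp <- renderedFeaturePair()
  s1 <- scorePair(fp$a1, fp$a2, seed = 42)
  s2 <- scorePair(fp$a1, fp$a2, seed = 42)
  expect_equal(forwardPoints(s1), forwardPoints(s2))
  expect_equal(reversePoints(s1), reversePoints(s2))
  sw <- scorePair(fp$a2, fp$a1, seed = 42)
  expect_equal(averagePoints(sw), averagePoints(s1))
  expect_equal(forwardPoints(sw), reversePoints(s1))
})

test_that("inlier counts never exceed the candidate correspondence budget", {
  for (trial in 1:25) {
    a <- randomKeypointSet(sample(5:40, 1), seed = 100 + trial)
    b <- randomKeypointSet(sample(5:40, 1), seed = 200 + trial)
    m <- matchDirected(a, b, seed = trial)
    survivors <- nrow(OdontoID:::.ratioMatches(descriptors(a),
                                               descriptors(b), 0.7))
    expect_lte(m, max(survivors, 0))
    expect_lte(m, min(nKeypoints(a), nKeypoints(b)))
  }
})

test_that("same-individual scores dominate impostor scores over seeds", {
  fp <- renderedFeaturePair()
  gen <- vapply(1:10, function(s) averagePoints(scorePair(fp$a1, fp$a2,
                                                          seed = s)),
                numeric(1))
  imp <- vapply(1:10, function(s) averagePoints(scorePair(fp$a1, fp$b1,
                                                          seed = s)),
                numeric(1))
  expect_gt(min(gen), max(imp))
})

test_that("the MatchScore invariant is enforced", {
  expect_error(new("MatchScore", forwardPoints = 10L, reversePoints = 12L,
                   averagePoints = 10), "average")
  ok <- new("MatchScore", forwardPoints = 10L, reversePoints = 12L,
            averagePoints = 11)
  expect_equal(averagePoints(ok), 11)
})

test_that("candidate ranking equals an independent sort oracle", {
  fp <- renderedFeaturePair()
  db <- FeatureDatabase()
  addEntry(db, "other", 50, fp$b1)
  addEntry(db, "self", 30, fp$a1)
  addEntry(db, "noise", 40, randomKeypointSet(50, seed = 77))
  ranked <- rankCandidates(fp$a2, db, seed = 9)
  expect_equal(ranked$individual_id[1], "self")
  expect_equal(ranked$rank, 1:3)

  # oracle: score each entry independently with the derived seed and sort
  oracle <- vapply(1:3, function(id)
    averagePoints(scorePair(fp$a2, entryFeatures(db, id),
                            seed = OdontoID:::.deriveSeed(9, id))),
    numeric(1))
  ord <- order(-oracle, 1:3)
  expect_equal(ranked$entry_id, (1:3)[ord])
  expect_equal(ranked$average, oracle[ord])

  empty <- rankCandidates(fp$a2, db, candidates = dbEntries(db)[0, ],
                          seed = 9)
  expect_equal(nrow(empty), 0L)
})
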