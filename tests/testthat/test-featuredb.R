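test_that("entries persist, with multiple acquisitions per individual", {
  db <- FeatureDatabase()
  expect_equal(dbSize(db), 0L)
  ks <- randomKeypointSet(10, seed = 1)
  id1 <- addEntry(db, "A", 30, ks)
  expect_equal(dbSize(db), 1L)
  expect_equal(getEntry(db, id1)$individual_id, "A")

  id2 <- addEntry(db, "A", 35, randomKeypointSet(8, seed = 2))
  expect_equal(dbSize(db), 2L)
  expect_false(id1 == id2)

  for (i in 1:998) addEntry(db, sprintf("I%03d", i), (i %% 120) + 1,
                            emptyKeypointSet())
  expect_equal(dbSize(db), 1000L)
  expect_equal(nrow(dbEntries(db)), 1000L)

  expect_error(addEntry(db, "B", 200, ks), "0, 130")
  expect_error(getEntry(db, 99999), "no entry")
})

test_that("feature blobs round-trip bit-identically through the store", {
  db <- FeatureDatabase()
  ks <- randomKeypointSet(25, seed = 3)
  ks@descriptors <- OdontoID:::.f32(ks@descriptors)
  id <- addEntry(db, "X", 52.5, ks)
  back <- entryFeatures(db, id)
  expect_identical(serializeKeypointSet(back), serializeKeypointSet(ks))
})

test_that("age-radius queries match the brute-force oracle", {
  db <- FeatureDatabase()
  for (a in c(20, 24, 26, 36)) addEntry(db, paste0("I", a), a,
                                        emptyKeypointSet())
  hit <- queryByAge(db, 25, 5)
  expect_equal(hit$age_years, c(24, 26, 20))

  allhits <- queryByAge(db, 25, Inf)
  expect_equal(nrow(allhits), 4L)
  expect_equal(allhits$age_years, c(24, 26, 20, 36))

  expect_equal(nrow(queryByAge(db, 25.5, 0)), 0L)
  expect_error(queryByAge(db, 25, -1), ">= 0")

  # randomized fixtures against brute-force filter + sort
  set.seed(11)
  db2 <- FeatureDatabase()
  ages <- round(runif(60, 0, 95), 1)
  ids <- vapply(seq_along(ages), function(i)
    addEntry(db2, sprintf("P%02d", i), ages[i], emptyKeypointSet()),
    integer(1))
  for (trial in 1:20) {
    center <- runif(1, 0, 95); radius <- runif(1, 0, 30)
    got <- queryByAge(db2, center, radius)
    keep <- which(abs(ages - center) <= radius)
    ord <- keep[order(abs(ages[keep] - center), ids[keep])]
    expect_equal(got$entry_id, ids[ord])
  }

  # monotonicity: results for radius r are a subset of radius r' >= r
  for (trial in 1:10) {
    center <- runif(1, 0, 95); r <- runif(1, 0, 20)
    small <- queryByAge(db2, center, r)$entry_id
    big <- queryByAge(db2, center, r + runif(1, 0, 20))$entry_id
    expect_true(all(small %in% big))
  }
})

test_that("asymmetric queries widen one side only", {
  db <- FeatureDatabase()
  for (a in c(62, 71, 74, 78, 82)) addEntry(db, paste0("I", a), a,
                                            emptyKeypointSet())
  got <- asymmetricQuery(db, 75, 15, 5)
  expect_true(62 %in% got$age_years)
  expect_false(82 %in% got$age_years)

  sym <- asymmetricQuery(db, 75, 6, 6)
  expect_equal(sym, queryByAge(db, 75, 6))

  exact <- asymmetricQuery(db, 74, 0, 0)
  expect_equal(exact$age_years, 74)
})

test_that("databases persist to a single file and reload identically", {
  db <- FeatureDatabase()
  ks <- randomKeypointSet(12, seed = 9)
  addEntry(db, "A", 40, ks)
  addEntry(db, "B", 41.5, randomKeypointSet(7, seed = 10), sourceTag = "pm")
  path <- tempfile(fileext = ".db")
  saveDatabase(db, path)
  db2 <- loadDatabase(path)
  expect_equal(dbEntries(db2), dbEntries(db))
  expect_identical(serializeKeypointSet(entryFeatures(db2, 1)),
                   serializeKeypointSet(entryFeatures(db, 1)))
  # ids continue from the persisted counter
  id3 <- addEntry(db2, "C", 10, emptyKeypointSet())
  expect_equal(id3, 3L)
  unlink(path)
})
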