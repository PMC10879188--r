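# OdontoID

Computer-vision human identification from panoramic dental radiographs
(orthopantomograms, OPGs), accelerated by CNN-based dental age estimation.

## What it does, and for whom

Forensic teams identifying unknown deceased individuals compare postmortem
dental imagery against antemortem records. OdontoID implements that
workflow for OPGs, for use at database scale:

* **Privacy-preserving feature database.** Antemortem images are reduced to
  keypoint descriptors plus the age at acquisition; no pixels are stored
  and the descriptors cannot be inverted back to an image.
* **Identification by geometric-verified matching.** A query is scored
  against an entry by brute-force nearest-neighbour descriptor matching
  (Lowe ratio 0.7), RANSAC homography verification, in both directions:

  score(q, e) = ( inliers(q→e) + inliers(e→q) ) / 2

  The entry with the highest average "matching points" is the rank-1
  identification candidate.
* **Age-gated search.** A convolutional network estimates the subject's age
  A from the query image, and only entries with |age − A| ≤ r are scored,
  visited in ascending |age − A| with optional early stopping at a
  calibrated "significant match" threshold — so large databases are mostly
  pruned away rather than scanned.

The stages: deterministic preprocessing (8-bit normalization, 180×100 mm
centered crop, eight 3×3 compass Sobel kernels with gain 1.8 combined by
pixel-wise maximum, 6×6 averaging filter), a KAZE-family nonlinear
scale-space detector with upright 64-d descriptors (octaves 8, sublevels 5,
PM_G2 diffusivity), and a CNN regressor (four blocks of three conv+BN pairs,
32→256 filters, dense 1024, single linear output; Adam, MSE) trained
natively in R — no external deep-learning framework.

Clinical data cannot be shipped, so the package includes a seeded
synthetic-OPG generator (`makeCohort()`, `renderOpg()`) producing
identity-stable, age-coded fixtures that every empirical test runs on. See
`vignettes/odontoid-methods.Rmd` for the models, parameter meanings, and
design decisions.

## Worked example

```r
library(OdontoID)

# a synthetic cohort: 20 individuals, ages uniform on [2, 89]
cohort <- makeCohort(20, masterSeed = 1234)
fx <- makeFixtureDb(cohort, seed = 1234)   # enrolls one render each,
fx$db                                      # holds out one query each
#> FeatureDatabase: 20 entries, 20 individuals (schema v1)
#>   age range: 2.8 - 82.3 years

# identify one held-out query with no age filter (full scan)
rep <- identify(fx$queries[[1]], fx$db,
                SearchPolicy(mode = "fixed", radiusYears = Inf), seed = 7)
rep
#> SearchReport: 20/20 rows evaluated (100.0%), stop: full_scan
#>   rank 1: IND00001 (entry 1, 67.0 matching points)

head(rankedCandidates(rep), 3)
#>   entry_id individual_id age_years forward reverse average rank
#> 1        1      IND00001  11.89220      67      67    67.0    1
#> 2        4      IND00004  56.23401       6       6     6.0    2
#> 3        2      IND00002  56.14005       6       5     5.5    3
```

The rank-1 entry is the query's own individual with 67 averaged
RANSAC-inlier "matching points"; different-individual entries score ~5 —
that separation is what makes rank-1 identification and early stopping
work. With a trained age model (`buildAgeModel()`, `trainAgeModel()`,
`predictAge()`), passing `model =` to `identify()` and a finite
`radiusYears` prunes the candidate set to the estimated-age neighbourhood
before any matching happens.

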