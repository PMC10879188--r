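#' Search policy for age-gated identification
#'
#' Controls how database candidates are selected and visited when
#' identifying a query radiograph. In \code{"fixed"} mode a single age
#' radius (possibly infinite) gates the candidate set; in
#' \code{"expanding"} mode the radius grows through \code{radiusSchedule}
#' until the whole database has been queried. In both modes candidates are
#' visited in ascending absolute difference from the estimated age and the
#' search may stop early once a candidate's average matching points reach
#' \code{earlyStopThreshold} (a "significant match"). Optionally the
#' younger-side radius is widened for elderly subjects, whose CNN age
#' estimates tend to be too low.
#'
#' @slot mode \code{"fixed"} or \code{"expanding"}.
#' @slot radiusYears fixed-mode radius in years (\code{Inf} = no gate).
#' @slot radiusSchedule expanding-mode radii, strictly ascending
#'   (default 5, 10, 15, Inf).
#' @slot earlyStopThreshold average matching points deemed a significant
#'   match (\code{Inf} disables early stopping).
#' @slot widenYounger widen the younger-side radius for old estimates?
#' @slot asymmetricBiasAge estimated age above which widening applies
#'   (default 70).
#' @slot asymmetricFactor younger-side widening factor (default 1.5).
#' @slot topK number of ranked candidates reported (default 10).
#' @seealso [identify()], [expandingSearch()], [calibrateEarlyStop()]
#' @export
setClass("SearchPolicy",
  representation(mode = "character", radiusYears = "numeric",
                 radiusSchedule = "numeric", earlyStopThreshold = "numeric",
                 widenYounger = "logical", asymmetricBiasAge = "numeric",
                 asymmetricFactor = "numeric", topK = "integer"),
  prototype(mode = "fixed", radiusYears = Inf,
            radiusSchedule = c(5, 10, 15, Inf), earlyStopThreshold = Inf,
            widenYounger = FALSE, asymmetricBiasAge = 70,
            asymmetricFactor = 1.5, topK = 10L))

setValidity("SearchPolicy", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("fixed", "expanding"))
    msgs <- c(msgs, "mode must be 'fixed' or 'expanding'")
  if (object@radiusYears < 0) msgs <- c(msgs, "radiusYears must be >= 0")
  rs <- object@radiusSchedule
  if (length(rs) < 1 || any(diff(rs) <= 0))
    msgs <- c(msgs, "radiusSchedule must be strictly ascending")
  if (object@earlyStopThreshold < 0)
    msgs <- c(msgs, "earlyStopThreshold must be non-negative")
  if (object@asymmetricFactor < 1)
    msgs <- c(msgs, "asymmetricFactor must be >= 1")
  if (object@topK < 1) msgs <- c(msgs, "topK must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SearchPolicy-class
#' @param mode,radiusYears,radiusSchedule,earlyStopThreshold see slots.
#' @param widenYounger,asymmetricBiasAge,asymmetricFactor,topK see slots.
#' @return A \code{SearchPolicy}.
#' @export
SearchPolicy <- function(mode = "fixed", radiusYears = Inf,
                         radiusSchedule = c(5, 10, 15, Inf),
                         earlyStopThreshold = Inf, widenYounger = FALSE,
                         asymmetricBiasAge = 70, asymmetricFactor = 1.5,
                         topK = 10L) {
  new("SearchPolicy", mode = mode, radiusYears = radiusYears,
      radiusSchedule = as.numeric(radiusSchedule),
      earlyStopThreshold = earlyStopThreshold,
      widenYounger = widenYounger, asymmetricBiasAge = asymmetricBiasAge,
      asymmetricFactor = asymmetricFactor, topK = as.integer(topK))
}

#' SearchReport: result of one identification search
#'
#' @slot ranked data.frame of the top-k candidates (entry_id,
#'   individual_id, age_years, forward, reverse, average, rank).
#' @slot rowsEvaluated number of database entries scored.
#' @slot dbSize database size at search time.
#' @slot fractionEvaluated rowsEvaluated / dbSize.
#' @slot estimatedAge CNN age estimate used for gating (NA without model).
#' @slot stopReason one of \code{"early_stop"},
#'   \code{"schedule_exhausted"}, \code{"full_scan"}.
#' @slot queryId identifier of the query image (if known).
#' @export
setClass("SearchReport",
  representation(ranked = "data.frame", rowsEvaluated = "integer",
                 dbSize = "integer", fractionEvaluated = "numeric",
                 estimatedAge = "numeric", stopReason = "character",
                 queryId = "character"))

#' @describeIn SearchReport ranked candidate table.
#' @param x a \code{SearchReport}.
#' @export
setMethod("rankedCandidates", "SearchReport", function(x) x@ranked)

#' @describeIn SearchReport number of entries scored.
#' @export
setMethod("rowsEvaluated", "SearchReport", function(x) x@rowsEvaluated)

#' @describeIn SearchReport fraction of the database scored.
#' @export
setMethod("fractionEvaluated", "SearchReport",
          function(x) x@fractionEvaluated)

#' @describeIn SearchReport CNN age estimate used for gating.
#' @export
setMethod("estimatedAge", "SearchReport", function(x) x@estimatedAge)

#' @describeIn SearchReport why the search ended.
#' @export
setMethod("stopReason", "SearchReport", function(x) x@stopReason)

setMethod("show", "SearchReport", function(object) {
  cat(sprintf(
    "SearchReport: %d/%d rows evaluated (%.1f%%), stop: %s\n",
    object@rowsEvaluated, object@dbSize,
    100 * object@fractionEvaluated, object@stopReason))
  if (!is.na(object@estimatedAge))
    cat(sprintf("  estimated age: %.1f years\n", object@estimatedAge))
  if (nrow(object@ranked)) {
    top <- object@ranked[1, ]
    cat(sprintf("  rank 1: %s (entry %d, %.1f matching points)\n",
                top$individual_id, top$entry_id, top$average))
  }
})

# age window for one radius under the (possibly asymmetric) policy
.gateWindow <- function(est, radius, policy) {
  younger <- radius
  if (policy@widenYounger && !is.na(est) &&
      est >= policy@asymmetricBiasAge)
    younger <- radius * policy@asymmetricFactor
  c(lower = est - younger, upper = est + radius)
}

# core gated-search engine shared by both policy modes
.gatedSearch <- function(queryFeatures, estAge, db, radii, policy,
                         matchCfg, seed, queryId = NA_character_) {
  n <- dbSize(db)
  scored <- new.env(parent = emptyenv())  # entry_id -> c(fwd, rev)
  rows <- 0L
  bestAvg <- -Inf
  stopReason <- NA_character_
  for (radius in radii) {
    if (is.na(estAge)) {
      if (is.finite(radius))
        stop("a finite search radius requires an age estimate")
      cand <- .orderedCandidates(db, NA_real_, -Inf, Inf)
    } else {
      wdw <- .gateWindow(estAge, radius, policy)
      cand <- asymmetricQuery(db, estAge, estAge - wdw["lower"],
                              wdw["upper"] - estAge)
    }
    for (i in seq_len(nrow(cand))) {
      id <- cand$entry_id[i]
      key <- as.character(id)
      if (!is.null(scored[[key]])) next  # cached: never rescored
      feats <- entryFeatures(db, id)
      s <- .deriveSeed(seed, id)
      fwd <- matchDirected(queryFeatures, feats, matchCfg, s)
      rev <- matchDirected(feats, queryFeatures, matchCfg, s)
      scored[[key]] <- c(fwd, rev)
      rows <- rows + 1L
      avg <- (fwd + rev) / 2
      if (avg > bestAvg) bestAvg <- avg
      if (bestAvg >= policy@earlyStopThreshold) {
        stopReason <- "early_stop"
        break
      }
    }
    if (!is.na(stopReason)) break
  }
  if (is.na(stopReason))
    stopReason <- if (is.infinite(radii[length(radii)])) "full_scan"
                  else "schedule_exhausted"
  ids <- as.integer(ls(scored))
  if (length(ids)) {
    tab <- dbEntries(db)
    tab <- tab[match(ids, tab$entry_id), , drop = FALSE]
    sc <- t(vapply(as.character(ids), function(k) scored[[k]],
                   numeric(2)))
    ranked <- data.frame(entry_id = ids,
                         individual_id = tab$individual_id,
                         age_years = tab$age_years,
                         forward = as.integer(sc[, 1]),
                         reverse = as.integer(sc[, 2]),
                         average = (sc[, 1] + sc[, 2]) / 2,
                         stringsAsFactors = FALSE)
    ranked <- ranked[order(-ranked$average, ranked$entry_id), ,
                     drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
    rownames(ranked) <- NULL
    ranked <- utils::head(ranked, policy@topK)
  } else {
    ranked <- data.frame(entry_id = integer(0),
                         individual_id = character(0),
                         age_years = numeric(0), forward = integer(0),
                         reverse = integer(0), average = numeric(0),
                         rank = integer(0), stringsAsFactors = FALSE)
  }
  new("SearchReport", ranked = ranked, rowsEvaluated = rows,
      dbSize = as.integer(n), fractionEvaluated = rows / n,
      estimatedAge = as.numeric(estAge), stopReason = stopReason,
      queryId = queryId)
}

#' Identify a query radiograph against the feature database
#'
#' Full pipeline: preprocess the query, extract features, estimate the
#' subject's age with the CNN (when a model is supplied), select and order
#' database candidates per the search policy, and rank them by average
#' matching points. Every database entry is scored at most once.
#'
#' @param queryImg the query [Radiograph-class] (raw, not preprocessed).
#' @param db a non-empty [FeatureDatabase-class].
#' @param policy a [SearchPolicy-class]. Without a model, only infinite
#'   radii are valid.
#' @param model a trained [AgeCnnModel-class], or \code{NULL} for the
#'   no-age-filter path.
#' @param preCfg,featCfg,matchCfg stage configurations.
#' @param seed master seed for the per-entry RANSAC streams.
#' @param queryId optional query identifier recorded in the report
#'   (defaults to the image's individual id).
#' @return A [SearchReport-class].
#' @export
identify <- function(queryImg, db, policy = SearchPolicy(), model = NULL,
                     preCfg = PreprocessConfig(), featCfg = FeatureConfig(),
                     matchCfg = MatchConfig(), seed = 1L,
                     queryId = NA_character_) {
  stopifnot(is(db, "FeatureDatabase"), is(policy, "SearchPolicy"))
  if (dbSize(db) == 0L) stop("the feature database is empty")
  if (is.na(queryId)) queryId <- individualId(queryImg)
  pp <- preprocessRadiograph(queryImg, preCfg)
  qf <- extractFeatures(pp, featCfg)
  est <- if (!is.null(model)) as.numeric(predictAge(model, queryImg))
         else NA_real_
  radii <- if (policy@mode == "fixed") policy@radiusYears
           else policy@radiusSchedule
  if (is.na(est) && is.finite(radii[length(radii)]))
    stop("a finite search radius requires an age-estimation model")
  .gatedSearch(qf, est, db, radii, policy, matchCfg, seed, queryId)
}

#' Expanding age-radius search over precomputed query features
#'
#' Streams database entries in ascending absolute difference between entry
#' age and the estimated age, expanding the radius through the policy
#' schedule; stops early when the best average matching points reach the
#' policy threshold. Scores are cached, so no entry is ever scored twice;
#' with an infinite final radius and no early stop the result equals the
#' exhaustive ranking.
#'
#' @param queryFeatures the query [KeypointSet-class].
#' @param estAge estimated age in years used as the search center.
#' @param db a [FeatureDatabase-class].
#' @param policy a [SearchPolicy-class] (its \code{radiusSchedule} and
#'   \code{earlyStopThreshold} are used).
#' @param matchCfg a [MatchConfig-class].
#' @param seed master seed.
#' @param queryId optional query identifier for the report.
#' @return A [SearchReport-class].
#' @export
expandingSearch <- function(queryFeatures, estAge, db,
                            policy = SearchPolicy(mode = "expanding"),
                            matchCfg = MatchConfig(), seed = 1L,
                            queryId = NA_character_) {
  stopifnot(is(queryFeatures, "KeypointSet"))
  if (dbSize(db) == 0L) stop("the feature database is empty")
  .gatedSearch(queryFeatures, estAge, db, policy@radiusSchedule, policy,
               matchCfg, seed, queryId)
}

#' Calibrate the early-stop ("significant match") threshold
#'
#' Samples impostor pairs (entries of different individuals), computes
#' their bidirectional average matching points, and returns
#' \code{mean + nSd * sd} of that impostor distribution — a score that
#' different-individual comparisons essentially never reach.
#'
#' @param db a [FeatureDatabase-class] with at least two individuals.
#' @param matchCfg a [MatchConfig-class].
#' @param nPairs number of impostor pairs to sample (default 100).
#' @param nSd number of standard deviations above the impostor mean
#'   (default 5).
#' @param seed integer seed.
#' @return The calibrated threshold (numeric), with the impostor scores in
#'   \code{attr(, "impostor_scores")}.
#' @export
calibrateEarlyStop <- function(db, matchCfg = MatchConfig(), nPairs = 100L,
                               nSd = 5, seed = 1L) {
  stopifnot(is(db, "FeatureDatabase"))
  tab <- dbEntries(db)
  if (length(unique(tab$individual_id)) < 2L)
    stop("need entries from at least two individuals")
  set.seed(seed)
  scores <- numeric(nPairs)
  for (i in seq_len(nPairs)) {
    repeat {
      pick <- sample.int(nrow(tab), 2L)
      if (tab$individual_id[pick[1]] != tab$individual_id[pick[2]]) break
    }
    a <- entryFeatures(db, tab$entry_id[pick[1]])
    b <- entryFeatures(db, tab$entry_id[pick[2]])
    scores[i] <- averagePoints(scorePair(a, b, matchCfg,
                                         seed = .deriveSeed(seed, i)))
  }
  thr <- mean(scores) + nSd * stats::sd(scores)
  attr(thr, "impostor_scores") <- scores
  thr
}
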