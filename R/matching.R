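#' Matching configuration
#'
#' Parameters of descriptor correspondence scoring: exhaustive (brute-force)
#' nearest-neighbour matching in Euclidean descriptor space with Lowe's
#' ratio test, followed by seeded RANSAC estimation of a geometric model on
#' the corresponding keypoint coordinates. The surviving inlier count is the
#' "matching points" score between two images.
#'
#' @slot ratioThreshold Lowe ratio (nearest / second-nearest distance)
#'   below which a correspondence is kept (default 0.7).
#' @slot geometricModel \code{"homography"} (default), \code{"affine"} or
#'   \code{"similarity"}.
#' @slot ransacReprojThreshold maximum transfer error in pixels for an
#'   inlier (default 3).
#' @slot ransacConfidence RANSAC stopping confidence (default 0.995).
#' @slot minCorrespondences fewer ratio-test survivors than this yields a
#'   score of 0 (default 4).
#' @slot maxRansacIterations iteration cap (default 250).
#' @export
setClass("MatchConfig",
  representation(
    ratioThreshold = "numeric",
    geometricModel = "character",
    ransacReprojThreshold = "numeric",
    ransacConfidence = "numeric",
    minCorrespondences = "integer",
    maxRansacIterations = "integer"
  ),
  prototype(
    ratioThreshold = 0.7,
    geometricModel = "homography",
    ransacReprojThreshold = 3.0,
    ransacConfidence = 0.995,
    minCorrespondences = 4L,
    maxRansacIterations = 250L
  )
)

setValidity("MatchConfig", function(object) {
  msgs <- character(0)
  if (object@ratioThreshold <= 0 || object@ratioThreshold > 1)
    msgs <- c(msgs, "ratioThreshold must lie in (0, 1]")
  if (!object@geometricModel %in% c("homography", "affine", "similarity"))
    msgs <- c(msgs, "unknown geometricModel")
  if (object@ransacReprojThreshold <= 0)
    msgs <- c(msgs, "ransacReprojThreshold must be positive")
  if (object@ransacConfidence <= 0 || object@ransacConfidence >= 1)
    msgs <- c(msgs, "ransacConfidence must lie in (0, 1)")
  if (object@minCorrespondences < 1)
    msgs <- c(msgs, "minCorrespondences must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname MatchConfig-class
#' @param ratioThreshold,geometricModel,ransacReprojThreshold see slots.
#' @param ransacConfidence,minCorrespondences,maxRansacIterations see slots.
#' @return A \code{MatchConfig}.
#' @export
MatchConfig <- function(ratioThreshold = 0.7, geometricModel = "homography",
                        ransacReprojThreshold = 3.0,
                        ransacConfidence = 0.995, minCorrespondences = 4L,
                        maxRansacIterations = 250L) {
  new("MatchConfig", ratioThreshold = ratioThreshold,
      geometricModel = geometricModel,
      ransacReprojThreshold = ransacReprojThreshold,
      ransacConfidence = ransacConfidence,
      minCorrespondences = as.integer(minCorrespondences),
      maxRansacIterations = as.integer(maxRansacIterations))
}

#' MatchScore: bidirectional matching-point count
#'
#' Matching is performed twice — query against candidate and candidate
#' against query — and the two RANSAC-inlier counts are averaged.
#'
#' @slot forwardPoints inliers in the query-to-candidate direction.
#' @slot reversePoints inliers in the candidate-to-query direction.
#' @slot averagePoints their arithmetic mean (may end in .5).
#' @export
setClass("MatchScore",
  representation(forwardPoints = "integer", reversePoints = "integer",
                 averagePoints = "numeric"))

setValidity("MatchScore", function(object) {
  if (!isTRUE(all.equal(object@averagePoints,
                        (object@forwardPoints + object@reversePoints) / 2)))
    "averagePoints must equal (forward + reverse) / 2" else TRUE
})

#' @describeIn MatchScore forward-direction inlier count.
#' @param x a \code{MatchScore}.
#' @export
setMethod("forwardPoints", "MatchScore", function(x) x@forwardPoints)

#' @describeIn MatchScore reverse-direction inlier count.
#' @export
setMethod("reversePoints", "MatchScore", function(x) x@reversePoints)

#' @describeIn MatchScore averaged matching points.
#' @export
setMethod("averagePoints", "MatchScore", function(x) x@averagePoints)

setMethod("show", "MatchScore", function(object) {
  cat(sprintf("MatchScore: forward %d, reverse %d, average %.1f\n",
              object@forwardPoints, object@reversePoints,
              object@averagePoints))
})

# diagnostic counter for directed-match invocations
.match_counter <- new.env(parent = emptyenv())
.match_counter$n <- 0L

#' Count of directed-match invocations
#'
#' Diagnostic counter incremented by every [matchDirected()] call; used to
#' verify that search policies never score a database entry more than once.
#'
#' @param reset reset the counter to zero after reading?
#' @return The invocation count so far.
#' @export
matchCallCount <- function(reset = FALSE) {
  n <- .match_counter$n
  if (reset) .match_counter$n <- 0L
  n
}

# derive a bounded child seed from a master seed and a stream id
.deriveSeed <- function(seed, id) {
  as.integer((((as.numeric(seed) %% 2147483647) * 48271 +
                 as.numeric(id) * 7919 + 12345) %% 2147483646) + 1)
}

# ratio-test correspondences a -> b; returns index pairs (rows of a, b)
.ratioMatches <- function(qd, cd, ratio) {
  nq <- nrow(qd); nc <- nrow(cd)
  d2 <- matrix(rowSums(qd^2), nq, nc) +
    matrix(rowSums(cd^2), nq, nc, byrow = TRUE) -
    2 * tcrossprod(qd, cd)
  d2[d2 < 0] <- 0
  if (nc == 1L) {
    best <- rep(1L, nq)
    keep <- rep(TRUE, nq)  # no second neighbour: ratio test vacuous
    bestd <- d2[, 1]
  } else {
    best <- max.col(-d2, ties.method = "first")
    bestd <- d2[cbind(seq_len(nq), best)]
    d2[cbind(seq_len(nq), best)] <- Inf
    secondd <- d2[cbind(seq_len(nq), max.col(-d2, ties.method = "first"))]
    keep <- sqrt(bestd) <= ratio * sqrt(secondd)
  }
  qi <- which(keep)
  ci <- best[keep]
  dd <- bestd[keep]
  # enforce one-to-one on the candidate side: keep the closest pair
  o <- order(dd, qi)
  qi <- qi[o]; ci <- ci[o]
  dup <- duplicated(ci)
  cbind(query = qi[!dup], candidate = ci[!dup])
}

#' Directed matching-point count between two keypoint sets
#'
#' Nearest-neighbour descriptor correspondences (Euclidean metric, Lowe
#' ratio test, one-to-one on the candidate side) are verified with seeded
#' RANSAC under the configured geometric model; the returned score is the
#' inlier count. Fewer than \code{minCorrespondences} surviving pairs give
#' 0. Reproducible for a fixed seed.
#'
#' @param query,candidate [KeypointSet-class] objects.
#' @param cfg a [MatchConfig-class].
#' @param seed integer RANSAC seed.
#' @return Non-negative integer inlier count ("matching points").
#' @export
matchDirected <- function(query, candidate, cfg = MatchConfig(), seed = 1L) {
  stopifnot(is(query, "KeypointSet"), is(candidate, "KeypointSet"))
  .match_counter$n <- .match_counter$n + 1L
  if (nKeypoints(query) == 0L || nKeypoints(candidate) == 0L) return(0L)
  if (descriptorLength(query) != descriptorLength(candidate))
    stop("descriptor lengths differ (",
         descriptorLength(query), " vs ", descriptorLength(candidate), ")")
  pairs <- .ratioMatches(query@descriptors, candidate@descriptors,
                         cfg@ratioThreshold)
  if (nrow(pairs) < cfg@minCorrespondences) return(0L)
  pa <- as.matrix(query@keypoints[pairs[, 1], c("x", "y")])
  pb <- as.matrix(candidate@keypoints[pairs[, 2], c("x", "y")])
  res <- .ransac_geometric(pa, pb, cfg@geometricModel,
                           cfg@ransacReprojThreshold, cfg@ransacConfidence,
                           cfg@maxRansacIterations, seed)
  as.integer(res$inliers)
}

#' Bidirectional match score between two keypoint sets
#'
#' Runs [matchDirected()] in both directions with the same seed and
#' averages the two inlier counts, so
#' \code{scorePair(a, b)} and \code{scorePair(b, a)} have equal averages.
#'
#' @param a,b [KeypointSet-class] objects.
#' @param cfg a [MatchConfig-class].
#' @param seed integer seed used for both directions.
#' @return A [MatchScore-class].
#' @export
scorePair <- function(a, b, cfg = MatchConfig(), seed = 1L) {
  fwd <- matchDirected(a, b, cfg, seed)
  rev <- matchDirected(b, a, cfg, seed)
  new("MatchScore", forwardPoints = fwd, reversePoints = rev,
      averagePoints = (fwd + rev) / 2)
}

#' Rank database candidates against a query
#'
#' Scores every candidate entry with [scorePair()] (per-entry seeds derived
#' from the master seed) and sorts descending by average matching points,
#' ties broken by ascending entry id. The head of the result is the rank-1
#' identification candidate.
#'
#' @param query a [KeypointSet-class].
#' @param db a [FeatureDatabase-class].
#' @param candidates data.frame of candidate entries (as returned by
#'   [queryByAge()] or [dbEntries()]); \code{NULL} scores the whole
#'   database.
#' @param cfg a [MatchConfig-class].
#' @param seed master seed; entry seeds are derived per entry id.
#' @return data.frame with columns \code{entry_id}, \code{individual_id},
#'   \code{age_years}, \code{forward}, \code{reverse}, \code{average},
#'   \code{rank}.
#' @export
rankCandidates <- function(query, db, candidates = NULL,
                           cfg = MatchConfig(), seed = 1L) {
  stopifnot(is(query, "KeypointSet"), is(db, "FeatureDatabase"))
  if (is.null(candidates)) candidates <- dbEntries(db)
  n <- nrow(candidates)
  fwd <- integer(n); rev <- integer(n)
  for (i in seq_len(n)) {
    feats <- entryFeatures(db, candidates$entry_id[i])
    s <- .deriveSeed(seed, candidates$entry_id[i])
    fwd[i] <- matchDirected(query, feats, cfg, s)
    rev[i] <- matchDirected(feats, query, cfg, s)
  }
  out <- data.frame(entry_id = candidates$entry_id,
                    individual_id = candidates$individual_id,
                    age_years = candidates$age_years,
                    forward = fwd, reverse = rev,
                    average = (fwd + rev) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$average, out$entry_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
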