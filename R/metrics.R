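#' EvaluationMetrics: accuracy statistics for age predictions
#'
#' Summary of predicted-versus-actual ages: mean absolute error (MAE), mean
#' signed error, SD and SE of the absolute errors, a normal-approximation
#' 95% confidence interval for the MAE, root mean squared error, the
#' coefficient of determination against the actual ages, and success rates
#' (percentage of predictions within a tolerance) for a set of tolerances.
#'
#' @slot mae mean absolute error, years.
#' @slot signedMeanError mean of (predicted - actual), years.
#' @slot sd standard deviation of the absolute errors, years.
#' @slot se standard error of the MAE, years.
#' @slot ci95 numeric(2): mae +/- 1.96 se.
#' @slot rmse root mean squared error, years.
#' @slot rSquared 1 - SS_res / SS_tot.
#' @slot successRate named numeric: tolerance (years) -> percent within.
#' @slot n number of prediction pairs.
#' @export
setClass("EvaluationMetrics",
  representation(mae = "numeric", signedMeanError = "numeric",
                 sd = "numeric", se = "numeric", ci95 = "numeric",
                 rmse = "numeric", rSquared = "numeric",
                 successRate = "numeric", n = "integer"))

setMethod("show", "EvaluationMetrics", function(object) {
  cat(sprintf(
    "EvaluationMetrics (n = %d)\n  MAE %.2f +/- %.2f years (95%% CI %.2f, %.2f)\n",
    object@n, object@mae, object@sd, object@ci95[1], object@ci95[2]))
  cat(sprintf("  signed mean error %.2f, RMSE %.2f, R^2 %.3f\n",
              object@signedMeanError, object@rmse, object@rSquared))
  sr <- paste(sprintf("±%s: %.1f%%", names(object@successRate),
                      object@successRate), collapse = "  ")
  cat("  success rates ", sr, "\n", sep = "")
})

#' Evaluate age predictions against actual ages
#'
#' @param predicted,actual equal-length numeric vectors of ages in years.
#' @param tolerances tolerances (years) for the success rates
#'   (default 5, 10, 15, 20).
#' @return An [EvaluationMetrics-class].
#' @examples
#' m <- evaluatePredictions(c(3, 5), c(1, 5))
#' m@mae          # 1.0
#' m@successRate  # 100% within every tolerance
#' @export
evaluatePredictions <- function(predicted, actual,
                                tolerances = c(5, 10, 15, 20)) {
  if (length(predicted) != length(actual) || length(actual) == 0L)
    stop("predicted and actual must have equal, non-zero length")
  err <- predicted - actual
  aerr <- abs(err)
  n <- length(err)
  mae <- mean(aerr)
  sdv <- if (n > 1) stats::sd(aerr) else 0
  se <- sdv / sqrt(n)
  ssTot <- sum((actual - mean(actual))^2)
  r2 <- if (ssTot > 0) 1 - sum(err^2) / ssTot else NA_real_
  sr <- vapply(tolerances, function(t) 100 * mean(aerr <= t), numeric(1))
  names(sr) <- as.character(tolerances)
  new("EvaluationMetrics", mae = mae, signedMeanError = mean(err),
      sd = sdv, se = se, ci95 = c(mae - 1.96 * se, mae + 1.96 * se),
      rmse = sqrt(mean(err^2)), rSquared = r2, successRate = sr,
      n = as.integer(n))
}

#' Age-stratified evaluation
#'
#' Assigns every prediction pair to one age group by the actual age (bins
#' are \code{[edge_i, edge_{i+1})}; the last bin includes its upper edge)
#' and evaluates each group separately. Pairs outside the bin range are
#' collected in an \code{overflow} group.
#'
#' @inheritParams evaluatePredictions
#' @param binEdges ascending bin edges in years
#'   (default \code{c(2, 10, 20, ..., 90)}, the decade groups 2-9 up to
#'   80-89).
#' @return data.frame with one row per non-empty group: \code{group},
#'   \code{n}, \code{mae}, \code{sd}, \code{se}, \code{ci_low},
#'   \code{ci_high}, and one \code{success_*} column per tolerance.
#' @export
stratifyByAge <- function(predicted, actual,
                          binEdges = c(2, seq(10, 90, by = 10)),
                          tolerances = c(5, 10, 15, 20)) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (any(diff(binEdges) <= 0)) stop("binEdges must be ascending")
  k <- length(binEdges) - 1L
  idx <- findInterval(actual, binEdges, rightmost.closed = TRUE)
  labels <- sprintf("%g-%g", binEdges[-length(binEdges)],
                    binEdges[-1] - 1)
  rows <- list()
  for (b in c(seq_len(k), 0L)) {
    sel <- if (b == 0L) idx < 1 | idx > k else idx == b
    if (!any(sel)) next
    m <- evaluatePredictions(predicted[sel], actual[sel], tolerances)
    row <- data.frame(group = if (b == 0L) "overflow" else labels[b],
                      n = m@n, mae = m@mae, sd = m@sd, se = m@se,
                      ci_low = m@ci95[1], ci_high = m@ci95[2],
                      stringsAsFactors = FALSE)
    for (t in tolerances)
      row[[paste0("success_", t)]] <- m@successRate[[as.character(t)]]
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize identification outcomes
#'
#' An identification succeeds when the rank-1 (highest average matching
#' points) entry belongs to the searched individual; a report with no
#' ranked candidates counts as a failure. Evaluated-row fractions are
#' aggregated as mean and SD.
#'
#' @param reports named list of [SearchReport-class] objects; names are
#'   query ids.
#' @param truth named character vector mapping query id to the true
#'   individual id; every report must have a truth entry.
#' @return One-row data.frame with \code{n}, \code{successes},
#'   \code{success_rate} (percent), \code{mean_fraction_evaluated},
#'   \code{sd_fraction_evaluated}.
#' @export
identificationSummary <- function(reports, truth) {
  if (is(reports, "SearchReport")) reports <- list(reports)
  ids <- names(reports)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("reports must be a named list (query ids)")
  missing <- setdiff(ids, names(truth))
  if (length(missing))
    stop("missing truth for queries: ", paste(missing, collapse = ", "))
  ok <- vapply(ids, function(q) {
    r <- rankedCandidates(reports[[q]])
    nrow(r) > 0 && r$individual_id[1] == truth[[q]]
  }, logical(1))
  fr <- vapply(reports, fractionEvaluated, numeric(1))
  data.frame(n = length(ok), successes = sum(ok),
             success_rate = 100 * mean(ok),
             mean_fraction_evaluated = mean(fr),
             sd_fraction_evaluated = if (length(fr) > 1) stats::sd(fr)
                                     else 0)
}
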