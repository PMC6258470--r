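#' @include AllClasses.R
NULL

#' Construct a decoy set
#'
#' @param targetId character(1).
#' @param records data.frame with columns \code{decoyId}, \code{rmsd}
#'   (Angstrom to native), \code{score} (predicted global score).
#' @param nativeId decoyId of the native record, or NA.
#' @return a \code{\link{DecoySet}}.
#' @export
decoySet <- function(targetId, records, nativeId = NA_character_) {
  records$decoyId <- as.character(records$decoyId)
  new("DecoySet", targetId = targetId,
      records = records[, c("decoyId", "rmsd", "score")],
      nativeId = as.character(nativeId))
}

#' Enrichment Score of a decoy set
#'
#' Overlap statistic between the best-scored decile and the lowest-RMSD
#' decile: with \code{k = floor(0.1 N)} structures in each decile,
#' \code{ES = |intersection| / (0.1 * 0.1 * N)}. A perfectly rank-correlated
#' scoring gives ES = 10, an uninformative one gives ES = 1 in expectation
#' (hypergeometric mean k^2/N over the 0.01 N denominator), and ES below 1
#' indicates anti-correlation. Ties at the decile boundary are broken by
#' \code{decoyId} lexicographic order so the statistic is deterministic.
#'
#' @param decoys a \code{\link{DecoySet}} (or its records data.frame) with
#'   at least 10 records.
#' @return list with \code{es}, \code{k}, \code{intersectionSize},
#'   \code{nDecoys}.
#' @examples
#' r <- data.frame(decoyId = sprintf("d%03d", 1:100), rmsd = 1:100,
#'                 score = 1:100)
#' enrichmentScore(decoySet("t", r))$es   # 10
#' @export
enrichmentScore <- function(decoys) {
  r <- if (is(decoys, "DecoySet")) decoys@records else decoys
  n <- nrow(r)
  if (n < 10L) stop("Enrichment Score needs at least 10 decoys, got ", n)
  k <- floor(0.1 * n)
  byScore <- r$decoyId[order(r$score, r$decoyId)][seq_len(k)]
  byRmsd <- r$decoyId[order(r$rmsd, r$decoyId)][seq_len(k)]
  inter <- length(intersect(byScore, byRmsd))
  list(es = inter / (0.1 * 0.1 * n), k = k, intersectionSize = inter,
       nDecoys = n)
}

#' Count natives identified across decoy sets
#'
#' A target counts as identified iff its native record has the strict
#' minimum global score in the set; a tie with any decoy is conservative
#' (not identified) and recorded in the detail table.
#'
#' @param decoySets list of \code{\link{DecoySet}}s, each with its native
#'   flagged.
#' @return list with \code{identified}, \code{total} and a \code{detail}
#'   data.frame (targetId, nativeScore, bestOtherScore, identified, tied).
#' @export
countNativeIdentified <- function(decoySets) {
  detail <- do.call(rbind, lapply(decoySets, function(ds) {
    stopifnot(is(ds, "DecoySet"))
    if (is.na(ds@nativeId))
      stop("decoy set ", ds@targetId, " has no native flagged")
    r <- ds@records
    nativeScore <- r$score[r$decoyId == ds@nativeId]
    others <- r$score[r$decoyId != ds@nativeId]
    bestOther <- if (length(others)) min(others) else Inf
    data.frame(targetId = ds@targetId, nativeScore = nativeScore,
               bestOtherScore = bestOther,
               identified = nativeScore < bestOther,
               tied = nativeScore == bestOther,
               stringsAsFactors = FALSE)
  }))
  rownames(detail) <- NULL
  list(identified = sum(detail$identified), total = nrow(detail),
       detail = detail)
}

#' Pearson correlation between actual and predicted unfitness
#'
#' Standard product-moment coefficient via \code{stats::cor}, with guards
#' for degenerate input.
#'
#' @param actual,predicted numeric vectors of equal length >= 3.
#' @return numeric(1) in [-1, 1].
#' @export
labelPredictionCorrelation <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (length(actual) < 3L) stop("need at least 3 pairs")
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("zero variance in actual or predicted scores")
  stats::cor(actual, predicted)
}
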