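#' Maximal tail score
#'
#' The greatest tail-injury score (0-4) a pig received at any assessment.
#'
#' @param scores Integer vector of a single pig's scores.
#' @return Integer in 0-4.
#' @export
max_tail_score <- function(scores) {
  if (!length(scores)) stop("no scores for pig", call. = FALSE)
  if (any(!(scores %in% 0:4))) {
    stop("scores must lie in 0-4", call. = FALSE)
  }
  as.integer(max(scores))
}

#' Victimization status
#'
#' A pig is a victim of tail biting when its maximal tail score is 2 or
#' greater, i.e. it showed observable blood on the tail at least once.
#'
#' @param mts Maximal tail score(s), integer 0-4.
#' @return Logical vector.
#' @export
classify_victim <- function(mts) {
  if (any(!(mts %in% 0:4))) stop("MTS must lie in 0-4", call. = FALSE)
  mts >= 2
}

mts_class_levels <- c("0", "1", ">=2")

mts_class <- function(mts) {
  factor(ifelse(mts >= 2, ">=2", as.character(mts)),
         levels = mts_class_levels)
}

#' Score tails: per-pig MTS, class, and victim flag
#'
#' @param scores Tail-score data frame
#'   (`pig_id,assessment_index,score`).
#' @return Data frame with one row per pig: `pig_id`, `mts`, `mts_class`
#'   (factor `0`/`1`/`>=2`), `victim`.
#' @export
score_tails <- function(scores) {
  sp <- split(scores$score, scores$pig_id)
  mts <- vapply(sp, max_tail_score, integer(1))
  data.frame(
    pig_id = names(sp),
    mts = mts,
    mts_class = mts_class(mts),
    victim = classify_victim(mts),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Treatment-by-MTS-class contingency table
#'
#' Counts pigs in each litter-origin treatment falling into the MTS classes
#' 0, 1, and >= 2.
#'
#' @param mts_df Output of [score_tails()].
#' @param roster Data frame with `pig_id` and `treatment`.
#' @return Contingency table (treatments x classes).
#' @export
mts_class_table <- function(mts_df, roster) {
  tr <- roster$treatment[match(mts_df$pig_id, roster$pig_id)]
  if (anyNA(tr)) {
    stop(sprintf("pig(s) missing a treatment: %s",
                 paste(utils::head(mts_df$pig_id[is.na(tr)], 5L),
                       collapse = ", ")), call. = FALSE)
  }
  table(treatment = factor(tr, levels = unique(roster$treatment)),
        mts_class = mts_df$mts_class)
}

#' Pearson chi-square test on a contingency table
#'
#' \eqn{X^2 = \sum (O - E)^2 / E} with expected counts from the row and
#' column margins, `df = (r-1)(c-1)`, upper-tail chi-square p-value, and no
#' continuity correction.
#'
#' @param tab Contingency table or count matrix.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin: expected counts undefined",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Median and interquartile range
#'
#' Median by midpoint of order statistics; quartiles by linear
#' interpolation between order statistics at positions
#' `0.25(n-1)+1` and `0.75(n-1)+1` (the default sample-quantile
#' convention, `type = 7`).  The convention is configurable because
#' quartiles of small ordinal samples depend on it.
#'
#' @param values Numeric vector.
#' @param type Sample-quantile type passed to [stats::quantile()].
#' @return Named vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values, type = 7) {
  if (!length(values)) stop("empty value set", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
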