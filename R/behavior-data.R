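#' @title CSV schemas for behavioral observations
#' @description
#' Three long-format UTF-8 CSV schemas (header required) carry all
#' observations:
#' \itemize{
#'   \item scans: `pen_id,period,scan_index,pig_id,lying,partners`
#'     (`partners` semicolon-separated, empty allowed);
#'   \item bites: `pen_id,period,timestamp_min,biter,recipient`;
#'   \item tail scores: `pig_id,assessment_index,score`.
#' }
#' `read_*` functions validate on read and fail with the offending row
#' number; `write_*` functions are exact inverses so that
#' `read(write(x))` is the identity.
#' @name behavior-io
NULL

scan_cols <- c("pen_id", "period", "scan_index", "pig_id", "lying",
               "partners")
bite_cols <- c("pen_id", "period", "timestamp_min", "biter", "recipient")
score_cols <- c("pig_id", "assessment_index", "score")

check_header <- function(df, expected, path) {
  if (!identical(names(df), expected)) {
    stop(sprintf("'%s': expected header %s, found %s", path,
                 paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
}

#' Read scan-sampled lying observations
#'
#' @param path CSV path (schema in [behavior-io]).
#' @return Validated scan-record data frame.
#' @export
read_scans <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    pen_id = "character", period = "integer", scan_index = "integer",
    pig_id = "character", lying = "integer", partners = "character"
  ), na.strings = NULL)
  check_header(df, scan_cols, path)
  validate_scans(df, path)
  df
}

validate_scans <- function(df, path = "<scans>") {
  bad <- which(is.na(df$lying) | !(df$lying %in% c(0L, 1L)) |
                 is.na(df$period) | is.na(df$scan_index) |
                 df$pig_id == "" | df$pen_id == "")
  if (length(bad)) {
    stop(sprintf("'%s': malformed row(s) at line(s) %s", path,
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  has_partner <- df$partners != ""
  bad <- which(has_partner & df$lying == 0L)
  if (length(bad)) {
    stop(sprintf(
      "'%s': pig with partners but lying = 0 at line(s) %s", path,
      paste(utils::head(bad + 1L, 5L), collapse = ", ")), call. = FALSE)
  }
  plist <- strsplit(df$partners, ";", fixed = TRUE)
  self <- which(mapply(function(p, id) id %in% p, plist, df$pig_id))
  if (length(self)) {
    stop(sprintf("'%s': pig listed as its own partner at line(s) %s", path,
                 paste(utils::head(self + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  # partnership symmetry within each scan
  n_part <- lengths(plist)
  idx <- rep.int(seq_len(nrow(df)), n_part)
  if (length(idx)) {
    key_fwd <- paste(df$pen_id[idx], df$period[idx], df$scan_index[idx],
                     df$pig_id[idx], unlist(plist), sep = "\r")
    key_rev <- paste(df$pen_id[idx], df$period[idx], df$scan_index[idx],
                     unlist(plist), df$pig_id[idx], sep = "\r")
    miss <- which(!(key_rev %in% key_fwd))
    if (length(miss)) {
      stop(sprintf("'%s': asymmetric lying-together partnership at line(s) %s",
                   path,
                   paste(utils::head(unique(idx[miss]) + 1L, 5L),
                         collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}

#' @rdname read_scans
#' @param records Scan-record data frame.
#' @export
write_scans <- function(records, path) {
  utils::write.csv(records[, scan_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read/write tail-biting events
#'
#' @param path CSV path (schema in [behavior-io]).
#' @return Validated bite-event data frame.
#' @export
read_bites <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    pen_id = "character", period = "integer", timestamp_min = "numeric",
    biter = "character", recipient = "character"
  ), na.strings = NULL)
  check_header(df, bite_cols, path)
  bad <- which(df$biter == df$recipient | df$biter == "" |
                 df$recipient == "" | is.na(df$period))
  if (length(bad)) {
    stop(sprintf("'%s': malformed bite event at line(s) %s", path,
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' @rdname read_bites
#' @param events Bite-event data frame.
#' @export
write_bites <- function(events, path) {
  utils::write.csv(events[, bite_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read/write tail-injury scores
#'
#' @param path CSV path (schema in [behavior-io]).
#' @return Validated tail-score data frame.
#' @export
read_tail_scores <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    pig_id = "character", assessment_index = "integer", score = "integer"
  ), na.strings = NULL)
  check_header(df, score_cols, path)
  bad <- which(is.na(df$score) | !(df$score %in% 0:4))
  if (length(bad)) {
    stop(sprintf("'%s': tail score outside 0-4 at line(s) %s", path,
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' @rdname read_tail_scores
#' @param scores Tail-score data frame.
#' @export
write_tail_scores <- function(scores, path) {
  utils::write.csv(scores[, score_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Build per-scan binary lying-together matrices for one pen-period
#'
#' Converts long-format scan records into one symmetric binary pair matrix
#' and one 0/1 lying vector per scan instant, in scan order.  Pig order is
#' lexicographic by `pig_id` and fixed across scans.
#'
#' @param records Scan-record data frame.
#' @param pen_id,period Pen and observation period to extract.
#' @return A list of class `scan_matrices`; each element is
#'   `list(pair = <k x k binary matrix>, lying = <0/1 vector>)`.  The pig
#'   order is attached as attribute `pigs`, `pen_id`/`period` as attributes.
#' @export
build_scan_matrices <- function(records, pen_id, period) {
  sub <- records[records$pen_id == pen_id & records$period == period, ,
                 drop = FALSE]
  if (!nrow(sub)) stop("no records for that pen and period", call. = FALSE)
  pigs <- sort(unique(sub$pig_id))
  scans <- sort(unique(sub$scan_index))
  k <- length(pigs)
  # completeness: every pig at every scan
  have <- table(factor(sub$scan_index, levels = scans),
                factor(sub$pig_id, levels = pigs))
  if (any(have != 1L)) {
    miss <- which(have != 1L, arr.ind = TRUE)
    stop(sprintf("incomplete scans for pen %s period %s: %s", pen_id, period,
                 paste(sprintf("(scan %s, pig %s)",
                               scans[miss[, 1]], pigs[miss[, 2]])[
                                 seq_len(min(5L, nrow(miss)))],
                       collapse = ", ")), call. = FALSE)
  }
  out <- vector("list", length(scans))
  for (s in seq_along(scans)) {
    rows <- sub[sub$scan_index == scans[s], , drop = FALSE]
    rows <- rows[match(pigs, rows$pig_id), , drop = FALSE]
    M <- matrix(0L, k, k, dimnames = list(pigs, pigs))
    plist <- strsplit(rows$partners, ";", fixed = TRUE)
    for (a in seq_len(k)) {
      b <- match(plist[[a]], pigs)
      if (anyNA(b)) {
        stop(sprintf("unknown partner id in pen %s period %s scan %s",
                     pen_id, period, scans[s]), call. = FALSE)
      }
      M[a, b] <- 1L
    }
    if (!identical(M, t(M))) {
      stop(sprintf("asymmetric lying-together matrix at scan %s", scans[s]),
           call. = FALSE)
    }
    lying <- as.integer(rows$lying)
    names(lying) <- pigs
    out[[s]] <- list(pair = M, lying = lying)
  }
  structure(out, class = "scan_matrices", pigs = pigs, pen_id = pen_id,
            period = period)
}

#' Aggregate per-scan matrices over an observation period
#'
#' Element-wise sums of the binary pair matrices and lying vectors: `x(a,b)`
#' counts scans in which pigs a and b lay together, `n(a)` counts scans in
#' which pig a lay — the quantities entering the half-weight association
#' index.
#'
#' @param mats A `scan_matrices` list (or plain list of
#'   `list(pair, lying)`).
#' @param pen_id,period Carried into the result; defaults taken from the
#'   attributes of `mats` when present.
#' @return An object of class `lying_aggregate`: list with `pen_id`,
#'   `period`, `x` (symmetric integer matrix), `n` (integer vector),
#'   `scans_total`.
#' @export
aggregate_scans <- function(mats, pen_id = attr(mats, "pen_id"),
                            period = attr(mats, "period")) {
  if (!length(mats)) stop("empty scan-matrix list", call. = FALSE)
  dims <- vapply(mats, function(m) nrow(m$pair), integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(mats, function(m) length(m$lying), integer(1)) != dims[1])) {
    stop("inconsistent matrix dimensions", call. = FALSE)
  }
  x <- Reduce(`+`, lapply(mats, `[[`, "pair"))
  n <- Reduce(`+`, lapply(mats, `[[`, "lying"))
  agg <- structure(list(pen_id = pen_id, period = period, x = x, n = n,
                        scans_total = length(mats)),
                   class = "lying_aggregate")
  validate_lying_aggregate(agg)
  agg
}

validate_lying_aggregate <- function(agg) {
  x <- agg$x; n <- agg$n
  if (!isTRUE(all.equal(x, t(x))) || any(diag(x) != 0)) {
    stop("aggregate matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  if (any(n > agg$scans_total) || any(n < 0)) {
    stop("lying counts exceed total scans", call. = FALSE)
  }
  lim <- outer(n, n, pmin)
  if (any(x > lim)) {
    stop("x(a,b) exceeds min(n(a), n(b))", call. = FALSE)
  }
  invisible(agg)
}

#' @export
print.lying_aggregate <- function(x, ...) {
  cat(sprintf("Lying aggregate, pen %s period %s: %d pigs, %d scans\n",
              x$pen_id, x$period, nrow(x$x), x$scans_total))
  invisible(x)
}

#' Aggregate all pen-periods of a scan table
#'
#' @param records Scan-record data frame.
#' @return List of [aggregate_scans()] results, one per pen-period present,
#'   named `"<pen_id>:<period>"`.
#' @export
aggregate_all_scans <- function(records) {
  combos <- unique(records[, c("pen_id", "period")])
  combos <- combos[order(combos$pen_id, combos$period), , drop = FALSE]
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    out[[i]] <- aggregate_scans(
      build_scan_matrices(records, combos$pen_id[i], combos$period[i]))
  }
  names(out) <- paste(combos$pen_id, combos$period, sep = ":")
  out
}

#' Lying-time budget
#'
#' Percent of scans a pig was observed lying during one observation period.
#'
#' @param agg A `lying_aggregate`.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
lying_time_budget <- function(agg) {
  if (!inherits(agg, "lying_aggregate")) stop("need a lying_aggregate")
  if (agg$scans_total == 0) stop("scans_total is zero", call. = FALSE)
  100 * agg$n / agg$scans_total
}

#' Export a square matrix with pig ids on both margins
#'
#' @param m Matrix with `dimnames`.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
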