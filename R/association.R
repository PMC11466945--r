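#' Half-weight association index
#'
#' The HWI for a dyad is \deqn{HWI = \frac{x}{(n_a + n_b)/2}} where `x` is
#' the number of scans the two pigs were lying together and `n_a`, `n_b`
#' the numbers of scans each was lying over the same observation period.
#' It corrects the raw co-occurrence count for the time each member was
#' observable in the lying state and ranges from 0 (never together) to 1
#' (together whenever either was lying).
#'
#' When `n_a + n_b = 0` (neither pig ever lay) the index is defined as 0
#' rather than NaN, which keeps downstream network metrics total.
#'
#' All arguments are vectorized.
#'
#' @param x Count of scans lying together.
#' @param n_a,n_b Counts of scans each pig was lying.
#' @return HWI value(s) in `[0, 1]`.
#' @export
half_weight_index <- function(x, n_a, n_b) {
  if (any(x < 0 | n_a < 0 | n_b < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(x > pmin(n_a, n_b))) {
    stop("x cannot exceed min(n_a, n_b)", call. = FALSE)
  }
  denom <- (n_a + n_b) / 2
  ifelse(denom == 0, 0, x / denom)
}

#' Build an undirected HWI-weighted association network
#'
#' Applies [half_weight_index()] to every dyad of a lying aggregate.
#'
#' @param agg A `lying_aggregate` (see [aggregate_scans()]).
#' @return Object of class `association_network`: list with `pen_id`,
#'   `period`, `nodes` (ordered pig ids) and `W`, the symmetric HWI matrix
#'   with zero diagonal.
#' @export
build_association_network <- function(agg) {
  validate_lying_aggregate(agg)
  n <- agg$n
  denom <- outer(n, n, "+") / 2
  W <- ifelse(denom == 0, 0, agg$x / denom)
  diag(W) <- 0
  dimnames(W) <- dimnames(agg$x)
  structure(list(pen_id = agg$pen_id, period = agg$period,
                 nodes = rownames(W), W = W),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("Association network, pen %s period %s: %d pigs, mean HWI %.3f\n",
              x$pen_id, x$period, length(x$nodes),
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

#' Export a network as a weighted edge list CSV
#'
#' Undirected networks are written as `pig_a,pig_b,hwi` over the upper
#' triangle; directed networks as `biter,recipient,count` over all nonzero
#' arcs.
#'
#' @param net An `association_network` or `bite_network`.
#' @param path Output CSV path.
#' @param keep_zero Keep zero-weight dyads (default `FALSE`).
#' @export
write_edge_list <- function(net, path, keep_zero = FALSE) {
  if (inherits(net, "association_network")) {
    idx <- which(upper.tri(net$W), arr.ind = TRUE)
    df <- data.frame(pig_a = net$nodes[idx[, 1]],
                     pig_b = net$nodes[idx[, 2]],
                     hwi = net$W[idx], stringsAsFactors = FALSE)
    if (!keep_zero) df <- df[df$hwi > 0, , drop = FALSE]
  } else if (inherits(net, "bite_network")) {
    idx <- which(net$A >= 0 & row(net$A) != col(net$A), arr.ind = TRUE)
    df <- data.frame(biter = net$nodes[idx[, 1]],
                     recipient = net$nodes[idx[, 2]],
                     count = net$A[idx], stringsAsFactors = FALSE)
    if (!keep_zero) df <- df[df$count > 0, , drop = FALSE]
  } else {
    stop("unsupported network type", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
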