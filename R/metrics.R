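#' @title Graph-metric engine for small weighted pen networks
#' @description
#' Density, node strength, Brandes betweenness centrality and Freeman-style
#' centralizations for the small (typically 8-node) weighted networks that
#' arise from pen observations.  All metrics are implemented directly on
#' adjacency matrices so each can be verified against brute-force
#' enumeration oracles; `igraph` is used only as an independent
#' cross-check in the test suite, never in the computation itself.
#'
#' Conventions shared by all functions:
#' \itemize{
#'   \item an edge/arc is present iff its weight is `> 0`;
#'   \item undirected networks are stored as symmetric matrices;
#'   \item an edgeless network has density 0 and all centralizations 0
#'     (vacuous spread), keeping sparse aggregated bite pens in-frame;
#'   \item weighted shortest paths use edge length `1/weight`, the standard
#'     strength-to-length inversion, so strong associations are short.
#' }
#' @name graph-metrics
NULL

check_adjacency <- function(A, directed) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (any(A < 0)) stop("negative edge weight", call. = FALSE)
  if (any(diag(A) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (!directed && !isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("undirected adjacency must be symmetric", call. = FALSE)
  }
  invisible(A)
}

#' Network density
#'
#' Fraction of realized dyads: edges with weight > 0 divided by
#' `n(n-1)/2` (undirected) or ordered pairs `n(n-1)` (directed).
#'
#' @param A Square adjacency matrix with zero diagonal.
#' @param directed Directed network?
#' @return Density in `[0, 1]`.
#' @export
net_density <- function(A, directed = FALSE) {
  check_adjacency(A, directed)
  n <- nrow(A)
  if (n < 2L) stop("density undefined for n < 2", call. = FALSE)
  E <- A > 0
  if (directed) sum(E) / (n * (n - 1)) else sum(E) / (n * (n - 1))
}

#' Node strength (weighted degree)
#'
#' Sum of a node's edge weights.  For an undirected HWI network this is the
#' sum of a pig's association indices with all pen-mates; for a directed
#' bite network, `mode = "in"` is the total number of bites received
#' (column sums) and `mode = "out"` the total performed (row sums).
#'
#' @param A Adjacency matrix.
#' @param mode `"total"` (row sums of a symmetric matrix), `"in"`, or
#'   `"out"`.
#' @return Named numeric vector.
#' @export
node_strength <- function(A, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  switch(mode,
         total = rowSums(A),
         out = rowSums(A),
         `in` = colSums(A))
}

#' Unweighted degree
#'
#' Number of distinct neighbors (edges with weight > 0).
#'
#' @inheritParams node_strength
#' @return Named integer vector.
#' @export
node_degree <- function(A, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  node_strength((A > 0) + 0, mode)
}

# Brandes' accumulation over ordered source-target pairs on a directed
# length matrix (L[i,j] = edge length, Inf = no arc).  Returns the
# directed-pair betweenness; callers halve it for undirected graphs.
brandes_directed <- function(L, tol = 1e-10) {
  n <- nrow(L)
  B <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_settled <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_settled <- c(order_settled, v)
      nb <- which(is.finite(L[v, ]) & !done)
      for (w in nb) {
        alt <- dist[v] + L[v, w]
        if (alt < dist[w] - tol) {
          dist[w] <- alt
          sigma[w] <- sigma[v]
          preds[[w]] <- v
        } else if (abs(alt - dist[w]) <= tol) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_settled)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) B[w] <- B[w] + delta[w]
    }
  }
  B
}

#' Betweenness centrality
#'
#' Unnormalized betweenness \eqn{B(v) = \sum_{s \ne v \ne t}
#' \sigma_{st}(v)/\sigma_{st}}, summed over unordered pairs for undirected
#' networks and ordered pairs for directed ones.  All shortest paths are
#' counted fractionally; pairs with no connecting path contribute zero.
#' Edge lengths are 1 (unweighted) or `1/weight` (weighted).
#'
#' @param A Adjacency matrix (weights, or any nonzero pattern if
#'   unweighted).
#' @param directed Directed network?
#' @param weighted Use `1/weight` edge lengths?
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(A, directed = FALSE, weighted = FALSE) {
  check_adjacency(A, directed)
  L <- matrix(Inf, nrow(A), ncol(A))
  if (weighted) {
    L[A > 0] <- 1 / A[A > 0]
  } else {
    L[A > 0] <- 1
  }
  B <- brandes_directed(L)
  if (!directed) B <- B / 2
  names(B) <- rownames(A)
  B
}

#' Freeman degree centralization
#'
#' \deqn{C = \frac{\sum_v (d_{max} - d(v))}{D_{max}}} on unweighted degrees
#' (edge present iff weight > 0) by default, with the star-graph maximum
#' \eqn{D_{max} = (n-1)(n-2)} for undirected networks and \eqn{(n-1)^2} for
#' directed in- or out-degree, so a star (in-star/out-star) scores exactly
#' 1 and a complete network 0.  With `weighted = TRUE` the same spread is
#' computed on strengths, normalized by the star of the same size with all
#' edges at the observed maximum weight.
#'
#' @param A Adjacency matrix.
#' @param directed Directed network?
#' @param mode Degree mode; `"total"` for undirected, `"in"`/`"out"` for
#'   directed.
#' @param weighted Use strengths instead of binary degrees?
#' @return Centralization in `[0, 1]`.
#' @export
degree_centralization <- function(A, directed = FALSE,
                                  mode = c("total", "in", "out"),
                                  weighted = FALSE) {
  mode <- match.arg(mode)
  check_adjacency(A, directed)
  n <- nrow(A)
  if (n < 3L) stop("centralization undefined for n < 3", call. = FALSE)
  if (!directed && mode != "total") {
    stop("undirected networks have only total degree", call. = FALSE)
  }
  d <- if (weighted) node_strength(A, mode) else node_degree(A, mode)
  if (all(d == 0)) return(0)
  dmax_graph <- if (directed) (n - 1)^2 else (n - 1) * (n - 2)
  scale <- if (weighted) max(A) else 1
  sum(max(d) - d) / (dmax_graph * scale)
}

#' Freeman betweenness centralization
#'
#' \deqn{C = \frac{\sum_v (B_{max} - B(v))}{D_{max}}} with unnormalized
#' betweenness values and the star-graph maximum
#' \eqn{D_{max} = (n-1)^2(n-2)/2} (undirected) or \eqn{(n-1)^2(n-2)}
#' (directed), so an undirected star scores exactly 1.
#'
#' @inheritParams betweenness_centrality
#' @return Centralization in `[0, 1]`.
#' @export
betweenness_centralization <- function(A, directed = FALSE,
                                       weighted = FALSE) {
  check_adjacency(A, directed)
  n <- nrow(A)
  if (n < 3L) stop("centralization undefined for n < 3", call. = FALSE)
  if (all(A == 0)) return(0)
  B <- betweenness_centrality(A, directed = directed, weighted = weighted)
  dmax <- if (directed) (n - 1)^2 * (n - 2) else (n - 1)^2 * (n - 2) / 2
  sum(max(B) - B) / dmax
}

#' Pen-level metric set
#'
#' Dispatches the metric battery by network type.  Association networks
#' (undirected, HWI-weighted) yield density, degree centralization and
#' betweenness centralization; tail-biting networks (directed) yield
#' density, in- and out-degree centralization and betweenness
#' centralization.
#'
#' Defaults follow the classical Freeman definitions: centralization on
#' unweighted degrees (set `weighted_centralization = TRUE` for the
#' strength-based variant, which is the informative one for dense HWI
#' networks), betweenness over `1/HWI` path lengths for association
#' networks and unweighted paths for the sparse bite networks
#' (`betweenness_weighted` overrides).
#'
#' @param net An `association_network` or `bite_network`.
#' @param weighted_centralization Strength-based degree centralization?
#' @param betweenness_weighted `NULL` for the type default, else logical.
#' @return One-row data frame (a pen-metric set).
#' @export
pen_metrics <- function(net, weighted_centralization = FALSE,
                        betweenness_weighted = NULL) {
  if (inherits(net, "association_network")) {
    bw <- if (is.null(betweenness_weighted)) TRUE else betweenness_weighted
    data.frame(
      pen_id = net$pen_id,
      period = net$period,
      density = net_density(net$W, directed = FALSE),
      degree_centralization = degree_centralization(
        net$W, directed = FALSE, weighted = weighted_centralization),
      betweenness_centralization = betweenness_centralization(
        net$W, directed = FALSE, weighted = bw),
      stringsAsFactors = FALSE
    )
  } else if (inherits(net, "bite_network")) {
    bw <- if (is.null(betweenness_weighted)) FALSE else betweenness_weighted
    data.frame(
      pen_id = net$pen_id,
      periods = paste(net$periods, collapse = "+"),
      density = net_density(net$A, directed = TRUE),
      in_degree_centralization = degree_centralization(
        net$A, directed = TRUE, mode = "in",
        weighted = weighted_centralization),
      out_degree_centralization = degree_centralization(
        net$A, directed = TRUE, mode = "out",
        weighted = weighted_centralization),
      betweenness_centralization = betweenness_centralization(
        net$A, directed = TRUE, weighted = bw),
      stringsAsFactors = FALSE
    )
  } else {
    stop("unsupported network type", call. = FALSE)
  }
}

#' Pig-level metric set
#'
#' Association networks: strength (sum of HWI values with all pen-mates)
#' and betweenness centrality.  Bite networks: weighted in-/out-strength
#' (bites received/performed), unweighted in-/out-degree (number of
#' distinct biters/victims) and betweenness centrality.
#'
#' @inheritParams pen_metrics
#' @return Data frame, one row per pig.
#' @export
pig_metrics <- function(net, betweenness_weighted = NULL) {
  if (inherits(net, "association_network")) {
    bw <- if (is.null(betweenness_weighted)) TRUE else betweenness_weighted
    data.frame(
      pen_id = net$pen_id,
      period = net$period,
      pig_id = net$nodes,
      strength = node_strength(net$W),
      betweenness = betweenness_centrality(net$W, directed = FALSE,
                                           weighted = bw),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else if (inherits(net, "bite_network")) {
    bw <- if (is.null(betweenness_weighted)) FALSE else betweenness_weighted
    data.frame(
      pen_id = net$pen_id,
      periods = paste(net$periods, collapse = "+"),
      pig_id = net$nodes,
      in_strength = node_strength(net$A, "in"),
      out_strength = node_strength(net$A, "out"),
      in_degree = node_degree(net$A, "in"),
      out_degree = node_degree(net$A, "out"),
      betweenness = betweenness_centrality(net$A, directed = TRUE,
                                           weighted = bw),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    stop("unsupported network type", call. = FALSE)
  }
}
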