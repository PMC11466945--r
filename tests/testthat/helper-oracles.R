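# Independent brute-force oracles for the graph-metric engine, written
# against the definitions only (no shared code with R/).

# Exhaustive simple-path enumeration betweenness: enumerate every simple
# path between every (ordered or unordered) pair by DFS, keep the
# minimum-length ones, and credit interior vertices fractionally.
enum_betweenness <- function(A, directed = FALSE, weighted = FALSE,
                             tol = 1e-9) {
  n <- nrow(A)
  L <- matrix(Inf, n, n)
  L[A > 0] <- if (weighted) 1 / A[A > 0] else 1
  if (!directed) L <- pmin(L, t(L))
  B <- numeric(n)
  paths_between <- function(s, t) {
    found <- list()
    dfs <- function(v, visited, len) {
      if (v == t) {
        found[[length(found) + 1L]] <<- list(path = visited, len = len)
        return(invisible(NULL))
      }
      for (w in seq_len(n)) {
        if (is.finite(L[v, w]) && !(w %in% visited)) {
          dfs(w, c(visited, w), len + L[v, w])
        }
      }
    }
    dfs(s, s, 0)
    found
  }
  pair_list <- if (directed) {
    idx <- expand.grid(s = seq_len(n), t = seq_len(n))
    idx[idx$s != idx$t, ]
  } else {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    data.frame(s = idx[, 1], t = idx[, 2])
  }
  for (r in seq_len(nrow(pair_list))) {
    s <- pair_list$s[r]; t <- pair_list$t[r]
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    geo <- ps[lens <= min(lens) + tol]
    for (g in geo) {
      inner <- setdiff(g$path, c(s, t))
      B[inner] <- B[inner] + 1 / length(geo)
    }
  }
  B
}

# Freeman centralization straight from the definition
enum_degree_centralization <- function(A, directed = FALSE,
                                       mode = "total") {
  n <- nrow(A)
  E <- A > 0
  d <- switch(mode, total = rowSums(E), `in` = colSums(E), out = rowSums(E))
  if (all(d == 0)) return(0)
  dmax <- if (directed) (n - 1)^2 else (n - 1) * (n - 2)
  sum(max(d) - d) / dmax
}

# Random adjacency matrices for sweeps
rand_undirected <- function(n, p = 0.4, weighted = FALSE) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- runif(length(up)) < p
  w <- if (weighted) round(runif(length(up), 0.1, 2), 3) else 1
  A[up[on]] <- (w * on)[on]
  A <- A + t(A)
  A
}

rand_directed <- function(n, p = 0.3, weighted = FALSE) {
  A <- matrix(0, n, n)
  off <- which(row(A) != col(A))
  on <- runif(length(off)) < p
  w <- if (weighted) sample(1:5, length(off), replace = TRUE) else 1
  A[off[on]] <- (w * on)[on]
  A
}

# enumerate all labeled undirected graphs on n nodes as adjacency matrices
all_undirected_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

is_connected_adj <- function(A) {
  n <- nrow(A)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(rbind((A > 0)[frontier, , drop = FALSE])) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

star_graph <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- 1; A[2:n, 1] <- 1
  A
}

complete_graph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

# small valid lying aggregate built from counts
make_aggregate <- function(x, n, scans_total, pen_id = "penA", period = 15) {
  ids <- sprintf("p%d", seq_along(n))
  dimnames(x) <- list(ids, ids)
  names(n) <- ids
  structure(list(pen_id = pen_id, period = period, x = x, n = n,
                 scans_total = scans_total), class = "lying_aggregate")
}

# Exhaustive geodesic counting via walk enumeration: sigma_st equals the
# number of walks of minimal length (minimal-length walks are simple), so
# betweenness follows from the combination rule
# B(v) = sum_{s,t} [d(s,v) + d(v,t) == d(s,t)] sigma_sv sigma_vt / sigma_st.
# Unweighted graphs only; independent of the Brandes accumulation.
power_betweenness <- function(A, directed = FALSE) {
  n <- nrow(A)
  E <- (A > 0) + 0
  if (!directed) E <- pmax(E, t(E))
  # BFS distances via boolean powers
  D <- matrix(Inf, n, n); diag(D) <- 0
  reach <- diag(n) > 0
  Pk <- diag(n)
  sig <- vector("list", n)  # sig[[k+1]] = E^k walk counts
  sig[[1]] <- diag(n)
  for (k in seq_len(n - 1)) {
    Pk <- Pk %*% E
    sig[[k + 1]] <- Pk
    newly <- (Pk > 0) & !reach
    D[newly] <- k
    reach <- reach | (Pk > 0)
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(D[s, t])) sigma[s, t] <- sig[[D[s, t] + 1]][s, t]
  }
  B <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == v || t == s || !is.finite(D[s, t])) next
        if (!directed && t < s) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          B[v] <- B[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  B
}
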