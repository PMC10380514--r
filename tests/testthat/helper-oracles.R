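# Independent brute-force oracles used to cross-check the package's
# graph-centrality and statistics code. These deliberately avoid igraph,
# phyper and p.adjust.

# ---- graph construction -----------------------------------------------------

# adjacency matrix from an edge-mask over the C(n,2) vertex pairs
adj_from_mask <- function(n, mask) {
  A <- matrix(0L, n, n)
  pairs <- utils::combn(n, 2)
  for (j in seq_len(ncol(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
      A[pairs[1, j], pairs[2, j]] <- 1L
      A[pairs[2, j], pairs[1, j]] <- 1L
    }
  }
  dimnames(A) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  A
}

adj_is_connected <- function(A) {
  n <- nrow(A)
  R <- diag(1, n) + A
  P <- R
  for (k in seq_len(n)) P <- (P %*% R > 0) * 1
  all(P > 0)
}

# every connected labeled simple graph on n nodes (n small)
enumerate_connected_graphs <- function(n) {
  m <- choose(n, 2)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    A <- adj_from_mask(n, mask)
    if (adj_is_connected(A)) out[[length(out) + 1L]] <- A
  }
  out
}

random_connected_adj <- function(n, p_edge = 0.4) {
  repeat {
    m <- choose(n, 2)
    mask <- sum(bitwShiftL(1L, which(stats::runif(m) < p_edge) - 1L))
    A <- adj_from_mask(n, mask)
    if (adj_is_connected(A)) return(A)
  }
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# ---- centrality oracles (matrix powers + subset testing) --------------------

# shortest-path distances and path counts via powers of the adjacency matrix:
# d(i,j) is the smallest k with (A^k)[i,j] > 0, and that entry is the number
# of shortest paths.
oracle_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(1, n)
  P <- diag(1, n)
  for (k in seq_len(n - 1)) {
    P <- P %*% A
    new <- is.infinite(D) & P > 0
    D[new] <- k
    S[new] <- P[new]
  }
  list(D = D, S = S)
}

oracle_degree <- function(A) rowSums(A)

oracle_harmonic <- function(A) {
  D <- oracle_paths(A)$D
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)])
  }, numeric(1))
}

# ordered-pair betweenness: every ordered (s, t), s != t != v
oracle_betweenness <- function(A) {
  sp <- oracle_paths(A)
  D <- sp$D; S <- sp$S
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + S[s, v] * S[v, t] / S[s, t]
    }
    tot
  }, numeric(1))
}

# maximal cliques by exhaustive subset testing
oracle_maximal_cliques <- function(A) {
  n <- nrow(A)
  cliques <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    k <- length(members)
    if (k >= 2) {
      pairs <- utils::combn(members, 2)
      if (!all(A[t(pairs)] == 1)) next
    }
    outside <- setdiff(seq_len(n), members)
    maximal <- !any(vapply(outside, function(u) all(A[u, members] == 1),
                           logical(1)))
    if (maximal) cliques[[length(cliques) + 1L]] <- members
  }
  cliques
}

oracle_mcc <- function(A) {
  cl <- oracle_maximal_cliques(A)
  mcc <- numeric(nrow(A))
  for (cq in cl) mcc[cq] <- mcc[cq] + factorial(length(cq) - 1)
  mcc
}

# ---- statistics oracles -----------------------------------------------------

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
oracle_hypergeom_upper <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)  # marked items are 1..K
  mean(ov >= k)
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- pmin(1, sorted * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- misc -------------------------------------------------------------------

tmp_file <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small canonical evidence file used across IO tests
evidence_fixture_lines <- function() {
  c("drug\ttarget\tlevel\teffect\tsystem\tsource_id",
    "thalidomide\tVEGFA\tgene\tdownregulated\thESC\tS1",
    "thalidomide\tCRBN\tprotein\tbound\tHUVEC\tS2",
    "lenalidomide\tVEGFA\tgene\tdownregulated\thESC\tS3")
}
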