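#' @title Enrichment analyses
#' @description Hypergeometric over-representation analysis (ORA),
#'   frequency-ranked gene-set enrichment analysis (GSEA) on the
#'   cross-dataset vote-count metric, and TF-target regulon enrichment with
#'   candidate ranking.
#' @name enrichment
NULL

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items when `n` items are drawn without replacement from
#' a universe of `N` containing `K` marked items.
#'
#' @param k observed overlap.
#' @param K gene-set (marked) size.
#' @param n query (draw) size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis
#'
#' One upper-tail hypergeometric test per gene set (each set intersected
#' with the universe first; sets empty after intersection are not tested),
#' Benjamini-Hochberg adjusted across the tested sets, sorted by raw p.
#'
#' @param query character vector of query symbols; must be a subset of the
#'   universe.
#' @param sets a `gene_sets` collection (named list of member vectors).
#' @param universe background symbols; defaults to the union of all set
#'   members and the query.
#' @param alpha significance level recorded on the output (default 0.05).
#' @return data.frame of class `enrichment_table`: set_id, k, K, n, N, p,
#'   p_adj, significant, members (list column of overlap symbols).
#' @export
ora <- function(query, sets, universe = NULL, alpha = 0.05) {
  query <- unique(query)
  if (is.null(universe))
    universe <- union(unique(unlist(sets, use.names = FALSE)), query)
  universe <- unique(universe)
  stray <- setdiff(query, universe)
  if (length(stray) > 0)
    stop("query symbols outside the universe: ",
         paste(stray, collapse = ", "), call. = FALSE)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    ov <- intersect(members, query)
    k <- length(ov)
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE,
               members = I(list(sort(ov))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0))
    out$members <- list()
    return(structure(out, class = c("enrichment_table", "data.frame"),
                     alpha = alpha))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$set_id),
             c("set_id", "k", "K", "n", "N", "p", "p_adj", "significant",
               "members")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"), alpha = alpha)
}

# Ranked list from frequency scores: score descending, symbol ascending
# within ties (documented tie order; optionally a seeded shuffle within
# score ties).
ranked_gene_list <- function(scores, tie_shuffle = FALSE, seed = NULL) {
  g <- scores$gene; s <- scores$score
  if (tie_shuffle) {
    if (is.null(seed)) stop("tie_shuffle requires a seed", call. = FALSE)
    set.seed(seed)
    jitter <- sample.int(length(g))
    o <- order(-s, jitter)
  } else {
    o <- order(-s, g)
  }
  list(gene = g[o], score = s[o])
}

gsea_es <- function(ranked_scores, hit, weight) {
  # ranked_scores: numeric vector along the ranked list; hit: logical
  w <- abs(ranked_scores)^weight
  hit_mass <- sum(w[hit])
  n_miss <- sum(!hit)
  inc <- numeric(length(hit))
  if (hit_mass > 0) {
    inc[hit] <- w[hit] / hit_mass
  } else {
    inc[hit] <- 1 / sum(hit)  # uniform fallback when every hit scores 0
  }
  inc[!hit] <- -1 / n_miss
  running <- cumsum(inc)
  i <- which.max(abs(running))
  list(es = running[i], running = running)
}

#' Frequency-ranked gene-set enrichment analysis
#'
#' Genes are ranked by their vote-count score (number of datasets where they
#' were significantly differentially expressed), score descending. The
#' running enrichment score increments at set members proportionally to
#' score^weight and decrements uniformly at non-members; the enrichment
#' score (ES) is the signed extremum of the running profile. The null is a
#' gene-label permutation with a fixed seed; p-values are BH-adjusted across
#' sets. Sets with no member in the universe, or spanning the whole
#' universe, are skipped with a warning.
#'
#' @param scores a `frequency_scores` table covering the full universe
#'   (score-0 genes included).
#' @param sets a `gene_sets` collection.
#' @param weight exponent on the score in hit increments (default 1;
#'   weight 0 gives the classical Kolmogorov-Smirnov statistic).
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed mandatory RNG seed for the permutation null.
#' @param tie_shuffle break score ties randomly (seeded) instead of by
#'   symbol.
#' @return data.frame of class `gsea_table`: set_id, size, es, nes, p_perm,
#'   p_adj, plus list column `running_profile`.
#' @export
gsea <- function(scores, sets, weight = 1, n_perm = 1000, seed,
                 tie_shuffle = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  rl <- ranked_gene_list(scores, tie_shuffle = tie_shuffle, seed = seed)
  genes <- rl$gene; s <- rl$score
  Nn <- length(genes)

  set.seed(seed)
  res <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], genes)
    if (length(members) == 0) {
      warning("set ", id, " has no member in the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    if (length(members) == Nn) {
      warning("set ", id, " spans the whole universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    hit <- genes %in% members
    obs <- gsea_es(s, hit, weight)
    K <- sum(hit)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(Nn)
      ph[sample.int(Nn, K)] <- TRUE
      gsea_es(s, ph, weight)$es
    }, numeric(1))
    p_perm <- (1 + sum(abs(perm_es) >= abs(obs$es))) / (n_perm + 1)
    same_sign <- if (obs$es >= 0) perm_es[perm_es > 0] else perm_es[perm_es < 0]
    nes <- if (length(same_sign) > 0) obs$es / mean(abs(same_sign)) else NA_real_
    data.frame(set_id = id, size = K, es = obs$es, nes = nes,
               p_perm = p_perm, stringsAsFactors = FALSE,
               running_profile = I(list(obs$running)))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    out <- data.frame(set_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_perm = numeric(0), p_adj = numeric(0))
    out$running_profile <- list()
    return(structure(out, class = c("gsea_table", "data.frame")))
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_perm, method = "BH")
  out <- out[, c("set_id", "size", "es", "nes", "p_perm", "p_adj",
                 "running_profile")]
  rownames(out) <- NULL
  structure(out, class = c("gsea_table", "data.frame"),
            ranked_genes = genes, ranked_scores = s)
}

#' TF-target regulon enrichment
#'
#' For each TF in the regulon database: k = |regulon targets in the query|,
#' with an upper-tail hypergeometric p against the supplied universe. TFs
#' with raw p strictly below `alpha` are retained (the screening rule is on
#' the raw p; a BH-adjusted column is additionally reported), ranked by k
#' descending with ties by p ascending.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param regulons a `regulon_db` data.frame (tf, target, ...).
#' @param universe background gene symbols.
#' @param alpha raw-p screening threshold (strict; default 0.05).
#' @return data.frame of class `tf_enrichment`: tf, k, K, n, N, p, p_adj,
#'   targets (list column of regulated query genes). Attribute `all` holds
#'   the unfiltered table.
#' @export
regulon_enrichment <- function(query, regulons, universe, alpha = 0.05) {
  if (nrow(regulons) == 0) stop("empty regulon database", call. = FALSE)
  query <- unique(query)
  universe <- unique(universe)
  stray <- setdiff(query, universe)
  if (length(stray) > 0)
    stop("query symbols outside the universe: ",
         paste(stray, collapse = ", "), call. = FALSE)
  tsets <- regulon_targets(regulons)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(tsets), function(tf) {
    targets <- intersect(unique(tsets[[tf]]), universe)
    K <- length(targets)
    if (K == 0) return(NULL)
    ov <- intersect(targets, query)
    k <- length(ov)
    data.frame(tf = tf, k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N),
               stringsAsFactors = FALSE, targets = I(list(sort(ov))))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  all_tab <- do.call(rbind, rows)
  all_tab$p_adj <- stats::p.adjust(all_tab$p, method = "BH")
  all_tab <- all_tab[order(-all_tab$k, all_tab$p, all_tab$tf),
                     c("tf", "k", "K", "n", "N", "p", "p_adj", "targets")]
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tf_enrichment", "data.frame"),
            alpha = alpha, all = all_tab)
}
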