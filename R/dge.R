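#' @title Differential-expression integration
#' @description Per-dataset significance filtering, cross-dataset frequency
#'   (vote-count) scoring, cumulative summaries against a genome universe,
#'   and the dual-evidence query filter that combines vote counts with
#'   literature evidence.
#' @name dge_integration
NULL

#' Simple two-group differential-expression caller
#'
#' A deliberately simple caller used to exercise synthetic expression
#' matrices end-to-end: per gene, the log2 fold change is
#' mean(case) - mean(control) and the p-value comes from a two-sided Welch
#' (unequal-variance) two-sample t test, adjusted across all genes by
#' Benjamini-Hochberg. This is not a moderated-model fit; real studies
#' should supply precomputed DE tables.
#'
#' @param mat numeric matrix of log2 expression, genes in rows (rownames are
#'   gene symbols), samples in columns.
#' @param groups character/factor vector of length `ncol(mat)` with values
#'   `"case"` and `"control"`.
#' @param dataset_id identifier recorded in the output.
#' @return data.frame of class `de_table` with columns
#'   `gene, lfc, p_raw, p_adj, zero_variance` and attribute `dataset_id`.
#' @export
call_de_simple <- function(mat, groups, dataset_id = "dataset") {
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control")))
    stop("groups must be 'case' or 'control'", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("gene rows must be unique", call. = FALSE)
  icase <- which(groups == "case"); ictrl <- which(groups == "control")
  if (length(icase) < 2 || length(ictrl) < 2)
    stop("each group needs at least 2 samples", call. = FALSE)

  xc <- mat[, icase, drop = FALSE]
  xk <- mat[, ictrl, drop = FALSE]
  n1 <- length(icase); n2 <- length(ictrl)
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xk - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  zero_var <- se2 <= 0
  tstat <- ifelse(zero_var, 0, lfc / sqrt(se2))
  df <- ifelse(zero_var, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  p_raw[zero_var] <- 1
  out <- data.frame(gene = rownames(mat), lfc = lfc, p_raw = p_raw,
                    p_adj = stats::p.adjust(p_raw, method = "BH"),
                    zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("de_table", "data.frame"), dataset_id = dataset_id)
}

#' Read / write per-dataset DE result tables
#'
#' Tab-separated with header `gene lfc p_raw p_adj`; the dataset id is taken
#' from the file name unless given.
#'
#' @param path file path.
#' @param dataset_id optional dataset identifier; defaults to the file
#'   basename without extension.
#' @return data.frame of class `de_table`.
#' @export
read_de_table <- function(path, dataset_id = NULL) {
  df <- read_tsv_base(path)
  need <- c("gene", "lfc", "p_raw", "p_adj")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    io_stop("DE table schema error: missing column(s) ",
            paste(miss, collapse = ", "), path = path)
  df <- df[, intersect(c(need, "zero_variance"), names(df))]
  df$gene <- canonicalize_symbols(df$gene)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  structure(df, class = c("de_table", "data.frame"), dataset_id = dataset_id)
}

#' @rdname read_de_table
#' @param x a `de_table`.
#' @export
write_de_table <- function(x, path) {
  cols <- intersect(c("gene", "lfc", "p_raw", "p_adj", "zero_variance"),
                    names(x))
  write_tsv_base(as.data.frame(x)[, cols], path)
}

#' Significance filter for one dataset
#'
#' A gene is significant iff `|lfc| > lfc_threshold` and
#' `p_adj < alpha`, both strict (boundary values are excluded).
#'
#' @param records a `de_table` (columns gene, lfc, p_adj).
#' @param lfc_threshold absolute log2-fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of significant gene symbols (unique, sorted).
#' @export
filter_significant <- function(records, lfc_threshold = 1, alpha = 0.05) {
  keep <- abs(records$lfc) > lfc_threshold & records$p_adj < alpha
  sort(unique(records$gene[keep]))
}

#' Cross-dataset frequency (vote-count) scores
#'
#' Each gene's score is the number of datasets in which it was significant:
#' a gene differentially expressed in four studies receives score 4. When a
#' gene universe is supplied, genes never significant are materialized with
#' score 0 (needed for genome-wide summaries and ranked-list enrichment).
#'
#' @param sig_sets named list of per-dataset significant gene sets; names are
#'   dataset ids and must be distinct.
#' @param universe optional character vector of all genes.
#' @return data.frame of class `frequency_scores` with columns `gene`,
#'   `score`, and a list column `dataset_ids`; attribute `n_datasets`.
#' @export
frequency_scores <- function(sig_sets, universe = NULL) {
  if (length(sig_sets) > 0 &&
      (is.null(names(sig_sets)) || anyDuplicated(names(sig_sets))))
    stop("sig_sets must have distinct dataset-id names", call. = FALSE)
  sig_sets <- lapply(sig_sets, unique)
  gene <- unlist(sig_sets, use.names = FALSE)
  if (length(gene) == 0) {
    out <- data.frame(gene = character(0), score = integer(0),
                      stringsAsFactors = FALSE)
    out$dataset_ids <- list()
  } else {
    ds <- rep(names(sig_sets), lengths(sig_sets))
    by_gene <- split(ds, gene)
    out <- data.frame(gene = names(by_gene),
                      score = lengths(by_gene),
                      stringsAsFactors = FALSE, row.names = NULL)
    out$dataset_ids <- unname(by_gene)
  }
  if (!is.null(universe)) {
    universe <- unique(universe)
    extra <- setdiff(universe, out$gene)
    if (length(extra) > 0) {
      zero <- data.frame(gene = extra, score = 0L, stringsAsFactors = FALSE)
      zero$dataset_ids <- rep(list(character(0)), length(extra))
      out <- rbind(out, zero)
    }
  }
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("frequency_scores", "data.frame"),
            n_datasets = length(sig_sets))
}

#' Cumulative frequency-score summary
#'
#' For k = 1..max(score): the number of genes significant in at least k
#' datasets and the percentage of the genome that represents (one decimal,
#' raw fraction retained).
#'
#' @param scores a `frequency_scores` table.
#' @param genome_size number of genes in the reference genome; must be at
#'   least the number of scored genes.
#' @return data.frame of class `cumulative_summary` with columns
#'   `k, count, pct, fraction`; attribute `genome_size`.
#' @export
cumulative_summary <- function(scores, genome_size) {
  n_scored <- sum(scores$score > 0)
  if (genome_size < nrow(scores) || genome_size < n_scored)
    stop("genome_size smaller than the number of scored genes", call. = FALSE)
  kmax <- max(scores$score, 0)
  if (kmax == 0) {
    out <- data.frame(k = integer(0), count = integer(0),
                      pct = numeric(0), fraction = numeric(0))
  } else {
    k <- seq_len(kmax)
    count <- vapply(k, function(kk) sum(scores$score >= kk), integer(1))
    out <- data.frame(k = k, count = count,
                      pct = vapply(count, pct1, numeric(1), total = genome_size),
                      fraction = count / genome_size)
  }
  structure(out, class = c("cumulative_summary", "data.frame"),
            genome_size = genome_size)
}

#' Dual-evidence query filter
#'
#' Keeps genes differentially expressed in at least two datasets, plus genes
#' differentially expressed in exactly one dataset that carry independent
#' literature evidence of a drug-induced effect. Literature genes never
#' differentially expressed are ruled out.
#'
#' @param scores a `frequency_scores` table over all datasets.
#' @param literature_genes character vector of gene-level literature targets.
#' @return sorted character vector: the query gene set.
#' @export
dual_evidence_filter <- function(scores, literature_genes) {
  literature_genes <- unique(literature_genes)
  keep <- scores$score >= 2 |
    (scores$score == 1 & scores$gene %in% literature_genes)
  sort(unique(scores$gene[keep]))
}
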