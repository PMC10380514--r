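#' @title Synthetic scenarios with planted ground truth
#' @description Generates fully self-contained scenarios exercising every
#'   pipeline stage: several case/control expression datasets in which the
#'   targets of a hidden set of "degraded" C2H2 TFs are shifted, a regulon
#'   database with heavy-tailed regulon sizes (one SP1-like TF forced to the
#'   largest regulon), a scored interaction network with a planted hub, a
#'   literature evidence table covering part of the affected targets, TF
#'   domain annotations, and development gene sets containing the planted
#'   TFs. Ground truth (degraded TFs, hub) travels with the bundle.
#' @name synthetic_data
NULL

#' Scenario parameters
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 2000 genes, 60 TFs of which 3 are degraded, 8 case/control
#' datasets (6 vs 6 samples), a mean |log2 shift| of 2 on degraded-TF
#' targets with per-dataset response probability 0.6, and residual noise SD
#' 0.5 on the log2 scale.
#'
#' @param n_genes total gene universe size (TFs and proteins included).
#' @param n_tfs number of transcription factors.
#' @param n_degraded_tfs number of planted degraded TFs (all C2H2).
#' @param n_lit_proteins number of literature protein symbols (the planted
#'   hub is one of them).
#' @param regulon_exponent,regulon_min,regulon_max truncated power-law for
#'   regulon sizes.
#' @param n_datasets number of case/control expression datasets.
#' @param n_case,n_control samples per group per dataset.
#' @param effect_lfc mean |log2 shift| applied to responding targets of
#'   degraded TFs in case samples (> 1 required for default recovery).
#' @param detect_prob per-dataset probability that a true target responds.
#' @param noise_sd residual SD of log2 expression.
#' @param ppi_edge_prob edge probability of the background protein network.
#' @param hub_symbol symbol of the planted hub protein.
#' @param c2h2_fraction fraction of non-planted TFs annotated C2H2.
#' @param lit_coverage fraction of degraded-TF targets that receive a
#'   gene-level literature evidence entry.
#' @param seed global seed; fanned out into per-component substreams.
#' @return list of class `scenario_params`.
#' @export
scenario_params <- function(n_genes = 2000, n_tfs = 60, n_degraded_tfs = 3,
                            n_lit_proteins = 30,
                            regulon_exponent = 2, regulon_min = 10,
                            regulon_max = 150,
                            n_datasets = 8, n_case = 6, n_control = 6,
                            effect_lfc = 2, detect_prob = 0.6,
                            noise_sd = 0.5,
                            ppi_edge_prob = 0.08, hub_symbol = "CRBN",
                            c2h2_fraction = 0.3, lit_coverage = 0.3,
                            seed = 1) {
  p <- as.list(environment())
  stopifnot(n_genes >= 1, n_tfs >= 1, n_degraded_tfs >= 1,
            n_degraded_tfs <= n_tfs, n_datasets >= 1,
            n_case >= 2, n_control >= 2,
            detect_prob >= 0, detect_prob <= 1,
            c2h2_fraction >= 0, c2h2_fraction <= 1,
            lit_coverage >= 0, lit_coverage <= 1,
            regulon_min >= 1, regulon_max >= regulon_min,
            noise_sd > 0)
  n_filler <- n_genes - n_tfs - n_lit_proteins - 1L
  if (n_filler < regulon_max)
    stop("regulons would exhaust the gene universe: need at least ",
         regulon_max, " non-TF, non-protein genes, have ", n_filler,
         call. = FALSE)
  p$seed <- as.integer(seed)
  structure(p, class = "scenario_params")
}

# truncated power-law regulon sizes
rpowerlaw_sizes <- function(n, exponent, min_size, max_size) {
  u <- stats::runif(n)
  s <- round(min_size * (1 - u)^(-1 / (exponent - 1)))
  pmin(pmax(s, min_size), max_size)
}

#' Generate a synthetic scenario bundle
#'
#' Deterministic for a fixed seed: the global seed fans out to independent
#' substreams for regulons, each expression dataset, the evidence table, the
#' interaction network, annotations and gene sets, so components are
#' individually reproducible.
#'
#' @param p a `scenario_params` list.
#' @return list of class `scenario_bundle` with elements `params`,
#'   `universe`, `datasets` (each with `matrix`, `groups`, `de`), `evidence`
#'   (evidence_table), `edges` (scored_edges), `regulons` (regulon_db),
#'   `annotations` (tf_annotations), `dev_sets` (gene_sets) and
#'   `ground_truth` (`degraded_tfs`, `hub`, `targets`, `direction`).
#' @export
generate_scenario <- function(p = scenario_params()) {
  if (!inherits(p, "scenario_params")) p <- do.call(scenario_params, p)
  seeds <- fan_out_seeds(p$seed, 8 + p$n_datasets)

  tf_syms <- sprintf("TF%03d", seq_len(p$n_tfs))
  prot_syms <- c(p$hub_symbol,
                 sprintf("P%03d", seq_len(p$n_lit_proteins - 1L)))
  n_filler <- p$n_genes - p$n_tfs - length(prot_syms)
  filler <- sprintf("G%04d", seq_len(n_filler))
  universe <- c(tf_syms, prot_syms, filler)

  # -- regulons (substream 1) -------------------------------------------------
  set.seed(seeds[1])
  degraded <- sort(sample(tf_syms, p$n_degraded_tfs))
  sizes <- rpowerlaw_sizes(p$n_tfs, p$regulon_exponent, p$regulon_min,
                           p$regulon_max)
  names(sizes) <- tf_syms
  # the first degraded TF gets the strictly largest regulon (SP1-like)
  sizes <- pmin(sizes, p$regulon_max - 1L)
  sizes[degraded[1]] <- p$regulon_max
  reg_rows <- lapply(tf_syms, function(tf) {
    targets <- sample(filler, sizes[[tf]])
    mode <- sample(c("activation", "repression", "unknown"),
                   length(targets), replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
    data.frame(tf = tf, target = targets, mode = mode,
               references = 1L + stats::rpois(length(targets), 1),
               stringsAsFactors = FALSE)
  })
  regulons <- structure(do.call(rbind, reg_rows),
                        class = c("regulon_db", "data.frame"))

  # per-gene expected shift direction when its regulating TF is degraded:
  # activated targets drop, repressed targets rise, unknown gets a fixed
  # random sign
  deg_rows <- regulons[regulons$tf %in% degraded, , drop = FALSE]
  deg_rows <- deg_rows[!duplicated(deg_rows$target), , drop = FALSE]
  dir <- ifelse(deg_rows$mode == "activation", -1,
                ifelse(deg_rows$mode == "repression", 1,
                       sample(c(-1, 1), nrow(deg_rows), replace = TRUE)))
  direction <- stats::setNames(dir, deg_rows$target)
  true_targets <- names(direction)

  # -- expression datasets (substreams 2..) ----------------------------------
  datasets <- vector("list", p$n_datasets)
  names(datasets) <- sprintf("d%02d", seq_len(p$n_datasets))
  for (d in seq_len(p$n_datasets)) {
    set.seed(seeds[1 + d])
    n_s <- p$n_case + p$n_control
    mu <- stats::rnorm(p$n_genes, mean = 7, sd = 1)
    mat <- matrix(stats::rnorm(p$n_genes * n_s, mean = mu, sd = p$noise_sd),
                  nrow = p$n_genes, ncol = n_s)
    rownames(mat) <- universe
    colnames(mat) <- c(sprintf("case_%02d", seq_len(p$n_case)),
                       sprintf("ctrl_%02d", seq_len(p$n_control)))
    groups <- c(rep("case", p$n_case), rep("control", p$n_control))
    responding <- true_targets[stats::runif(length(true_targets)) <
                                 p$detect_prob]
    if (length(responding) > 0) {
      idx <- match(responding, universe)
      mat[idx, seq_len(p$n_case)] <- mat[idx, seq_len(p$n_case)] +
        direction[responding] * p$effect_lfc
    }
    de <- call_de_simple(mat, groups, dataset_id = names(datasets)[d])
    datasets[[d]] <- list(matrix = mat, groups = groups, de = de,
                          responding = sort(responding))
  }

  # -- evidence table (substream after datasets) ------------------------------
  set.seed(seeds[2 + p$n_datasets])
  systems <- c("hESC", "HUVEC", "embryonic tissue")
  ev_prot <- do.call(rbind, lapply(prot_syms, function(s) {
    n_e <- sample(1:3, 1)
    data.frame(drug = sample(c("thalidomide", "lenalidomide", "pomalidomide"),
                             n_e, replace = TRUE, prob = c(0.8, 0.07, 0.13)),
               target = s, level = "protein",
               effect = sample(c("degraded", "bound", "inhibited",
                                 "downregulated"), n_e, replace = TRUE),
               system = sample(systems, n_e, replace = TRUE),
               source_id = sprintf("SRC%02d", sample.int(48, n_e)),
               stringsAsFactors = FALSE)
  }))
  covered <- true_targets[stats::runif(length(true_targets)) <
                            p$lit_coverage]
  decoys <- sample(setdiff(filler, true_targets),
                   min(10, n_filler - length(true_targets)))
  gene_targets <- c(covered, decoys)
  ev_gene <- if (length(gene_targets) > 0) {
    eff <- ifelse(gene_targets %in% names(direction) &
                    direction[gene_targets] < 0,
                  "downregulated", "upregulated")
    data.frame(drug = sample(c("thalidomide", "lenalidomide", "pomalidomide"),
                             length(gene_targets), replace = TRUE,
                             prob = c(0.8, 0.07, 0.13)),
               target = gene_targets, level = "gene", effect = eff,
               system = sample(systems, length(gene_targets), replace = TRUE),
               source_id = sprintf("SRC%02d", sample.int(48,
                                                         length(gene_targets),
                                                         replace = TRUE)),
               stringsAsFactors = FALSE)
  } else NULL
  evidence <- rbind(ev_prot, ev_gene)
  evidence <- evidence[!duplicated(evidence), , drop = FALSE]
  rownames(evidence) <- NULL
  evidence <- structure(evidence, class = c("evidence_table", "data.frame"),
                        n_duplicates = 0L,
                        row_errors = data.frame(line = integer(0),
                                                message = character(0)))

  # -- interaction network (planted hub) --------------------------------------
  set.seed(seeds[3 + p$n_datasets])
  others <- setdiff(prot_syms, p$hub_symbol)
  isolated <- utils::head(others, 3)
  side <- utils::head(setdiff(others, isolated), 3)
  pool <- setdiff(others, c(isolated, side))
  pairs <- t(utils::combn(pool, 2))
  keep <- stats::runif(nrow(pairs)) < p$ppi_edge_prob
  e_a <- pairs[keep, 1]; e_b <- pairs[keep, 2]
  e_s <- stats::runif(sum(keep), 0.45, 0.95)
  # hub attached to (max other degree) + 2 distinct neighbors
  deg <- table(factor(c(e_a, e_b), levels = pool))
  hub_deg <- min(length(pool), max(as.integer(deg), 0) + 2L)
  hub_nb <- sample(pool, hub_deg)
  e_a <- c(e_a, rep(p$hub_symbol, hub_deg))
  e_b <- c(e_b, hub_nb)
  e_s <- c(e_s, stats::runif(hub_deg, 0.55, 0.99))
  # small side component (excluded by main_component)
  if (length(side) >= 2) {
    e_a <- c(e_a, side[-length(side)])
    e_b <- c(e_b, side[-1])
    e_s <- c(e_s, stats::runif(length(side) - 1, 0.45, 0.95))
  }
  # sub-threshold edges that the score filter must drop
  n_low <- 5L
  low <- cbind(sample(prot_syms, n_low, replace = TRUE),
               sample(prot_syms, n_low, replace = TRUE))
  low <- low[low[, 1] != low[, 2], , drop = FALSE]
  e_a <- c(e_a, low[, 1]); e_b <- c(e_b, low[, 2])
  e_s <- c(e_s, stats::runif(nrow(low), 0.05, 0.35))
  # augmentation edges: every degraded TF reaches the main pool (the
  # SP1-like TF is wired to the hub itself)
  for (i in seq_along(degraded)) {
    nb <- unique(c(if (i == 1) p$hub_symbol,
                   sample(c(pool, p$hub_symbol), sample(1:3, 1))))
    e_a <- c(e_a, rep(degraded[i], length(nb)))
    e_b <- c(e_b, nb)
    e_s <- c(e_s, stats::runif(length(nb), 0.5, 0.95))
  }
  lo <- pmin(e_a, e_b); hi <- pmax(e_a, e_b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(a = lo[first], b = hi[first], score = e_s[first],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  edges <- structure(edges, class = c("scored_edges", "data.frame"))

  # -- TF annotations ---------------------------------------------------------
  set.seed(seeds[4 + p$n_datasets])
  non_planted <- setdiff(tf_syms, degraded)
  n_c2h2_extra <- round(p$c2h2_fraction * length(non_planted))
  c2h2_extra <- sample(non_planted, n_c2h2_extra)
  annotations <- data.frame(
    symbol = c(tf_syms, prot_syms, filler),
    is_tf = c(rep(TRUE, length(tf_syms)),
              rep(FALSE, length(prot_syms) + length(filler))),
    dbd_class = c(ifelse(tf_syms %in% c(degraded, c2h2_extra), "C2H2",
                         "other"),
                  rep("unknown", length(prot_syms) + length(filler))),
    stringsAsFactors = FALSE)
  annotations <- structure(annotations,
                           class = c("tf_annotations", "data.frame"))

  # -- development gene sets --------------------------------------------------
  set.seed(seeds[5 + p$n_datasets])
  other_c2h2 <- setdiff(c2h2_extra, degraded)
  dev_sets <- list(
    embryonic_development = unique(c(degraded,
                                     sample(other_c2h2,
                                            min(2, length(other_c2h2))))),
    eye_development = unique(c(degraded[1], degraded[-1],
                               sample(other_c2h2,
                                      min(1, length(other_c2h2))))),
    heart_development = unique(c(degraded,
                                 sample(non_planted, 1))),
    immune_response = sample(setdiff(non_planted, other_c2h2), 5),
    metabolic_process = sample(setdiff(non_planted, other_c2h2), 6)
  )
  attr(dev_sets, "descriptions") <- stats::setNames(
    gsub("_", " ", names(dev_sets)), names(dev_sets))
  class(dev_sets) <- "gene_sets"

  structure(list(
    params = p, universe = universe, tf_symbols = tf_syms,
    protein_symbols = prot_syms, datasets = datasets, evidence = evidence,
    edges = edges, regulons = regulons, annotations = annotations,
    dev_sets = dev_sets,
    ground_truth = list(degraded_tfs = degraded, hub = p$hub_symbol,
                        targets = true_targets, direction = direction)
  ), class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d genes, %d TFs (%d degraded), %d datasets, seed %d\n",
    x$params$n_genes, x$params$n_tfs, x$params$n_degraded_tfs,
    x$params$n_datasets, x$params$seed))
  cat("  planted degraded TFs:",
      paste(x$ground_truth$degraded_tfs, collapse = ", "),
      "| planted hub:", x$ground_truth$hub, "\n")
  invisible(x)
}

#' Materialize a scenario bundle to a directory
#'
#' Writes every component in the exact dialects the readers consume, plus a
#' flat `config.txt` so [run_pipeline()] (or the CLI) can run on the
#' directory unchanged.
#'
#' @param bundle a `scenario_bundle`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(file.path(dir, "de"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(bundle$datasets))
    write_de_table(bundle$datasets[[id]]$de,
                   file.path(dir, "de", paste0(id, ".tsv")))
  write_evidence_table(bundle$evidence, file.path(dir, "evidence.tsv"))
  write_string_edges(bundle$edges, file.path(dir, "string_edges.tsv"))
  write_regulons(bundle$regulons, file.path(dir, "regulons.tsv"))
  write_tf_annotations(bundle$annotations,
                       file.path(dir, "tf_annotations.tsv"))
  write_gmt(bundle$dev_sets, file.path(dir, "dev_sets.gmt"))
  writeLines(bundle$universe, file.path(dir, "universe.txt"))
  writeLines(c("de_dir: de",
               "evidence: evidence.tsv",
               "edges: string_edges.tsv",
               "regulons: regulons.tsv",
               "tf_annotations: tf_annotations.tsv",
               "dev_sets: dev_sets.gmt",
               "universe: universe.txt",
               "lfc: 1", "alpha_de: 0.05", "string_score: 0.400",
               "alpha_tf: 0.05", "alpha_ora: 0.05",
               paste("seed:", bundle$params$seed)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Pipeline configuration for a materialized scenario directory
#' @param dir directory written by [write_scenario()].
#' @param outdir optional pipeline output directory.
#' @return a `pipeline_config`.
#' @export
scenario_config <- function(dir, outdir = NULL) {
  cfg <- read_pipeline_config(file.path(dir, "config.txt"))
  cfg$outdir <- outdir
  cfg
}

#' Recovery metrics against planted ground truth
#'
#' Precision and recall of planted degraded TFs over the novel-C2H2
#' candidate class of a pipeline report.
#'
#' @param report a `candidate_table`, `final_report`, or `tf_prioritization`
#'   result.
#' @param truth the bundle's `ground_truth` list (or a `scenario_bundle`).
#' @param prioritized_only use only candidates surviving the development
#'   filter (default FALSE: the full novel_C2H2 class).
#' @return list: `tp`, `fp`, `fn`, `precision` (NA with
#'   `precision_undefined = TRUE` when nothing was predicted), `recall`,
#'   `predicted`, `truth`.
#' @export
ground_truth_metrics <- function(report, truth, prioritized_only = FALSE) {
  if (inherits(report, "tf_prioritization")) report <- report$report
  if (inherits(truth, "scenario_bundle")) truth <- truth$ground_truth
  df <- as.data.frame(report)
  pred <- df$tf[df$candidate_class == "novel_C2H2"]
  if (prioritized_only && "dev_ontology_hit" %in% names(df))
    pred <- df$tf[df$candidate_class == "novel_C2H2" &
                    df$dev_ontology_hit %in% TRUE]
  pred <- unique(pred)
  planted <- truth$degraded_tfs
  tp <- length(intersect(pred, planted))
  fp <- length(setdiff(pred, planted))
  fn <- length(setdiff(planted, pred))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       precision_undefined = tp + fp == 0,
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       predicted = sort(pred), truth = sort(planted))
}
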