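#' @title Candidate classification and pipeline orchestration
#' @description Three-set Venn classification of enriched TFs against the
#'   literature protein set and the C2H2 domain list, the
#'   embryonic-development over-representation filter, the final ranked
#'   report, and the end-to-end pipeline runner.
#' @name prioritization_pipeline
NULL

#' Three-set Venn partition
#'
#' Partitions the union of L (literature proteins), T (enriched TFs) and Z
#' (C2H2 TFs) into the seven disjoint regions of the Venn diagram.
#'
#' @param L,T_,Z character vectors (canonicalized internally).
#' @return list of class `venn3`: `regions` (named list of 7 disjoint symbol
#'   sets: `LTZ, LT, LZ, TZ, L_only, T_only, Z_only`) and `cardinalities`.
#' @export
venn_partition <- function(L, T_, Z) {
  L <- unique(L); T_ <- unique(T_); Z <- unique(Z)
  inL <- function(x) x %in% L; inT <- function(x) x %in% T_
  inZ <- function(x) x %in% Z
  u <- sort(unique(c(L, T_, Z)))
  regions <- list(
    LTZ    = u[inL(u) & inT(u) & inZ(u)],
    LT     = u[inL(u) & inT(u) & !inZ(u)],
    LZ     = u[inL(u) & !inT(u) & inZ(u)],
    TZ     = u[!inL(u) & inT(u) & inZ(u)],
    L_only = u[inL(u) & !inT(u) & !inZ(u)],
    T_only = u[!inL(u) & inT(u) & !inZ(u)],
    Z_only = u[!inL(u) & !inT(u) & inZ(u)]
  )
  structure(list(regions = regions,
                 cardinalities = vapply(regions, length, integer(1))),
            class = "venn3")
}

CANDIDATE_CLASSES <- c("known_C2H2", "novel_C2H2", "known_nonC2H2", "other")

#' Classify enriched TFs
#'
#' Maps each enriched TF to its candidate class from its Venn region:
#' in T, Z and L -> `known_C2H2` (C2H2 TFs already reported in the
#' literature); in T and L but not Z -> `known_nonC2H2`; in T and Z but not
#' L -> `novel_C2H2` (the prioritization focus: C2H2 TFs never reported as
#' drug-affected); T only -> `other`.
#'
#' @param enriched a `tf_enrichment` table (TFs passing the regulon screen).
#' @param L literature protein symbols.
#' @param Z C2H2 TF symbols.
#' @return data.frame of class `candidate_table`: tf, venn_region,
#'   candidate_class, regulon_overlap_k, p.
#' @export
classify_candidates <- function(enriched, L, Z) {
  L <- unique(L); Z <- unique(Z)
  tf <- enriched$tf
  inL <- tf %in% L; inZ <- tf %in% Z
  region <- ifelse(inL & inZ, "LTZ",
                   ifelse(inL, "LT", ifelse(inZ, "TZ", "T_only")))
  cls <- ifelse(inL & inZ, "known_C2H2",
                ifelse(inL, "known_nonC2H2",
                       ifelse(inZ, "novel_C2H2", "other")))
  out <- data.frame(tf = tf, venn_region = region, candidate_class = cls,
                    regulon_overlap_k = enriched$k, p = enriched$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("candidate_table", "data.frame"))
}

#' Embryonic-development over-representation filter
#'
#' Runs ORA of the novel-C2H2 candidate list against a user-supplied
#' development gene-set collection; a candidate is a development hit iff it
#' belongs to at least one set significant at `alpha` after BH. Only hits
#' are retained in the prioritized output; the full annotated table is kept.
#'
#' @param candidates a `candidate_table` (normally the novel_C2H2 subset).
#' @param dev_sets a `gene_sets` collection of development terms.
#' @param universe ORA background symbols.
#' @param alpha BH significance level (default 0.05).
#' @return list of class `dev_filter`: `candidates` (input annotated with
#'   `dev_ontology_hit`), `prioritized` (hits only), `ora` (the
#'   `enrichment_table`), `skipped` (TRUE when dev_sets was empty).
#' @export
embryonic_filter <- function(candidates, dev_sets, universe, alpha = 0.05) {
  if (length(dev_sets) == 0) {
    warning("empty development gene-set collection; filter skipped",
            call. = FALSE)
    candidates$dev_ontology_hit <- NA
    return(structure(list(candidates = candidates,
                          prioritized = candidates,
                          ora = NULL, skipped = TRUE),
                     class = "dev_filter"))
  }
  ora_tab <- ora(candidates$tf, dev_sets, universe = universe, alpha = alpha)
  sig_members <- unique(unlist(ora_tab$members[ora_tab$significant],
                               use.names = FALSE))
  candidates$dev_ontology_hit <- candidates$tf %in% sig_members
  structure(list(candidates = candidates,
                 prioritized = candidates[candidates$dev_ontology_hit, ,
                                          drop = FALSE],
                 ora = ora_tab, skipped = FALSE),
            class = "dev_filter")
}

#' Final prioritization report
#'
#' Joins, per enriched TF: candidate class, regulon overlap, development
#' hit, and pre-/post-augmentation centrality ranks with essentiality flags.
#' Sorted by candidate-class priority (known_C2H2, novel_C2H2,
#' known_nonC2H2, other), then regulon overlap descending.
#'
#' @param candidates a `candidate_table` with `dev_ontology_hit`.
#' @param centralities_before `essentiality` object for the literature
#'   network (or NULL).
#' @param centralities_after `essentiality` object for the augmented network
#'   (or NULL).
#' @param freq_scores optional `frequency_scores` to annotate each TF's own
#'   vote count.
#' @param class_priority ordering of candidate classes in the report.
#' @return data.frame of class `final_report`.
#' @export
final_report <- function(candidates, centralities_before = NULL,
                         centralities_after = NULL, freq_scores = NULL,
                         class_priority = c("known_C2H2", "novel_C2H2",
                                            "known_nonC2H2", "other")) {
  out <- as.data.frame(candidates)
  if (!"dev_ontology_hit" %in% names(out)) out$dev_ontology_hit <- NA

  pull_cent <- function(ess, suffix) {
    cols <- c("degree_rank", "closeness_rank", "betweenness_rank",
              "mcc_rank")
    if (is.null(ess)) {
      for (cl in c(cols, "essential"))
        out[[paste0(cl, suffix)]] <<- rep(NA, nrow(out))
      return(invisible(NULL))
    }
    tab <- ess$table
    idx <- match(out$tf, tab$node)
    for (cl in cols) out[[paste0(cl, suffix)]] <<- tab[[cl]][idx]
    out[[paste0("essential", suffix)]] <<- out$tf %in% ess$essential
  }
  pull_cent(centralities_before, "_pre")
  pull_cent(centralities_after, "_post")
  if (!is.null(freq_scores)) {
    out$freq_score <- freq_scores$score[match(out$tf, freq_scores$gene)]
  }
  prio <- match(out$candidate_class, class_priority)
  out <- out[order(prio, -out$regulon_overlap_k, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("final_report", "data.frame"))
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Thresholds default to the pipeline's standard values: |log2 FC| > 1 and
#' BH-adjusted p < 0.05 for differential expression, interaction score
#' > 0.400, raw regulon p < 0.05, ORA BH < 0.05.
#'
#' @param de_dir directory of per-dataset DE tables (`*.tsv`), or
#'   `de_files` as an explicit named vector of paths.
#' @param de_files optional named character vector of DE-table paths.
#' @param evidence,edges,regulons,tf_annotations,dev_sets,universe input
#'   file paths (universe: one gene symbol per line).
#' @param lfc,alpha_de,string_score,alpha_tf,alpha_ora thresholds.
#' @param n_perm GSEA permutations (used by the `enrich` entry point).
#' @param seed RNG seed recorded with the run.
#' @param outdir output directory; created if missing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(de_dir = NULL, de_files = NULL, evidence,
                            edges, regulons, tf_annotations, dev_sets,
                            universe = NULL,
                            lfc = 1, alpha_de = 0.05, string_score = 0.400,
                            alpha_tf = 0.05, alpha_ora = 0.05,
                            n_perm = 1000, seed = 1, outdir = NULL) {
  stopifnot(lfc > 0, alpha_de > 0, string_score > 0, alpha_tf > 0,
            alpha_ora > 0)
  structure(list(de_dir = de_dir, de_files = de_files, evidence = evidence,
                 edges = edges, regulons = regulons,
                 tf_annotations = tf_annotations, dev_sets = dev_sets,
                 universe = universe, lfc = lfc, alpha_de = alpha_de,
                 string_score = string_score, alpha_tf = alpha_tf,
                 alpha_ora = alpha_ora, n_perm = n_perm,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a flat key:value pipeline configuration file
#'
#' One `key: value` pair per line; keys mirror [pipeline_config()]
#' arguments. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path configuration file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  names(vals) <- trimws(keys)
  base <- dirname(normalizePath(path))
  getp <- function(k) {
    if (!k %in% names(vals)) return(NULL)
    p <- vals[[k]]
    if (file.exists(p)) p else file.path(base, p)
  }
  getn <- function(k, default) {
    if (k %in% names(vals)) as.numeric(vals[[k]]) else default
  }
  pipeline_config(
    de_dir = getp("de_dir"), evidence = getp("evidence"),
    edges = getp("edges"), regulons = getp("regulons"),
    tf_annotations = getp("tf_annotations"), dev_sets = getp("dev_sets"),
    universe = getp("universe"),
    lfc = getn("lfc", 1), alpha_de = getn("alpha_de", 0.05),
    string_score = getn("string_score", 0.400),
    alpha_tf = getn("alpha_tf", 0.05), alpha_ora = getn("alpha_ora", 0.05),
    n_perm = getn("n_perm", 1000), seed = getn("seed", 1),
    outdir = if ("outdir" %in% names(vals)) vals[["outdir"]] else NULL)
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: input ingestion, per-dataset significance filtering,
#' cross-dataset frequency scoring, the dual-evidence query filter, regulon
#' enrichment, candidate classification, the embryonic-development ORA
#' filter, network topology before and after augmentation with the
#' prioritized novel TFs, and the final report. Every stage's table is
#' written to `outdir` (when set) and row counts are logged. Any stage error
#' aborts with the stage name.
#'
#' @param config a `pipeline_config`.
#' @return list of class `tf_prioritization` with all stage outputs, a
#'   `summary` list of headline counts, and a `log` character vector.
#' @export
run_pipeline <- function(config) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- ingest
  evidence <- stage("evidence", read_evidence_table(config$evidence))
  ev_sum <- summarize_evidence(evidence)
  note("evidence: ", ev_sum$total, " entries")

  de_paths <- config$de_files
  if (is.null(de_paths)) {
    de_paths <- stage("de_tables", {
      if (is.null(config$de_dir) || !dir.exists(config$de_dir))
        stop("DE table directory not found: ", config$de_dir)
      p <- sort(list.files(config$de_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
      if (length(p) == 0) stop("no DE tables in ", config$de_dir)
      p
    })
  }
  de_tables <- stage("de_tables", lapply(de_paths, read_de_table))
  names(de_tables) <- vapply(de_tables, attr, character(1), "dataset_id")
  note("de_tables: ", length(de_tables), " datasets")

  regulons <- stage("regulons", read_regulons(config$regulons))
  annotations <- stage("tf_annotations",
                       read_tf_annotations(config$tf_annotations))
  dev_sets <- stage("dev_sets", read_gmt(config$dev_sets))
  edges <- stage("edges", read_string_edges(config$edges,
                                            threshold = config$string_score))
  universe <- if (!is.null(config$universe)) {
    stage("universe", canonicalize_symbols(readLines(config$universe)))
  } else NULL

  # -- DE filter + frequency scores
  sig_sets <- stage("de_filter", lapply(de_tables, filter_significant,
                                        lfc_threshold = config$lfc,
                                        alpha = config$alpha_de))
  note("de_filter: ", paste(lengths(sig_sets), collapse = "/"),
       " significant genes per dataset")
  scores <- stage("frequency", frequency_scores(sig_sets, universe = universe))
  cum <- if (!is.null(universe))
    stage("frequency", cumulative_summary(scores, length(universe))) else NULL
  note("frequency: ", sum(scores$score > 0), " genes scored >= 1")

  # -- dual-evidence filter
  lit_genes <- unique(evidence$target[evidence$level == "gene"])
  query <- stage("dual_evidence", dual_evidence_filter(scores, lit_genes))
  note("dual_evidence: ", length(query), " query genes")

  # -- regulon enrichment
  enr_universe <- if (!is.null(universe)) universe else
    unique(c(scores$gene, regulons$target, regulons$tf))
  enriched <- stage("regulon_enrichment",
                    regulon_enrichment(query, regulons, enr_universe,
                                       alpha = config$alpha_tf))
  note("regulon_enrichment: ", nrow(enriched), " TFs pass raw p < ",
       config$alpha_tf, " (", sum(attr(enriched, "all")$p_adj < config$alpha_tf),
       " after BH)")

  # -- classification
  lit_proteins <- unique(evidence$target[evidence$level == "protein"])
  z_set <- c2h2_tfs(annotations)
  venn <- venn_partition(lit_proteins, enriched$tf, z_set)
  candidates <- classify_candidates(enriched, lit_proteins, z_set)
  note("classification: ",
       paste(sprintf("%s=%d", CANDIDATE_CLASSES,
                     vapply(CANDIDATE_CLASSES,
                            function(cl) sum(candidates$candidate_class == cl),
                            integer(1))), collapse = ", "))

  # -- embryonic-development filter on novel C2H2 candidates
  novel <- candidates[candidates$candidate_class == "novel_C2H2", ,
                      drop = FALSE]
  ora_universe <- unique(annotations$symbol[annotations$is_tf])
  devf <- stage("dev_filter",
                embryonic_filter(novel, dev_sets, universe = ora_universe,
                                 alpha = config$alpha_ora))
  note("dev_filter: ", nrow(devf$prioritized), " of ", nrow(novel),
       " novel C2H2 candidates retained")
  candidates$dev_ontology_hit <- candidates$candidate_class != "novel_C2H2" |
    candidates$tf %in% devf$prioritized$tf

  # -- literature network
  net_before <- stage("network", build_graph(edges,
                                             restrict_to = lit_proteins))
  main_before <- stage("network", main_component(net_before))
  stats_before <- topology_stats(main_before$graph)
  cent_before <- stage("network", centralities(main_before$graph))
  ess_before <- rank_essential(cent_before)
  note("network: main component ", stats_before$n_nodes, " nodes / ",
       stats_before$n_edges, " edges; essential: ",
       paste(ess_before$essential, collapse = ", "))

  # -- augmented network with prioritized novel TFs
  new_tfs <- devf$prioritized$tf
  net_after <- stage("augment", augment_network(main_before$graph, new_tfs,
                                                edges))
  main_after <- stage("augment", main_component(net_after))
  cent_after <- stage("augment", centralities(main_after$graph))
  ess_after <- rank_essential(cent_after)
  note("augment: ", length(net_after$joined), " of ", length(new_tfs),
       " new TFs joined the network")

  # -- final report
  report <- final_report(candidates, ess_before, ess_after,
                         freq_scores = scores)

  summary <- list(
    n_evidence_entries = ev_sum$total,
    n_distinct_gene_targets = ev_sum$per_level$gene$n_distinct,
    n_distinct_protein_targets = ev_sum$per_level$protein$n_distinct,
    n_datasets = length(de_tables),
    de_counts_per_k = if (!is.null(cum)) stats::setNames(cum$count, cum$k)
      else NULL,
    n_query = length(query),
    n_enriched_tfs = nrow(enriched),
    venn_cardinalities = as.list(venn$cardinalities),
    n_novel_c2h2 = nrow(novel),
    n_prioritized = nrow(devf$prioritized),
    essential_before = ess_before$essential,
    essential_after = ess_after$essential
  )

  result <- structure(list(
    config = config, evidence_summary = ev_sum, sig_sets = sig_sets,
    frequency_scores = scores, cumulative_summary = cum, query = query,
    enrichment = enriched, venn = venn, candidates = candidates,
    dev_filter = devf, network_before = main_before,
    stats_before = stats_before, essentiality_before = ess_before,
    network_after = main_after, essentiality_after = ess_after,
    report = report, summary = summary, log = log
  ), class = "tf_prioritization")

  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

# Write every intermediate table plus a JSON headline summary.
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_report(result$frequency_scores, fp("frequency_scores.tsv"))
  if (!is.null(result$cumulative_summary))
    write_report(result$cumulative_summary, fp("cumulative_summary.tsv"))
  writeLines(result$query, fp("query_genes.txt"))
  write_report(result$enrichment, fp("regulon_enrichment.tsv"))
  write_report(result$candidates, fp("candidates.tsv"))
  if (!is.null(result$dev_filter$ora))
    write_report(result$dev_filter$ora, fp("dev_ora.tsv"))
  write_report(result$essentiality_before$table, fp("centralities_before.tsv"))
  write_report(result$essentiality_after$table, fp("centralities_after.tsv"))
  export_graph(result$network_before$graph,
               centralities(result$network_before$graph),
               fp("network_before.graphml"), format = "graphml")
  export_graph(result$network_after$graph,
               centralities(result$network_after$graph),
               fp("network_after.graphml"), format = "graphml")
  write_report(result$report, fp("final_report.tsv"))
  jsonlite::write_json(result$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, fp("pipeline.log"))
  invisible(outdir)
}

#' @export
print.tf_prioritization <- function(x, ...) {
  cat("TF prioritization run\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' @export
summary.tf_prioritization <- function(object, ...) {
  s <- object$summary
  cat("Headline counts:\n")
  cat("  evidence entries:        ", s$n_evidence_entries, "\n")
  cat("  query genes:             ", s$n_query, "\n")
  cat("  enriched TFs:            ", s$n_enriched_tfs, "\n")
  cat("  novel C2H2 candidates:   ", s$n_novel_c2h2,
      "(", s$n_prioritized, "after development filter )\n")
  cat("  essential (literature):  ",
      paste(s$essential_before, collapse = ", "), "\n")
  cat("  essential (augmented):   ",
      paste(s$essential_after, collapse = ", "), "\n")
  invisible(s)
}
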