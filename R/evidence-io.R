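#' @title Evidence-table and tabular-format readers/writers
#' @description Readers and writers for every external table dialect the
#'   pipeline touches: literature evidence tables, STRING-style scored edge
#'   lists, TRRUST-style regulons, GMT gene-set collections and TF domain
#'   annotations. All symbol columns are canonicalized on read.
#' @name evidence_io
NULL

EVIDENCE_COLS  <- c("drug", "target", "level", "effect", "system", "source_id")
DRUG_LEVELS   <- c("thalidomide", "lenalidomide", "pomalidomide")
LEVEL_LEVELS  <- c("gene", "protein")
EFFECT_LEVELS <- c("downregulated", "upregulated", "degraded", "bound",
                   "inhibited", "other")

#' Read a literature evidence table
#'
#' Parses a tab-separated table of literature reports of drug effects on
#' genes or proteins, with header
#' `drug target level effect system source_id`. Target symbols are
#' canonicalized (uppercase, trimmed), exact duplicate rows are dropped
#' (with the count recorded), and rows with an unknown drug or level token
#' are rejected row-by-row while valid rows are retained.
#'
#' @param path path to the tab-separated evidence file.
#' @param alias optional alias table passed to [canonicalize_symbols()].
#' @return a data.frame of class `evidence_table` with one row per retained
#'   entry and attributes `n_duplicates` (exact duplicates dropped) and
#'   `row_errors` (data.frame of line numbers and messages for rejected rows).
#' @export
read_evidence_table <- function(path, alias = NULL) {
  df <- read_tsv_base(path)
  missing_cols <- setdiff(EVIDENCE_COLS, names(df))
  if (length(missing_cols) > 0)
    io_stop("evidence table schema error: missing column(s) ",
            paste(missing_cols, collapse = ", "), path = path)
  df <- df[, EVIDENCE_COLS]
  df$target <- canonicalize_symbols(df$target, alias)
  df$drug <- tolower(trimws(df$drug))
  df$level <- tolower(trimws(df$level))
  df$effect <- tolower(trimws(df$effect))

  line_no <- seq_len(nrow(df)) + 1L  # +1 for the header line
  errs <- character(nrow(df))
  errs[!(df$drug %in% DRUG_LEVELS)] <- "unknown drug token"
  errs[!(df$level %in% LEVEL_LEVELS)] <- "unknown level token"
  errs[!(df$effect %in% EFFECT_LEVELS)] <- "unknown effect token"
  errs[!nzchar(df$target)] <- "empty target symbol"
  bad <- nzchar(errs)
  row_errors <- data.frame(line = line_no[bad], message = errs[bad],
                           stringsAsFactors = FALSE)
  df <- df[!bad, , drop = FALSE]

  dup <- duplicated(df)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("evidence_table", "data.frame"),
            n_duplicates = n_dup,
            row_errors = row_errors)
}

#' Write an evidence table
#' @param x an `evidence_table` (or compatible data.frame).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_evidence_table <- function(x, path) {
  write_tsv_base(as.data.frame(x)[, EVIDENCE_COLS], path)
}

#' Summarize an evidence table
#'
#' Counts entries by drug and by level, distinct targets per level,
#' replicated targets (same target, same level, reported in at least two
#' distinct sources), and targets reported at both the gene and protein
#' level. Percentages are one-decimal round-half-even; raw fractions are
#' kept.
#'
#' @param t an `evidence_table`.
#' @return list of class `evidence_summary`.
#' @export
summarize_evidence <- function(t) {
  t <- as.data.frame(t)
  total <- nrow(t)
  by_drug <- vapply(DRUG_LEVELS, function(d) sum(t$drug == d), integer(1))
  by_level <- vapply(LEVEL_LEVELS, function(l) sum(t$level == l), integer(1))

  per_level <- lapply(LEVEL_LEVELS, function(l) {
    sub <- t[t$level == l, , drop = FALSE]
    distinct <- unique(sub$target)
    # replicated: same target at this level in >= 2 distinct source_ids
    n_src <- tapply(sub$source_id, sub$target,
                    function(s) length(unique(s)))
    replicated <- names(n_src)[n_src >= 2]
    list(n_entries = nrow(sub),
         distinct_targets = sort(distinct),
         n_distinct = length(distinct),
         replicated_targets = sort(replicated),
         n_replicated = length(replicated))
  })
  names(per_level) <- LEVEL_LEVELS

  both <- intersect(per_level$gene$distinct_targets,
                    per_level$protein$distinct_targets)

  structure(list(
    total = total,
    by_drug = by_drug,
    by_level = by_level,
    level_pct = vapply(by_level, pct1, numeric(1), total = total),
    level_fraction = if (total > 0) by_level / total else by_level * NA_real_,
    per_level = per_level,
    gene_protein_overlap = sort(both),
    n_gene_protein_overlap = length(both)
  ), class = "evidence_summary")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat("Evidence summary:", x$total, "entries\n")
  cat("  by drug: ",
      paste(sprintf("%s=%d", names(x$by_drug), x$by_drug), collapse = ", "),
      "\n", sep = "")
  for (l in names(x$per_level)) {
    pl <- x$per_level[[l]]
    cat(sprintf("  %s-level: %d entries (%.1f%%), %d distinct targets, %d replicated\n",
                l, pl$n_entries, x$level_pct[[l]], pl$n_distinct,
                pl$n_replicated))
  }
  cat("  targets at both levels:", x$n_gene_protein_overlap, "\n")
  invisible(x)
}

# ---- STRING-style scored edge lists ----------------------------------------

STRING_NODE_COLS <- list(a = c("protein1", "node1", "a", "gene1"),
                         b = c("protein2", "node2", "b", "gene2"))
STRING_SCORE_COLS <- c("combined_score", "score")
STRING_CHANNEL_COLS <- c("experimental", "coexpression", "experiments",
                         "database", "textmining", "neighborhood", "fusion",
                         "cooccurence")

#' Read a STRING-style scored edge list
#'
#' Accepts tab- or space-separated files with two protein columns and one or
#' more score columns. Scores on the 0-999 integer dialect (detected when the
#' maximum value exceeds 1) are divided by 1000. Self-loops are dropped,
#' duplicate unordered pairs are merged keeping the maximum score, and only
#' edges with score strictly greater than `threshold` are retained.
#'
#' @param path path to the edge-list file.
#' @param threshold minimum (strict) score to retain an edge; default 0.400.
#' @param channels optional character vector of channel column names
#'   (e.g. `c("experimental", "coexpression")`); when given, the edge score
#'   is the maximum over those channels instead of the combined score.
#' @return data.frame of class `scored_edges` with columns `a`, `b`, `score`
#'   (a < b lexicographically), and attribute `row_errors`.
#' @export
read_string_edges <- function(path, threshold = 0.400, channels = NULL) {
  if (!file.exists(path)) io_stop("file not found", path = path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  nm <- tolower(names(df))
  pick <- function(cands, fallback) {
    i <- which(nm %in% cands)
    if (length(i) > 0) i[1] else fallback
  }
  ia <- pick(STRING_NODE_COLS$a, 1L)
  ib <- pick(STRING_NODE_COLS$b, 2L)

  if (!is.null(channels)) {
    idx <- which(nm %in% tolower(channels))
    if (length(idx) == 0)
      io_stop("edge list schema error: none of the requested channel columns (",
              paste(channels, collapse = ", "), ") present", path = path)
  } else {
    idx <- which(nm %in% STRING_SCORE_COLS)
    if (length(idx) == 0) idx <- which(nm %in% STRING_CHANNEL_COLS)
    if (length(idx) == 0) {
      num <- setdiff(which(vapply(df, is.numeric, logical(1))), c(ia, ib))
      idx <- utils::tail(num, 1)
    }
    if (length(idx) == 0)
      io_stop("edge list schema error: no recognized score column", path = path)
  }

  score_raw <- df[, idx, drop = FALSE]
  bad_num <- !vapply(score_raw, is.numeric, logical(1))
  if (any(bad_num)) {
    # attempt coercion; rows failing it become row errors
    for (j in which(bad_num)) score_raw[[j]] <- suppressWarnings(as.numeric(score_raw[[j]]))
  }
  score <- do.call(pmax, c(unname(as.list(score_raw)), list(na.rm = TRUE)))
  line_no <- seq_len(nrow(df)) + 1L
  bad <- !is.finite(score)
  row_errors <- data.frame(line = line_no[bad],
                           message = rep("non-numeric score", sum(bad)),
                           stringsAsFactors = FALSE)

  a <- canonicalize_symbols(df[[ia]])
  b <- canonicalize_symbols(df[[ib]])
  keep <- !bad
  a <- a[keep]; b <- b[keep]; score <- score[keep]

  if (length(score) > 0 && max(score) > 1) score <- score / 1000

  loop <- a == b
  a <- a[!loop]; b <- b[!loop]; score <- score[!loop]

  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo) > 0) {
    key <- paste(lo, hi, sep = "\r")
    score <- tapply(score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, character(1), 1L)
    hi <- vapply(parts, `[`, character(1), 2L)
    score <- unname(score)
  }

  keep <- score > threshold
  out <- data.frame(a = lo[keep], b = hi[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scored_edges", "data.frame"),
            row_errors = row_errors)
}

#' Write a scored edge list
#' @param x data.frame with columns `a`, `b`, `score`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_string_edges <- function(x, path) {
  df <- as.data.frame(x)[, c("a", "b", "score")]
  names(df) <- c("protein1", "protein2", "combined_score")
  write_tsv_base(df, path)
}

# ---- TRRUST-style regulons --------------------------------------------------

#' Read a TRRUST-style regulon table
#'
#' Tab-separated with columns `tf`, `target`, `mode`
#' (activation/repression/unknown) and `references` (citation count or
#' comma-separated PMID list, stored as a count).
#'
#' @param path path to the regulon file.
#' @return data.frame of class `regulon_db` (tf, target, mode, references);
#'   self-regulating rows (tf == target) are kept but flagged in the
#'   `self_regulating` attribute.
#' @export
read_regulons <- function(path) {
  df <- read_tsv_base(path)
  need <- c("tf", "target", "mode", "references")
  names(df) <- tolower(names(df))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    io_stop("regulon schema error: missing column(s) ",
            paste(miss, collapse = ", "), path = path)
  df <- df[, need]
  df$tf <- canonicalize_symbols(df$tf)
  df$target <- canonicalize_symbols(df$target)
  df$mode <- tolower(trimws(df$mode))
  df$mode[!(df$mode %in% c("activation", "repression"))] <- "unknown"
  # references may be a PMID list; store a count
  refs <- df$references
  if (!is.numeric(refs)) {
    refs <- vapply(strsplit(as.character(refs), "[,;]"),
                   function(v) length(v[nzchar(trimws(v))]), integer(1))
  }
  df$references <- as.integer(refs)
  df <- df[!duplicated(df[, c("tf", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("regulon_db", "data.frame"),
            self_regulating = df$tf[df$tf == df$target])
}

#' Write a regulon table
#' @param x a `regulon_db` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regulons <- function(x, path) {
  write_tsv_base(as.data.frame(x)[, c("tf", "target", "mode", "references")],
                 path)
}

#' Regulon database as a list of target sets
#' @param db a `regulon_db`.
#' @return named list (one element per TF) of character target vectors.
#' @export
regulon_targets <- function(db) {
  split(db$target, db$tf)
}

# ---- GMT gene sets ----------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Standard Broad GMT: one set per line, tab-separated, `set_id`,
#' description, then members. Lines with fewer than three fields are
#' reported as row errors and skipped.
#'
#' @param path path to the .gmt file.
#' @return named list of character member vectors, class `gene_sets`, with
#'   attributes `descriptions` (named character) and `row_errors`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_stop("file not found", path = path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 3
  row_errors <- data.frame(line = which(bad),
                           message = rep("GMT line with fewer than 3 fields",
                                         sum(bad)),
                           stringsAsFactors = FALSE)
  fields <- fields[!bad]
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    io_stop("GMT error: duplicate set_id ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), path = path)
  desc <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(canonicalize_symbols(f[-(1:2)])))
  names(members) <- ids
  names(desc) <- ids
  structure(members, class = "gene_sets",
            descriptions = desc, row_errors = row_errors)
}

#' Write a GMT gene-set collection
#' @param sets named list of character member vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- TF annotations ---------------------------------------------------------

#' Read a TF annotation table
#'
#' Tab-separated with columns `symbol`, `is_tf` (TRUE/FALSE), `dbd_class`
#' (C2H2 / other / unknown). A C2H2 domain class on a non-TF row violates
#' the annotation contract and is an error.
#'
#' @param path path to the annotation file.
#' @return data.frame of class `tf_annotations`.
#' @export
read_tf_annotations <- function(path) {
  df <- read_tsv_base(path)
  names(df) <- tolower(names(df))
  need <- c("symbol", "is_tf", "dbd_class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    io_stop("annotation schema error: missing column(s) ",
            paste(miss, collapse = ", "), path = path)
  df <- df[, need]
  df$symbol <- canonicalize_symbols(df$symbol)
  df$is_tf <- as.logical(df$is_tf)
  cls <- df$dbd_class
  df$dbd_class <- ifelse(toupper(trimws(cls)) == "C2H2", "C2H2",
                         ifelse(tolower(trimws(cls)) == "other", "other",
                                "unknown"))
  if (any(df$dbd_class == "C2H2" & !df$is_tf))
    io_stop("annotation error: C2H2 dbd_class on a non-TF row", path = path)
  df <- df[!duplicated(df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("tf_annotations", "data.frame"))
}

#' Write a TF annotation table
#' @param x a `tf_annotations` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tf_annotations <- function(x, path) {
  write_tsv_base(as.data.frame(x)[, c("symbol", "is_tf", "dbd_class")], path)
}

#' C2H2 transcription factors from an annotation table
#' @param annot a `tf_annotations` data.frame.
#' @return character vector of C2H2 TF symbols.
#' @export
c2h2_tfs <- function(annot) {
  sort(annot$symbol[annot$is_tf & annot$dbd_class == "C2H2"])
}

#' Write any tabular pipeline object to a tab-separated file
#' @param obj a data.frame (or coercible object).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(obj, path) {
  df <- as.data.frame(obj)
  # flatten list columns for text output
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","),
                        character(1))
  }
  write_tsv_base(df, path)
}
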