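#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted by default; an optional alias table (named character vector,
#' `names` = alias, value = canonical symbol) can be supplied to remap
#' symbols after the basic cleanup.
#'
#' @param x character vector of gene symbols.
#' @param alias optional named character vector mapping alias -> symbol.
#' @return character vector of canonical symbols.
#' @export
canonicalize_symbols <- function(x, alias = NULL) {
  out <- toupper(trimws(as.character(x)))
  if (!is.null(alias)) {
    names(alias) <- toupper(trimws(names(alias)))
    hit <- match(out, names(alias))
    out[!is.na(hit)] <- toupper(trimws(alias[hit[!is.na(hit)]]))
  }
  out
}

#' One-decimal percentage (round half to even)
#'
#' Percentages throughout the package are reported to one decimal using R's
#' round-half-even convention; the raw fraction is always kept alongside so
#' no information is lost to formatting.
#'
#' @param count numerator.
#' @param total denominator.
#' @return numeric percentage rounded to one decimal.
#' @export
pct1 <- function(count, total) {
  if (total <= 0) return(NA_real_)
  round(100 * count / total, 1)
}

# Stop with a consistent message naming the offending file/stage.
io_stop <- function(..., path = NULL) {
  msg <- paste0(...)
  if (!is.null(path)) msg <- paste0(msg, " [file: ", path, "]")
  stop(msg, call. = FALSE)
}

# Read a tab-separated file with a header, keeping strings as characters.
read_tsv_base <- function(path) {
  if (!file.exists(path)) io_stop("file not found", path = path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "")
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Deterministic sub-seeds fanned out from one global seed, so individual
# components of a scenario are reproducible in isolation.
fan_out_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
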