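# Shared internal helpers: hash-headed TSV IO, row keys, small numeric utils.

geomean <- function(x) exp(mean(log(x)))

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Read a tab-separated table with a '#'-prefixed header line
#'
#' All plain-text tables in this package share one dialect: tab-separated,
#' UTF-8, no quoting, first line a header prefixed with `#`.
#'
#' @param path File path.
#' @param col_types Optional readr column specification.
#' @return A tibble.
#' @keywords internal
#' @noRd
read_tsv_hash <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    warn(paste0("empty file: ", path))
    return(tibble::tibble())
  }
  cols <- strsplit(sub("^#\\s*", "", header), "\t", fixed = TRUE)[[1]]
  readr::read_tsv(path, skip = 1L, col_names = cols, col_types = col_types,
                  quote = "", progress = FALSE,
                  show_col_types = FALSE, na = c("NA", ""))
}

write_tsv_hash <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = FALSE, quote = "none",
                   progress = FALSE)
  invisible(path)
}

# Row keys for exon count tables: gene_id:E### (bin index zero-padded to 3).
make_row_key <- function(gene_id, bin_index) {
  if (any(grepl(":", gene_id, fixed = TRUE))) {
    abort("gene_id must not contain ':' (reserved for count-table row keys)")
  }
  sprintf("%s:E%03d", gene_id, bin_index)
}

parse_row_key <- function(key) {
  ok <- grepl("^[^:]+:E[0-9]{3,}$", key)
  if (!all(ok)) {
    abort(paste0("malformed row key(s): ",
                 paste(head(key[!ok], 5L), collapse = ", ")))
  }
  tibble::tibble(
    gene_id = sub(":E[0-9]+$", "", key),
    bin_index = as.integer(sub("^.*:E", "", key))
  )
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
}
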