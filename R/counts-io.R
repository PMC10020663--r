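#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `condition` (`control` or
#'   `treatment`), `sex` (`M`, `F` or `NA`) and `replicate`.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path) {
  tab <- read_tsv_hash(path)
  validate_sample_table(tab)
  tibble::tibble(
    sample_id = as.character(tab$sample_id),
    condition = as.character(tab$condition),
    sex = as.character(tab$sex),
    replicate = as.integer(tab$replicate)
  )
}

validate_sample_table <- function(samples) {
  required <- c("sample_id", "condition", "sex", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    abort(paste0("sample table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (!all(samples$condition %in% c("control", "treatment"))) {
    abort("condition must be 'control' or 'treatment'")
  }
  if (!all(samples$sex %in% c("M", "F") | is.na(samples$sex))) {
    abort("sex must be 'M', 'F' or NA")
  }
  invisible(samples)
}

#' Write a sample metadata table
#' @param samples Sample tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  write_tsv_hash(samples, path)
}

#' Read an exon-by-sample count matrix
#'
#' The count TSV has one row per exon bin keyed `gene_id:E###` (bin index
#' zero-padded to three digits) and one column per sample. Counts must be
#' non-negative integers; every row key must exist in the gene models and
#' every column in the sample table.
#'
#' @param path Count TSV path.
#' @param models Exon-bin tibble from [read_exon_annotation()].
#' @param samples Sample tibble.
#' @param allow_missing If `TRUE`, bins present in `models` but absent from
#'   the file are tolerated (treated as absent, not zero-filled); the
#'   default is an error.
#' @return A count tibble with columns `gene_id`, `bin_index` and one
#'   integer column per sample.
#' @export
read_counts <- function(path, models, samples, allow_missing = FALSE) {
  tab <- read_tsv_hash(path)
  if (nrow(tab) == 0L) {
    return(tibble::tibble(gene_id = character(), bin_index = integer()))
  }
  key_col <- names(tab)[1L]
  keys <- parse_row_key(as.character(tab[[key_col]]))
  count_cols <- setdiff(names(tab), key_col)
  unknown <- setdiff(count_cols, samples$sample_id)
  if (length(unknown) > 0L) {
    abort(paste0("count columns not in sample table: ",
                 paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(samples$sample_id, count_cols)
  if (length(absent) > 0L) {
    abort(paste0("samples missing from count table: ",
                 paste(absent, collapse = ", ")))
  }
  vals <- as.matrix(tab[count_cols])
  if (!is.numeric(vals) || any(!is.finite(vals)) ||
      any(vals < 0) || any(vals != floor(vals))) {
    abort("counts must be non-negative integers")
  }
  counts <- dplyr::bind_cols(keys, tibble::as_tibble(tab[count_cols]))
  counts[count_cols] <- lapply(counts[count_cols], as.integer)

  model_keys <- paste(models$gene_id, models$bin_index)
  count_keys <- paste(counts$gene_id, counts$bin_index)
  orphan <- !count_keys %in% model_keys
  if (any(orphan)) {
    abort(paste0("count row(s) not in gene models: ",
                 paste(head(count_keys[orphan], 5L), collapse = ", ")))
  }
  if (!allow_missing && length(setdiff(model_keys, count_keys)) > 0L) {
    abort(paste0(length(setdiff(model_keys, count_keys)),
                 " exon bin(s) in the models have no count row ",
                 "(set allow_missing = TRUE to accept)"))
  }
  # canonical order and columns
  counts <- counts[order(counts$gene_id, counts$bin_index),
                   c("gene_id", "bin_index", samples$sample_id)]
  tibble::as_tibble(counts)
}

#' Write an exon-by-sample count matrix
#' @param counts Count tibble (`gene_id`, `bin_index`, sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  sample_cols <- setdiff(names(counts), c("gene_id", "bin_index"))
  out <- dplyr::bind_cols(
    tibble::tibble(exon_id = make_row_key(counts$gene_id, counts$bin_index)),
    counts[sample_cols]
  )
  write_tsv_hash(out, path)
}

#' Import per-exon statistics from an external exon-usage tool
#'
#' Adapter for feeding the cryptic-transcription caller with statistics
#' computed elsewhere (e.g. a published differential exon-usage package).
#' `column_map` names the file columns holding each required field.
#'
#' @param path Statistics TSV path.
#' @param column_map Named character vector with entries `gene_id`, `p`,
#'   `log2fc`, and either `bin_index` or `row_key`; optionally `mean_count`
#'   (used together with `filter` to set the `expressed` flag).
#' @param filter [filter_params()] used for the `expressed` flag when a
#'   `mean_count` column is mapped; without one all exons are flagged
#'   expressed with a warning.
#' @return A tibble of per-exon test results with `source = "imported"`.
#' @export
read_exon_stats <- function(path, column_map, filter = filter_params()) {
  tab <- read_tsv_hash(path)
  need <- c("gene_id", "p", "log2fc")
  if (!all(need %in% names(column_map))) {
    abort("column_map must name 'gene_id', 'p' and 'log2fc' columns")
  }
  if (!any(c("bin_index", "row_key") %in% names(column_map))) {
    abort("column_map must name a 'bin_index' or 'row_key' column")
  }
  bad <- setdiff(unname(column_map), names(tab))
  if (length(bad) > 0L) {
    abort(paste0("mapped column(s) absent from file: ", paste(bad, collapse = ", ")))
  }
  if ("row_key" %in% names(column_map)) {
    keys <- parse_row_key(as.character(tab[[column_map[["row_key"]]]]))
    gene_id <- keys$gene_id
    bin_index <- keys$bin_index
  } else {
    gene_id <- as.character(tab[[column_map[["gene_id"]]]])
    raw_idx <- as.character(tab[[column_map[["bin_index"]]]])
    bin_index <- suppressWarnings(as.integer(sub("^E", "", raw_idx)))
    if (any(is.na(bin_index))) {
      abort(paste0("unparseable exon index at row(s): ",
                   paste(head(which(is.na(bin_index)), 5L), collapse = ", ")))
    }
  }
  p <- suppressWarnings(as.numeric(as.character(tab[[column_map[["p"]]]])))
  lfc <- suppressWarnings(as.numeric(as.character(tab[[column_map[["log2fc"]]]])))
  bad_rows <- which(is.na(p) | is.na(lfc))
  if (length(bad_rows) > 0L) {
    abort(paste0("unparseable p or log2fc at row(s): ",
                 paste(head(bad_rows, 10L), collapse = ", ")))
  }
  if (any(p < 0 | p > 1)) {
    abort(paste0("p-value outside [0, 1] at row(s): ",
                 paste(head(which(p < 0 | p > 1), 10L), collapse = ", ")))
  }
  if (anyDuplicated(paste(gene_id, bin_index))) {
    dup <- paste(gene_id, bin_index)[duplicated(paste(gene_id, bin_index))]
    abort(paste0("duplicate (gene, exon) row(s): ", paste(head(dup, 5L), collapse = ", ")))
  }
  if ("mean_count" %in% names(column_map)) {
    mc <- as.numeric(tab[[column_map[["mean_count"]]]])
    expressed <- mc > filter$min_count
  } else {
    warn("no mean_count column mapped; flagging all imported exons as expressed")
    expressed <- rep(TRUE, nrow(tab))
  }
  tibble::tibble(
    gene_id = gene_id,
    bin_index = bin_index,
    mean_control = NA_real_,
    mean_treatment = NA_real_,
    log2fc = lfc,
    p = p,
    direction = dplyr::case_when(lfc > 0 ~ "up", lfc < 0 ~ "down", TRUE ~ "none"),
    expressed = expressed,
    source = "imported"
  ) |>
    dplyr::arrange(.data$gene_id, .data$bin_index)
}

#' Export cryptic-TSS calls as a BED6 track
#'
#' Writes one BED record per passing gene spanning its cryptic-TSS exon bin
#' (0-based half-open), with `name` the gene id, `score` the downstream
#' significant fraction scaled to 0-1000, and the gene strand.
#'
#' @param calls Cryptic-call tibble (see [call_all()]).
#' @param models Exon-bin tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cryptic_bed <- function(calls, models, path) {
  pass <- calls[calls$decision == "PASS", , drop = FALSE]
  unknown <- setdiff(pass$gene_id, models$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("call(s) reference unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(pass) == 0L) {
    writeLines("# no passing cryptic-transcription calls", path)
    return(invisible(path))
  }
  bins <- dplyr::inner_join(
    pass, models,
    by = c("gene_id", ctss_index = "bin_index")
  )
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   bins$chrom, bins$start, bins$end, bins$gene_id,
                   as.integer(round(1000 * bins$downstream_frac)), bins$strand)
  writeLines(lines, path)
  invisible(path)
}
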