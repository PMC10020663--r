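#' Exon-bin gene models
#'
#' A set of gene models is represented as a tibble of exon bins with one row
#' per bin and columns `gene_id`, `bin_index`, `chrom`, `start`, `end`,
#' `strand`. Coordinates are stored 0-based half-open internally; GFF input
#' and output use the standard 1-based inclusive convention, BED output
#' 0-based half-open. `bin_index` counts bins in transcriptional (5' to 3')
#' order: ascending genomic coordinate on the `+` strand, descending on `-`.
#'
#' @param models A tibble of exon bins.
#' @return `validate_exon_models()` returns its input invisibly after
#'   checking all structural invariants; it aborts with an informative
#'   message on the first violation.
#' @export
validate_exon_models <- function(models) {
  required <- c("gene_id", "bin_index", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(models))
  if (length(missing) > 0L) {
    abort(paste0("exon models lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(models) == 0L) return(invisible(models))
  if (!all(models$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(models$start != floor(models$start)) ||
      any(models$end != floor(models$end))) {
    abort("exon coordinates must be integers")
  }
  if (any(models$start >= models$end)) {
    bad <- models$gene_id[models$start >= models$end][1L]
    abort(paste0("empty or inverted exon bin in gene ", bad))
  }
  by_gene <- dplyr::group_by(models, .data$gene_id)
  mixed <- dplyr::summarise(by_gene, n_strand = dplyr::n_distinct(.data$strand))
  if (any(mixed$n_strand > 1L)) {
    abort(paste0("mixed strands within gene ",
                 mixed$gene_id[mixed$n_strand > 1L][1L]))
  }
  chk <- dplyr::summarise(
    by_gene,
    contiguous = identical(sort(.data$bin_index), seq_len(dplyr::n())),
    overlapping = {
      o <- order(.data$start)
      any(.data$start[o][-1L] < .data$end[o][-length(o)])
    },
    ordered = {
      o <- order(.data$bin_index)
      s <- .data$start[o]
      if (.data$strand[1L] == "+") all(diff(s) > 0) else all(diff(s) < 0)
    }
  )
  if (any(!chk$contiguous)) {
    abort(paste0("bin_index not contiguous from 1 in gene ",
                 chk$gene_id[!chk$contiguous][1L]))
  }
  if (any(chk$overlapping)) {
    abort(paste0("overlapping exon bins within gene ",
                 chk$gene_id[chk$overlapping][1L]))
  }
  if (any(!chk$ordered)) {
    abort(paste0("bin_index not in transcriptional order in gene ",
                 chk$gene_id[!chk$ordered][1L]))
  }
  invisible(models)
}

#' Order exon bins transcriptionally
#'
#' Sorts the bins of a single gene 5' to 3' (ascending genomic start on the
#' `+` strand, descending on `-`) and rewrites `bin_index` as 1..E.
#'
#' @param bins Tibble of exon bins for one gene (columns `start`, `end`, and
#'   optionally the other model columns).
#' @param strand `"+"` or `"-"`; taken from a `strand` column when omitted.
#' @return The reordered tibble with a fresh `bin_index` column.
#' @export
transcriptional_order <- function(bins, strand = NULL) {
  strand <- strand %||% unique(bins$strand)
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    abort("strand must be a single '+' or '-'")
  }
  o <- order(bins$start, decreasing = (strand == "-"))
  out <- bins[o, , drop = FALSE]
  out$bin_index <- seq_len(nrow(out))
  out
}

#' Read flattened exon-bin annotation
#'
#' Reads a flattened (collapsed exon counting bin) annotation in either the
#' GFF dialect produced by exon-flattening preprocessors (`exonic_part`
#' records carrying `gene_id` and `exonic_part_number` attributes, 1-based
#' inclusive coordinates) or a plain TSV with columns `gene_id`, `chrom`,
#' `start`, `end`, `strand` (1-based inclusive) and optional `exon_index`.
#'
#' Coordinates are converted to the internal 0-based half-open convention;
#' when no bin index is present in the file, indices are assigned in
#' transcriptional order. The result is validated (no overlapping bins
#' within a gene, consistent strand, contiguous indices).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff"` or `"tsv"`.
#' @return A tibble of exon bins (see [validate_exon_models()]).
#' @export
read_exon_annotation <- function(path, format = c("auto", "gff", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$|\\.gtf$", path, ignore.case = TRUE)) "gff" else "tsv"
  }
  raw <- if (format == "gff") read_annotation_gff(path) else read_annotation_tsv(path)
  if (nrow(raw) == 0L) {
    warn(paste0("no exon bins found in ", path))
    return(empty_exon_models())
  }
  models <- raw |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$strand) > 1L) {
        abort(paste0("mixed strands within gene ", key$gene_id))
      }
      if (all(is.na(df$bin_index))) {
        df <- transcriptional_order(df, df$strand[1L])
      } else if (any(is.na(df$bin_index))) {
        abort(paste0("gene ", key$gene_id, " has a partial exon index"))
      } else {
        df <- df[order(df$bin_index), , drop = FALSE]
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "bin_index", "chrom", "start", "end", "strand") |>
    dplyr::arrange(.data$gene_id, .data$bin_index)
  validate_exon_models(models)
  models
}

read_annotation_gff <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  body <- readLines(path)
  if (!any(nzchar(body) & !startsWith(body, "#"))) {
    return(empty_exon_models())
  }
  gr <- rtracklayer::import(path)
  keep <- as.character(gr$type) == "exonic_part"
  gr <- gr[keep]
  if (length(gr) == 0L) return(empty_exon_models())
  df <- as.data.frame(gr)
  idx <- df$exonic_part_number
  tibble::tibble(
    gene_id = as.character(df$gene_id),
    bin_index = if (is.null(idx)) NA_integer_ else as.integer(idx),
    chrom = as.character(df$seqnames),
    # GFF is 1-based inclusive; internal storage is 0-based half-open
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
}

read_annotation_tsv <- function(path) {
  tab <- read_tsv_hash(path)
  if (nrow(tab) == 0L) return(empty_exon_models())
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("annotation TSV lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(tab$start) || !is.numeric(tab$end) ||
      any(tab$start != floor(tab$start)) || any(tab$end != floor(tab$end))) {
    abort("non-integer coordinates in annotation TSV")
  }
  tibble::tibble(
    gene_id = as.character(tab$gene_id),
    bin_index = if ("exon_index" %in% names(tab)) as.integer(tab$exon_index) else NA_integer_,
    chrom = as.character(tab$chrom),
    start = as.integer(tab$start) - 1L,
    end = as.integer(tab$end),
    strand = as.character(tab$strand)
  )
}

empty_exon_models <- function() {
  tibble::tibble(
    gene_id = character(), bin_index = integer(), chrom = character(),
    start = integer(), end = integer(), strand = character()
  )
}

#' Write exon-bin annotation
#'
#' Inverse of [read_exon_annotation()]: emits either the flattened-GFF
#' dialect (`aggregate_gene` plus `exonic_part` records, 1-based inclusive)
#' or the plain TSV dialect (1-based inclusive with an `exon_index` column).
#'
#' @param models Exon-bin tibble.
#' @param path Output file.
#' @param format `"gff"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_exon_annotation <- function(models, path, format = c("gff", "tsv")) {
  format <- match.arg(format)
  validate_exon_models(models)
  if (format == "tsv") {
    out <- tibble::tibble(
      gene_id = models$gene_id,
      chrom = models$chrom,
      start = models$start + 1L,
      end = models$end,
      strand = models$strand,
      exon_index = models$bin_index
    )
    return(write_tsv_hash(out, path))
  }
  lines <- character(0)
  for (g in split(models, factor(models$gene_id, unique(models$gene_id)))) {
    gid <- g$gene_id[1L]
    lines <- c(lines, sprintf(
      "%s\tcrypticall\taggregate_gene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"",
      g$chrom[1L], min(g$start) + 1L, max(g$end), g$strand[1L], gid
    ))
    lines <- c(lines, sprintf(
      paste0("%s\tcrypticall\texonic_part\t%d\t%d\t.\t%s\t.\t",
             "transcripts \"%s.t1\"; exonic_part_number \"%03d\"; gene_id \"%s\""),
      g$chrom, g$start + 1L, g$end, g$strand, gid, g$bin_index, gid
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Number of genes in an annotation
#'
#' Convenience helper for overlap tests: the universe size N implied by an
#' annotation is its number of distinct gene models.
#'
#' @param models Exon-bin tibble or path to an annotation file.
#' @return Integer count of distinct genes.
#' @export
universe_size <- function(models) {
  if (is.character(models)) models <- read_exon_annotation(models)
  dplyr::n_distinct(models$gene_id)
}
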