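#' Cryptic-transcription caller parameters
#'
#' Controls the rule cascade of [call_cryptic()]. Defaults follow the
#' published protocol: per-exon significance at raw p < 0.05, at least 60
#' percent of downstream exons significantly elevated, and the candidate
#' internal TSS required to lie among the first half of the gene's exons.
#'
#' @param sig_alpha Per-exon significance threshold defining an elevated
#'   ("significantly higher") exon.
#' @param min_downstream_frac Minimum fraction of downstream exons that
#'   must be significantly elevated; exactly this value passes (the rule
#'   filters out genes strictly below it).
#' @param first_half_rule Require the candidate TSS among the first half
#'   of all exons.
#' @param half_boundary `"ceiling"` reads "first half" inclusively for odd
#'   exon numbers (c <= ceil(E/2)); `"floor"` uses floor(E/2).
#' @param include_tss_in_downstream Count the candidate TSS exon itself in
#'   the downstream set (it is itself elevated under internal initiation).
#' @param require_expressed_denominator Restrict the downstream-fraction
#'   denominator to expressed exons.
#' @param min_exons Minimum exon count for a gene to be callable.
#' @return A `caller_params` list.
#' @export
caller_params <- function(sig_alpha = 0.05, min_downstream_frac = 0.60,
                          first_half_rule = TRUE,
                          half_boundary = c("ceiling", "floor"),
                          include_tss_in_downstream = TRUE,
                          require_expressed_denominator = FALSE,
                          min_exons = 1) {
  half_boundary <- match.arg(half_boundary)
  if (sig_alpha <= 0 || sig_alpha >= 1) abort("sig_alpha must be in (0, 1)")
  if (min_downstream_frac <= 0 || min_downstream_frac > 1) {
    abort("min_downstream_frac must be in (0, 1]")
  }
  structure(list(
    sig_alpha = sig_alpha, min_downstream_frac = min_downstream_frac,
    first_half_rule = first_half_rule, half_boundary = half_boundary,
    include_tss_in_downstream = include_tss_in_downstream,
    require_expressed_denominator = require_expressed_denominator,
    min_exons = as.integer(min_exons)
  ), class = "caller_params")
}

call_reasons <- c("PASS", "NO_UP", "FULL_LENGTH_UP", "DOWNSTREAM_FRAC",
                  "LATE_TSS", "NOT_EXPRESSED", "TOO_FEW_EXONS")

#' Call cryptic transcription for one gene
#'
#' Applies the rule cascade to a gene's exon-level statistics, in
#' transcriptional order:
#' \enumerate{
#'   \item at least one exon must be significantly elevated in treatment
#'     (`NO_UP` otherwise);
#'   \item a gene whose first annotated and expressed exon is itself
#'     significantly elevated is discarded as a full-length upregulation
#'     (`FULL_LENGTH_UP`);
#'   \item the candidate cryptic TSS is the first significantly elevated
#'     exon;
#'   \item genes with fewer than `min_downstream_frac` of the downstream
#'     exons significantly elevated are filtered out (`DOWNSTREAM_FRAC`);
#'   \item the candidate TSS must lie among the first half of all exons
#'     (`LATE_TSS`).
#' }
#' Genes with no expressed exon (`NOT_EXPRESSED`) or fewer than `min_exons`
#' bins (`TOO_FEW_EXONS`) are screened out up front.
#'
#' @param results Tibble of per-exon statistics for one gene with columns
#'   `bin_index` (1..E, complete), `p`, `direction`, `expressed`, and
#'   optionally `gene_id`.
#' @param params [caller_params()].
#' @param n_exons Total exon count E; defaults to the number of result
#'   rows, and must agree with it.
#' @return One-row tibble: `gene_id`, `decision` (`PASS`/`FAIL`), `reason`,
#'   `ctss_index`, `downstream_frac`, `n_exons`.
#' @export
call_cryptic <- function(results, params = caller_params(), n_exons = NULL) {
  gene <- if ("gene_id" %in% names(results)) {
    unique(results$gene_id)
  } else {
    NA_character_
  }
  if (length(gene) != 1L) abort("call_cryptic() expects a single gene")
  E <- as.integer(n_exons %||% nrow(results))
  if (E != nrow(results)) {
    abort(paste0("gene ", gene, ": n_exons (", E, ") does not match the ",
                 nrow(results), " exon results"))
  }
  o <- order(results$bin_index)
  results <- results[o, , drop = FALSE]
  if (!identical(as.integer(results$bin_index), seq_len(E))) {
    abort(paste0("gene ", gene, ": exon results must cover bins 1..E ",
                 "without gaps or duplicates"))
  }

  done <- function(reason, ctss = NA_integer_, frac = NA_real_) {
    tibble::tibble(
      gene_id = gene,
      decision = if (reason == "PASS") "PASS" else "FAIL",
      reason = reason, ctss_index = as.integer(ctss),
      downstream_frac = frac, n_exons = E
    )
  }

  if (E < params$min_exons) return(done("TOO_FEW_EXONS"))
  expressed <- as.logical(results$expressed)
  if (!any(expressed)) return(done("NOT_EXPRESSED"))
  sig_up <- results$p < params$sig_alpha & results$direction == "up"
  if (!any(sig_up)) return(done("NO_UP"))
  x1 <- which(expressed)[1L]
  if (sig_up[x1]) return(done("FULL_LENGTH_UP"))
  ctss <- which(sig_up)[1L]
  D <- if (params$include_tss_in_downstream) seq(ctss, E) else {
    if (ctss < E) seq(ctss + 1L, E) else integer(0)
  }
  if (params$require_expressed_denominator) D <- D[expressed[D]]
  # an empty denominator imposes no downstream constraint
  frac <- if (length(D) == 0L) 1 else mean(sig_up[D])
  if (frac < params$min_downstream_frac) {
    return(done("DOWNSTREAM_FRAC", ctss, frac))
  }
  half <- if (params$half_boundary == "ceiling") ceiling(E / 2) else floor(E / 2)
  if (params$first_half_rule && ctss > half) {
    return(done("LATE_TSS", ctss, frac))
  }
  done("PASS", ctss, frac)
}

#' Call cryptic transcription across all genes
#'
#' Runs [call_cryptic()] for every gene present in an exon-level results
#' table and tallies decisions by reason.
#'
#' @param results Exon-level statistics tibble ([exon_test()] output or
#'   [read_exon_stats()] import).
#' @param models Optional exon-bin tibble used to check that each gene's
#'   results cover its full exon complement.
#' @param params [caller_params()].
#' @return A `cryptic_calls` object: list with `calls` (one row per gene,
#'   ordered by `gene_id`), `summary` (counts per reason), and `params`.
#'   `tidy()` extracts the calls, `glance()` the summary as one row.
#' @export
call_all <- function(results, models = NULL, params = caller_params()) {
  if (nrow(results) == 0L) {
    calls <- tibble::tibble(gene_id = character(), decision = character(),
                            reason = character(), ctss_index = integer(),
                            downstream_frac = double(), n_exons = integer())
  } else {
    n_exons_of <- NULL
    if (!is.null(models)) {
      n_exons_of <- models |>
        dplyr::count(.data$gene_id, name = "n_exons")
      extra <- setdiff(unique(results$gene_id), n_exons_of$gene_id)
      if (length(extra) > 0L) {
        abort(paste0("results reference gene(s) absent from models: ",
                     paste(head(extra, 5L), collapse = ", ")))
      }
    }
    calls <- results |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_split() |>
      purrr::map(function(df) {
        ne <- if (is.null(n_exons_of)) NULL else {
          n_exons_of$n_exons[n_exons_of$gene_id == df$gene_id[1L]]
        }
        call_cryptic(df, params, n_exons = ne)
      }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$gene_id)
  }
  summary <- tibble::tibble(reason = call_reasons) |>
    dplyr::left_join(dplyr::count(calls, .data$reason), by = "reason") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(list(calls = calls, summary = summary, params = params),
            class = "cryptic_calls")
}

#' @export
print.cryptic_calls <- function(x, ...) {
  cat("<cryptic_calls> ", nrow(x$calls), " genes, ",
      sum(x$calls$decision == "PASS"), " PASS\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cryptic_calls <- function(x, ...) x$calls

#' @export
glance.cryptic_calls <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "reason",
                             values_from = "n")
  names(wide) <- paste0("n_", tolower(names(wide)))
  dplyr::bind_cols(tibble::tibble(n_genes = nrow(x$calls)), wide)
}

#' Evaluate calls against simulation ground truth
#'
#' Joins calls to the per-gene truth table of a simulated experiment and
#' computes recovery metrics: sensitivity over CRYPTIC genes, specificity
#' and pass rate over NULL genes, false discovery rate among passing calls,
#' exact cryptic-TSS recovery among true positives, and a class-by-reason
#' confusion table.
#'
#' @param calls `cryptic_calls` object or its calls tibble.
#' @param truth `cryptic_sim` object, its `truth` element, or the per-gene
#'   truth tibble.
#' @return A `cryptic_eval` list with `metrics` (one-row tibble),
#'   `confusion` (class x reason counts), and `per_gene` (joined table).
#' @export
evaluate_vs_truth <- function(calls, truth) {
  if (inherits(calls, "cryptic_calls")) calls <- calls$calls
  if (inherits(truth, "cryptic_sim")) truth <- truth$truth
  if (is.list(truth) && !is.data.frame(truth) && "genes" %in% names(truth)) {
    truth <- truth$genes
  }
  if (!setequal(calls$gene_id, truth$gene_id)) {
    abort("calls and truth cover different gene universes")
  }
  per_gene <- dplyr::inner_join(
    calls, dplyr::rename(truth, true_ctss = "ctss_index"), by = "gene_id"
  )
  pass <- per_gene$decision == "PASS"
  is_cryptic <- per_gene$class == "CRYPTIC"
  is_null <- per_gene$class == "NULL"
  tp <- pass & is_cryptic
  metrics <- tibble::tibble(
    n_genes = nrow(per_gene),
    n_pass = sum(pass),
    sensitivity = if (any(is_cryptic)) mean(pass[is_cryptic]) else NA_real_,
    specificity = if (any(is_null)) mean(!pass[is_null]) else NA_real_,
    null_pass_rate = if (any(is_null)) mean(pass[is_null]) else NA_real_,
    fdr = if (any(pass)) mean(!is_cryptic[pass]) else 0,
    ctss_exact_rate = if (any(tp)) {
      mean(per_gene$ctss_index[tp] == per_gene$true_ctss[tp])
    } else {
      NA_real_
    }
  )
  confusion <- per_gene |>
    dplyr::count(.data$class, .data$reason) |>
    dplyr::arrange(.data$class, .data$reason)
  structure(list(metrics = metrics, confusion = confusion,
                 per_gene = per_gene),
            class = "cryptic_eval")
}

#' @export
print.cryptic_eval <- function(x, ...) {
  cat("<cryptic_eval>\n")
  print(x$metrics)
  print(x$confusion, n = 30)
  invisible(x)
}

#' @export
glance.cryptic_eval <- function(x, ...) x$metrics

#' @export
tidy.cryptic_eval <- function(x, ...) x$confusion
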