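#' Expression prefilter parameters
#'
#' Features are kept when strictly more than `min_count` reads are seen in
#' at least `min_samples` samples.
#'
#' @param min_count Count threshold (strict inequality).
#' @param min_samples Minimum number of samples exceeding it.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_count = 10, min_samples = 2) {
  if (min_count < 1 || min_samples < 1) {
    abort("min_count and min_samples must be >= 1")
  }
  structure(list(min_count = min_count, min_samples = min_samples),
            class = "filter_params")
}

#' Two-group test parameters
#'
#' @param deg_alpha Significance threshold for reporting gene-level
#'   differential expression.
#' @param deu_alpha Significance threshold for reporting exon-level
#'   differential usage.
#' @param pseudocount Symmetric pseudocount used inside ratios and
#'   variance terms; raw zeros are preserved in outputs.
#' @param dispersion_floor,dispersion_cap Clamp for the per-feature moment
#'   dispersion estimate.
#' @param mode `"absolute"` tests normalized exon counts directly;
#'   `"relative"` replaces the library size factor with a per-gene factor
#'   so that exon counts are tested relative to their own gene's total.
#' @return A `test_params` list.
#' @export
test_params <- function(deg_alpha = 0.01, deu_alpha = 0.001,
                        pseudocount = 0.5, dispersion_floor = 1e-8,
                        dispersion_cap = 10,
                        mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (deg_alpha <= 0 || deg_alpha >= 1 || deu_alpha <= 0 || deu_alpha >= 1) {
    abort("alphas must lie in (0, 1)")
  }
  if (dispersion_floor >= dispersion_cap) abort("dispersion_floor must be < cap")
  structure(list(deg_alpha = deg_alpha, deu_alpha = deu_alpha,
                 pseudocount = pseudocount,
                 dispersion_floor = dispersion_floor,
                 dispersion_cap = dispersion_cap, mode = mode),
            class = "test_params")
}

key_cols <- function(counts) intersect(c("gene_id", "bin_index"), names(counts))

counts_matrix <- function(counts) {
  kc <- key_cols(counts)
  m <- as.matrix(counts[setdiff(names(counts), kc)])
  rownames(m) <- if ("bin_index" %in% kc) {
    make_row_key(counts$gene_id, counts$bin_index)
  } else {
    counts$gene_id
  }
  m
}

#' Prefilter low-expression features
#'
#' Keeps features with counts strictly greater than `min_count` in at least
#' `min_samples` samples, at either exon level (`gene_id` + `bin_index`
#' keys) or gene level (`gene_id` key).
#'
#' @param counts Count tibble.
#' @param params [filter_params()].
#' @return A list with `counts` (the kept rows) and `removed` (a tibble of
#'   the removed feature keys).
#' @export
prefilter <- function(counts, params = filter_params()) {
  kc <- key_cols(counts)
  m <- counts_matrix(counts)
  keep <- rowSums(m > params$min_count) >= params$min_samples
  list(counts = counts[keep, , drop = FALSE],
       removed = counts[!keep, kc, drop = FALSE])
}

passes_filter <- function(m, params) {
  rowSums(m > params$min_count) >= params$min_samples
}

#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors with the median-of-ratios method:
#' each sample's factor is the median, over features with all-positive
#' counts, of the ratio of its count to the feature's geometric mean across
#' samples.
#'
#' @param counts Count tibble (exon- or gene-level).
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort(paste0("no feature has all-positive counts; size factors cannot ",
                 "be estimated (consider pooling counts to gene level)"))
  }
  lref <- rowMeans(log(m[all_pos, , drop = FALSE]))
  s <- apply(m[all_pos, , drop = FALSE], 2L,
             function(col) median(exp(log(col) - lref)))
  tibble::tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Normalize counts by size factors
#'
#' @param counts Count tibble.
#' @param sf Size-factor tibble from [size_factors()].
#' @return The count tibble with sample columns divided by their factors.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  out <- counts
  for (i in seq_len(nrow(sf))) {
    out[[sf$sample_id[i]]] <- counts[[sf$sample_id[i]]] / sf$size_factor[i]
  }
  out
}

#' Per-feature moment dispersion estimates
#'
#' Method-of-moments NB dispersion on normalized counts: with pooled
#' within-group residual variance v and overall mean m, alpha-hat is
#' `(v - m) / m^2` clamped to `[floor, cap]`; features with zero mean get
#' the floor.
#'
#' @param norm_counts Normalized count tibble.
#' @param samples Sample tibble (>= 2 samples per condition).
#' @param params [test_params()] supplying the clamp.
#' @return A tibble of feature keys plus `alpha`.
#' @export
estimate_dispersion <- function(norm_counts, samples, params = test_params()) {
  check_groups(norm_counts, samples)
  kc <- key_cols(norm_counts)
  m <- counts_matrix(norm_counts)[, samples$sample_id, drop = FALSE]
  grp <- samples$condition
  n_total <- ncol(m)
  if (n_total <= 2L) abort("dispersion estimation needs more than 2 samples")
  rss <- 0
  for (g in unique(grp)) {
    sub <- m[, grp == g, drop = FALSE]
    rss <- rss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- rss / (n_total - 2L)
  mu <- rowMeans(m)
  alpha <- ifelse(mu > 0, (v - mu) / mu^2, params$dispersion_floor)
  alpha <- pmin(pmax(alpha, params$dispersion_floor), params$dispersion_cap)
  dplyr::bind_cols(norm_counts[kc], tibble::tibble(alpha = unname(alpha)))
}

check_groups <- function(counts, samples) {
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing) > 0L) {
    abort(paste0("samples absent from count table: ",
                 paste(missing, collapse = ", ")))
  }
  tab <- table(samples$condition)
  if (!all(c("control", "treatment") %in% names(tab)) || any(tab < 2)) {
    abort("need at least 2 samples in each of control and treatment")
  }
  invisible(TRUE)
}

# Core two-group NB Wald machinery shared by exon_test() and gene_test().
# The log mean ratio is compared to a delta-method standard error
# (1/n_g)(1/(mean_g + eps) + alpha) summed over groups; the reference
# distribution is t with (n_total - 2) degrees of freedom, which keeps the
# test calibrated at the small replicate numbers this design targets.
wald_nb_test <- function(norm_m, raw_m, samples, alpha_hat, params) {
  eps <- params$pseudocount
  ctrl <- samples$sample_id[samples$condition == "control"]
  trt <- samples$sample_id[samples$condition == "treatment"]
  nc <- length(ctrl)
  nt <- length(trt)
  mc <- rowMeans(norm_m[, ctrl, drop = FALSE])
  mt <- rowMeans(norm_m[, trt, drop = FALSE])
  se2 <- (1 / nc) * (1 / (mc + eps) + alpha_hat) +
    (1 / nt) * (1 / (mt + eps) + alpha_hat)
  z <- log((mt + eps) / (mc + eps)) / sqrt(se2)
  p <- 2 * pt(-abs(z), df = nc + nt - 2L)
  log2fc <- log2((mt + eps) / (mc + eps))
  tibble::tibble(
    mean_control = unname(mc),
    mean_treatment = unname(mt),
    log2fc = unname(log2fc),
    stat = unname(z),
    p = unname(p),
    direction = dplyr::case_when(log2fc > 0 ~ "up",
                                 log2fc < 0 ~ "down",
                                 TRUE ~ "none")
  )
}

#' Exon-level two-group NB test
#'
#' Tests each exon bin for a treatment-versus-control difference with a
#' negative-binomial Wald statistic on group means of normalized counts.
#' In `absolute` mode counts are normalized by library size factors; in
#' `relative` mode each gene's counts are instead scaled by a per-gene
#' factor (the gene total in each sample over its geometric mean across
#' samples), testing exon usage relative to the gene — genes with a zero
#' total in any sample are skipped and reported in the
#' `skipped_genes` attribute.
#'
#' @param counts Exon count tibble (`gene_id`, `bin_index`, samples).
#' @param samples Sample tibble.
#' @param params [test_params()].
#' @param filter [filter_params()] used for the per-exon `expressed` flag
#'   (evaluated on raw counts; no rows are dropped here).
#' @param sf Optional precomputed [size_factors()].
#' @param dispersions Optional precomputed [estimate_dispersion()] output.
#' @return A tibble with one row per exon: `gene_id`, `bin_index`,
#'   `mean_control`, `mean_treatment`, `log2fc`, `stat`, `p`, `p_bh`,
#'   `direction`, `expressed`, `source`.
#' @export
exon_test <- function(counts, samples, params = test_params(),
                      filter = filter_params(), sf = NULL,
                      dispersions = NULL) {
  check_groups(counts, samples)
  raw_m <- counts_matrix(counts)[, samples$sample_id, drop = FALSE]
  skipped <- character(0)

  if (params$mode == "absolute") {
    sf <- sf %||% size_factors(counts)
    norm_m <- sweep(raw_m, 2L, sf$size_factor[match(colnames(raw_m),
                                                    sf$sample_id)], "/")
    keep <- rep(TRUE, nrow(counts))
  } else {
    totals <- rowsum(raw_m, counts$gene_id)
    ok <- rowSums(totals > 0) == ncol(totals)
    skipped <- rownames(totals)[!ok]
    if (length(skipped) > 0L) {
      warn(paste0(length(skipped), " gene(s) with a zero total in some ",
                  "sample skipped in relative mode"))
    }
    g_fac <- totals / exp(rowMeans(log(totals)))
    g_fac[!ok, ] <- NA_real_
    norm_m <- raw_m / g_fac[counts$gene_id, , drop = FALSE]
    keep <- counts$gene_id %in% rownames(totals)[ok]
  }

  idx <- which(keep)
  norm_counts <- dplyr::bind_cols(counts[idx, key_cols(counts)],
                                  tibble::as_tibble(norm_m[idx, , drop = FALSE]))
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(norm_counts, samples, params)
  }
  res <- wald_nb_test(norm_m[idx, , drop = FALSE], raw_m[idx, , drop = FALSE],
                      samples, dispersions$alpha, params)
  out <- dplyr::bind_cols(counts[idx, c("gene_id", "bin_index")], res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$expressed <- unname(passes_filter(raw_m[idx, , drop = FALSE], filter))
  out$source <- "native"
  out <- dplyr::relocate(out, "p_bh", .after = "p")
  attr(out, "skipped_genes") <- skipped
  dplyr::arrange(out, .data$gene_id, .data$bin_index)
}

#' Sum exon counts to gene level
#' @param counts Exon count tibble.
#' @return Gene-level count tibble (`gene_id` + sample columns).
#' @export
sum_to_genes <- function(counts) {
  counts |>
    dplyr::select(-"bin_index") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop")
}

#' Gene-level two-group NB test
#'
#' Applies the prefilter and the same NB Wald machinery as [exon_test()] to
#' per-gene summed counts.
#'
#' @param gene_counts Gene-level count tibble (see [sum_to_genes()]).
#' @param samples Sample tibble.
#' @param params [test_params()].
#' @param filter [filter_params()]; genes failing it are excluded.
#' @return A tibble with one row per kept gene: `gene_id`, means, `log2fc`,
#'   `stat`, `p`, `p_bh`, `direction`.
#' @export
gene_test <- function(gene_counts, samples, params = test_params(),
                      filter = filter_params()) {
  check_groups(gene_counts, samples)
  kept <- prefilter(gene_counts, filter)$counts
  if (nrow(kept) == 0L) {
    return(tibble::tibble(gene_id = character(), mean_control = double(),
                          mean_treatment = double(), log2fc = double(),
                          stat = double(), p = double(), p_bh = double(),
                          direction = character()))
  }
  raw_m <- counts_matrix(kept)[, samples$sample_id, drop = FALSE]
  sf <- size_factors(kept)
  norm_m <- sweep(raw_m, 2L, sf$size_factor[match(colnames(raw_m),
                                                  sf$sample_id)], "/")
  norm_counts <- dplyr::bind_cols(kept["gene_id"], tibble::as_tibble(norm_m))
  disp <- estimate_dispersion(norm_counts, samples, params)
  res <- wald_nb_test(norm_m, raw_m, samples, disp$alpha, params)
  out <- dplyr::bind_cols(kept["gene_id"], res)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- dplyr::relocate(out, "p_bh", .after = "p")
  dplyr::arrange(out, .data$gene_id)
}
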