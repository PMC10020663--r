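#' Simulation configuration
#'
#' Configuration for the synthetic exon-count generator. Defaults mirror
#' the replicate structure of the experiment the pipeline targets (five
#' control and six treatment biological replicates per sex, analysed one
#' sex at a time) and standard bulk RNA-seq count behaviour: per-exon
#' baselines drawn log-normally around a gene-level mean, negative-binomial
#' counts with variance mu + alpha * mu^2, and mild library-size variation.
#'
#' Gene classes:
#' \describe{
#'   \item{NULL}{no treatment effect}
#'   \item{DE_UP / DE_DOWN}{all exons scaled by f (or 1/f) in treatment —
#'     full-length differential expression}
#'   \item{CRYPTIC}{exons from an internal start j (within the first half
#'     of the gene, j >= 2) scaled by f — internal initiation}
#'   \item{DECOY_PARTIAL}{elevation starts at an early internal j but
#'     covers only `partial_coverage` of the downstream bins — built to
#'     fail the downstream-fraction rule}
#'   \item{DECOY_LATE}{all bins from a late internal j (past the first
#'     half) elevated — built to fail the first-half rule}
#' }
#'
#' @param n_genes Number of genes.
#' @param exon_count_range Inclusive range of exon-bin counts per gene.
#'   Classes that need an internal start in the first half (CRYPTIC,
#'   DECOY_PARTIAL) draw from at least 3 exons so that the start index
#'   range `[2, ceil(E/2)]` is non-empty.
#' @param n_control,n_treatment Replicates per group (at least 2).
#' @param class_proportions Named proportions over the six classes; must
#'   sum to 1.
#' @param fold_range Range of the multiplicative treatment effect f.
#' @param dispersion NB dispersion alpha (variance mu + alpha * mu^2).
#' @param gene_mean_logmean,gene_mean_logsd Natural-log location and scale
#'   of the per-gene baseline mean.
#' @param exon_weight_logsd Log-scale spread of per-exon weights around the
#'   gene mean.
#' @param library_factor_range Range of uniform per-sample library factors.
#' @param low_expression_prob Probability an exon's baseline is multiplied
#'   by 0.01 (an effectively unexpressed bin).
#' @param partial_coverage Fraction of downstream bins elevated in
#'   DECOY_PARTIAL genes.
#' @param seed Integer RNG seed; the whole experiment is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       exon_count_range = c(2L, 25L),
                       n_control = 5,
                       n_treatment = 6,
                       class_proportions = c(
                         "NULL" = 0.80, DE_UP = 0.05, DE_DOWN = 0.05,
                         CRYPTIC = 0.05, DECOY_PARTIAL = 0.025,
                         DECOY_LATE = 0.025
                       ),
                       fold_range = c(2, 4),
                       dispersion = 0.1,
                       gene_mean_logmean = 4.0,
                       gene_mean_logsd = 1.0,
                       exon_weight_logsd = 0.5,
                       library_factor_range = c(0.7, 1.3),
                       low_expression_prob = 0.05,
                       partial_coverage = 0.4,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    n_control = as.integer(n_control),
    n_treatment = as.integer(n_treatment),
    class_proportions = class_proportions,
    fold_range = as.numeric(fold_range),
    dispersion = as.numeric(dispersion),
    gene_mean_logmean = as.numeric(gene_mean_logmean),
    gene_mean_logsd = as.numeric(gene_mean_logsd),
    exon_weight_logsd = as.numeric(exon_weight_logsd),
    library_factor_range = as.numeric(library_factor_range),
    low_expression_prob = as.numeric(low_expression_prob),
    partial_coverage = as.numeric(partial_coverage),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

sim_classes <- c("NULL", "DE_UP", "DE_DOWN", "CRYPTIC",
                 "DECOY_PARTIAL", "DECOY_LATE")

validate_sim_config <- function(cfg) {
  p <- cfg$class_proportions
  if (!setequal(names(p), sim_classes)) {
    abort(paste0("class_proportions must be named exactly: ",
                 paste(sim_classes, collapse = ", ")))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("class_proportions must be non-negative and sum to 1")
  }
  if (cfg$n_genes < 0) abort("n_genes must be >= 0")
  if (cfg$n_control < 2 || cfg$n_treatment < 2) {
    abort("at least 2 replicates per condition are required")
  }
  ranges <- list(exon_count_range = cfg$exon_count_range,
                 fold_range = cfg$fold_range,
                 library_factor_range = cfg$library_factor_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L]) {
      abort(paste0(nm, " must be an ordered pair"))
    }
  }
  if (cfg$exon_count_range[1L] < 1L) abort("genes need at least one exon bin")
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  invisible(cfg)
}

#' Simulate an exon-count experiment with known ground truth
#'
#' Generates gene models on one synthetic chromosome (100 bp exon bins with
#' 100 bp gaps, genes tiled without overlap, random strand), a sample table,
#' an exon-by-sample NB count matrix, and a per-gene truth table. Counts for
#' exon e of gene g in sample s are drawn NB with mean
#' `mu_ge * t_s * effect` where `mu_ge` is the log-normal per-exon baseline,
#' `t_s` the sample library factor, and `effect` the class-specific fold on
#' affected exons. The result is a deterministic function of the config
#' (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list of class `cryptic_sim` with elements `models`, `samples`,
#'   `counts`, and `truth` (itself holding `genes`, `exon_means`, and
#'   `library_factors` tibbles), plus the `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_genes
  samples <- tibble::tibble(
    sample_id = c(sprintf("C%02d", seq_len(config$n_control)),
                  sprintf("T%02d", seq_len(config$n_treatment))),
    condition = rep(c("control", "treatment"),
                    c(config$n_control, config$n_treatment)),
    sex = NA_character_,
    replicate = c(seq_len(config$n_control), seq_len(config$n_treatment))
  )
  if (n == 0L) {
    return(structure(list(
      models = empty_exon_models(), samples = samples,
      counts = tibble::tibble(gene_id = character(), bin_index = integer()),
      truth = list(
        genes = tibble::tibble(gene_id = character(), class = character(),
                               n_exons = integer(), ctss_index = integer(),
                               fold = double(), affected_bins = character(),
                               base_mean = double()),
        exon_means = tibble::tibble(gene_id = character(),
                                    bin_index = integer(),
                                    base_mean = double()),
        library_factors = tibble::tibble(sample_id = samples$sample_id,
                                         factor = NA_real_)
      ),
      config = config
    ), class = "cryptic_sim"))
  }

  gene_id <- sprintf("g%04d", seq_len(n))
  class <- sample(sim_classes, n, replace = TRUE,
                  prob = config$class_proportions[sim_classes])
  lo <- config$exon_count_range[1L]
  hi <- config$exon_count_range[2L]
  E <- sample(seq(lo, hi), n, replace = TRUE)
  # an internal TSS in the first half needs ceil(E/2) >= 2, i.e. E >= 3
  needs_early_j <- class %in% c("CRYPTIC", "DECOY_PARTIAL")
  if (any(needs_early_j) && lo < 3L) {
    E[needs_early_j] <- sample(seq(max(3L, lo), hi),
                               sum(needs_early_j), replace = TRUE)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_mean <- exp(rnorm(n, config$gene_mean_logmean, config$gene_mean_logsd))
  fold <- runif(n, config$fold_range[1L], config$fold_range[2L])
  fold[class == "NULL"] <- NA_real_
  t_s <- runif(nrow(samples), config$library_factor_range[1L],
               config$library_factor_range[2L])

  # per-gene cryptic TSS index and affected exon set
  ctss <- rep(NA_integer_, n)
  affected <- vector("list", n)
  for (i in seq_len(n)) {
    e <- E[i]
    affected[[i]] <- switch(
      class[i],
      "NULL" = integer(0),
      DE_UP = seq_len(e),
      DE_DOWN = seq_len(e),
      CRYPTIC = {
        ctss[i] <- resample_one(seq(2L, ceiling(e / 2)))
        seq(ctss[i], e)
      },
      DECOY_PARTIAL = {
        ctss[i] <- resample_one(seq(2L, ceiling(e / 2)))
        down <- seq(ctss[i], e)
        size <- max(1L, round(config$partial_coverage * length(down)))
        # the decoy's internal start itself is always elevated so that the
        # downstream-fraction rule, not the first-half rule, is what fails
        sort(c(ctss[i], resample(setdiff(down, ctss[i]), size - 1L)))
      },
      DECOY_LATE = {
        ctss[i] <- resample_one(seq(ceiling(e / 2) + 1L, e))
        seq(ctss[i], e)
      }
    )
  }

  # per-exon baselines and counts
  total <- sum(E)
  exon_gene <- rep(seq_len(n), E)
  bin_index <- unlist(lapply(E, seq_len), use.names = FALSE)
  weights <- exp(rnorm(total, 0, config$exon_weight_logsd))
  low <- runif(total) < config$low_expression_prob
  base_mu <- gene_mean[exon_gene] * weights * ifelse(low, 0.01, 1)

  eff <- matrix(1, nrow = total, ncol = nrow(samples))
  trt <- samples$condition == "treatment"
  is_affected <- mapply(function(g, b) b %in% affected[[g]], exon_gene, bin_index)
  mult <- ifelse(class[exon_gene] == "DE_DOWN", 1 / fold[exon_gene], fold[exon_gene])
  mult[is.na(mult) | !is_affected] <- 1
  eff[, trt] <- mult
  mu <- base_mu * eff * matrix(t_s, nrow = total, ncol = nrow(samples), byrow = TRUE)
  counts <- matrix(
    as.integer(rnbinom(length(mu), mu = as.vector(mu),
                       size = 1 / config$dispersion)),
    nrow = total
  )
  colnames(counts) <- samples$sample_id

  # genomic layout: 100 bp bins, 100 bp gaps, 1 kb between genes
  models <- vector("list", n)
  cursor <- 0L
  for (i in seq_len(n)) {
    starts <- cursor + (seq_len(E[i]) - 1L) * 200L
    idx <- if (strand[i] == "+") seq_len(E[i]) else rev(seq_len(E[i]))
    models[[i]] <- tibble::tibble(
      gene_id = gene_id[i], bin_index = idx, chrom = "chrS",
      start = as.integer(starts), end = as.integer(starts + 100L),
      strand = strand[i]
    )
    cursor <- as.integer(starts[E[i]] + 100L + 1000L)
  }
  models <- dplyr::arrange(dplyr::bind_rows(models),
                           .data$gene_id, .data$bin_index)

  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(gene_id = gene_id[exon_gene], bin_index = bin_index),
    tibble::as_tibble(counts)
  ) |>
    dplyr::arrange(.data$gene_id, .data$bin_index)

  truth <- list(
    genes = tibble::tibble(
      gene_id = gene_id, class = class, n_exons = E, ctss_index = ctss,
      fold = fold,
      affected_bins = vapply(affected, paste, character(1), collapse = ","),
      base_mean = gene_mean
    ),
    exon_means = tibble::tibble(
      gene_id = gene_id[exon_gene], bin_index = bin_index, base_mean = base_mu
    ) |>
      dplyr::arrange(.data$gene_id, .data$bin_index),
    library_factors = tibble::tibble(sample_id = samples$sample_id, factor = t_s)
  )

  structure(
    list(models = models, samples = samples, counts = counts_tbl,
         truth = truth, config = config),
    class = "cryptic_sim"
  )
}

# sample() misbehaves on length-1 numeric vectors; these do not
resample <- function(x, size) x[sample.int(length(x), size)]
resample_one <- function(x) x[sample.int(length(x), 1L)]

#' @export
print.cryptic_sim <- function(x, ...) {
  cat("<cryptic_sim> ", dplyr::n_distinct(x$counts$gene_id), " genes, ",
      nrow(x$counts), " exon bins, ", nrow(x$samples), " samples (",
      sum(x$samples$condition == "control"), " control / ",
      sum(x$samples$condition == "treatment"), " treatment), seed ",
      x$config$seed, "\n", sep = "")
  print(table(x$truth$genes$class))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits the four pipeline input files in the package's plain-text dialects:
#' `annotation.gff`, `counts.tsv`, `samples.tsv`, and `truth.tsv` (one row
#' per gene).
#'
#' @param sim A `cryptic_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files (default is an error).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_fixture <- function(sim, dir, force = FALSE) {
  if (!inherits(sim, "cryptic_sim")) abort("sim must be a cryptic_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gff"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  if (!force && any(file.exists(paths))) {
    abort(paste0("fixture file(s) already exist in ", dir,
                 " (use force = TRUE to overwrite)"))
  }
  write_exon_annotation(sim$models, paths[["annotation"]], format = "gff")
  write_counts(sim$counts, paths[["counts"]])
  write_sample_table(sim$samples, paths[["samples"]])
  write_tsv_hash(sim$truth$genes, paths[["truth"]])
  invisible(paths)
}
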