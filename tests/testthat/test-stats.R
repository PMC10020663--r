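test_that("prefilter keeps features with >min_count in at least min_samples", {
  m <- rbind(c(11L, 12L, 0L, 0L, 0L),
             c(11L, 10L, 10L, 10L, 10L),
             c(10L, 10L, 10L, 10L, 10L))
  counts <- make_counts(m, gene_id = c("a", "b", "c"), bin_index = c(1L, 1L, 1L))
  out <- prefilter(counts, filter_params())
  expect_equal(out$counts$gene_id, "a")
  expect_equal(sort(out$removed$gene_id), c("b", "c"))
})

test_that("size factors implement the median-of-ratios formula", {
  # identical columns -> all factors 1
  same <- make_counts(matrix(c(5L, 9L, 13L), 3, 4), "g", 1:3)
  expect_equal(size_factors(same)$size_factor, rep(1, 4))

  # two samples, second column doubled: factors (1/sqrt(2), sqrt(2))
  m <- matrix(c(10L, 50L, 200L, 20L, 100L, 400L), ncol = 2)
  two <- make_counts(m, "g", 1:3)
  expect_equal(size_factors(two)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # scaling sample j by c multiplies its factor by c^(1 - 1/n) and every
  # other factor by c^(-1/n) (the geometric-mean reference absorbs c^(1/n))
  set.seed(1)
  m <- matrix(rpois(60, 80) + 1L, ncol = 6)
  base <- size_factors(make_counts(m, "g", 1:10))$size_factor
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  scaled <- size_factors(make_counts(m2, "g", 1:10))$size_factor
  expect_equal(scaled[3] / base[3], 5^(1 - 1 / 6), tolerance = 1e-9)
  expect_equal(scaled[-3] / base[-3], rep(5^(-1 / 6), 5), tolerance = 1e-9)

  # no all-positive row -> error advising gene-level pooling
  sparse <- make_counts(rbind(c(0L, 5L), c(5L, 0L)), c("a", "b"), c(1L, 1L))
  expect_error(size_factors(sparse), "pooling")
})

test_that("moment dispersion matches hand calculation and clamps", {
  samples <- make_samples(2, 2)
  # control (90, 110), treatment (90, 110): v = 400/2 = 200, m = 100
  counts <- make_counts(matrix(c(90, 110, 90, 110), 1), "g", 1L)
  disp <- estimate_dispersion(counts, samples)
  expect_equal(disp$alpha, (200 - 100) / 100^2)

  # Poisson-like (v = m) and underdispersed data clamp to the floor
  pois <- make_counts(matrix(c(99, 101, 99, 101), 1), "g", 1L)
  expect_equal(estimate_dispersion(pois, samples)$alpha,
               test_params()$dispersion_floor)
  flat <- make_counts(matrix(c(100, 100, 100, 100), 1), "g", 1L)
  expect_equal(estimate_dispersion(flat, samples)$alpha,
               test_params()$dispersion_floor)
})

test_that("exon test reproduces the delta-method statistic", {
  samples <- make_samples(5, 6)
  counts <- make_counts(matrix(c(rep(100L, 5), rep(200L, 6)), 1), "g", 1L)
  ones <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  disp <- tibble::tibble(gene_id = "g", bin_index = 1L, alpha = 0.1)
  res <- exon_test(counts, samples, test_params(pseudocount = 0),
                   sf = ones, dispersions = disp)
  # z = ln(2) / sqrt((1/5)(1/100 + 0.1) + (1/6)(1/200 + 0.1)) = 3.487
  expect_equal(res$stat, 3.4875, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(-res$stat, df = 9))
  expect_equal(res$direction, "up")
  expect_equal(res$log2fc, 1)

  # equal group means: zero statistic, p = 1, no direction
  eq <- make_counts(matrix(rep(100L, 11), 1), "g", 1L)
  res_eq <- exon_test(eq, samples, sf = ones, dispersions = disp)
  expect_equal(res_eq$stat, 0)
  expect_equal(res_eq$p, 1)
  expect_equal(res_eq$direction, "none")

  # all-zero treatment group: pseudocount keeps everything finite
  zt <- make_counts(matrix(c(rep(50L, 5), rep(0L, 6)), 1), "g", 1L)
  res_zt <- exon_test(zt, samples, sf = ones)
  expect_true(is.finite(res_zt$log2fc) && res_zt$log2fc < 0)
  expect_true(res_zt$p > 0 && res_zt$p < 1)

  # expressed flag applies the prefilter rule to that exon's raw counts
  expect_true(res$expressed)
  expect_true(res_zt$expressed)  # five control samples still exceed 10
  weak <- make_counts(matrix(c(rep(10L, 5), rep(3L, 6)), 1), "g", 1L)
  expect_false(exon_test(weak, samples, sf = ones)$expressed)
})

test_that("p decreases monotonically with effect size at fixed scale", {
  samples <- make_samples(5, 6)
  ones <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  ps <- sapply(seq(100, 400, by = 20), function(mt) {
    counts <- make_counts(matrix(c(rep(100L, 5), rep(as.integer(mt), 6)), 1),
                          "g", 1L)
    disp <- tibble::tibble(gene_id = "g", bin_index = 1L, alpha = 0.1)
    exon_test(counts, samples, sf = ones, dispersions = disp)$p
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("library-size changes are absorbed by normalization", {
  set.seed(8)
  samples <- make_samples(5, 6)
  m <- matrix(rnbinom(50 * 11, mu = 150, size = 10) + 1L, ncol = 11)
  counts <- make_counts(m, rep(sprintf("g%02d", 1:10), each = 5),
                        rep(1:5, 10))
  base <- exon_test(counts, samples)
  m2 <- m
  m2[, 7] <- m2[, 7] * 3L
  counts2 <- make_counts(m2, counts$gene_id, counts$bin_index)
  scaled <- exon_test(counts2, samples)
  expect_lt(max(abs(base$p - scaled$p)), 0.01)

  # doubling every treatment column leaves gene-level inference unchanged
  gsum <- sum_to_genes(counts)
  gt1 <- gene_test(gsum, samples)
  gsum2 <- gsum
  trt <- samples$sample_id[samples$condition == "treatment"]
  gsum2[trt] <- gsum2[trt] * 2L
  gt2 <- gene_test(gsum2, samples)
  expect_lt(max(abs(gt1$p - gt2$p)), 0.01)
})

test_that("gene test excludes genes failing the prefilter", {
  samples <- make_samples(2, 2)
  counts <- make_counts(rbind(rep(0L, 4), rep(100L, 4)),
                        c("dead", "alive"), c(1L, 1L))
  res <- gene_test(sum_to_genes(counts), samples)
  expect_equal(res$gene_id, "alive")
})

test_that("relative mode tests exon usage within genes", {
  samples <- make_samples(3, 3)
  # gene with uniform doubling in treatment: strong absolute signal,
  # no relative signal once the per-gene factor absorbs the gene total
  m <- matrix(rep(c(100L, 100L, 100L, 200L, 200L, 200L), times = 4),
              ncol = 6, byrow = TRUE)
  counts <- make_counts(m, "g", 1:4)
  rel <- exon_test(counts, samples, test_params(mode = "relative"))
  expect_true(all(abs(rel$log2fc) < 0.01))
  abs_mode <- exon_test(counts, samples,
                        sf = tibble::tibble(sample_id = samples$sample_id,
                                            size_factor = 1))
  expect_true(all(abs_mode$log2fc > 0.9))

  # genes with a zero total in any sample are flagged and skipped
  m0 <- rbind(m, matrix(0L, 2, 6))
  counts0 <- make_counts(m0, rep(c("g", "z"), c(4, 2)), c(1:4, 1:2))
  expect_warning(
    rel0 <- exon_test(counts0, samples, test_params(mode = "relative")),
    "skipped"
  )
  expect_equal(attr(rel0, "skipped_genes"), "z")
  expect_false("z" %in% rel0$gene_id)
})

test_that("the null rejection rate is near nominal", {
  set.seed(31)
  samples <- make_samples(5, 6)
  m <- matrix(rnbinom(800 * 11, mu = 100, size = 10), ncol = 11)
  counts <- make_counts(m, sprintf("g%03d", 1:800), rep(1L, 800))
  ones <- tibble::tibble(sample_id = samples$sample_id, size_factor = 1)
  res <- exon_test(counts, samples, sf = ones)
  expect_gt(mean(res$p < 0.05), 0.02)
  expect_lt(mean(res$p < 0.05), 0.09)
})
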