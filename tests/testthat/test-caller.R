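test_that("worked cascade examples classify as specified", {
  sig <- function(idx, E) seq_len(E) %in% idx

  # E=10, elevated {3..7}: TSS 3, 5/8 downstream = 0.625 >= 0.6, early half
  r <- call_cryptic(make_results(sig(3:7, 10)))
  expect_equal(r$decision, "PASS")
  expect_equal(r$ctss_index, 3L)
  expect_equal(r$downstream_frac, 0.625)

  # E=10, elevated {3..6}: 4/8 = 0.5 < 0.6
  r <- call_cryptic(make_results(sig(3:6, 10)))
  expect_equal(r$reason, "DOWNSTREAM_FRAC")
  expect_equal(r$downstream_frac, 0.5)

  # E=10, elevated {7..10}: fraction 1 but TSS past the first half
  r <- call_cryptic(make_results(sig(7:10, 10)))
  expect_equal(r$reason, "LATE_TSS")
  expect_equal(r$downstream_frac, 1)

  # first expressed exon elevated: full-length upregulation
  r <- call_cryptic(make_results(sig(c(1, 5, 6, 7, 8, 9, 10), 10)))
  expect_equal(r$reason, "FULL_LENGTH_UP")

  # nothing elevated
  r <- call_cryptic(make_results(sig(integer(0), 10)))
  expect_equal(r$reason, "NO_UP")
})

test_that("boundary cases sit exactly on the published thresholds", {
  sig <- function(idx, E) seq_len(E) %in% idx
  # downstream fraction exactly 0.60 passes (the rule removes < 60%):
  # E=6, TSS 2, elevated {2,3,4}: 3/5 = 0.6
  r <- call_cryptic(make_results(sig(c(2, 3, 4), 6)))
  expect_equal(r$downstream_frac, 0.6)
  expect_equal(r$decision, "PASS")

  # TSS exactly at ceil(E/2) is still the first half (odd E)
  # E=9, ceil(9/2)=5, elevated {5..9}: 5/5 downstream
  r <- call_cryptic(make_results(sig(5:9, 9)))
  expect_equal(r$ctss_index, 5L)
  expect_equal(r$decision, "PASS")
  # one later fails
  r <- call_cryptic(make_results(sig(6:9, 9)))
  expect_equal(r$reason, "LATE_TSS")
})

test_that("caller matches the brute-force oracle on all patterns, E <= 8", {
  params <- caller_params()
  for (E in 2:8) {
    for (code in 0:(2^E - 1)) {
      sig_up <- as.logical(bitwAnd(code, 2^(seq_len(E) - 1L)) > 0)
      got <- call_cryptic(make_results(sig_up), params)$reason
      expect_identical(got, oracle_call(sig_up), label = paste0(
        "E=", E, " pattern=", paste(as.integer(sig_up), collapse = "")
      ))
    }
  }
})

test_that("caller matches the oracle on random patterns with partial expression", {
  set.seed(99)
  params <- caller_params()
  for (i in 1:500) {
    E <- sample(2:25, 1)
    sig_up <- runif(E) < runif(1, 0.05, 0.6)
    expressed <- runif(E) < 0.9
    res <- make_results(sig_up, expressed)
    if (!any(expressed)) {
      expect_identical(call_cryptic(res, params)$reason, "NOT_EXPRESSED")
    } else {
      expect_identical(call_cryptic(res, params)$reason,
                       oracle_call(sig_up, expressed))
    }
  }
})

test_that("degenerate genes get the screening reasons", {
  r <- call_cryptic(make_results(c(FALSE, TRUE), c(FALSE, FALSE)))
  expect_equal(r$reason, "NOT_EXPRESSED")
  r <- call_cryptic(make_results(c(FALSE, TRUE, TRUE)),
                    caller_params(min_exons = 5))
  expect_equal(r$reason, "TOO_FEW_EXONS")
  # two-exon genes can structurally never pass under the first-half rule
  r <- call_cryptic(make_results(c(FALSE, TRUE)))
  expect_equal(r$reason, "LATE_TSS")
})

test_that("malformed exon result sets are rejected", {
  res <- make_results(c(FALSE, TRUE, TRUE, TRUE))
  expect_error(call_cryptic(res[-2L, ]), "gaps")
  expect_error(call_cryptic(res, n_exons = 6), "does not match")
  dup <- dplyr::bind_rows(res, res[2L, ])
  expect_error(call_cryptic(dup), "gaps|duplicates")
})

test_that("call_all is conservative, ordered and summarised", {
  res <- dplyr::bind_rows(
    make_results(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE), gene_id = "gB"),
    make_results(rep(FALSE, 4), gene_id = "gA"),
    make_results(c(TRUE, TRUE, TRUE, TRUE), gene_id = "gC")
  )
  out <- call_all(res)
  expect_s3_class(out, "cryptic_calls")
  expect_equal(out$calls$gene_id, c("gA", "gB", "gC"))
  expect_equal(sum(out$summary$n), 3L)
  expect_equal(out$calls$decision == "PASS", out$calls$reason == "PASS")

  expect_equal(nrow(call_all(res[0L, ])$calls), 0L)

  # gene universe check against models
  models <- tibble::tibble(gene_id = "gB", bin_index = 1:6, chrom = "c",
                           start = seq(0, 1000, length.out = 6),
                           end = seq(50, 1050, length.out = 6), strand = "+")
  expect_error(call_all(res, models), "absent from models")
})

test_that("tightening sig_alpha never converts NO_UP into PASS", {
  set.seed(5)
  for (i in 1:50) {
    E <- sample(3:12, 1)
    res <- make_results(runif(E) < 0.4)
    loose <- call_cryptic(res, caller_params(sig_alpha = 0.05))
    strict <- call_cryptic(res, caller_params(sig_alpha = 0.001))
    if (loose$reason == "NO_UP") expect_false(strict$decision == "PASS")
  }
})

test_that("strand does not affect calls when bins are ordered 5' to 3'", {
  # mirror-image genes: same per-bin statistics in transcriptional order
  sig <- c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  plus <- call_cryptic(make_results(sig, gene_id = "plus"))
  minus <- call_cryptic(make_results(sig, gene_id = "minus"))
  expect_equal(plus$reason, minus$reason)
  expect_equal(plus$ctss_index, minus$ctss_index)
  # and via annotation: reversed genomic layout yields identical bin order
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#gene_id\tchrom\tstart\tend\tstrand",
               sprintf("p\tc\t%d\t%d\t+", seq(1, 701, 100), seq(50, 750, 100)),
               sprintf("m\tc\t%d\t%d\t-", seq(1, 701, 100), seq(50, 750, 100))),
             path)
  models <- read_exon_annotation(path)
  res <- dplyr::bind_rows(make_results(sig, gene_id = "p"),
                          make_results(sig, gene_id = "m"))
  out <- call_all(res, models)$calls
  expect_equal(out$reason[out$gene_id == "p"], out$reason[out$gene_id == "m"])
})

test_that("truth evaluation agrees with a brute-force recount", {
  set.seed(12)
  n <- 200
  classes <- sample(c("NULL", "CRYPTIC", "DE_UP", "DECOY_LATE"), n, TRUE)
  truth <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), class = classes,
    ctss_index = ifelse(classes %in% c("CRYPTIC", "DECOY_LATE"),
                        sample(2:5, n, TRUE), NA_integer_),
    n_exons = 10L, fold = 3, affected_bins = "", base_mean = 100
  )
  calls <- tibble::tibble(
    gene_id = truth$gene_id,
    decision = sample(c("PASS", "FAIL"), n, TRUE, prob = c(0.2, 0.8)),
    ctss_index = sample(c(2:5, NA), n, TRUE),
    downstream_frac = 0.8, n_exons = 10L
  )
  calls$reason <- ifelse(calls$decision == "PASS", "PASS", "NO_UP")
  ev <- evaluate_vs_truth(calls, truth)

  pass <- calls$decision == "PASS"
  cr <- truth$class == "CRYPTIC"
  nul <- truth$class == "NULL"
  expect_equal(ev$metrics$sensitivity, sum(pass & cr) / sum(cr))
  expect_equal(ev$metrics$specificity, sum(!pass & nul) / sum(nul))
  expect_equal(ev$metrics$fdr, sum(pass & !cr) / sum(pass))
  tp <- pass & cr
  expect_equal(ev$metrics$ctss_exact_rate,
               mean(calls$ctss_index[tp] == truth$ctss_index[tp]))

  # trivial extremes
  perfect <- dplyr::mutate(
    calls,
    decision = ifelse(cr, "PASS", "FAIL"),
    reason = ifelse(cr, "PASS", "NO_UP"),
    ctss_index = truth$ctss_index
  )
  evp <- evaluate_vs_truth(perfect, truth)
  expect_equal(evp$metrics$sensitivity, 1)
  expect_equal(evp$metrics$fdr, 0)
  allfail <- dplyr::mutate(calls, decision = "FAIL", reason = "NO_UP")
  eva <- evaluate_vs_truth(allfail, truth)
  expect_equal(eva$metrics$sensitivity, 0)
  expect_equal(eva$metrics$specificity, 1)

  expect_error(evaluate_vs_truth(calls[-1L, ], truth), "universes")
})
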