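#' Upper-tail hypergeometric probability of a gene-list overlap
#'
#' Exact probability of observing an overlap of at least `k` genes between
#' a list of `a` and a list of `b` genes drawn from a universe of `N`,
#' summed in log space so that very small tail probabilities (down to the
#' 1e-131 scale seen in genome-wide comparisons) remain accurate. This is
#' the one-sided (enrichment) Fisher exact test used for gene-list
#' comparisons.
#'
#' @param k Observed overlap size.
#' @param a,b List sizes.
#' @param N Universe size (total genes eligible for both lists).
#' @return The tail probability `P(X >= k)`.
#' @export
hypergeometric_upper_tail <- function(k, a, b, N) {
  for (v in list(k = k, a = a, b = b, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || v != floor(v) || v < 0) {
      abort("k, a, b, N must be single non-negative integers")
    }
  }
  if (a > N || b > N) abort("list sizes cannot exceed the universe N")
  if (k > min(a, b)) abort("overlap k cannot exceed min(a, b)")
  if (k < a + b - N) {
    abort(paste0("infeasible table: an overlap of at least ", a + b - N,
                 " is forced by a + b > N, but k = ", k))
  }
  if (k == 0) return(1)
  i <- seq(k, min(a, b))
  lterms <- lchoose(a, i) + lchoose(N - a, b - i) - lchoose(N, b)
  exp(logsumexp(lterms))
}

#' Fisher overlap test between two gene lists
#'
#' Computes the overlap, one-sided hypergeometric p-value, odds ratio and
#' Jaccard index for two gene lists over an explicit universe of `N` genes.
#'
#' @param list_a,list_b Character vectors of gene ids (deduplicated).
#' @param universe_n Universe size N; see [universe_size()] for deriving it
#'   from an annotation.
#' @param labels Length-2 labels for reporting.
#' @return One-row tibble: `label_a`, `label_b`, `a`, `b`, `k`, `N`,
#'   `p_upper`, `odds_ratio`, `jaccard`.
#' @export
fisher_overlap <- function(list_a, list_b, universe_n,
                           labels = c("A", "B")) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  a <- length(list_a)
  b <- length(list_b)
  k <- length(intersect(list_a, list_b))
  N <- as.integer(universe_n)
  if (a > N || b > N) abort("gene lists are larger than the universe N")
  if (N - a - b + k < 0) {
    abort("negative contingency cell: the lists are not drawn from the stated universe")
  }
  or <- if (k == a || k == b) {
    Inf
  } else {
    k * (N - a - b + k) / ((a - k) * (b - k))
  }
  tibble::tibble(
    label_a = labels[1L], label_b = labels[2L],
    a = a, b = b, k = k, N = N,
    p_upper = hypergeometric_upper_tail(k, a, b, N),
    odds_ratio = or,
    jaccard = if (a + b - k == 0) NA_real_ else k / (a + b - k)
  )
}

#' Calibrate the overlap universe size from a printed p-value
#'
#' Published overlap tests often report list sizes, the overlap and a
#' p-value but not the universe N they were computed against. For an
#' enriched overlap (k > a*b/N) the upper-tail p is strictly decreasing in
#' N, so N can be recovered by inverting the exact test: this function
#' verifies monotonicity over the search range, bisects on log10 p, and
#' finishes with a local scan to return the integer N whose exact p is
#' closest to the target on the log10 scale.
#'
#' @param a,b,k Overlap query sizes.
#' @param p_target The printed p-value to invert.
#' @param n_range Integer search range for N; the lower bound is raised to
#'   `a + b - k` (the smallest feasible universe).
#' @return One-row tibble: `N`, `p_achieved`, `log10_error`.
#' @export
calibrate_universe <- function(a, b, k, p_target, n_range = c(0, 1e6)) {
  if (p_target <= 0 || p_target >= 1) abort("p_target must be in (0, 1)")
  lo <- max(ceiling(n_range[1L]), a + b - k, a, b)
  hi <- floor(n_range[2L])
  if (lo >= hi) abort("empty universe search range")
  f <- function(N) log10(hypergeometric_upper_tail(k, a, b, N))
  target <- log10(p_target)
  # monotonicity guard: p must decrease in N across the bracket
  probe <- unique(round(seq(lo, hi, length.out = 8)))
  pv <- vapply(probe, f, numeric(1))
  if (any(diff(pv) >= 0)) {
    abort("p is not strictly decreasing in N over the range; cannot invert")
  }
  if (target > pv[1L] || target < pv[length(pv)]) {
    abort(sprintf(
      "p_target %.3g unattainable in range: p(N=%d) = %.3g, p(N=%d) = %.3g",
      p_target, lo, 10^pv[1L], hi, 10^pv[length(pv)]))
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) >= target) lo <- mid else hi <- mid
  }
  cand <- seq(max(lo - 2L, a + b - k, a, b), hi + 2L)
  err <- abs(vapply(cand, f, numeric(1)) - target)
  N <- cand[which.min(err)]
  tibble::tibble(N = as.integer(N),
                 p_achieved = hypergeometric_upper_tail(k, a, b, N),
                 log10_error = min(err))
}

#' Cross-analysis membership table
#'
#' Integrates named gene lists (e.g. differential expression, differential
#' exon usage, cryptic transcription, differential binding) into one table
#' of membership indicators, with a count of how many analyses each gene
#' appeared in.
#'
#' @param lists Named list of character vectors of gene ids.
#' @return A tibble with `gene_id`, one logical column per label, and
#'   `n_analyses`; genes sorted alphabetically.
#' @export
membership_table <- function(lists) {
  if (length(lists) == 0L) abort("at least one gene list is required")
  labels <- names(lists)
  if (is.null(labels) || any(!nzchar(labels))) abort("all lists must be named")
  if (anyDuplicated(labels)) abort("duplicate list labels")
  lists <- lapply(lists, function(x) unique(as.character(x)))
  genes <- sort(unique(unlist(lists, use.names = FALSE)))
  out <- tibble::tibble(gene_id = genes)
  for (lab in labels) out[[lab]] <- genes %in% lists[[lab]]
  out$n_analyses <- rowSums(as.matrix(out[labels]))
  out
}
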