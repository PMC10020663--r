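# Builders for small in-memory fixtures used across test files.

# Exon-result tibble for one gene from a significance pattern. Exons with
# sig_up get p = 0.01 and direction "up"; the rest alternate between a
# clearly non-significant p and a significant-but-down p so that the
# "direction = up" half of the SIG_UP definition is exercised.
make_results <- function(sig_up, expressed = rep(TRUE, length(sig_up)),
                         gene_id = "g1") {
  E <- length(sig_up)
  decoy_down <- !sig_up & (seq_len(E) %% 2L == 0L)
  tibble::tibble(
    gene_id = gene_id,
    bin_index = seq_len(E),
    mean_control = 100,
    mean_treatment = ifelse(sig_up, 300, 100),
    log2fc = ifelse(sig_up, log2(3), ifelse(decoy_down, -1, 0.05)),
    p = ifelse(sig_up, 0.01, ifelse(decoy_down, 0.01, 0.8)),
    direction = ifelse(sig_up, "up", ifelse(decoy_down, "down", "up")),
    expressed = expressed,
    source = "native"
  )
}

# A small count tibble with explicit per-sample columns.
make_counts <- function(mat, gene_id, bin_index) {
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(gene_id = gene_id, bin_index = bin_index),
    tibble::as_tibble(mat)
  )
}

make_samples <- function(n_control, n_treatment) {
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_control + n_treatment)),
    condition = rep(c("control", "treatment"), c(n_control, n_treatment)),
    sex = NA_character_,
    replicate = c(seq_len(n_control), seq_len(n_treatment))
  )
}
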