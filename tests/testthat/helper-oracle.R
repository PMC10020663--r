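# Independent brute-force reference for the cryptic-transcription cascade.
# Written as a literal, step-by-step reading of the published filtering
# rules; deliberately kept separate from the package implementation.
oracle_call <- function(sig_up, expressed = rep(TRUE, length(sig_up)),
                        min_frac = 0.6, first_half = TRUE) {
  E <- length(sig_up)
  # screen: a gene with no expressed exon cannot be assessed
  if (sum(expressed) == 0) {
    return("NOT_EXPRESSED")
  }
  # rule 1: significantly higher read counts for at least one exon
  n_up <- 0
  for (e in seq_len(E)) if (sig_up[e]) n_up <- n_up + 1
  if (n_up == 0) {
    return("NO_UP")
  }
  # rule 2: discard if the first annotated and expressed exon is higher
  # (likely an upregulated full-length mRNA)
  first_expressed <- NA
  for (e in seq_len(E)) {
    if (expressed[e]) {
      first_expressed <- e
      break
    }
  }
  if (sig_up[first_expressed]) {
    return("FULL_LENGTH_UP")
  }
  # rule 3: the new cryptic TSS is the first significantly higher exon
  tss <- NA
  for (e in seq_len(E)) {
    if (sig_up[e]) {
      tss <- e
      break
    }
  }
  # rule 4: filter out if significantly higher for < 60% of the
  # downstream exons (TSS exon included)
  n_down <- 0
  n_down_up <- 0
  for (e in tss:E) {
    n_down <- n_down + 1
    if (sig_up[e]) n_down_up <- n_down_up + 1
  }
  if (n_down_up / n_down < min_frac) {
    return("DOWNSTREAM_FRAC")
  }
  # added rule 5: the first differentially used exon must be among the
  # first half of all exons
  if (first_half && tss > ceiling(E / 2)) {
    return("LATE_TSS")
  }
  "PASS"
}
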