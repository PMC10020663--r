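# crypticall

Detection of cryptic (intragenic) transcription from exon-level RNA-seq
counts.

## The problem

The histone mark H3K36me3 is deposited co-transcriptionally over gene
bodies and suppresses transcription initiation from within them. When the
mark is lost or reduced, RNA polymerase can initiate at internal, "cryptic"
promoters, producing 5'-truncated transcripts. In count data this leaves a
characteristic footprint: a gene whose *downstream* exon bins gain reads in
the treatment group while its 5' exons do not. `crypticall` implements the
exon-level screen for that footprint, the two-group count statistics that
feed it, the gene-list overlap statistics used to compare screens across
sexes and assays, and a ground-truth simulator that makes the whole
pipeline testable end to end. It is aimed at analysts working with bulk
RNA-seq designs of the usual small-replicate kind (here: five control vs
six treated biological replicates, analysed one sex at a time).

## The method

**Counting units** are flattened exon bins (the "collapsed exon counting
bin" GFF produced by exon-flattening preprocessors), indexed 1..E in
transcriptional (5'→3') order per gene.

**Per-exon statistic.** Counts are normalized with median-of-ratios size
factors s_j. For exon i with normalized group means m_c, m_t (n_c, n_t
replicates) and a per-feature method-of-moments NB dispersion α̂ (variance
μ + α μ²), the package tests

    z = ln((m_t + ε) / (m_c + ε)) / sqrt( (1/n_c)(1/(m_c+ε) + α̂) + (1/n_t)(1/(m_t+ε) + α̂) )

against a t reference with n_c + n_t − 2 degrees of freedom (ε = 0.5 is a
pseudocount). The same machinery applied to per-gene summed counts gives
the differential-expression track.

**Cryptic-transcription caller.** With SIG_UP(i) := p_i < α and the exon
elevated in treatment, a gene is called cryptically transcribed iff, in
order: (1) some exon is SIG_UP; (2) the first annotated *and expressed*
exon is not (otherwise it is a full-length upregulation); (3) the candidate
cryptic TSS c is the first SIG_UP exon; (4) at least 60% of the downstream
exons (c..E) are SIG_UP; (5) c lies within the first half of the gene's
exons (c ≤ ⌈E/2⌉). Failures carry reason codes (`NO_UP`, `FULL_LENGTH_UP`,
`DOWNSTREAM_FRAC`, `LATE_TSS`, ...).

**Overlap statistics.** Gene lists are compared with the one-sided
(enrichment) Fisher exact test, i.e. the upper-tail hypergeometric
probability P(X ≥ k) for an overlap of k between lists of a and b genes in
a universe of N, computed exactly in log space. Because published overlap
tests often omit N, `calibrate_universe()` inverts the exact test to
recover it from a printed p-value.

**Simulator.** `simulate_experiment()` draws NB exon counts over multi-exon
gene models with log-normal baselines, library factors, and six gene
classes — null, full-length up/down, cryptic, and two decoys built to fail
exactly one caller rule — so sensitivity, specificity and reason-coded
rejection can be measured against known truth.

## Worked example

```r
library(crypticall)

cfg <- sim_config(n_genes = 300, seed = 42)
run <- run_cryptic_pipeline("demo_run", sim = cfg)
run$calls
#> <cryptic_calls> 300 genes, 12 PASS
#>   reason              n
#> 1 PASS               12
#> 2 NO_UP             197
#> 3 FULL_LENGTH_UP     26
#> 4 DOWNSTREAM_FRAC    54
#> 5 LATE_TSS            9
#> 6 NOT_EXPRESSED       2
#> 7 TOO_FEW_EXONS       0
```

Twelve genes pass the cascade; the rest are rejected with the rule that
eliminated them. Against the simulation truth:

```r
glance(run$metrics)
#>   n_genes n_pass sensitivity specificity null_pass_rate    fdr ctss_exact_rate
#> 1     300     12           1           1              0 0.0833           0.818
```

Every simulated cryptic gene was recovered, no null gene passed, and 82%
of true positives had their internal TSS located at exactly the right exon
bin. The run directory contains the gene/exon test tables, the calls, a
BED track of cryptic TSS bins, overlap and membership tables for the DEG /
DEU / CT gene lists, and a JSON manifest echoing every threshold.

Inverting a published overlap (4 shared genes between lists of 30 and 26
at p = 8.2e-9) recovers the gene universe it was computed against:

```r
calibrate_universe(30, 26, 4, 8.2e-9, c(1e3, 1e6))
#>       N   p_achieved log10_error
#> 1 32978      8.2e-09   0.0000214
```

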