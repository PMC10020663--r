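---
title: "Detecting cryptic intragenic transcription from exon-bin counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic intragenic transcription from exon-bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticall)
```

# The signal being detected

Loss of gene-body H3K36me3 permits transcription initiation from internal
(cryptic) promoters. A truncated transcript contributes reads only to the
exon bins downstream of its internal start, so in a two-group comparison a
cryptically transcribed gene shows a step: 5' bins unchanged, bins from
some internal position j elevated. `crypticall` screens per-exon two-group
statistics for exactly that step, while rejecting the patterns that mimic
it — full-length upregulation (all bins elevated, including the first),
scattered elevation that covers too little of the gene's tail, and
elevation that begins so late in the gene that an internal promoter is a
less plausible reading than 3' artefacts.

# Per-exon and per-gene statistics

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. Library differences are removed with median-of-ratios
size factors computed over features with all-positive counts (the
implementation refuses matrices without any such feature and suggests
pooling to gene level, where zeros are rare). Dispersion is estimated per
feature by method of moments from normalized counts: with pooled
within-group variance $v$ and overall mean $m$,
$\hat\alpha = (v - m)/m^2$, clamped to $[10^{-8}, 10]$. There is no
trend or shrinkage; the estimator is simple, testable, and adequate at the
moderate counts the screen operates on, while the `expressed` flag (the
prefilter rule, count > 10 in at least 2 samples, evaluated per exon)
gates the caller away from the low-count regime where a moment estimator
is unreliable.

The test statistic for a feature is the log ratio of group means of
normalized counts over a delta-method standard error,
$$ z = \frac{\ln\frac{m_t+\varepsilon}{m_c+\varepsilon}}
{\sqrt{\tfrac{1}{n_c}\left(\tfrac{1}{m_c+\varepsilon}+\hat\alpha\right)
 + \tfrac{1}{n_t}\left(\tfrac{1}{m_t+\varepsilon}+\hat\alpha\right)}}, $$
with pseudocount $\varepsilon = 0.5$ applied only inside ratios and
variances (raw zeros are preserved in outputs; an all-zero group yields a
finite negative fold change rather than an infinity).

**Reference distribution.** $z$ is compared to a $t$ distribution with
$n_c + n_t - 2$ degrees of freedom rather than a standard normal. At the
replicate numbers this design targets (5 + 6), the plug-in of a noisy
moment dispersion into the standard error makes the normal reference
visibly anti-conservative (empirical type-I error near 0.08 at nominal
0.05 in null simulations), while the $t_{n-2}$ reference is calibrated —
the acceptance script measures the empirical type-I error on 5,000 null
exons with baseline mean at least 50 and the suite requires it to fall in
[0.035, 0.065], with power at fold 3, mean 100 above 0.95. This is the
package's deliberate small-sample correction, analogous to the moderated
references used by established count-model packages.

**Absolute versus relative mode.** Exon statistics can be computed against
library size factors (`mode = "absolute"`, the default) or against a
per-gene factor (the gene's total in each sample over its geometric mean
across samples; `mode = "relative"`), which tests exon *usage* within the
gene. The default is absolute because internal initiation elevates the
gene's own total: in relative mode a cryptic gene with half its bins
elevated at fold $f$ has most of the signal absorbed into the gene factor
(the per-bin relative fold shrinks toward $f/\gamma$ with
$\gamma \approx 1 + d(f-1)$ for affected mass fraction $d$), and the
screen loses most of its sensitivity. Relative mode is retained for users
who want usage-style statistics; genes with a zero total in any sample are
flagged and skipped there. Statistics from external exon-usage tools can
also be imported directly (`read_exon_stats()`), bypassing the native test
entirely.

Thresholds follow the original analyses and are all explicit parameters,
echoed into each run's manifest: gene-level reporting at p < 0.01,
exon-level reporting at p < 0.001, and caller significance at p < 0.05.
Raw p-values are compared to these thresholds (a Benjamini–Hochberg column
is emitted for reference but not used for calling).

# The caller cascade

For a gene with exons 1..E in transcriptional order, with
SIG_UP(i) := p_i < 0.05 and elevation in treatment:

1. some exon must be SIG_UP (`NO_UP` otherwise);
2. if the first annotated *and expressed* exon is SIG_UP the gene is
   discarded as a full-length upregulation (`FULL_LENGTH_UP`);
3. the candidate cryptic TSS c is the first SIG_UP exon;
4. the fraction of downstream exons (c..E) that are SIG_UP must be at
   least 0.60 (`DOWNSTREAM_FRAC`); exactly 0.60 passes, since the rule
   removes genes *below* 60%;
5. c must lie in the first half of the gene, c ≤ ⌈E/2⌉ (`LATE_TSS`);
   c = ⌈E/2⌉ passes exactly.

Genes with no expressed exon (`NOT_EXPRESSED`) or fewer than `min_exons`
bins (`TOO_FEW_EXONS`) are screened out first. The test suite proves the
implementation equivalent to an independent, literal transliteration of
the five rules over every significance pattern for E ≤ 8 and 10,000
random patterns for E ≤ 25.

Several readings of the protocol are genuinely open; the package fixes a
default and exposes the alternative:

* **Downstream denominator includes the TSS exon**
  (`include_tss_in_downstream = TRUE`): the TSS exon is itself elevated
  under internal initiation, and excluding it makes two-bin tails
  degenerate. With the flag off and c = E, the empty denominator is read
  as imposing no constraint.
* **"First half" is inclusive for odd E** (`half_boundary = "ceiling"`),
  with `"floor"` available.
* **"First annotated and expressed exon"** is read as the first exon that
  is both (unexpressed leading exons are skipped): an exon without
  expression cannot evidence full-length upregulation.
* **The downstream denominator counts all annotated exons** by default;
  `require_expressed_denominator = TRUE` restricts it to expressed ones.
* `min_exons = 1`: no gene-size filter beyond the rules themselves. A
  2-exon gene can structurally never pass (any candidate TSS at bin 2 is
  past ⌈2/2⌉ = 1) — an emergent property, not an added filter.

# The simulator and what it does (not) emulate

`simulate_experiment()` generates the statistical structure the screen
assumes: per-gene baselines $e^{N(4,1)}$ (median ≈ 55 counts), per-exon
log-normal weights (sd 0.5), 5% of exons effectively unexpressed
(baseline × 0.01), uniform library factors in [0.7, 1.3], NB counts at
dispersion 0.1, E uniform on 2..25, five control and six treatment
replicates, and treatment folds uniform on [2, 4]. Gene classes: 80%
null, 5% each full-length up/down and cryptic, 2.5% each of two decoys.
Cryptic genes elevate all bins from an internal start
j ∈ [2, ⌈E/2⌉]; since that interval is empty for E = 2, classes needing an
early internal start draw E ≥ 3. `DECOY_LATE` elevates all bins from a
late start j ∈ [⌈E/2⌉+1, E]. `DECOY_PARTIAL` elevates a subset of the
bins from an early start j covering 40% of them; the subset always
contains j itself so that the decoy fails specifically the
downstream-fraction rule rather than stumbling into the first-half rule —
each decoy class exercises exactly one rejection path by construction.

The simulator emulates count statistics, not reads: there is no positional
read model, no splicing realism, no correlated dispersion trend, no
batch structure, and no sex-specific effects (run twice with different
seeds to emulate sex-stratified analyses). Passing recovery tests
therefore demonstrates that the statistics and the cascade do what they
claim on data satisfying the NB model — not that the screen is robust to
alignment artefacts, 3' bias, or annotation errors in real libraries.

# Overlap statistics and universe calibration

Gene-list overlaps use the one-sided (enrichment) upper-tail
hypergeometric probability, summed in log space from `lchoose` terms, so
p-values down to the 1e-131 scale of genome-wide list comparisons remain
finite and stable to at least six significant digits across summation
orders. The universe N is always an explicit argument — published overlap
p-values are meaningless without it, and since papers often leave N
unprinted, `calibrate_universe()` recovers it by inverting the exact test
(monotonicity of p in N is verified over the search bracket before
bisection; the integer result minimises the log10 discrepancy and
round-trips exactly on synthetic instances). The acceptance suite checks
that a single calibrated N reconciles a set of published overlap
p-values to within their printed precision's reach.

# Numerical and reproducibility choices

* Coordinates: 0-based half-open internally; GFF in/out 1-based
  inclusive; BED 0-based half-open. One conversion site per format.
* Count-table row keys are `gene_id:E###`; a colon in a gene id is
  rejected at read time. Missing bins are an error, not a zero-fill —
  silent zero-fill would bias the caller's downstream denominator.
* Every run is a deterministic function of its configuration seed;
  fixture writes and pipeline outputs are byte-identical across re-runs
  (numeric columns are written at 12 significant digits).
* Failed pipeline stages abort with the stage name before any output file
  is written, so a run directory is never left half-populated.

Test problem sizes were chosen to make sampling error small relative to
the margins being asserted while keeping the default suite quick: 5,000
exons for calibration, ~600 exons for power, 2,000 genes for end-to-end
recovery, 10,508 patterns for caller–oracle equivalence, and 10^6 draws
for the Monte-Carlo overlap check.

# Known limitations

* **Reason-code migration on late decoys.** A late-elevation decoy has on
  average ~10 null exons before its true internal start; at caller
  significance 0.05 each has a ≈2.5% chance of a spurious upward call, so
  roughly one in six late decoys acquires an earlier false candidate TSS.
  The gene is still rejected — but by `DOWNSTREAM_FRAC` (the spurious
  early TSS dilutes the downstream fraction) or `FULL_LENGTH_UP` (when the
  spurious exon is the first) instead of `LATE_TSS`. Reason codes for
  rejected genes are therefore diagnostic, not exact, at the default
  significance level; decisions (PASS/FAIL) are unaffected.
* The moment dispersion estimator is anti-conservative at very low
  counts; the `expressed` gate, not the estimator, is what protects the
  caller there.
* The caller consumes marginal per-exon p-values and does not model
  dependence between exons of the same gene; its operating
  characteristics are established by simulation, not by a joint model.
* No multiple-testing correction is applied to the handful of overlap
  tests, matching the practice the package reproduces.
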