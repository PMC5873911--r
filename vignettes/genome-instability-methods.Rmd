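---
title: "Methods: coverage-based CNV calling and somatic SNP statistics for serially allografted tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based CNV calling and somatic SNP statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and its central confounder

`tumorGI` analyzes paired whole-genome sequencing of experimentally induced
Drosophila larval brain tumors propagated by serial allografting (tumor
sampled at rounds T0, T5, T10), with the donor larva's non-tumoural tissue as
the matched control. Two properties of this design shape everything below:

* **The control is polytene.** Larval tissues endoreplicate, and a set of
  under-replicated regions (URs) fails to reach full copy number in the
  control. When a non-polytene tumor is divided by such a control, every UR
  shows up as an apparent copy-number *gain*. These artifact gains are a
  useful positive control for the calling machinery, but they must be masked
  out before biology is read off the CNV map.
* **The tumor is a lineage.** Lesions (CNVs and SNPs) are born and lost along
  the allograft series, so the unit of analysis is the trajectory
  (birth, retention, turnover), not a single sample.

# Coverage model and GC correction

Coverage is summarized as mean depth in fixed 1 kb bins. Per-bin coverage
depends smoothly on local GC content; we model a sample's binned coverage
$y_i$ given GC $g_i$ as

$$\mathbb{E}[y_i] = \mu(g_i), \qquad \operatorname{Var}[y_i] \propto \mu^{1.5},$$

a Tweedie compound-Poisson GLM with log link, with $\log \mu(g)$ a penalized
cubic regression spline (10 knots, smoothness by GCV) fitted per sample via
`mgcv::gam`. `fit_gc_correction()` exposes the response-scale residuals
$y_i - \hat\mu(g_i)$ (deviance residuals are available via
`residual_type = "deviance"`).

For downstream *ratio* work the package uses the **fitted-rescaled corrected
track** $\tilde y_i = \bar{\hat\mu}\, y_i / \hat\mu(g_i)$. Dividing by the
relative fitted bias removes the GC curve while preserving the multiplicative
copy-number signal between samples; an additive residual re-centring, the
obvious alternative, distorts a 1.5-fold gain by the local bias factor and
was rejected for that reason. The raw residuals remain available and are what
the decorrelation diagnostics use.

# Filtering and normalization

`filter_bins()` removes bins with mappability exactly 0, then bins whose GC
lies **strictly below** the 0.08 quantile of the GC of the remaining bins
(strict "below", so a degenerate all-equal GC track removes nothing; the
quantile is computed after the mappability rule because unmappable bins carry
an unreliable GC-coverage relation). One kept set is shared by all samples of
a run.

`quantile_normalize()` is classic quantile normalization (each sample's
sorted values replaced by the across-sample mean of sorted values, ties
averaged), backed by `limma::normalizeQuantiles`. One caveat worth knowing:
with only **two** samples in the run (a single tumor/control pair), the
procedure averages the tumor's aberrant upper quantiles with the control's,
compressing large gains by a modest amount (roughly 0.1 on the log2 scale
for a gain covering a few percent of the genome). With run-sized sample sets
this effect is diluted; it never moved a state call in our validation runs
because the five-state decision margins are far wider.

# Ratio, segmentation, and state calling

`compute_log_ratio()` forms $\log_2\!\big((t_i + \varepsilon)/(c_i +
\varepsilon)\big)$ and subtracts the genome-wide median. The pseudo-count
$\varepsilon$ defaults to half the smallest positive coverage increment in
the pair (0.5 for integer counts), protecting empty bins without displacing
typical values.

`cbs_segment()` is circular binary segmentation. For a segment of $n$ bins,
every arc $(i, j]$ is scored with

$$T(i,j) = \frac{|\bar x_{\text{arc}} - \bar x_{\text{rest}}|}
{\sqrt{1/k + 1/(n-k)}}, \qquad k = j - i,$$

(the data SD is permutation-invariant and omitted); the best arc is accepted
as a split when its permutation p-value is below `alpha = 0.01` (up to 1000
permutations, with sequential early stopping in both directions: a test
stops "not significant" as soon as the exceedance count makes $p < \alpha$
impossible, and "significant" once $(\text{exc}+1)/(m+1) < \alpha$ with at
least 100 permutations done). The scan is exhaustive and exact — for every
width the statistic is monotone in the arc sum, which keeps the inner loop
cheap — and the statistic is validated in the test suite against a
brute-force double loop for $n \le 50$.

**The undo rule.** After recursion, adjacent segments are merged while the
difference of their means is smaller than `undo_sd = 3` standard errors of
that difference, $3\,\hat\sigma\sqrt{1/n_1 + 1/n_2}$, with $\hat\sigma$ the
MAD of bin values minus segment means. We deliberately interpret "3 standard
deviations between segments" as a statement about the *difference of segment
means* rather than about the raw per-bin SD: at realistic read-depth noise
(per-bin log2-ratio SD around 0.5 at 50 reads/bin with moderate
overdispersion) a threshold of 3 per-bin SDs (~1.6) would exceed the entire
single-copy step of $\log_2(3/2) \approx 0.585$ and merge every true
heterozygous CNV back into the baseline. The SE-based reading preserves the
rule's purpose — discarding splits that the segment's own noise could
explain — at every depth.

`postsegment_normalize()` re-anchors the profile so the *mode* of the
bin-weighted segment-mean distribution sits at 0. The mode is taken as the
observed segment mean maximizing a bin-weighted Gaussian kernel density
(bandwidth 0.1 log2 units) evaluated at the observed means; unlike a mean or
median anchor this picks the dominant (diploid) level even when a large
minority of the genome is aberrant.

`call_states()` assigns each segment the nearest of the five canonical
levels

| state | meaning | log2 level |
|---|---|---|
| $-2$ | double deletion | $-2$ (capped) |
| $-1$ | single deletion | $-1$ |
| $0$ | diploid | $0$ |
| $+1$ | single amplification | $\log_2(3/2) \approx 0.585$ |
| $\ge +2$ | high amplification | $\ge 1$ |

and requires $|\bar x| > \max(0.25,\; 2\hat\sigma/\sqrt{n_\text{bins}})$ to
leave the diploid state. This nearest-level rule with a noise margin is a
documented simplification of a full Bayesian mixture classifier; the margin
default 0.25 sits just inside the diploid/+1 midpoint (0.293). Only
non-diploid segments are emitted, with 1-based inclusive coordinates snapped
to bin edges.

`mask_and_recall()` runs the whole chain twice — once on the full filtered
grid and once after removing every bin overlapping the UR/repeat mask by at
least 1 bp — mirroring the two-pass design in which the unmasked map
validates the method (URs appear as gains) and the masked map is the
biological result. The masked re-run also re-anchors diploidy on cleaner
bins, which is why it can reveal calls absent from the unmasked map.

`infer_sex()` uses the X/autosome mean-coverage ratio together with a
repeat-free Y proxy region (a kl-2-like interval): males sit near
$X/A = 0.5$ with $Y/A \approx 0.5$, females near $X/A = 1$ with $Y/A
\approx 0$. The decision thresholds (0.75 on X/A, 0.25 on Y/A) are halfway
between the expected levels; an X/A ratio exactly at 0.75 is reported as
ambiguous rather than forced.

# SNP statistics

* **Spectrum.** `substitution_spectrum()` collapses the twelve raw
  substitutions onto the six pyrimidine-reference classes (G>T counts as
  C>A, both reporting the same base-pair change); the suite checks
  invariance under reverse-complementing every record.
* **Clustering.** `cluster_test()` counts, for each SNP, the SNPs within a
  50 kb window centred on it (±25 kb, focal SNP included) and computes the
  binomial tail $P(X \ge k)$, $X \sim \mathrm{Bin}(N, w/n_\text{eff})$,
  flagging raw $p \le 0.001$ (no multiple-testing correction by default,
  matching the published analysis; a Bonferroni option exists). The
  effective genome size $n_\text{eff}$ — positions with enough read support
  to call a SNP — is an *input*: it is defined by the somatic caller in real
  data, and emitted as truth by the simulator. Overlapping significant
  windows are merged into reported regions.
* **Region enrichment.** `region_enrichment_test()` is the exact upper-tail
  binomial probability, accumulated in log space so that tails near
  $10^{-14}$ are representable. The expected fraction $p_0$ is an input (the
  published 2% expectation for the 3R hotspot region is not reconstructible
  from region length alone).
* **Exome rate.** `exome_rate()` divides the count of (AAF ≥ 0.1 filtered)
  variants inside exome intervals by the callable exome size in Mb.
* **Turnover.** `snp_turnover()` identifies SNPs across time points by exact
  (chrom, pos, ref, alt) match — the matching rule is unstated in the source
  analysis, and exact identity is the conservative choice for point
  mutations.
* **Oxidation check.** `orientation_bias_check()` pools alt-read orientation
  counts over the C>A class (G>T records strand-flipped so orientation is
  relative to the pyrimidine strand) and applies an exact two-sided binomial
  test against 0.5; a sample is flagged only when the imbalance is
  significant ($p < 0.01$) *and* in the configured artifact direction,
  since 8-oxo-dG damage produces a directional, not merely unbalanced,
  skew.

The Mann-Whitney test (`mann_whitney()`) is the package-wide group
comparison. For $\min(n_a, n_b) \le 8$ the two-sided p-value is exact by
full enumeration of all $\binom{n_a+n_b}{n_a}$ rank assignments (average
ranks keep the enumeration exact under ties); larger samples use the normal
approximation with tie-corrected variance and continuity correction. The
permutation null of $U$ is symmetric about $n_a n_b / 2$, so the two-sided
p doubles the smaller tail, capped at 1.

# What the generator emulates — and what it does not

`simulate_genome()` / `simulate_lineage()` / `simulate_coverage()` produce
data with the statistical structure the pipeline assumes:

* a compact 6-arm genome (X, 2L, 2R, 3L, 3R, 4; 20 Mb at 1 kb bins, so a
  full pipeline run takes seconds) plus a short repeat-free Y proxy;
* a smooth (moving-average filtered) GC track, mean 0.45, SD 0.05; 2% of
  bins unmappable; URs covering 10% and repeats 5% of the non-Y genome;
* negative-binomial bin counts, mean
  $\text{depth} \times (\text{copy}/2) \times e^{b(g)} \times
  \text{mappability}$, size 20 (the standard overdispersed read-depth
  choice), with depth 50 by default (the study does not state per-sample
  depth); $b(g)$ quadratic in centred GC on the log scale;
* control coverage multiplied by `ur_factor` (default 0.3) inside URs,
  emulating incomplete endoreplication;
* lesion dynamics per recorded passage transition: Poisson births (4 CNVs,
  15 SNPs per transition by default) and independent survival with
  `retention_prob` (default 0.5). These defaults, on the 1/7-scale toy
  genome, reproduce the cohort's per-sample CNV counts and its 5-70%
  T0→T10 turnover range. A split passage (e.g. 9) divides its transition
  into a shared sub-step and independent remainders, so sublines share
  lesions born before the split and can each lose them afterwards;
* CNV sizes log-uniform on 10 kb–1 Mb; states mostly ±1 (92% single-copy,
  gains more frequent); SNP classes drawn from a configurable six-class
  spectrum, AAF from Beta(2, 4), orientation counts binomial with
  configurable skew.

Not emulated: read-level data (FASTQ/alignment), transposable-element
sequence content, real polytene band structure, mappability that correlates
with repeats, GC-dependence of *variant* calling, and sequencing batch
effects. Passing the recovery suite therefore demonstrates that the
*algorithms* behave as specified under the assumed noise model — not that
the pipeline is robust to every artifact of real libraries.

# Numerical conventions and degenerate inputs

* Coordinates: 0-based half-open on disk (coverage TSV, BED), 1-based
  inclusive in reports and call tables; conversions live in the I/O layer.
* Determinism: every generator function draws under a seed derived from
  `config$seed` and the sample id, and restores the caller's RNG state;
  identical configurations give byte-identical output. CBS permutations use
  R's RNG and are reproducible under `set.seed()`.
* Constant segments short-circuit the permutation test (a segment whose
  range is below 1e-12 never splits), avoiding floating-point ties in the
  arc scan.
* A constant GC track collapses the GC model to the intercept; fewer than
  500 mappable bins or an all-zero sample is an error, not a silent fit.
* Quantile ties: averaged ranks; GC-filter ties at the threshold survive
  (strict `<`); a mask covering a whole arm skips the arm with a warning.
* Mb figures in summary tables are reported unrounded; display rounding is
  left to the caller (the source analyses mix truncation and rounding, so no
  convention is imposed).

# Problem sizes used by the validation suite

The test suite runs the full pipeline on the default 20 Mb genome at depth
50 (three tumor/control comparisons for recovery; one polytene-control pair,
masked and unmasked, for the UR artifact check), 500 null segmentations of
100 bins for the false-split rate, 100 replicates of 476 uniform SNPs on a
110 Mb effective genome for the cluster test's type-I behaviour, and
4 × 400 lesions per retention level for turnover recovery. These sizes give
each stochastic check a sampling error comfortably inside its acceptance
margin while keeping a complete run under a minute.

# Known limitations

* The five-state caller is a nearest-level rule, not a mixture model;
  segment means lying near level midpoints inherit the margin's bias toward
  diploid.
* Breakpoints are bin-resolution; no sub-bin refinement is attempted.
* The two-sample quantile-normalization compression described above is
  inherent to pair-wise runs; feed whole runs (all samples of a tumor type)
  when absolute segment means matter.
* Allele-specific copy number, karyotype-level aneuploidy and functional
  annotation are out of scope; annotation classes on variants are consumed,
  never computed.
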