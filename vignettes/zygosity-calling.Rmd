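---
title: "Anchored zygosity calling of focal CDKN2A/B deletions: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored zygosity calling of focal CDKN2A/B deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalzyg)
```

## The problem

Homozygous deletion of the CDKN2A/B locus on 9p21 is a diagnostic
criterion for WHO grade 3 meningioma, and heterozygous loss and even
elevated CDKN2A expression in deletion-intact tumors carry prognostic
weight. Copy-number profiles derived from methylation arrays report, per
genomic bin, the log2 ratio of tumor to diploid-normal signal. In a bulk
tumor of purity $p$ (tumor-cell fraction), a region present at $c$
copies in the tumor shows an expected log2 ratio of

$$\ell(c, p) \;=\; \log_2\!\frac{p\,c + 2(1 - p)}{2}.$$

Purity compresses everything toward 0: at $p = 1$ a single-copy loss
sits at $-1$ and a homozygous deletion at $-\infty$, while at $p = 0.5$
they sit at $-0.415$ and $-1$. A fixed log2 cutoff therefore cannot
separate heterozygous from homozygous deletion across samples of varying
purity. Neuropathology practice resolves this by eye: a deletion is
called homozygous when its depth is clearly deeper than the single-copy
arm-level losses (1p, 10, 22q and similar) visible *in the same sample*.
`focalzyg` automates exactly that within-sample comparison.

## The anchored caller

For each sample the caller:

1. **Summarizes arms.** Each chromosome arm gets its median bin log2
   ratio; arms at or below $-0.15$ are losses, at or above $+0.15$
   gains. Arms with fewer than `min_bins_per_arm` (default 3) bins are
   excluded with a warning.
2. **Finds anchors.** Loss arms on chromosomes other than the target
   chromosome whose medians lie in $[-1.2, -0.15]$ are single-copy-loss
   anchors; $m$ is the median of their medians. The lower bound
   excludes arm-level losses deep enough to be homozygous — biologically
   rare, and poison for the calibration; the $-1.2$ value tolerates
   purity estimates slightly above 1 due to noise. The range admits
   purities down to about 0.17.
3. **Estimates purity.** A single-copy loss sits at
   $m = \log_2(1 - p/2)$, so $\hat p = 2(1 - 2^m)$, clipped to
   $[0.05, 1]$.
4. **Classifies the locus.** The locus depth $L$ (median of locus bins;
   at least `min_locus_bins = 3` required) is assigned to the nearest of
   three expected levels: $0$ (intact), $m$ (heterozygous deletion), and
   $\log_2(1 - \hat p)$ floored at $-4$ (homozygous deletion). Ties
   break toward the less extreme call — the conservative posture
   appropriate for a grade-defining criterion.

Distance to the nearest expected level, rather than a fixed ratio such
as "twice the anchor depth", is the central design choice: the
"homodel is about twice as deep as a single-copy loss" heuristic is only
exact at $p = 1$, whereas the three expected levels are correct at every
purity by construction.

**The intact guard.** On top of nearest-level classification, the
caller returns intact whenever $L > \max(m/2,\ -0.25)$. For typical
anchors ($m \le -0.5$, purity above roughly 0.59) this is a flat
$-0.25$ guard — midway between 0 and the $-0.35$ shallow-deletion bound
of the fixed rule below — which keeps bin noise around 0 from ever
producing a deletion call. For shallower anchors the flat guard would
swallow the heterozygous level itself (at purity 0.3 a single-copy loss
sits at $-0.234$), so the guard relaxes to the intact/heterodel midpoint
$m/2$, which is exactly the nearest-level boundary. This piecewise guard
is what makes the caller exact on noise-free profiles down to purity
0.3 while remaining conservative at ordinary purities.

**Fallback.** When no anchor arm exists the sample cannot be
calibrated, and the caller applies the fixed cutoffs published for
exome-based copy-number ratios: $L < -0.7$ homozygous deletion,
$-0.7 \le L \le -0.35$ heterozygous (both boundaries belong to the
shallow band), $L > -0.35$ intact. Such calls carry
`confidence_flag = "no_anchor_fallback"`; a locus covered by fewer than
3 bins likewise falls back with `low_bins`. The two modes agree on
noise-free profiles when the purity puts the single-copy level inside
the fixed shallow band (roughly $p \in [0.39, 0.62]$); at purity 1 a
single-copy loss sits at $-1$, below the fixed deep cutoff, so the
fixed rule — built for impure clinical exomes — would over-call it.
This is an inherent limitation of any fixed cutoff and the reason the
anchored mode exists.

**Extent of target-arm loss.** The lost fraction of the target arm is
the share of its bins at or below $m/2$ (the intact/heterodel
midpoint), reported in 5% increments ($[0,5), [5,10), \dots,
[95,100]$ — half-open except the last) and categorized: 0 none, below
5% focal, 5–95% segmental, above 95% broad.

## Expression stratification

Counts are normalized to counts-per-million with TMM-scaled effective
library sizes. The TMM implementation is the canonical one — 30%
two-sided trim on M-values, 5% on A-values, inverse asymptotic-variance
weights, reference chosen by the upper-quartile rule, factors rescaled
to geometric mean 1 — and is verified against the established reference
implementation to $10^{-6}$ in the test suite.

CDKN2A expression is standardized *within each cohort* (sample
standard deviation, $n - 1$), and deletion-intact samples with cohort
Z-score $\ge 1$ (boundary inclusive) are CDKN2A-high; deleted samples
are labeled `deleted` regardless of expression. Z-scores are computed
on $\log_2(\mathrm{CPM} + 1)$ by default: raw-CPM Z-scores are
dominated by the heavy right tail of expression data, and cohort
standardization is invariant to monotone affine transforms, so the log
scale changes only robustness, not the rule. A `log_transform = FALSE`
mode provides the literal raw-CPM behavior. The $Z \ge 1$ rule is
applied to CDKN2A only, not CDKN2B.

## Survival statistics

Kaplan–Meier estimation, the log-rank test (global, pairwise with
Benjamini–Hochberg adjustment, and an optional group-label permutation
p-value for small samples) and Cox proportional-hazards regression are
delegated to the standard survival machinery, surfaced with a uniform
table interface. Ties use Efron's approximation — the accepted default —
with Breslow available (note that record duplication is an exact
invariance of the Breslow partial likelihood only; Efron's correction
perturbs it slightly). Intervals and p-values are Wald, matching the
HR (CI) presentation style of clinical reports; convergence follows the
fitter's relative log-likelihood criterion at $10^{-11}$, and diverging
coefficients (separation) raise an explicit error rather than a quiet
huge hazard ratio. Schoenfeld-residual diagnostics are out of scope.
Inter-rater agreement uses Cohen's kappa (unweighted, linear or
quadratic weights) with the Fleiss–Cohen–Everitt asymptotic confidence
interval.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with known truth:

* **Genome.** Ten abstract 100 Mb chromosomes, p arm 0–45 Mb, q arm
  45–100 Mb, tiled at 200 kb (5000 bins per sample). The target locus is
  a 2 Mb window on chr9p covering 10 bins — 4.4% of the arm, so a
  locus-only deletion is focal under the 5% rule. Using an abstract
  genome keeps coordinates pure configuration; any real-locus BED is
  accepted.
* **Copy number.** One purity per sample, drawn uniformly from
  $(0.4, 0.95)$ — a realistic bulk-tumor range; no subclonality.
  Per-bin Gaussian noise in log2 space (default SD 0.15, the scale of
  array bin scatter). Deletion extents: focal deletes the locus window
  only; segmental a contiguous 25–75% of the arm containing the locus;
  broad the whole arm. Homozygous deletions are nested: the surrounding
  region is single-copy and the locus drops to zero copies, the pattern
  focal homodels show in practice. chr1p is lost in every sample
  (arm-level losses of 1p, 10, 22q are near-universal companions of
  CDKN2A/B deletion in aggressive meningiomas) and every other
  non-target arm independently with probability 0.15, providing
  anchors.
* **Zygosity mix.** 92% intact, 3% heterozygous, 5% homozygous —
  deletions are rare events, as in the pooled clinical material; the
  extent mix given deletion is 40/40/20 focal/segmental/broad.
* **Expression.** Negative-binomial counts for CDKN2A and CDKN2B with
  group-dependent means ordered homodel < intact-low < intact-high
  (25/220/750 for CDKN2A), a large dispersion for heterozygous samples
  (their expression is heterogeneous), 200 filler genes with log-normal
  per-gene means (so TMM/CPM have structure to normalize), log-normal
  per-sample depth, and a Gaussian copula coupling the two target genes
  (latent correlation 0.8). Note that the *total* observed
  CDKN2A–CDKN2B correlation also inherits the shared depth and group
  structure and is therefore higher than the latent parameter — as in
  real data, where co-regulation, copy number and depth all contribute.
  The latent parameter is validated in isolation (single group, fixed
  depth), where it is recovered within ±0.1.
* **Survival.** Weibull baseline (shape 1.2, characteristic time 90
  months — an increasing hazard with realistic median PFS),
  proportional hazards with configurable log-HRs (defaults: high
  expression log 2, heterodel 0.5, homodel 1.0, grade 2/3 0.4/0.9,
  subtotal resection 0.5), exponential censoring at 0.008 per month.
  Time is the minimum of event and censoring time.
* **Seeding.** One master seed; each generator (and each per-sample
  CNV profile) uses a stream derived deterministically from it, so all
  outputs are bit-reproducible and profiles can be regenerated
  individually.

What the generator does *not* emulate: probe-level intensities or
methylation beta values, GC waves and segmentation artifacts, subclonal
deletions, cohort-specific purity distributions (unreported for the
study material; a single uniform range is used), or correlation between
deletion status and clinical covariates. Passing tests therefore
demonstrate correctness of the calling logic under the stated noise
model, not robustness to every artifact of real arrays.

## Validation sizes and numerical choices

The test suite and acceptance script validate at these scales, chosen
to make Monte-Carlo noise negligible relative to the tolerances: exact
caller/truth agreement on a noise-free grid of purities 0.3–1.0 ×
{focal, segmental, broad} × {heterodel, homodel} (48 profiles); ≥ 95%
zygosity accuracy over 500 noisy samples at purity ≥ 0.5 and noise SD
0.15; TMM agreement with the reference implementation to $10^{-6}$ on a
200 × 6 matrix; a 6-subject log-rank permutation p checked against
exhaustive enumeration of all 20 label assignments; an 8-subject Cox
coefficient checked against brute-force partial-likelihood maximization
to $10^{-6}$; 95% CI coverage of a log 2 hazard ratio in ≥ 90% of 50
replicates at n = 500; and a 2000-sample demo in which the fitted
high-expression HR confidence interval excludes 1. The demo HR is
attenuated below the configured value (about 1.4 versus 2) because the
$Z \ge 1$ rule misclassifies part of the latent high group — the same
attenuation any threshold-based stratification of a continuous marker
suffers, and worth remembering when reading group HRs.

Numerical conventions: log2 depths are floored at $-4$ (far below any
decision boundary, avoiding $-\infty$); purity estimates are clipped to
$[0.05, 1]$; coordinates are 0-based half-open in memory and 1-based
inclusive in SEG files; percentages in prevalence reports are always
recomputed from counts.

## The prevalence fixture

`inst/extdata/cohort_deletion_counts.tsv` holds published per-cohort
deletion counts for 1577 meningiomas across six cohorts, of which 71
cases in one cohort were assayed by immunohistochemistry only and are
flagged for exclusion (28 of them homozygously deleted). Excluding them
from numerator and denominator reproduces the printed pooled figures:
108 deletions in 1506 patients (68 homozygous + 40 heterozygous,
7.2%). The source tabulation is internally inconsistent by one case:
its footnote counts 29 deletions among the 71 excluded cases (28
homozygous + 1 heterozygous), which would give 107/1506; the fixture
reproduces the printed pooled numbers and flags only the 28 homozygous
cases as excluded deletions.

## Known limitations

* The anchored caller assumes at least one genuine single-copy arm loss;
  in near-diploid genomes it silently degrades to the fixed rule, which
  over-calls deep deletions in high-purity samples.
* A single genome-wide purity is estimated; focal events in a minor
  subclone will be pulled toward the intact level and under-called.
* Extent scoring counts bins below a depth midpoint; it does not
  segment, so interleaved noise bins inflate the lost fraction slightly
  at high noise.
* The locus is treated as one window (CDKN2A and CDKN2B jointly);
  per-gene windows require supplying per-gene BED intervals.
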