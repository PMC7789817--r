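---
title: "Methods: epi-signature discovery, classification and array-based CNV calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epi-signature discovery, classification and array-based CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcan)
```

# Scope and model

`episcan` analyses peripheral-blood DNA methylation arrays for syndromes in
which a genomic defect leaves a reproducible genome-wide methylation
footprint (an *epi-signature*). The pipeline has four statistical layers —
per-probe differential methylation, regional (DMR) aggregation, supervised
classification, and intensity-based copy-number calling — plus a
phenotype-microarray module for cellular metabolic readouts. Each layer is
described below with its assumptions, tunable parameters and the numerical
decisions taken where the design was genuinely open.

## Measurement scales

A probe's methylation level is the beta value
$\beta = M/(M + U + \text{offset})$ where $M, U$ are the methylated and
unmethylated channel intensities. Betas are bounded, interpretable
fractions and are used for effect sizes and visualisation; inference runs
on the M-value $\mathrm{M} = \log_2 \beta/(1-\beta)$, whose variance is
far closer to constant across the methylation range. `compute_beta()`
defaults to offset 0 (the plain intensity ratio); the Illumina convention
of offset 100 is available and the value used is carried in the dataset.
M-values clip betas into $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$, which bounds M-values at about $\pm 19.9$ without
perturbing interior probes; `beta_to_m()` and `m_to_beta()` invert each
other to $10^{-12}$ on that interior.

## Quality control

Probe filters remove, in order of precedence: probes failing detection
($p > 0.01$ in **any** retained sample — a conservative rule that keeps
the probe set identical across samples), sex-chromosome probes, probes
with SNPs at the interrogated site, and cross-reactive probes. Sample QC
excludes arrays with a failed-probe fraction strictly above 5% (a sample
at exactly 5% is retained), records predicted sex, and checks that the
genome-wide beta distribution is bimodal.

Two QC statistics are deliberately simple, declared thresholds rather
than estimated ones:

* **Sex prediction** compares the median log2 total intensity of chrY
  probes against chrX; the male call threshold (Y − X > −2) separates the
  two intensity regimes (Y at autosomal level in males, at background in
  females) with a wide margin and is configurable.
* **Bimodality** passes when the fraction of betas in the open interval
  (0.3, 0.7) is below 0.35. A healthy blood methylome concentrates near 0
  and 1; a flat (uniform) profile has mid-range mass 0.4 and fails. A dip
  test would need critical tables; the mid-range-mass rule is transparent
  and directly testable.

## Matched-control selection

Controls are matched 4:1 to cases by greedy nearest-neighbour age matching
within exact (sex, batch) strata, without replacement, ties broken by pool
order for determinism. After each pass, a PCA of the matched controls'
M-values flags scores beyond 3 SD on PC1 or PC2; flagged controls are
removed from the pool and matching repeats (at most 10 iterations). The
outlier pass runs on the matched *controls* only: cases are expected to
separate from controls precisely when a signature exists, and cannot be
replaced, so including them would conflate signal with artefact.

## Cell-type deconvolution

Blood methylation is a mixture over leukocyte subtypes, and case/control
differences in cell composition masquerade as methylation differences.
Per-sample proportions are estimated by projecting the sample's betas at
the reference's discriminating probes onto the cell-type profiles under
$w \ge 0$, $\sum w \le 1$. With at most a handful of cell types the
constrained least-squares problem is solved *exactly* by enumerating
active sets (each subset of zeroed coordinates, with and without the sum
constraint active) — a convex QP's optimum is the equality solve of its
own active set, so enumeration cannot miss it. The packaged reference is
synthetic (each type owns a block of high-contrast probes); any real
sorted-cell reference of the same shape can be substituted.

In the regression design the **last proportion column is dropped**
(baseline cell type): estimated proportions sum to nearly one and would
otherwise be collinear with the intercept.

## Differential methylation

Per probe, ordinary least squares of M-values on an intercept, the group
indicator, and covariates (cell proportions, optionally others). Residual
variances are moderated by an empirical-Bayes prior: a scaled
inverse-chi-square prior $(d_0, s_0^2)$ is fit by method of moments on
$\log s^2$ (using the digamma/trigamma moments of the log of a variance
estimate; the trigamma inverse is solved by Newton iteration to relative
$10^{-12}$), the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d\,s^2)/(d_0 + d)$, and the moderated t uses
$d + d_0$ degrees of freedom. Degenerate inputs are handled explicitly:
when the observed variances are (numerically) constant there is nothing to
shrink and the prior is taken as $d_0 = \infty$ with the variances used
as-is, so the moderated t equals the ordinary t.

Signature probes require **both** $|\Delta\beta| > 0.10$ on the beta scale
and BH-adjusted $q < 0.01$ (strict inequalities; a probe at exactly the
threshold is excluded). The effect-size guard suppresses statistically
significant but biologically negligible probes; tests are two-sided
throughout.

## DMR calling

Per chromosome, probe t-statistics are smoothed with a Gaussian kernel of
bandwidth $\sigma = \lambda/C$ ($\lambda = 1000$ bp, $C = 2$ by default),
standardised as $z_i = \sum_j w_{ij} t_j / \sqrt{\sum_j w_{ij}^2}$ so that
an isolated probe keeps $z_i = t_i$ while dense agreeing probes gain
power. Kernel weights are truncated beyond $8\sigma$ (below $10^{-13}$),
which makes smoothing effectively linear-time. Candidate probes are those
significant after genome-wide BH of the smoothed p-values (threshold
0.05); candidates at most 1 kb apart are chained, and a region is reported
when it has ≥ 3 probes, mean $|\Delta\beta| > 0.10$, and Stouffer-combined
FDR < 0.01. The Stouffer statistic combines member probes' adjusted
q-values as signed normal quantiles,
$z = \sum_i \Phi^{-1}(1 - q_i/2)\,\mathrm{sign}(t_i)/\sqrt{n}$ (q floored
at $10^{-300}$ to keep the quantile finite), and its two-sided p-value is
BH-adjusted across regions. The *signed* combination is this package's
declared definition: it rewards directionally coherent regions, matching
the biology of contiguous hyper- or hypomethylation; region boundaries are
reported at member-probe positions, 1-based inclusive in memory and BED
(0-based half-open) on disk.

## MVP classification

Features are probes (within an optional cross-platform mask) whose group
mean betas differ by at least 0.10. One linear SVM per class
(one-vs-rest) is trained at a cost chosen by stratified 10-fold
cross-validation over {0.01, 0.1, 1, 10}, ties resolved toward the
smaller (more regularised) cost. Per-class Platt sigmoids
$P = 1/(1 + e^{Af + B})$ are fit by Newton's method with backtracking on
the **out-of-fold** decision values, so calibration never sees
resubstitution optimism; the smoothed targets $(N_+ + 1)/(N_+ + 2)$ and
$1/(N_- + 2)$ regularise the fit. The MVP score is the calibrated
per-class probability; the predicted class is the arg-max, and the
conventional 0.5 exceedance is reported alongside rather than enforced.
One-vs-rest with per-class sigmoids (rather than pairwise coupling) keeps
the score directly interpretable as "probability of carrying this class's
signature". Scoring new samples imputes up to 10% missing feature probes
with training-control means and refuses beyond that.

Validation harnesses mirror a small-cohort study design: leave-two-out
(all $\binom{n}{2}$ case pairs; per fold, probes are re-selected on the
remaining cases, all samples MDS-embedded, and held-out cases assigned to
the nearer of the case/control centroids), classical (Torgerson) MDS, and
Ward (`ward.D2`) clustering. Degenerate MDS input (all samples identical)
returns zero coordinates with a warning rather than failing.

## Copy-number analysis

Methylated plus unmethylated intensities are summed, quantile normalized
across the sample and its batch controls (tie values receive the average
of tied target quantiles), divided by the per-probe control median
(non-positive medians dropped with a warning), and log10-transformed. A
heterozygous deletion halves the total intensity, so its expected
log-ratio is $\log_{10} 0.5 \approx -0.30$.

Before segmentation, single-probe spikes are trimmed: values deviating
more than 3 MAD from their window-5 running median are replaced by that
median. Trimming — rather than filtering every value — matters: a full
running median serially correlates neighbouring probes, and the
segmentation permutation test (which shuffles probe values) then grossly
overstates significance on null data. Outlier replacement leaves the null
essentially exchangeable while still removing the spikes that would
otherwise fragment segments.

Segmentation recursively splits each segment at the position maximising
the standardized mean difference
$|\bar x_L - \bar x_R| / \sqrt{1/n_L + 1/n_R}$ (the segment SD is
permutation-invariant and omitted); the split is accepted when fewer than
$\alpha$ of `n_perm` within-segment shuffles reach the observed maximum
(p computed as $(1 + \#\{exceed\})/(1 + n_{perm})$, default
$\alpha = 0.01$, 10,000 permutations; package tests use 500 with
$\alpha$ unchanged). Single change-point (binary) splits with this
statistic are used throughout — an interior event is found by two
successive boundary splits. Adjacent segments with mean difference
< 0.05 are merged (probe-count-weighted, iterated to a fixed point), and
segments with mean log-ratio ≤ −0.1 spanning ≥ 5 probes are called
deletions. The −0.1 threshold sits at a third of the theoretical
single-copy signal, tolerating the compression that rank-based
normalization applies to extreme intensities; a 20% mosaic deletion
(average factor 0.9, log-ratio ≈ −0.046) is deliberately below it.

## Critical-region mapping

The critical region is the intersection of all signature-positive
deletion intervals minus the signature-negative ones. Negatives are
subtracted as **open** intervals (their interiors): deletion breakpoints
are boundary coordinates, and a breakpoint shared between a positive and a
negative deletion belongs to the region shared by positives and absent
from every negative's interior. Single-base slivers arising at such
boundaries are dropped. Intervals are 1-based inclusive; lengths in Mb are
$(\text{end} - \text{start})/10^6$ rounded half-up, the convention used in
published deletion tables (R's default banker's rounding would disagree at
exact half-digits). The packaged 22q13.3 deletion table (11 positive, 5
negative intervals) exercises this operation end to end.

## Phenotype-microarray statistics

The plate model covers PM-M1–M4 (energy sources), PM-M5–M8 (metabolic
effectors) at 96 wells each, plus the 8 analyzed tryptophan-plate wells —
776 wells in total, read kinetically every 15 min over 24 h (96 points).
Per well: relative absorbance $A_{590} - A_{750}$, minus the mean of the
blank-plate triplicate, floored at $10^{-3}$ (keeping the logarithm
finite), then log10. The endpoint value is the tested quantity; kinetic
slope (least-squares, OD/h), endpoint and trapezoidal AUC are computed and
reported but not tested per-well. Case and control lines are compared by
the two-sided Mann-Whitney test (exact for $n_x + n_y \le 12$ without
ties; normal approximation with tie and continuity corrections otherwise;
identical constant groups give $p = 1$), with BH correction across all
analyzed wells — the same BH implementation used genome-wide.

# The synthetic-data generator

The generator is the package's study-condition definition, not a tuning
knob. Defaults mirror the discovery design: 11 cases vs 44 matched
controls; a 1,000-probe signature at $\Delta\beta = 0.15$ with 80% of
probes hypermethylated (signatures of this kind are
hypermethylation-dominated); age range 3–19 years; balanced sexes; two
batches. Within-cohort variance of signature probes is not characterised
in published cohorts, so the noise level (`noise_sd = 0.05`, the
beta-scale SD at $\beta = 0.5$) was chosen once as a realistic array-scale
dispersion and is applied as Gaussian noise on the M scale (SD
$= 0.05 \cdot 4/\log 2$), back-transformed — betas therefore stay strictly
inside (0, 1) with no truncation artefacts, at the cost of a slight
attenuation of the realised beta-shift near the boundaries (planted shifts
use mid-range baselines, keeping the bias well inside ±0.05).

Cell-composition structure is a Dirichlet-weighted mixture of reference
profiles per sample; unequal concentration vectors between groups create
genuine confounding for the covariate adjustment to absorb. Intensities
are probe-level lognormal base levels (sdlog 0.8 — real array intensities
span orders of magnitude) times per-sample lognormal noise (sdlog 0.1),
exactly consistent with the betas at offset 0. The broad probe-level
spread is essential for the CNV chain: with a narrow intensity
distribution, quantile normalization has no low-intensity mass to map
halved probes onto and erases the deletion signal. Deletions multiply
both channels by a factor (0.5 heterozygous, 0.9 for a 20% mosaic);
plate runs use scaled-logistic kinetics with additive Gaussian noise and
a media-only blank triplicate.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: probe-type (Infinium I/II) chemistry and dye
bias, spatially structured batch effects, age- and sex-dependent
methylation drift, correlated probe blocks outside planted DMRs, mosaic
heterogeneity beyond a uniform intensity factor, and real plate
compound-specific kinetics.

# Problem sizes

Desk-scale sizes keep the full suite and the acceptance script fast while
preserving the regimes of interest: 20,000 probes across 3 autosomes plus
chrX/chrY for differential recovery (1,000 planted probes, 11 vs 44);
about 1,200 background probes around planted blocks for DMR fixtures;
10,000 probes and 500 extra controls for the classifier harness; 12,000
probes at ~1 kb spacing for CNV recovery of 0.1–5 Mb deletions with 500
permutations; the full 776-well layout with 11 vs 50 lines for the
metabolome screens.

# Known limitations

* Normalization internals of raw array data (IDAT parsing, background
  correction) are out of scope; the pipeline starts from intensity or
  beta matrices.
* The deconvolution reference shipped is synthetic; absolute proportion
  estimates on real blood require a real sorted-cell reference.
* The segmentation permutation test assumes exchangeable probe noise
  within a segment; long-range intensity waves (GC effects) would need an
  additional correction.
* The Stouffer-DMR definition, the one-vs-rest Platt scheme, the sex and
  bimodality thresholds, and the −0.1 deletion threshold are declared
  package conventions — reasonable, tested, and configurable, but not
  estimated from data.
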