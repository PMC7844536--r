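---
title: "Quantifying relative Wolbachia density: models, decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relative Wolbachia density: models, decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbaq)
```

## The measurement

*Wolbachia* is a maternally transmitted intracellular endosymbiont whose
abundance per host cell ("density") is a phenotype of interest in studies
of host-symbiont regulation. Because absolute fluorescence intensity is
not comparable across specimens, density is measured *relatively*: the
bacterial signal in a cell type of interest (COI — the somatic hub of the
testis, or the female germline) is normalized to the same signal in the
surrounding cells (SC — the mitotic germline around the hub, or the
follicle-cell layer around an egg chamber), imaged in the same stack under
the same settings. The statistic is

$$
\text{relative density} \;=\;
\frac{\sum_{\text{COI}} I \,/\, |\text{COI}|}
     {\sum_{\text{SC}} I \,/\, |\text{SC}|},
$$

where $I$ is bacterial-channel intensity, the sums run over the selected
z-slices, and $|\cdot|$ is the region's pixel count. The ratio cancels
global intensity scaling and pixel geometry, which is why areas are kept
in pixel counts rather than $\mu m^2$ and why intensities enter raw: a
multiplicative change in laser power or detector gain common to both
regions leaves the statistic unchanged. An additive background does
*not* cancel — it pulls the ratio toward 1 — so background subtraction
(per-slice median of the region exterior) is available behind a flag but
is off by default, matching the raw-sum definition of the statistic.

### Segmentation

The original measurements delineated COI and SC from anatomy by hand. Any
automated replacement must be stated and tunable, so `segment_regions()`
uses a deliberately simple, fully documented rule: per-slice Otsu
threshold of the boundary-marker channel (guarded by a whole-stack Otsu
threshold, so slices without boundary signal stay empty), morphological
closing, hole filling, and the largest enclosed component. For hubs the
enclosed interior is the COI and the SC is a dilation band whose outer
radius defaults to twice the COI equivalent radius — a proxy for the
mitotic region, with the factor exposed as `sc_outer_factor`. For egg
chambers the thresholded boundary (the follicle shell) *is* the SC and
the interior is the COI. The band is measured outward from the filled
boundary so it cannot overshoot into signal-free space, which would
deflate the SC density and inflate the ratio.

### Slice selection

"All middle z-slices" (hub) is operationalized as slices whose COI
cross-sectional area is at least 50% of the maximal slice area
(`min_area_frac`, configurable). The rationale is that cap slices of a
roughly spherical cell cluster have small, unrepresentative sections;
the half-max rule keeps the central band (for an ideal sphere, the
slices within $r\sqrt{3}/2$ of the equator). For the germline the five
consecutive slices centred on the maximal-area slice are used
(`k = 5`), shifted inward at stack edges and clamped with a warning when
`k` exceeds the stack.

## The synthetic-data generators

Each generator is seeded, draws from one private RNG stream (the global
stream is untouched), and returns ground truth alongside the data.

**Stacks.** `simulate_stack()` builds the two geometries as idealized
solids: a hub is a sphere (default radius 45% of the half-stack) with a
thin boundary shell and an SC annulus out to twice the COI radius; an egg
chamber is an ellipsoid with a follicle shell occupying the outer 15% of
its radius, in which the boundary marker and the SC coincide. Bacterial
puncta are placed uniformly at random within each region at Poisson
counts, with COI intensity per voxel scaled by the target ratio $r$, so
the expected COI/SC voxel-density ratio equals $r$ before blur and noise;
the realized ratio is recomputed from the placed puncta and reported as
truth. Puncta are Gaussian blobs (the point-spread sigmas default to 0 =
single-voxel impulses); noise, when enabled, is Poisson shot noise plus
Gaussian read noise. Default background is 0 so that the clean-stack
recovery properties are exact; realistic nonzero backgrounds are a knob,
with the documented caveat that raw-sum ratios are diluted by them. The
spatial distribution of bacteria within a region is not known to be
uniform in real tissue; a `clustering` knob concentrates puncta around
parent sites but makes no fidelity claim. No photobleaching, z
attenuation, or spectral bleed-through is modelled, and the DNA channel
is cosmetic — passing recovery tests on these stacks demonstrates the
correctness of the measurement code, not robustness to real optics.

**Cohorts.** `simulate_cohort()` draws per-specimen densities
log-normally. Because all groups share `sd_log`, the ratio of arithmetic
means equals `exp(delta mean_log)` exactly, so a group at
`mean_log = log(2.87)` has a true 2.87-fold increase — the effect size
reported for Atg1 knockdown in the hub, used with the study's group
sizes (37 vs 47) in the power property test. Cohort `sd_log` defaults in
tests to 0.3–0.6, the range in which raincloud plots of the real data
visually sit.

**qPCR plates.** `simulate_qpcr()` shifts the RNAi group's target CT by
$-\log_2(1-\text{knockdown})$ over a control $\Delta C_T$, with optional
per-replicate noise and a sample-level offset common to both genes
(which cancels in $\Delta C_T$). Noise-free plates round-trip the
knockdown fraction exactly through `knockdown_efficiency()`.

**Metabolomes.** `simulate_metabolome()` plants mean shifts (in SD
units) into named pathway blocks of a standard-normal feature matrix —
a caricature that exercises the ranking and permutation machinery, not a
model of LC-MS data (no heteroscedasticity, missingness, or correlated
features).

## The statistical decision tree

Normality is gated per group by Shapiro-Wilk at $\alpha = 0.05$; the
nonparametric branch is taken if *any* group fails — a conservative,
reproducible rule (the original analysis gated per dataset). Zero-variance
groups cannot be tested for normality and are routed nonparametric.

Two groups: two-sided Mann-Whitney U, computed by full enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments (tie-aware) when both groups have at
most 8 observations, otherwise the tie-corrected normal approximation
with continuity correction; or a two-sided unpaired t test. The t test
defaults to Welch (unequal variances) rather than the pooled-variance
Student form: the source analysis says only "unpaired Student's t", and
Welch is the safer default when group variances are not known to be
equal; `var_equal = TRUE` restores the pooled form. Sidedness is always
two-sided — directional claims are interpretations of a two-sided
rejection, not one-sided tests.

Multiple groups: Kruskal-Wallis (tie-corrected) then, only when the
omnibus rejects, all-pairs Dunn z tests on the pooled ranks with
Bonferroni multiplication over all $k(k-1)/2$ unordered pairs (capped at
1); or one-way ANOVA then Tukey HSD via the studentized range. The
Bonferroni count is all pairs because the source does not state a
smaller comparison family.

Proportions (tropism scoring) use the two-proportion chi-square test with
continuity correction plus per-group Wilson score intervals; box-plot
summaries use type-7 (linear interpolation) quantiles and 1.5 IQR
whiskers, with outliers flagged rather than dropped.

## The additive epistasis model

Two perturbations that individually increase density `fold_a` and
`fold_b` are expected, if they act in independent pathways, to combine to
`fold_a + fold_b` — the literal sum (2.33 and 3.89 give 6.22; 2 and 3
give 5). The literal rule has a known artifact: two null perturbations
(1, 1) "expect" 2. The deviation-additive alternative
`fold_a + fold_b - 1` removes it and is available as `rule =
"deviation"`, but the literal sum is the default because it is the
model's stated rule. The expectation is undefined for decrease-direction
folds and raises an error rather than guessing a convention.

`classify_epistasis()` runs the gated four-group comparison and applies
the verdict table: a combined group that differs from control but is
statistically indistinguishable from one single (and distinguishable from
the other) shares that single's pathway; one that differs from both
singles and lands closer (absolute distance on the fold scale) to the
additive expectation than to either single fold is independent-additive.
"Indistinguishable" is failure to reject at the Bonferroni-adjusted
$\alpha$ — an accept-the-null heuristic, flagged in every result. This
heuristic is asymmetric by construction: the multiplicity correction
that protects the same-pathway call also removes power from the
combined-vs-single comparison, so near the decision boundary (moderate
effect sizes at n around 30) the classifier errs toward shared-pathway
verdicts. Measured over 200 simulated cohorts at the study's effect
sizes (singles 2.33 and 3.89, `sd_log` 0.3, n = 30), a truly additive
combined group (6.22-fold) is labelled independent-additive in roughly
three quarters of runs under the default, and in over 95% with
`adjust = "none"` (raw pairwise p). The default stays conservative; the
knob and this trade-off are the user's call. An equivalence test (TOST)
would be the principled replacement for the accept-the-null heuristic
and is a known limitation, not implemented because it requires an
equivalence margin the source provides no basis for.

## qPCR quantification

Relative quantities use $2^{-\Delta\Delta C_T}$: technical replicates are
averaged on the CT scale (standard practice; the source is silent),
$\Delta C_T$ = target minus reference (wsp vs 14-3-3 for bacterial
titre; RNAi target vs RPL32 for knockdown), and $\Delta\Delta C_T$ is
anchored at the calibrator group's mean. Amplification efficiency is
fixed at 2 — no efficiency correction is applied in the source — but is
a parameter. Knockdown efficiency is $(1 - \text{mean relative
quantity}) \times 100$, clipped at 0 with an over-expression flag.
Plate-wide CT shifts cancel exactly.

## Preranked set enrichment

The ranking statistic is a signed Welch t per feature (the upstream
platform's exact statistic is undisclosed; this default is documented and
deterministic, with ties broken by feature id and zero-variance
separations capped at $10^8$). The enrichment score is the standard
weighted Kolmogorov-Smirnov running sum: hits add
$|s|^p / \sum_{\text{hits}} |s|^p$, misses subtract $1/(N-k)$, ES is the
signed extremum (magnitude ties resolve positive; weight $p$ defaults
to 1, and $p = 0$ — used by the exhaustive-enumeration tests — is
scale-invariant). The permutation null draws random member sets of the
pathway's size from the ranked universe: from a ranked list alone,
feature-label permutation is the only available scheme. NES divides ES
by the mean |ES| of same-sign nulls, and the p value uses the add-one
estimator $(1 + \#\{|ES_{null}| \ge |ES|\})/(1 + \#\text{same-sign
nulls})$, so p is never 0 and the estimator is slightly conservative.
These conventions are stated explicitly because the source delegates
them to an external web platform; the package therefore does not claim
to reproduce that platform's NES values numerically, only the method
class. The z-score/PCA overview standardizes features (dropping
constants with a warning) and reports sample coordinates and variance
explained from `prcomp`.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to be
informative yet quick: density recovery uses 64 x 80 x 80 stacks
(sphere radius 14 voxels, about 3,000 SC and 230–12,000 COI puncta)
over 20 seeds per target ratio; the type-I-error check uses 2,000 null
cohorts; classifier recovery uses 200 seeds per scenario; enrichment
calibration uses 20 pathway collections of 20 pathways at 200
permutations each. Monte-Carlo checks assert bands of at least three
binomial standard errors around their nominal values. Degenerate inputs
are errors, not guesses: empty simulated regions, blank boundary
channels, zero SC intensity, all-tied samples (reported as p = 1 with a
degeneracy flag), pathways that vanish after intersection with the
universe (skipped with a warning), and decrease-direction folds in the
additive rule.

## Known limitations

- Segmentation is a stated stand-in for expert manual outlines; its
  accuracy on real anatomy is untested and unclaimed.
- The simulators omit optical realism (PSF anisotropy is a parameter,
  bleed-through and attenuation are absent), so recovery results bound
  algorithmic, not instrumental, error.
- The same-pathway verdict accepts a null; see above.
- Enrichment results depend on the documented ranking and permutation
  conventions; other platforms' NES values will differ in detail.
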