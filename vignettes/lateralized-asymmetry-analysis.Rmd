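---
title: "Lateralized asymmetry analysis: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralized asymmetry analysis: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lrasym` implements the quantitative machinery for detecting left–right
side-specific effects of a unilateral brain injury (UBI) that are
transmitted humorally rather than through descending neural tracts: animals
with a completely transected spinal cord still develop hindlimb asymmetries
after a one-sided cortical lesion, and the package quantifies those
asymmetries in posture, in biomechanical resistance to stretch, and in
bilateral gene expression of the hypothalamus ("encoding" region) and
lumbar spinal cord ("decoding" region).

This vignette records the models, the tunable parameters with their
defaults and units, the design decisions taken where more than one
reasonable choice existed, and what the synthetic data generator does and
does not emulate.

## Postural asymmetry

Hindlimb postural asymmetry (HL-PA) is measured as replicate readings in
millimetres, negative for left and positive for right hindlimb flexion.
Three dependent but non-redundant measures are derived per rat and
timepoint:

* **PAS** — the signed per-rat value, the median of the (typically 6)
  replicate readings;
* **MPA** = |PAS|;
* **P_A** — the probability that a rat's MPA strictly exceeds the
  asymmetry threshold (default 1 mm; a 1.5 mm *selection* threshold is
  used when cohorts are preselected for antagonist treatment).

The threshold comparison is strict (`MPA > 1` mm); a rat at exactly the
threshold is not asymmetric.

Group inference is robust Bayesian. Locations use a Student-t response
with identity link and a group-indexing (no-intercept) parameterization;
P_A uses a Bernoulli response with logit link. Outcomes are standardized
before fitting and summaries are back-transformed. Priors on the
standardized scale: group effects ~ normal(0, 10), residual scales ~
half-Student-t(3, 0, 10), and the t degrees of freedom nu ~ gamma(2, 0.1).
The reference settings are 4 chains of 40 000 iterations with a 20 000
warm-up; the test suite and the bundled examples run 4 × 2000 (or 2 ×
2000), which is enough for the assertions made there because every
assertion carries an explicit Monte-Carlo allowance (e.g. "posterior
median within 0.05 of 0.5"). Convergence is reported via split-chain
R-hat and effective sample size; R-hat ≥ 1.1 flags the result with a
warning rather than failing silently.

Two numerical guards matter. First, the residual scale is truncated below
at 0.001 on the standardized scale so that exactly degenerate data (all
readings identical) keeps a finite likelihood; the truncation is far below
any scientifically meaningful scale. Second, when the outcome variance is
zero the standardization divisor falls back to 1.

Whether the group models should consume per-rat medians or raw replicates
with a rat-level random effect is genuinely open; both are supported
(`fit_robust_location(..., rat = )` adds a Gaussian rat effect), and the
per-rat-median route is what the bundled pipeline uses because the
replicate correlation within rat is high and medians are robust to single
aberrant readings.

Contrasts (Δ, difference of two group posteriors) and contrasts of
contrasts (ΔΔ, e.g. the effect of rhizotomy on the injury-vs-sham
difference) are computed draw-by-draw on the joint posterior, so posterior
correlation between groups propagates. A contrast is significant when its
95% highest-posterior-density interval excludes zero *and* the adjusted
p-value is ≤ .05. Multiplicity is adjusted by a single-step max-|t|
Monte-Carlo method on the centred joint draws — the contrast family's
covariance enters through the draws themselves — with Bonferroni available
as a conservative fallback. The posterior tail probability uses add-one
smoothing, so a p-value of exactly zero cannot occur at finite sample
size.

## Stretch resistance

The biomechanical measure is the mechanical work `W` (gram·mm) to stretch
a hindlimb: the force trace, sampled at 100 Hz during a 5 mm/s ramp, is
smoothed by local regression and integrated over the 0–10 mm window
(samples beyond 10 mm inform the smoother but not the integral). Smoothing
uses span 0.4 with the robust bisquare ("symmetric") family; the robustness
iteration count follows the `stats::loess` convention with the
conventional default of 4, and the local polynomial degree is 2
(configurable, recorded in output). The fit uses the exact ("direct")
surface rather than the interpolated one so that results are reproducible
to numerical precision against an independent local-regression
implementation.

Integration is trapezoidal at the observed distances with linear
interpolation to the exact window endpoints. The five technical replicate
stretches are integrated separately and their works averaged afterwards;
averaging after integration is invariant to replicate-specific sampling
jitter, which averaging the traces first is not.

Asymmetry is reported both as differences (`W_L − W_R`, and the
contralesional−ipsilesional `W_C − W_I` once the lesion side is known) and
as log2 indices (`AI = log2` of the work ratio), because the two can
depend differently on the stretching distance; no rule prefers one, so
both are always emitted. For sham animals the contra/ipsi fields are
undefined and reported as missing.

## qPCR expression

Relative quantities assume 100% amplification efficiency (RQ = 2^−Cq;
the base is configurable per assay) and are normalized to the geometric
mean of two reference genes per sample; samples missing a reference Cq are
excluded with a logged count. Reference-gene stability follows the geNorm
definitions: M is the mean standard deviation of pairwise log2 ratios
across samples, candidates are excluded worst-first with M recomputed
among the survivors, and the pairwise variation V(n/n+1) is the SD of
log2 of the ratio of successive normalization factors. The conventional
thresholds (M below 1.5, V below 0.15) are interpretive guides, not
enforced cutoffs. Stability can be computed per region or on pooled
samples; both modes are available because the appropriate sample set
depends on whether normalization is done within or across regions.

Fold changes are reported as the ratio of the larger to the smaller group
median — always ≥ 1 — together with an explicit direction flag. This
reconciles two conventions ("case over control" versus "magnitude with
direction") without ambiguity about printed magnitudes. Group comparisons
use the Mann–Whitney test; lateralization uses the one-sample Wilcoxon
signed-rank test on per-rat log2(L/R) values, applied to the pooled
treatment groups only when no gene shows a significant group difference
in its asymmetry index (the pooling rule is configurable). Tie handling
follows `stats::wilcox.test`: exact enumeration for small untied samples,
mid-ranks with normal approximation and continuity correction otherwise.
All corrections are Bonferroni at an explicitly configured family size,
because the family is a design choice (e.g. 17 pituitary tests, 56
hypothalamus tests, 28/20 lateralization tests) rather than a property of
the data frame at hand.

Two asymmetry-index definitions circulate: the median over rats of the
per-rat log2(L/R), and log2 of the ratio of side medians. The per-rat
version is the default (it admits a per-rat test); the ratio-of-medians
version is also computed and reported alongside.

The left–right concordance analysis regresses right-side log2 fold
changes on left-side ones by ordinary least squares with an intercept;
the attenuation slope `a`, its standard 95% confidence interval, Pearson
and Spearman correlations, and a paired signed-rank test on |logFC|
quantify how much weaker and how consistent the contralateral response is.

## Left/right dominant co-expression networks

Genes are assigned per region to a left-dominant network (LdN, asymmetry
index > 0) or right-dominant network (RdN, AI < 0) under three
categorization variants: (1) median AI of the combined case + control
group, (2) median AI of the control group only, (3) mean AI of the
combined group. An AI of exactly zero leaves a gene unassigned rather
than arbitrarily labelled — possible with tied values, even though real
data essentially never hits it. A gene whose label disagrees across
variants "wobbles"; wobbling genes are retained per-variant (each
variant's analysis uses its own labels) rather than excluded, because
exclusion would make the three variants' pair sets inconsistent in a way
the stability flag already captures.

A *pattern* is a named set of gene-pair Spearman correlations: within one
module (the left- or right-side measurements of a region's genes), between
modules, or between CNS areas. Cross-module and cross-area pairs may
repeat a gene symbol — the two sides are distinct measurements. Patterns
are summarized by the coordination strength (mean |rho|) and the
proportion of strictly positive correlations; a rho of exactly zero counts
as non-positive. Pairs with an undefined correlation (a constant gene)
are dropped with a log entry.

Inference is by permutation. Four resampling schemes generate nulls:

1. **rat_ids** — rows permuted independently per measurement, destroying
   all co-expression; the null for "is this pattern's structure different
   from that pattern's" when the patterns involve different gene sets;
2. **treatment** — group labels permuted; always used for case-vs-control
   comparisons of a fixed pattern;
3. **module_within_rat** — each rat's left and right modules swapped by a
   fair coin; the natural exchangeable null for left-vs-right module
   comparisons (tasks 2, 5 and 7), valid whenever sides are exchangeable
   within rat under the null;
4. **area_within_module** — the two areas swapped within each rat and
   module, for inter-area exchange nulls.

The mapping of the seven comparison tasks to schemes is not uniquely
dictated; the defaults pair the module-exchange tasks (2, 5, 7) with
`module_within_rat` and the network-membership tasks (1, 3, 4, 6) with
`rat_ids`, and every task accepts an explicit `scheme` argument that is
recorded in the output. Two-sided p-values use the add-one estimator
(b + 1)/(R + 1), which cannot be zero at finite R. The reference
replicate count is 10^6; the package default is 10^4 and the test suite
uses 2000, with assertions sized to the corresponding Monte-Carlo error.
Benjamini–Hochberg correction is applied within pre-registered families —
separate families for strength and proportion, split by intra-area region
versus inter-area — and a comparison is *stringently* significant when
adjusted p ≤ .05 under all three categorization variants, or under two
while the third has raw p < .05 and adjusted p < .10.

## The synthetic study

The generator reproduces the statistical structure the analyses assume,
with defaults fixed at the study conditions: 12 injured and 11 sham rats;
a left-side lesion; a 12-gene panel split into two 6-gene networks with
lateralization offsets λ = ±0.8 log2 units; block-structured noise
correlation on the log scale (0.4 within networks, −0.2 between — fixture
choices, since inter-gene correlation magnitudes are not published);
injury effects of −0.8 log2 units on half of each network's genes, applied
fully on the ipsilesional side and attenuated by the factor 0.64 on the
contralateral side (the published attenuation estimate); six posture
replicates per rat around a 3 mm true asymmetry with 0.5 mm replicate SD
(consistent with 1 mm being the 94th percentile of uninjured animals);
and 100 Hz force ramps over 0–10 mm at 5 mm/s, linear with a 2 g/mm slope
from a 1 g baseline, the flexed (contralesional) limb scaled by 1.5, with
0.2 g additive noise. Expression noise is multiplicative log-normal
because every downstream statistic operates on log2 ratios. Each assay
draws from its own seeded stream derived from the master seed, so adding
one assay never perturbs another's draws.

What the generator does *not* emulate: outlier rats and heavy-tailed
measurement error (the robust models are therefore exercised mostly in
their Gaussian regime), missing-data patterns, batch or plate effects in
qPCR, nonlinear force–distance profiles, between-rat variability in the
true asymmetry, and any pharmacological dynamics. Passing tests therefore
demonstrate correctness of the estimators and calibration of the
inference under the assumed structure — not robustness to everything real
data can do.

## Test and verification sizes

The suite verifies each operation against an independent oracle: a
hand-coded tricube/bisquare local regression for the smoother (50 random
traces, 10^-6 RMS), fine-grid quadrature for the work integral,
brute-force rank-then-Pearson for the correlation matrices (100 random
6 × 10 tables, 10^-12), a hand-worked 4-gene × 6-sample example for the
geNorm M and V values (10^-10), exhaustive 2^5 enumeration for the
module-exchange permutation null on 5-rat instances, a 200-dataset null
simulation at R = 2000 for type-I calibration, and 100 seeded replications
at n = 200 for the 95% HPD coverage of the Student-t location model.
These sizes are the package's own verification design, chosen so each
check's Monte-Carlo error is small relative to the tolerance it asserts.

## Known limitations

* The Bayesian backend is JAGS; the reference analyses used a
  Hamiltonian-Monte-Carlo sampler. With the priors and settings above the
  posteriors agree to Monte-Carlo error, but individual table cells from
  the original tooling are not expected to reproduce digit-for-digit,
  and the multiplicity adjustment (max-|t| on posterior draws) is a
  Monte-Carlo analogue, not a reimplementation, of the multivariate-t
  adjustment of frequentist summaries.
* The XLSX import is schema-driven and expects tidy long-format sheets;
  it does not parse any particular workbook's bespoke cell layout.
* Pattern comparisons assume the same rats underlie every measurement of
  a pattern; designs with partially overlapping animal sets are not
  supported.
* The permutation engine is exact only under the exchangeability its
  scheme encodes; the `rat_ids` scheme tests "no structure at all", which
  is wider than "equal structure", and that conservatism is inherited by
  the tasks that use it.
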