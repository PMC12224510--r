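---
title: "Spatiotemporal ventilation biomarkers from 4D lung displacement fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal ventilation biomarkers from 4D lung displacement fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xvent)
```

## The measurement and the problem

X-ray velocimetry (XV) tracks the motion of lung tissue during quiet tidal
breathing and reconstructs it as a four-dimensional displacement field: at
every voxel of a lung-masked lattice, a 3-vector displacement relative to
end-exhalation, resolved over seven phase points of the inspiratory breath.
Because regional tissue motion is a surrogate of regional ventilation, the
spatial and temporal structure of this field carries information about
small-airways disease — disease that spirometry, a single global number,
is often blind to.

`xvent` implements the downstream analysis of such fields: deriving
physiologically interpretable scalar fields, condensing them into a fixed
catalogue of 154 per-subject biomarkers, searching low-dimensional
*composite* biomarkers that best separate a disease group from controls
under repeated cross-validation, and producing a scalar ventilation
heterogeneity score (the 4DH score) per subject. Since clinical XV
reconstructions are proprietary and no public datasets exist, the package
ships a seeded synthetic cohort generator that emulates the statistical
structure the analysis assumes; every claim the test suite makes is a claim
about these synthetic conditions, not about patients.

## The three derived fields

Let $u(x, p)$ be the displacement of the tissue at voxel $x$ at phase
$p \in \{0, \dots, 6\}$, with $u(x, 0) \equiv 0$.

**Expansion.** The local fractional volume change at a phase is the
finite-strain Jacobian determinant
$$ e(x, p) = \det\!\left(I + \nabla u(x, p)\right) - 1 . $$
We deliberately use the full determinant rather than its linearization
$\nabla \cdot u$: tidal deformations reach tens of percent of local volume,
where the divergence underestimates true volume change (a uniform 10%
linear dilatation has $e = 1.1^3 - 1 = 0.331$, while the divergence gives
0.300). Gradients are computed by central differences on interior voxels
and one-sided differences where a neighbour leaves the lung mask; voxels
whose entire stencil leaves the mask are dropped from the field's support.
Expansion biomarkers use the final phase (full inspiration) only.

**Flow.** The rate of expansion over a time interval $(p_1, p_2)$ is
$$ f(x) = \frac{e(x, p_2) - e(x, p_1)}{p_2 - p_1}, $$
with the phase step as the time unit — physical seconds-per-phase would
rescale every flow field by one constant and is irrelevant after the
per-fold standardization used in classification. Nine intervals are used:
the six consecutive phase steps, the two half-breaths (0–3, 3–6), and the
whole breath (0–6). This symmetric choice spans temporal scales from the
finest resolvable step to the whole inspiration.

**Oscillation.** Per voxel, form the increment series
$v_p = u(x, p{+}1) - u(x, p)$ and count direction reversals:
$$ o(x) = \frac{\#\{p : v_p \cdot v_{p+1} < 0\}}{n_\text{phases} - 2} \in [0, 1]. $$
Four variants are computed: raw displacement increments, velocity vectors
(increments per unit time), and the element-wise signed square
$v \mapsto v\,|v|$ of each, which preserves direction while emphasizing
large excursions. With the phase step normalized to 1 the velocity variants
coincide numerically with the displacement variants (a positive scalar
cannot change the sign of a dot product); they are kept as distinct
catalogue entries so the bank structure — and any future use of non-uniform
phase timing — is unchanged. The reversal-count definition was chosen as
the simplest index that is bounded, dimensionless, and invariant to uniform
rescaling of the displacements; alternatives (e.g. angular variance of
increments) exist, and this convention is declared rather than recovered
from any external definition of "oscillation".

## The biomarker bank

Each scalar field is summarized by eleven spatially resolved statistics:

| statistic | convention |
|---|---|
| mean, median, max, sum | ordinary |
| sd, iqr | sample sd; quartile difference (type-7 quantiles) |
| skewness, kurtosis | moment-based; kurtosis is excess; both 0 for constant fields |
| shannon_entropy | 64 equal bins over the field's own range, in bits; 0 for constant fields |
| pct_low, pct_high | % of voxels below/above reference cut-offs |

Seven of the eleven (mean, iqr, entropy, skewness, kurtosis, and the two
tail percentages) are fixed by the named biomarkers the analysis must
express; the remaining four (median, sd, max, sum) were chosen for
robustness and because the named markers "maximum flow heterogeneity" and
"sum of flow heterogeneity" force max- and dispersion-type entries to
exist. The tail cut-offs are anchored to the pooled voxel distribution of
the *control* subjects (10th and 90th percentiles per source field), so a
disease-driven shift of the field moves `pct_low`/`pct_high` away from
their control-reference value of about 10%. When no reference is supplied
the field's own percentiles are used.

Eleven statistics over 1 expansion field + 9 flow fields + 4 oscillation
variants give the catalogue:

```{r}
bank <- enumerate_bank()
table(bank$source)
nrow(bank)
```

Named biomarkers (`named_biomarker_map()`) resolve onto single catalogue
entries, except the flow "mean × interquartile range" marker, which is the
product of two entries. The "sum of flow heterogeneity" marker is mapped to
the whole-breath flow standard deviation — a dispersion reading of
"heterogeneity"; a sum-of-absolute-deviations reading would be monotonically
related on these fields and was not used.

## Composite search and the 4DH score

For a binary contrast (e.g. COPD-like vs control), every candidate subset
of up to four biomarkers is scored by the mean fold-level AUC of a logistic
decision boundary under stratified 3-fold cross-validation repeated 100
times, with subject order reshuffled (seeded) each repeat. Features are
standardized with training-fold means and standard deviations only. The
logistic fit carries a small ridge penalty ($\lambda = 10^{-4}$ on
standardized slopes, intercept unpenalized) so that perfectly separable
folds — common at these sample sizes — still yield finite weights; the fit
is an iteratively reweighted least squares kernel in C++ with a modest
iteration cap, which stabilizes the held-out *ranking* (all AUC needs)
long before the coefficients of a separable fit stop growing.

The candidate space for 154 biomarkers at dimension four is
$\sum_{r=1}^{4} \binom{154}{r} = 23{,}141{,}965$; `count_composites()`
reproduces this number exactly, and exhaustive evaluation is used whenever
the space fits the caller's budget (and in tests, where small banks make
exhaustive brute-force comparison possible). Above the budget a staged beam
search is used: all singletons are evaluated at the full 100 repeats, the
top `beam` subsets of each dimension are expanded by one feature, expansion
candidates are screened at a reduced repeat count (default 15), and the
surviving top candidates are re-evaluated ("confirmed") at the full repeat
count before ranking — reported AUCs therefore never rest on screening
runs. The default beam width is 25: wider beams multiply runtime linearly
while, on the synthetic cohorts the package targets, the recovered top
composites stop changing well below that width. Ties in the ranking break
toward smaller dimension, then lexicographic catalogue ids, making results
reproducible to the byte.

The selected composite is refit on all contrast subjects to give the 4DH
score — the linear predictor $w \cdot z + b$ on standardized biomarkers —
and an abnormality call against a threshold. The default threshold is the
Youden-optimal point of the full-data ROC; an externally chosen operating
point can be supplied instead. No nested cross-validation is performed: the
reported CV AUC quantifies robustness of a candidate, not an unbiased
estimate of out-of-sample performance, and the candidate space receives no
multiple-testing correction.

## The synthetic cohort generator

Each subject's field is
$$ u(x, p) = a \, c(x) \, g_p(x) \, (x - x_0) \;+\; \text{osc}(x, p) \;+\; \varepsilon, $$
a radial inflation from the lung centroid (uniform dilatation baseline,
$a = 0.1$ giving ~33% volume expansion at full inspiration) modulated by:

- a **compliance map** $c(x)$: 1 outside lesions, reduced by
  `compliance_contrast` inside spherical low-compliance blobs, and elevated
  by 50% in a random `emphysema_frac` of voxels (advanced-COPD analogue);
- an **inflation curve** $g_p(x)$: a logistic in phase index, normalized to
  run 0 → 1 over the breath, whose midpoint is delayed inside lesions by a
  per-lesion phase lag — lagged regions inflate later and trap gas
  (reach < 1 by end-inspiration);
- **oscillatory increments**: a random fraction of voxels receives
  alternating-sign radial increments of 0.25 voxels, creating genuine
  direction reversals;
- Gaussian voxel noise $\varepsilon$ (sd 0.02 voxels) at phases ≥ 1.

`severity` scales all pathological effects through per-subject, per-channel
log-normal severity realizations (sd 0.5 on the log scale, independently
for the compliance, lag and reversal channels), and a log-normal
between-subject spread (sd 0.12) multiplies the global amplitude. The
independent channels matter: they are what makes *composite* biomarkers
genuinely outperform singletons, because no single statistic sees all three
pathology axes. A zero-severity, zero-noise configuration reproduces the
deterministic control template exactly.

The frozen group defaults share the same effect magnitudes and differ
chiefly in severity — disease as a more severe version of baseline regional
heterogeneity — plus structural signatures: the GOLD 3–4 analogue adds an
emphysema channel (high-compliance voxels, giving the expansion field a
right tail), and the constrictive-bronchiolitis analogue has many small
lesions dominated by phase lag and reversals rather than compliance loss,
with preserved (control-like) simulated spirometry. FEV1 percent predicted
is drawn as $\max(25, 100 - 55\,\text{severity} + N(0, 8^2))$ for the COPD
groups and $N(95, 10^2)$ truncated at 60 for controls and the DR-CB
analogue; only the sign structure of these formulas (severity lowers FEV1;
DR-CB spirometry preserved) is meaningful.

What the generator does *not* emulate: airway-tree geometry, gravity-
dependent ventilation gradients, cardiac motion artefacts, reconstruction
noise correlated along projection angles, and inter-scanner variation.
Passing recovery tests on these cohorts therefore demonstrates that the
pipeline finds planted spatiotemporal structure at realistic effect sizes —
not that it would achieve the same AUCs on clinical data.

## Numerical choices and problem sizes

- Lattice 24³ with a spherical mask (radius `min(shape)/2 - 2`, ~4,200 lung
  voxels) is the default: large enough for stable spatial statistics, small
  enough that a 20 + 20 cohort simulates, derives and searches in well
  under a minute. The test suite uses 16³ for module tests and 24³ for the
  recovery experiments (ten cohorts of 20 + 20).
- Degenerate inputs: constant fields return 0 for all dispersion and shape
  statistics; zero-variance features are dropped (zeroed) inside CV folds;
  single-class folds are impossible under stratification and rejected
  otherwise.
- All randomness flows from explicit seeds: per-subject seeds derive from a
  master seed and a stable hash of (group, index); per-repeat CV shuffles
  derive from the CV seed. Reruns are byte-identical.
- Field I/O uses uncompressed double-precision NIfTI (one volume per phase
  plus mask and JSON sidecar), which round-trips bitwise.

## Known limitations

The oscillation index and the interval set are declared conventions; the
named-biomarker mapping onto catalogue entries involves two judgment calls
(the dispersion reading of "flow heterogeneity", and the whole-breath
interval as the source of named flow markers). The search is a beam
search above the exhaustive budget and can in principle miss composites
whose members are all individually uninformative. CV-AUC rankings of
millions of candidates on tens of subjects overfit by construction;
the package reports robustness spreads, not validated performance.
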