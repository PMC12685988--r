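---
title: "Compression mechanics of calcified nodules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression mechanics of calcified nodules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crushcurve)
```

## The measurement model

A uniaxial load-compression test of a calcified nodule records load $F$
(N) and crosshead displacement (mm) every 20 ms at 2.00 mm/min until the
measured load reaches 2000 N (`machine_spec()` holds these constants,
with accuracies of ±0.1 N and ±0.01 mm). Engineering stress and strain
are ill-defined for a crumbling, irregular specimen, so the analysis uses
a deliberately simple deforming-contact model:

* the nodule volume is conserved: $V_0 = A_0 H_0$, measured once from a
  frontal photograph ($A_0$, mm²) and calipers ($H_0$, mm);
* the current height is $H = H_0 (1-\varepsilon)$ with
  $\varepsilon = L / H_0$, $L$ the displacement past the origin;
* only a fraction $R_c$ of the volume-conserving cross-section
  $V_0 / H$ touches the platens: $R_c = \min(0.5 + \varepsilon, 1)$,
  i.e. one half at first contact, ramping linearly to full contact at
  half height. The clamp at 1 beyond half height is the continuous
  extension of the stated ramp;
* stress is $\sigma = F / A$ with $A = R_c V_0 / H = R_c A_0 /
  (1-\varepsilon)$.

The displacement origin is the first sample whose preload stress
$F / A_0$ exceeds 0.02 N/mm². At touch-down the instantaneous contact
area is unknowable, so the threshold is applied to the one measured
area, $A_0$. Samples at or beyond $\varepsilon = 0.95$ are discarded;
a strain reaching 1.0 earlier indicates inconsistent geometry and is an
error, not a warning.

Two numerical details matter here. Strain is forced non-decreasing with
a running maximum before any interpolation or integration: the platen
position cannot physically retreat, and displacement jitter is within
the stated machine accuracy; on noise-free data the running maximum is
the identity, so exactness results are unaffected. And the reader's
displacement-monotonicity check tolerates dips up to the machine
accuracy (0.01 mm) for the same reason — hard-failing on instrument
jitter would reject valid recordings.

## Stiffness parameters

* **Compression Strength** $\mathrm{CS}(s)$: the peak stress over
  $\varepsilon \in [0, s]$ — what the nodule can push back with up to
  that strain.
* **Compression Energy** $\mathrm{CE}(s)$: the trapezoidal integral of
  $\sigma$ over $[0, s]$. MPa × (dimensionless strain) is MJ/m³ =
  J/cm³ identically, so no unit conversion appears anywhere.

Both are evaluated on the **raw** origin-corrected curve, not the 0.05
grid: a peak between grid points is still a peak. The 0.05-strain grid
(linear interpolation between bracketing samples, grid truncated at the
last multiple below the achieved strain) exists for cohort tables and
classification only. The trapezoid rule is exact for the piecewise-linear
data model the sampled curve defines; if the first corrected sample sits
above strain zero, a sample at $(0, \sigma_\text{first})$ is prepended so
the integral starts at the origin. Levels beyond the achieved strain are
reported missing, never extrapolated — cohort tables simply end where the
data end.

## Crush-pattern classification

Foam-like three-phase crushing (elastic rise; serrated plateau as
microfractures relieve stress; densification of the fragment bed) is
distinguished from a smooth gradual stiffening by two criteria, either of
which labels a curve `three_phase`:

1. **Area ratio ≥ 0.7**: the area under the gridded curve over strains
   0–0.5, after subtracting the 0.02 N/mm² preload baseline (clipped at
   zero), divided by the rectangle of height (stress at 0.5 − baseline)
   and width 0.5. A plateau fills its rectangle (ratio → 1); a convex
   power law $\sigma \propto \varepsilon^2$ gives ≈ 1/3; a linear rise
   gives ≈ 1/2. Whether the numerator should be baseline-subtracted is
   genuinely ambiguous; subtracting it matches the rectangle's stated
   base and is the convention here.
2. **A negative slope** between consecutive 0.05-grid points inside
   [0.05, 0.5]. The grid, not the raw samples, is the natural smoothing
   scale: raw serration at the ±0.1 N accuracy would trigger on noise.
   Decreases within floating-point rounding of the interpolation
   (relative $10^{-9}$) are ignored.

Curves that never reach 0.5 strain (e.g. the machine limit tripped
early) are flagged unclassifiable rather than forced into a class.

## The synthetic-data generator

The generator exists so that every stage — file parsing, origin
detection, the stress transform, CS/CE, classification, cohort
statistics — can be tested against known ground truth. Its target stress
law $\sigma^*(\varepsilon)$ has two families:

* **three_phase**: an elastic ramp of slope `elastic_modulus` capped at
  `plateau_stress` (default 12 MPa/strain and 0.6 MPa; the default
  yield strain 0.05 is where serration may begin), a flat plateau, and
  beyond `densification_onset` (default 0.55) the upturn
  $\sigma = p\,[1 + k\,((\varepsilon - \text{onset}) / (0.95 -
  \varepsilon))^{q}]$ with exponent $q > 1$ and a fixed gain $k = 10$.
  The divergence as $\varepsilon \to 0.95$ mimics foam densification;
  the gain is calibrated once so a typical cohort's stress grows roughly
  nine-fold between strains 0.1 and 0.7, the growth the reference cohort
  exhibits. The plateau is exactly flat so that noise-free round trips
  recover it exactly.
* **gradual**: $\sigma = c\,\varepsilon^{q}$, the smooth convex
  minority pattern.

Stage-II serration is a Poisson process of multiplicative stress drops
(`drop_rate` per unit strain between yield and onset; each drop removes
`drop_depth_fraction` of the stress with exponential recovery over 0.01
strain). This reproduces the jagged plateau phenomenology without
claiming a fracture-physics model.

The forward transform inverts the analysis exactly: the recorded load is
$F = \sigma^*(\varepsilon)\, R_c A_0 / (1-\varepsilon)$ at machine
cadence, preceded by a preload ramp that rises to exactly the
0.02 N/mm² origin threshold and a contact sample at twice the threshold.
Because the ramp never strictly exceeds the threshold before the contact
sample, origin detection lands exactly on the generator's contact point
and the noise-free round trip recovers $\sigma^*$ to floating-point
precision for every strain after it (the contact sample itself carries
the preload pedestal). Gaussian noise is added at the accuracy scale
(load sd 0.1 N; displacement jitter sd 0.001 mm — kept below the stated
0.01 mm accuracy, which is a bound on reading error, not a per-sample
standard deviation). Truncation is applied to the *noisy* load, as a
real machine stops on its measured signal, so no recorded load ever
exceeds the limit.

### Cohort structure

`cohort_spec()` defaults encode the study conditions: 129 nodules, 118
three-phase (counts assigned exactly, not binomially), dialysis flags at
20/118 within three-phase and 7/11 within gradual (again exact), CT
density normal with median 937 HU and IQR [842, 1018], and low-strain
stiffness CS10 lognormal with median 0.38 MPa and IQR [0.23, 0.86] —
both scale parameters derived from the IQR via the normal quantile. CT
and log CS10 are coupled by a Gaussian copula at $\rho = 0.45$; since
both marginals are location–scale transforms of the latent normals, the
target Pearson correlation transfers exactly in expectation. Per-nodule
curve parameters are derived so the noise-free stress at strain 0.1
equals the drawn CS10 (elastic slope CS10/0.05, plateau CS10;
for gradual curves the power law is anchored the same way).

Geometry has no published distributional form; the projected area is
taken lognormal matching the published calcium-area quartiles
(23.67 [15.9, 35.22] mm²) and the height lognormal with median 3 mm and
log-sd 0.2 (nodules larger than 2 mm were tested). These are documented
assumptions, fixed once.

What the generator does **not** emulate: real nodules' heterogeneous
composition (interspersed fibrotic tissue), strain-rate and fixation
effects, correlated nodules within a patient (patient ids are assigned
but curves are drawn independently), and the full spread of the
published per-strain quartile table — the flat-plateau family
understates the gentle within-plateau hardening real curves show, so
cohort-level agreement is asserted only for the CS10 marginal, the
pattern counts and the CT correlation that the generator is explicitly
calibrated to. Passing tests therefore validate the *analysis*, and the
generator's calibration targets, not the full richness of specimen data.

## CT density

A phantom volume is background plus additive uniform ellipsoids plus
Gaussian noise. `make_mip()` takes the voxelwise maximum along one axis
restricted to a slab given in mm (15–20 mm is the convention; other
thicknesses warn). `mean_ct_number()` averages MIP pixels with value
≥ 600 HU (inclusive) whose centres fall inside the ROI polygon —
even–odd rule, 0-based pixel indices, pixel centre at its integer
coordinate. Interactive clinical tools leave rasterization unspecified;
one convention is fixed and documented here. An ROI with no qualifying
pixel yields a missing measurement, never zero. Matching ROIs to
physical nodules is a manual, procedural step: the mapping is an input.

## Cohort statistics

Quantiles use linear interpolation of order statistics (R's type 7,
configurable), pinned because summary values depend visibly on the
convention at n = 129. Dispersion rows (p75/p25, max/min) are quotients
of *unrounded* statistics; `format_quartile_table()` rounds afterwards —
ratios of pre-rounded cells are not reproducible and the two operations
are kept separable. Pearson correlations use the t-transform p value
with listwise deletion per parameter; group contrasts use the two-sided
Fisher exact test (binary outcomes) or the Mann–Whitney U test with
normal approximation and tie correction (continuous). No
multiple-testing correction is applied; p values are reported raw, as in
the source analyses, and should be read accordingly.

## Problem sizes and tolerances in the test suite

The suite exercises: exact round trips on single noise-free curves;
property checks (CS/CE monotone in level, CE(s) ≤ s·CS(s)) over 1000
randomly parameterised simulated recordings; quantile and Fisher engines
against exhaustive hand-coded oracles on all small cohorts (n ≤ 8) and
random 2×2 tables; the copula calibration at n = 2000 (±0.05 on r); and
the full pipeline on the default 129-nodule cohort. Numerical tolerances
are $10^{-12}$ for algebraic identities, $10^{-6}$ MPa for round trips,
and cohort-level sampling bands for stochastic calibration targets —
bands chosen from the sampling error of a median or correlation at
n = 129, not from observed outcomes.

## Known limitations

* Young's modulus is deliberately not estimated: with an assumed
  contact-ratio ramp, the low-strain slope is model-driven.
* Nodules from the same patient are treated as independent in all
  cohort statistics.
* The three-phase criteria are tentative screening rules, not a
  validated classifier; both thresholds are exposed in `run_config()`
  for sensitivity analysis.
* Stage I/II/III boundary estimation is out of scope — the stages are
  described qualitatively and no boundary criterion is defined.
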