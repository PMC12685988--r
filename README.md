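# crushcurve

Mechanical analysis of calcified aortic-valve nodules under uniaxial
compression.

In calcific aortic stenosis, mineralized nodules form on the valve
leaflets. When such a valve is treated by transcatheter replacement the
nodules are not removed but crushed against the annulus, so their
compressive mechanics — how much stress they exert back and how much work
it takes to deform them — matter clinically. `crushcurve` implements the
full analysis chain for ex vivo load-compression testing of resected
nodules:

1. **Recording → stress–strain.** A testing machine logs load *F* (N) and
   displacement (mm) on a fixed cadence. The displacement origin is the
   first sample whose preload stress exceeds 0.02 N/mm². Because a nodule
   deforms substantially, stress is computed with a volume-conserving,
   evolving contact area: with initial projected area *A₀*, height *H₀*,
   volume *V₀ = A₀·H₀* and current height *H = H₀(1 − ε)*,

   σ = F / A,  A = R_c · V₀ / H,  ε = L / H₀,

   where the contact ratio *R_c* ramps linearly from 0.5 at first touch to
   1.0 at half height (clamped beyond).

2. **Stiffness parameters.** Compression Strength CS(s) is the peak stress
   over strains [0, s]; Compression Energy CE(s) is the area under the
   stress–strain curve over [0, s] (MPa·strain = J/cm³, the crushing work
   per unit initial volume). Both are reported at 10–50 % strain.

3. **Crush-pattern classification.** Nodules are labelled `three_phase`
   (elastic rise, serrated plateau from repeated microfracture, then
   densification — foam-like crushing) when the baseline-subtracted area
   under the curve over 0–0.5 strain is ≥ 0.7 of its reference rectangle
   or a negative slope appears on the 0.05-strain grid between 0.05 and
   0.5; otherwise `gradual`.

4. **CT densitometry.** Mean CT number of each nodule from a 15–20 mm
   maximum-intensity-projection slab, averaging ROI pixels ≥ 600 HU.

5. **Cohort statistics.** Per-strain stress quartile tables with
   dispersion-ratio rows, CS/CE median/IQR summaries, Pearson correlation
   of stiffness with CT density, and Fisher/Mann–Whitney group contrasts.

A synthetic-data module generates machine-realistic crush-curve recordings
(20 ms sampling, 2.00 mm/min, 2000 N cut-off, ±0.1 N / ±0.01 mm accuracy)
and CT phantoms, so every downstream stage is testable without specimens.

## Worked example

```r
library(crushcurve)

coh <- simulate_cohort(cohort_spec(n_nodules = 5, seed = 42))
rec <- coh$recordings[[1]]
rec
#> <crush_recording> nodule N001, 4236 samples, max load 1993.59 N

curve <- to_stress_strain(rec, coh$nodules[1, ])
round(stiffness_profile(curve)[, -1], 3)
#>    CS10  CS20  CS30  CS40  CS50  CE10  CE20  CE30  CE40  CE50 max_strain
#> 1 1.523 1.523 1.523 1.523 1.523 0.112 0.256 0.403 0.548 0.696      0.772

classify_phase(resample_to_grid(curve))
#> # A tibble: 1 × 5
#>   nodule_id area_ratio negative_slope_found label       classifiable
#> 1 N001           0.928 TRUE                 three_phase TRUE
```

This nodule plateaus at ~1.5 MPa (so CS is flat across levels while CE
grows with strain) and shows the serrated-plateau signature: area ratio
0.93 ≥ 0.7 and grid-level stress drops, hence `three_phase`.

The whole pipeline on the default 129-nodule synthetic cohort:

```r
res <- run_pipeline(run_config(cohort = cohort_spec(seed = 1)))
glance(res)
#>   n_nodules n_three_phase n_gradual n_unclassifiable median_cs10 median_cs50
#> 1       129           118         9                2       0.401       0.419
```

118 of 129 curves are classified three-phase (the generator's default mix),
the cohort median CS10 sits at ~0.4 MPa, and two extreme gradual curves hit
the 2000 N machine limit before 0.5 strain and are flagged unclassifiable.
`tidy(res)` returns the per-nodule table; `plot_quartile_band()`,
`plot_stiffness_box()`, `plot_ct_scatter()` and `autoplot()` draw the
standard figures.

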