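# uvskin

Quantitative assessment of UV-induced skin change in a murine model, for
researchers using optical diagnostics of photoaging and acute photodamage.
The package implements, and validates on synthetic data with known ground
truth:

* **Fluorescence tissue-content indices.** From a laser-fluorescence
  emission spectrum, η = I_f / (I_f + I_bs): collagen read at λ_f = 450 nm
  (excitation 365 nm, backscatter maximum near 380 nm) and porphyrins at
  λ_f = 630 nm (excitation 535 nm), averaged over five skin sites.
* **Collagen degradation rate.** Pooled OLS of η_collagen = k·t + b over
  weeks, with 95% CIs, weekly Mann–Whitney group comparisons, and a
  slope-ratio criterion separating photoaging from chronoaging (the
  chronoaging rate is about half the photoaging rate).
* **MED dosimetry.** The stepwise escalation calendar (1 → 2 → 4 → 6
  MED/week, Mon/Wed/Fri sessions, 55 MED total at MED = 300 mJ/cm²) in
  exact rational arithmetic, plus dose/exposure-time conversions.
* **Erythema colorimetry.** White-balance correction against a neutral
  phantom, RGB → CIELAB, and the relative erythema index
  Δa\* = (a\*_AS − a\*_NS)/a\*_NS × 100 over 40×40-px ROIs, with Tukey HSD
  contrasts across days and doses.
* **Trichrome histomorphometry.** Collagen fraction and physical area in
  Masson's-trichrome sections by HSV colour-threshold filtering over a
  segmented specimen.
* **Synthetic-data generators** for all of the above: spectra with
  invertible target η, longitudinal cohorts with withdrawal and mortality,
  dorsum photographs with a controllable Δa\*, and trichrome phantoms with
  an exact collagen fraction.

See `vignettes/uv-skin-assessment.Rmd` for the models, assumptions and
design choices, and the numbered scripts under `analysis/` for the full
workflow.

## Worked example

```r
library(uvskin)

# dose calendar: 55 MED over the 12-week experiment
sched <- build_schedule(med_mj_cm2 = 300, total_weeks = 12)
cumulative_dose(sched)
#> $dose_med
#> [1] 55
#> $dose_mj_cm2
#> [1] 16500

# simulate the cohort and estimate degradation rates per group
co  <- simulate_cohort(cohort_config(seed = 20260925))
rep <- degradation_report(co)
rep$fits$photoaging
#> <degradation_fit> eta = 0.4221 -0.0059 * t  (n = 167)
#>   k: se 0.0003, 95% CI [-0.0066, -0.0053], p = 1.89e-41
#>   b: se 0.0020, 95% CI [0.4182, 0.4261], p = 1.52e-202
rep$ratio$ratio          # control slope / photoaging slope
#> [1] 0.622361
rep$ratio$photoaging_like
#> [1] "b"                 # the photoaging fit declines faster

# erythema: synthetic dorsum image with a 20% target index
ph  <- generate_dorsum_image(dorsum_config(erythema_delta_a_target = 20), seed = 3)
img <- white_balance_correct(ph$image, ph$rois$phantom)
per_animal_delta_a(rgb_to_lab(img), ph$rois$irradiated, ph$rois$intact)$delta_a
#> [1] 20.24725

# trichrome: recover a known collagen fraction
tp <- generate_trichrome_image(trichrome_config(true_collagen_fraction = 0.37), seed = 1)
quantify_trichrome(tp$image, pixel_size_um = 2)
#> <morphometry_result> collagen fraction 0.370 (17256 / 46656 px), area 0.0690 mm2
```

The fitted slopes above recover the generative lines (control k ≈ −0.003,
b ≈ 0.431; photoaging k ≈ −0.006, b ≈ 0.420). The slope ratio — here 0.62
for one simulated cohort, scattering around the generative 0.5 — is the
quantitative criterion that the irradiated group photoages about twice as
fast as the control chronoages; averaged over 200 replicate cohorts the
fitted coefficients reproduce the generative values to three decimals.

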