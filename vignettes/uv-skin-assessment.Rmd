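---
title: "Quantifying UV-induced skin change: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying UV-induced skin change: models, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvskin)
```

`uvskin` implements a quantitative pipeline for assessing ultraviolet skin
damage in a murine model, spanning two exposure regimes: chronic UVA
irradiation over 12 weeks (photoaging, monitored by laser fluorescence
spectroscopy and trichrome histomorphometry) and single high-dose UVB
exposure (acute erythema, monitored by RGB colorimetry). Because raw study
data of this kind are rarely deposited, the package pairs every analysis
with a synthetic-data generator carrying known ground truth, so each method
can be validated by parameter recovery. This vignette documents the models,
the tunable parameters, the numerical choices, and what the validation does
and does not demonstrate.

## The tissue-content index

Laser fluorescence spectroscopy excites skin at a laser wavelength
$\lambda_e$ and records an emission spectrum containing both fluorescence
and residual backscattered excitation light (the detection filter attenuates
backscatter roughly 1000-fold below its cut-on). The scale-free tissue
content index of a fluorophore is

$$\eta = \frac{I_f}{I_f + I_{bs}},$$

where $I_f$ is the intensity at the fluorophore's readout wavelength and
$I_{bs}$ the backscatter intensity. Channel conventions:

* **Collagen**: $\lambda_e = 365$ nm, readout at $\lambda_f = 450$ nm,
  $I_{bs}$ taken as the spectrum maximum near 380 nm where the filtered
  backscatter residue peaks. We search a window of 370–390 nm; the residue
  location is physically determined but its width is not, so ±10 nm is a
  package choice exposed as an argument.
* **Porphyrins**: $\lambda_e = 535$ nm, readout at $\lambda_f = 630$ nm (the
  main of the two characteristic porphyrin peaks at 630 and 710 nm). No
  convention exists for this channel's backscatter window; we default to
  525–545 nm, symmetric about the excitation line, and document rather than
  assert that choice.

$I_f$ is read at the grid point nearest $\lambda_f$ — not at a local maximum
— because the index is defined at a fixed wavelength; nearest-neighbour ties
break toward the lower wavelength. $\eta$ is invariant under rescaling of
the whole spectrum, lies in $[0,1]$, and is monotone in $I_f$; all three
properties are tested.

In vivo, each animal-week value is the mean of five measurement sites
(`average_over_sites()`).

### The spectrum generator

`generate_spectrum()` builds Gaussian emission peaks (450 nm, SD 20 nm for
collagen; 630 + 710 nm for porphyrins, the secondary peak at half amplitude)
plus a backscatter residue (Gaussian at 380 nm after a 370 nm cut-on with
1000× attenuation below it, or at 535 nm in the porphyrin channel). Given a
target $\eta$, the backscatter amplitude is solved by `uniroot()` under the
*same* readout rules the index functions use, so the noiseless round trip is
exact to $10^{-3}$ on a 1 nm grid. Because the fluorophore tail overlaps the
backscatter search window, the achievable index is bounded slightly below 1
(≈0.99 for collagen); targets beyond the bound error, and targets of exactly
0 or 1 emit degenerate pure spectra with a warning. Noise is additive
Gaussian truncated at zero — a simplification; real spectra carry
wavelength-dependent shot noise and baseline drift that the generator does
not emulate.

## Dosimetry

The chronic arm escalates the dose stepwise, three sessions per week
(Mon/Wed/Fri): 1/3 MED per session in week 1, 2/3 in week 2, sessions of
{1, 4/3, 5/3} MED in week 3, then 2 MED per session thereafter, with
MED = 300 mJ/cm². Session doses are stored internally as integer thirds of
a MED, so weekly and cumulative totals are exact rational arithmetic.

The week-by-week prescription yields the stated 55 MED total only if the
2 MED sessions run for 8 weeks after week 3; running them through week 12
gives 61 MED. `build_schedule()` defaults to `last_irradiation_week = 11`
(reproducing 55 MED over a 12-week experiment, the final week observation
only) and exposes the parameter so either calendar can be constructed. The
week-3 doses are assigned to Mon/Wed/Fri in ascending order; no ordering is
implied by the prescription, and totals are unaffected.

`exposure_time()` converts dose to seconds at a given irradiance
(e.g. 300 mJ/cm² at 4.5 mW/cm² → 66.7 s; 9450 mJ/cm² at 150 W/m² = 15
mW/cm² → 630 s).

## The cohort simulator and the degradation model

The collagen index declines approximately linearly over the experiment,
$\eta_{collagen}(t) = kt + b$ with $t$ in weeks, and the slope $k$ — the
collagen degradation rate — is the proposed criterion separating photoaging
from chronoaging: the control (chronoaging) rate is about half the
photoaging rate.

`simulate_cohort()` generates each animal as a latent line $b_i + k_g t$:

* Group lines default to the fitted study values — control
  $(b, k) = (0.431, -0.003)$, photoaging $(0.420, -0.006)$.
* $b_i \sim N(b_g, 0.01)$ (between-animal SD); each week, five site
  measurements with SD 0.02 are averaged into one animal-week value, clipped
  to $[0,1]$. The published tables report only SDs of measured indices, not
  a noise law; additive truncated Gaussian noise at these magnitudes is the
  package's modelling choice, and both SDs are configurable.
* Porphyrin values are drawn about weekly group means taken from the
  observed series (weeks 1–3 and 5–12); week 4, absent from that series, is
  interpolated as the mean of its neighbours and flagged as synthetic.
* Attrition: after the measurements of weeks 5, 10 and 12, three photoaging
  and one control animal are withdrawn for biopsy; each remaining animal
  then dies that week with per-group hazard $h$. The hazards (0.068
  photoaging, 0.080 control) were calibrated analytically so the *expected*
  counts remaining at week 10 match the study conditions being emulated
  (8 photoaging, 3 control). A single hazard
  cannot match both, which is why the parameter is per-group. Censored
  records are emitted with `NA` values and a status flag; nothing is
  imputed.

`fit_linear_degradation()` fits pooled OLS on animal-week means with
t-based 95% CIs. Pooling animal-level observations (rather than regressing
weekly group means) is the statistically honest default when the regression
unit is unstated; the alternative can be reproduced by aggregating before
fitting. `slope_ratio()` labels the steeper-declining group photoaging-like
only when both slopes' CIs exclude zero and the ratio leaves [2/3, 3/2] —
there is no published formal cut-off, so the bounds are configurable
arguments, chosen to be symmetric on the ratio scale around the reported
factor-of-two separation.

Two statistical caveats are deliberate:

* Weekly group comparisons use the two-sided Mann–Whitney test (exact when
  the combined n ≤ 20 and untied, normal approximation with tie and
  continuity correction otherwise) with **no multiple-testing correction**
  across weeks — weekly inference is deliberately marginal, matching how
  such monitoring data are conventionally read; the report exposes per-week
  p-values and leaves interpretation to the reader.
* The pooled-OLS interval assumes iid errors. Under the generator's
  random-intercept noise the per-animal intercept shifts cancel from the
  slope estimate, so the naive slope CI is *conservative* (its coverage
  exceeds 95%). The CI-coverage validation therefore runs with the
  between-animal SD set to zero, where the iid assumption holds and coverage
  is nominal; under default noise the intervals err on the wide side, which
  we consider acceptable for this design. A mixed-effects model would be
  tighter but is outside this package's scope.

## Erythema colorimetry

Acute UVB erythema is quantified from 8-bit RGB dorsum photographs. The
relative erythema index is

$$\Delta a^* = \frac{a^*_{AS} - a^*_{NS}}{a^*_{NS}} \times 100,$$

with $a^*_{AS}$ the mean CIELAB $a^*$ over a 40×40-pixel ROI of irradiated
skin and $a^*_{NS}$ that of intact skin on the non-irradiated right dorsum;
per animal, $\Delta a^*$ is averaged over four irradiated ROIs against the
same intact reference. The index is exactly linear in $a^*_{AS}$ at fixed
$a^*_{NS}$ and zero at equality, and is guarded by a conditioning floor
(default $|a^*_{NS}| \ge 0.5$) since it divides by the intact-skin value.

**Conversion dialect.** The camera protocol disables gamma correction, so
raw values are treated as *linear* RGB by default: normalise to [0,1], map
through the standard sRGB-primaries/D65 matrix to XYZ, then the standard
two-branch XYZ→L\*a\*b\* transform. Both the gamma handling
(`gamma = "linear"|"srgb"`) and the reference white (`white = "D65"|"D50"`)
are arguments, because the exact published conversion variant is not
reproducible from the protocol description; none of the pipeline's
validated quantities depend on the dialect (the $\Delta a^*$ identities and
synthetic round trips hold under both). The D65 white is implemented as the
exact row sums of the primaries matrix so every neutral gray maps to
$a^* = b^* = 0$ to machine precision.

**White balance.** A white phantom in the frame anchors manual white
balance: `white_balance_correct()` scales each channel so the phantom ROI's
channel means become equal, errors when the phantom is saturated (mean ≥
254, gains unidentifiable), and records the gains. The pipeline's measured
$\Delta a^*$ is invariant (±1 point) to applied channel gains once
corrected — tested as a round trip.

**ROI convention.** Rectangles are 0-based, half-open
$[x_0,x_1)\times[y_0,y_1)$, x along columns, stated once here and in every
ROI docstring to avoid off-by-one ambiguity.

The dorsum phantom paints the irradiated half's colour by shifting $a^*$ in
Lab space and converting back to RGB, so the generative target lives in the
measurement space. Pixel noise (SD 1.5 counts) dithers the 8-bit
quantisation; at zero noise the constant-colour rounding alone can shift the
measured index by up to ~2 points, which is why the ±2-point round-trip
tolerance is stated at default noise. The phantom does not emulate animal
pose, fur remnants, specular highlights or illumination gradients — passing
round trips validate the measurement chain, not robustness to those
real-world nuisances.

Group contrasts use one-way ANOVA + Tukey HSD on per-animal $\Delta a^*$:
across the three imaging days within each dose group, and across the three
dose groups within each day (five animals each).

## Trichrome histomorphometry

Collagen content in Masson's-trichrome sections is the aniline-blue-stained
area divided by the total specimen area. `segment_specimen()` separates
tissue from the bright slide background (mean-channel lightness < 0.9, then
largest connected component); `collagen_mask()` thresholds in HSV (default
hue 0.50–0.78 around aniline blue, saturation ≥ 0.25, value 0.10–0.95) and
drops components under 8 px. There are no standard numeric thresholds for
aniline blue; the defaults were fixed once against the synthetic phantom
and frozen. The denominator is the specimen
foreground, not the frame. Physical area requires a user-supplied pixel
size — never inferred from a magnification figure, which does not determine
µm/px.

The trichrome phantom realises fibers by thresholding an anisotropic
smoothed noise field (moving-average scales 21×5 px giving elongated
streaks) inside the tissue region; the threshold is bisected so that the
*despeckled* truth mask (fragments < 8 px removed) hits the target fraction
essentially exactly. Collagen pixels are coloured per-pixel inside the blue
HSV range; the rest of the tissue is pink with dark magenta nuclei kept
outside the threshold's hue window. Recovery across fractions
{0.1, 0.25, 0.5, 0.75} is within ±0.02 (in practice ±0.001). Real slides
add stain variability, overlapping hues, tears and uneven illumination that
the phantom does not model; the round trip validates the thresholding
arithmetic, not cross-slide robustness.

## Problem sizes and determinism

Validation sizes used by the test suite and analysis scripts — 200
replicate cohorts for parameter recovery, 2000 Monte-Carlo replicates for
the rank-test size, 300–500 for CI coverage, 256×256 phantom images — were
chosen so each check's Monte-Carlo error is well inside its tolerance while
the whole suite remains quick to run on a laptop. Every stochastic function
takes an explicit seed and is bit-reproducible given one; replicate r of a
recovery study uses `base_seed + r`.

## Interfaces

The package's surface is its functions plus the numbered driver scripts
under `analysis/`, which narrate the full workflow (dosimetry → cohort
simulation → degradation rates → spectral indices → erythema → trichrome)
and write tables under `results/`. Readers and writers cover the cohort CSV
schema, spectra CSVs with excitation metadata, JSON/CSV reports, and
lossless PNG images; JPEG inputs are rejected outright because chroma
subsampling corrupts the $a^*$ plane. No shell wrapper is provided: for an
analysis package of this shape, scripted drivers over documented functions
are the reproducible interface.

## Known limitations

* The linear degradation model is a local approximation over 12 weeks; it
  is not meant to extrapolate.
* Pooled OLS ignores within-animal correlation (conservative for the slope
  under random intercepts, as discussed above).
* The porphyrin-channel backscatter window and the colour-conversion
  dialect are conventions, stated and configurable, not reproductions of
  the original instrument/software internals.
* All validation is against synthetic data whose generative assumptions are
  listed here; agreement demonstrates correct implementation and estimator
  behaviour under those assumptions, not field performance on real animals.
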