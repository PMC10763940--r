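---
title: "Methods: image-based colorimetric calibration for Cr(VI)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based colorimetric calibration for Cr(VI)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromocal)
```

## The measurement model

The assay oxidizes 3,3',5,5'-tetramethylbenzidine (TMB) with H2O2 in the
presence of hexavalent chromium; the blue oxidation product absorbs at
650 nm, so on an RGB scan of the reaction plate the *red* channel darkens
in proportion to the Cr(VI) concentration. chromocal models the response of
a well as a straight line in concentration,

$$ Y = m\,X + c + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2), $$

where $X$ is the Cr(VI) concentration in ppb and $Y$ is either the mean
red-channel intensity of the well ROI (the "UIIS index", 0-255 scale) or
the absorbance at 650 nm when the data come from a spectrophotometer. The
line is estimated by ordinary least squares (`fit_calibration()`, a wrapper
around `stats::lm`), with the classical closed-form standard errors and

$$ \bar R^2 = 1 - (1 - R^2)\,\frac{n-1}{n-2}. $$

Assumptions worth stating: the response is linear over the validated range
only (25-600 ppb for the imager); replicate wells are exchangeable and
enter the fit as individual points rather than per-concentration means, so
$n$ counts wells and the standard errors keep their textbook meaning;
errors are homoscedastic across the range. Weighted or nonlinear (4PL)
calibration is deliberately out of scope.

Concentration is recovered by inverting the line,
$\hat X = (Y - c)/m$ (`predict_concentration()`). A raw inverse outside the
validated range is reported as non-detectable (`N.D.`) rather than as an
extrapolated number. The interval is treated as **closed at both ends**:
the range endpoints are themselves calibrated concentrations, so a sample
landing exactly on 25 or 600 ppb is reportable; one ulp beyond is not.
Replicate wells of one sample are averaged **on the response scale** before
a single inversion, the usual practice for a linear calibration.

## Detection limits

`detection_limits()` computes $\mathrm{LOD} = 3.3\,\sigma/|m|$ and
$\mathrm{LOQ} = 10\,\sigma/|m|$, so LOQ/LOD is exactly $10/3.3$ whenever
both use the same $\sigma$. Three choices of $\sigma$ are offered:

* `slope_se` (default) - the standard error of the slope. With the
  imager's published uncertainties (slope $-0.06134 \pm 0.00222$) this is
  the only mode that yields the reported 0.12 / 0.36 ppb pair, which is
  why it is the default.
* `intercept_se` - the standard error of the intercept, the common ICH
  reading of "standard deviation of the response".
* `residual_sd` - the residual standard deviation of the fit.

The three can differ by an order of magnitude; the mode is stored in the
persisted model JSON so a archived calibration is unambiguous. Values are
reported rounded to 2 decimals with the raw values retained.

## The three selection procedures

**Channel selection** (`select_channel()`). Each candidate response - R,
the composite R+G+B, G, B - is fitted against concentration and the
channel with the highest adjusted $R^2$ wins. Exact ties break to the
fixed order R, R+G+B, G, B, i.e. toward the channel the chemistry predicts.
The composite is included because it inherits the red signal diluted by two
noisy flat channels, and ranks between R and G/B on well-behaved data.

**Reading-time selection** (`select_reading_time()`). For each time point
of a kinetics run the response is fitted against concentration. Times with
$|m_t| < 0.25\,\max_t |m_t|$ (the `slope_floor_frac` parameter) are
discarded as undeveloped - this encodes the observation that before the
colour has formed the concentration patterns are flat. Among the remaining
times the *earliest* one attaining the maximal adjusted $R^2$ is chosen, so
the assay reads as soon as, but not before, the signal has developed. If
every time is flat (zero response span up to numerical tolerance) the
function stops and advises a longer incubation.

**Reagent saturation** (`saturation_dose()`). Dose-response points are
first monotone-smoothed by isotonic regression (`stats::isoreg`) - the
physically expected shape for a substrate-limited chromogenic reaction -
and the optimum is the smallest dose whose smoothed response is within
`plateau_tol` (default 5%, relative) of the maximum smoothed response.
Monotonicity makes the qualifying set a suffix of the dose grid, so every
dose above the optimum automatically qualifies too. If only the top dose
qualifies the curve is still rising; the result is then flagged
`not_saturated` and the top dose returned with a warning. The 5% default is
a package choice: it is tight enough to separate the knee of a Hill-shaped
curve from its rising flank at the dose grids used here, and loose enough
that absorbance noise of a few 1e-4 AU cannot promote a flank point. A
coarse dose grid can allow a strictly linear but steeply rising curve to
qualify as "saturated"; with the grids used here (15 and 10 doses) it does
not.

## Well localization and feature extraction

Wells are located by a deterministic template grid: plate scanners hold
the plate in a fixed fixture, so the centre of well A1, the 9 mm pitch and
the well radius (supplied in pixels in the `plate_layout`) define all 96
positions without blob detection. The ROI is a central disk of
`roi_fraction` (default 0.6) of the well radius, avoiding the meniscus
shadow and wall shading; the statistic is the arithmetic mean per channel
(median available for robustness to specks). `composite_rgb` is defined as
the exact sum of the three per-channel statistics.

An optional refinement (`refine = TRUE`) searches integer offsets within
±3 px for the position minimizing the luminance variance inside a disk of
the *full* well radius - a well-centred disk sees uniform liquid, while an
off-centre one mixes in background across the well wall. The search uses
the full radius deliberately: an interior disk never crosses the wall, so
small offsets would be invisible to it. The refinement is off by default
because the template is exact for fixtured scanners.

Images are held in memory as numeric arrays on the 0-255 scale and are
quantized to 8 bits per channel only when written to PNG/TIFF, so
synthetic plates can carry exact fractional well means; a file round trip
is accurate to one intensity unit.

## What the synthetic generator emulates

`generator_config()` defaults describe the study conditions this package
is tested under:

* red-channel truth: slope $-0.06134$ R-units/ppb, intercept $100.49757$;
  G and B nearly flat (slopes $-0.003$ and $-0.0015$; intercepts 160 and
  190) with larger noise, so channel selection is exercised realistically
  and the adjusted-$R^2$ ranking R > R+G+B > G > B emerges;
* concentration series 1, 25, 50, 75, 100, 200, 400, 600, 800, 1000 ppb;
* between-well noise SD 0.5 R-units and per-pixel noise SD 2.0;
* kinetics: a Hill-shaped development fraction reaching 0.95 at
  $t^\* = 15$ min. The Hill exponent defaults to 12 so that the 10-minute
  fraction is ≈ 0.13 - i.e. the pre-saturation readings are genuinely
  flat, which is the observed behaviour of the chemistry (negligible
  visible colour before 15 minutes) and what makes the slope-floor rule
  meaningful;
* reagent presets: Hill ($h = 2$) dose-response curves for TMB
  (0.1-1.5 mM, absorbance within 0.0047-0.0685 AU, $k = 0.25$ mM) and
  H2O2 (10-300 mM, within 0.0243-0.1523 AU, $k = 10$ mM), parameterized so
  the 5%-plateau rule lands on 0.9 mM and 50 mM respectively;
* plate geometry: standard 96-well dimensions (9 mm pitch, A1 centre at
  14.38/11.24 mm) rendered at a configurable dpi, default 150 - well below
  a production 600 dpi scan but with hundreds of pixels per ROI, which is
  what the mean statistic consumes.

Every generator sets the seed from the config, so outputs are bit-for-bit
reproducible. The generator does **not** emulate vignetting, specular
highlights, bubbles, dust, chromatic aberration, or plate misplacement
larger than a few pixels; passing tests therefore demonstrate correctness
of the pipeline's arithmetic and selection logic under idealized optics,
not robustness to real scanner artefacts.

## Validation metrics

Spike recovery is $100\,\hat X/X_{\text{spiked}}$ percent with recovery
error $\mathrm{RE} = 100 - \text{recovery}$, an exact identity maintained
at full precision. Method comparison excludes pairs where either
instrument reports N.D., computes the per-pair error fraction
$|x_{\text{test}} - x_{\text{ref}}|/x_{\text{ref}}$, and reports Pearson's
$r$ both over all included pairs and over the concordant subset (error
fraction ≤ `outlier_tol`, default 0.5) - field samples can disagree
grossly on a few samples, and a single discordant pair dominates $r$ at
these sample sizes, so both views are given rather than asserting one.
The bundled 27-sample river survey ships with the package
(`survey_samples()`); its error column holds fractions (0.068 = 6.8%), and
that is how the column is labelled here. One of its reported recovery rows
(250 ppb: recovery 100.0324 alongside RE −0.3024) is internally
inconsistent with the identity; the identity is treated as authoritative
and that row is excluded from identity checks. Ion selectivity is reported
as blank-subtracted signal ratios against Cr(VI), flagged above
`interference_tol` (default 0.1).

## Numerical choices and degenerate inputs

* Fits require ≥ 3 points and ≥ 2 distinct concentrations; identical
  concentrations have no slope and raise an error.
* A zero calibration slope cannot be inverted and cannot produce
  detection limits; both raise errors.
* `sigma = 0` yields LOD = LOQ = 0 (a noise-free instrument), not an
  error.
* Concentrations are stored at full precision; printing and CSV reports
  round ppb to 3 decimals and detection limits to 2, matching the
  precision conventions of assay reporting.
* Ties: channel selection breaks to the fixed order above;
  reading-time selection takes the earliest time at the maximal adjusted
  $R^2$.
* The generator refuses configurations whose channel means leave
  [0, 255], naming the offending concentration, rather than silently
  clipping truth.

## Problem sizes in the test suite

The suite simulates at sizes a workstation fits comfortably: plates are
rendered at 30-60 dpi (ROIs of tens to hundreds of pixels - the mean of a
few hundred pixels already estimates a well mean to ~0.1 intensity units),
tabular calibration studies use 500 wells per run with 200 replicate runs,
and the OLS-versus-oracle property runs 1000 random instances. The
acceptance checks of the pixels-to-ppb loop use one fully rendered plate
of 96 wells at 60 dpi with the default noise model.

## Known limitations

* Only straight-line calibration is supported; curvature outside the
  validated range is handled by refusing to report, not by modelling it.
* Inverse-prediction confidence intervals are not computed.
* The template grid assumes the plate is square to the scan axes;
  rotation is not modelled or corrected.
* Colour management (gamma, white balance, ICC profiles) is intentionally
  absent: the calibration is defined on raw scanner RGB, so calibration
  and samples must come from the same imaging pipeline.
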