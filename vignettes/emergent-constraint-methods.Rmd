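---
title: "Methods: constraining high-latitude GPP projections with greening sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraining high-latitude GPP projections with greening sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenec)
```

## The scientific problem

Fully coupled carbon-cycle models disagree strongly on how much
northern-high-latitude (NHL, 60–90°N) gross primary production (GPP) rises
when atmospheric CO2 doubles: ensemble spreads are of the same order as the
ensemble mean. An emergent constraint exploits the fact that the models'
divergent projections co-vary with a quantity that is also observable over
the historical period — here, the sensitivity of annual maximum leaf area
index (LAI~max~) to the common driver of high-latitude plant growth. The
satellite greening record then acts as a filter on the ensemble: models
whose historical greening sensitivity is far from the observed one carry
little weight in the constrained projection.

This vignette records the modelling choices, parameter meanings and
numerical details; the README shows the pipeline in action.

## The proxy driver ω

Warming and CO2 fertilization both drive NHL greening, and because CO2's
radiative effect drives the warming, annual CO2 concentration and growing
degree days above 0 °C (GDD0) are nearly collinear. A regression on either
alone would mis-attribute shared signal; a regression on both would be
ill-conditioned. We therefore avoid factor separation entirely and regress
on the leading principal component of the two standardized drivers:

* each series is centred and scaled by its **population** (divisor-*n*)
  standard deviation;
* the 2×2 covariance matrix **C** = **XᵀX**/*n* is eigendecomposed;
* ω = **X u₁** is the projection of maximal shared variance.

Conventions worth stating explicitly:

* **Divisor.** The divisor-*n* convention is used for standardization, the
  covariance, and var(ω) = λ₁, so the two eigenvalues sum to exactly 2 and
  the identities hold to 1e-9 in the tests. The regression's σ_x (below)
  uses the same convention by default, with an `sd_divisor = "n-1"` switch.
* **Sign.** An eigenvector's sign is arbitrary; `driver_pca()` orients
  **u₁** so the CO2 loading is positive. "Sensitivity to ω" then always
  means the response to *rising* CO2 and warmth, which is what makes
  sensitivities comparable across datasets. Without this convention the
  cross-ensemble scatter could mix signs member by member.
* **Degeneracy.** If the two drivers are exactly uncorrelated the
  covariance is isotropic (λ₁ = λ₂ = 1) and no leading direction exists;
  `driver_pca()` raises an error rather than returning an arbitrary axis.
  In practice NHL CO2/GDD0 correlations are far from zero.
* **Per-dataset PCA.** ω is computed separately for the observations and
  for every ensemble member from its own simulated drivers, mirroring how
  each model's internal climate drives its own greening.

## Field reductions

Gridded inputs are reduced before any regression:

* bi-monthly LAI composites are averaged within calendar months (a month
  with no composites stays missing — never zero);
* the NHL scalar is the cosine-of-latitude weighted mean over the closed
  band [60°, 90°], cell membership by cell centre; masked cells are dropped
  and weights renormalized, so a uniform field is reproduced exactly under
  any mask;
* LAI~max~ is the annual maximum of the monthly series, accepted only when
  at least 6 months (configurable) are present — the annual maximum is
  robust to polar-night gaps but not to a nearly empty year;
* GDD0 = Σ days~m~ · T~m~ · 1[T~m~ > 0], requiring all 12 months (a
  missing winter month could silently truncate the growing season).
  Days-in-month follow the dataset's calendar: Gregorian for observations,
  `"365_day"`/`"360_day"` for model output.

Regression windows default to 1982–2016 for observations and 1971–2005 for
model series (both configurable), maximizing record overlap and sample
size at 35 years each.

## The sensitivity regression and its error model

`fit_greening()` fits y = a + bx by least squares with the residual scale

s² = Σ(y − f)²/(N − 2),

the slope error σ_b = s/(σ_x√N), and the corresponding intercept error.
With the divisor-*n* σ_x this reproduces the textbook OLS standard error
exactly (σ_x√N = √Σ(x − x̄)²), which the tests confirm against `lm()`; the
divisor-(n−1) option shrinks σ_b by √((N−1)/N). The error model assumes
i.i.d. Gaussian residuals — adequate for interannual LAI noise, though real
records have some autocorrelation (see Limitations).

## Greening/browning classification

Pixel-level trends in summer (June–August) mean LAI are classified with the
two-sided Mann–Kendall test at p < 0.1. The variance of Kendall's S uses
the standard tie correction, with a continuity correction in the normal
approximation. For series shorter than 10 years without ties the exact
null distribution of S is evaluated (by convolution of the inversion-count
distribution), so tiny-series behaviour is exact; with ties at such lengths
the tie-corrected normal approximation is used. Pixels with fewer than 10
usable years, or whose series never exceeds a configurable LAI floor
(default 0: only bare/all-missing pixels), are labelled barren — the floor
is exposed because what counts as "vegetated" sparse tundra is a mask
decision, not a statistical one.

## The emergent constraint

**Ensemble fit.** ΔGPP at 2×CO2 is regressed on historical sensitivity by
*unweighted* OLS across members, with Pearson r and its t-based p-value.
Per-member sensitivity standard errors are carried for display but not used
as weights — the emergent relationship treats members as exchangeable; a
weighted fit would let a single over-confident member dominate. (A weighted
variant can be built from the returned pieces, but is deliberately not the
default.)

**Bootstrap contours.** The ensemble is tiny (7 members in the reference
configuration), so line uncertainty comes from resampling members with
replacement (resample size = ensemble size). Resamples with fewer than two
distinct x values cannot define a line and are redrawn. Fitting continues
past a minimum of 100 resamples until the median line — the line whose
slope and intercept are the medians over resamples — changes by less than
1% in both parameters from one count to the next, with a hard cap of
10,000. The 68% confidence contour half-width σ_f(x) is half the
16th–84th percentile spread of bootstrap-line predictions at each x:
a pointwise central-68% band, matching the "contours of equal
probability" role σ_f plays in the conditional density below. All
resampling is driven by a single integer seed; the same seed reproduces
the contours bit for bit.

**The constrained PDF.** With the observation PDF
P(x) = N(b′, σ_b²) and the conditional P(y|x) = N(f(x), σ_f(x)²),
the constrained projection is

P(y) = ∫ P(y|x) P(x) dx.

(The emergent-constraint literature occasionally typesets the integrand
with the conditioning reversed; the product-of-densities construction
implemented here is the one the standard derivation defines.) The integral
uses trapezoidal quadrature on a 2001-point x-grid spanning b′ ± 5σ_b,
with the y-grid spanning the predicted range ± 5·max σ_f at 2001 points
(all three configurable). At these defaults the truncation error of a
Gaussian at 5σ (~6e-7) is far below the 1e-4 acceptance band on the raw
posterior integral; if that band is exceeded the grids are refined once
(doubled span and density) before erroring. The posterior is then
renormalized on its grid (integral 1 within 1e-6) and summarized by its
gridded mean and standard deviation. A zero-σ_b observation is handled as
the delta-function limit: P(y) = N(f(b′), σ_f(b′)²).

The unconstrained reference is the Gaussian with the unweighted
multi-model mean and the ensemble (sample, divisor n−1) standard
deviation.

**Validation.** The gridded posterior is checked against an independent
Monte-Carlo sampler (draw x from P(x), then y|x) at 10⁶ draws across a
parameter sweep, at Kolmogorov distance < 0.01; the linear-f/constant-σ_f
case is checked against the closed-form convolution
sd = √(σ_f² + slope²σ_b²); bootstrap bands are checked for nominal
coverage over 500 synthetic ensembles; and 200 end-to-end replicates check
that the posterior mean brackets the known truth within 2 posterior sd at
the expected rate while always being sharper than the ensemble Gaussian.

## GPP → NPP scaling

ΔF~NPP~ = b · (Δ[CO2]/[CO2]~pi~) · ΔF~GPP~, with the standard GPP-to-NPP
conversion factor b = 0.5 (10% relative uncertainty), [CO2]~pi~ = 284 ppm,
and relative uncertainties combined in quadrature. Δ[CO2] over the
comparison period is a configuration input: the default 60.5 ppm is the
increase in the NOAA global annual mean from 1980 (≈338.9 ppm) to 2015
(≈399.4 ppm), the era covered by the long atmospheric-inversion records
against which NPP changes are compared. Users comparing against other
windows should set `scaling$dco2` accordingly.

## CO2 seasonal-cycle diagnostics

**Detrended seasonal cycle.** The long-term trend is removed with a
centred 2×12-month running mean (weights ½, 1, …, 1, ½ over 13 points),
which passes a linear trend through exactly and annihilates any pure
12-month periodic up to its mean; residual anomalies are averaged by
calendar month over an epoch (≥ 4 years, ≤ 20% missing months).

**Drawdown slope.** The statistic is the annual minimum of the
month-to-month first difference (one-sided forward differences, assigned
to the left month — the simplest estimator consistent with ppm month⁻¹
units; a centred difference would smear the minimum across two months).
No detrending is needed: constants vanish in differencing and a linear
trend adds the same constant monthly increment to every difference (the
tests verify raw-vs-detrended equality to 1e-9). Yearly minima are
smoothed with a 2-year moving window (mean of the year and its
predecessor; the first year keeps its single value), and the change over a
record is mean(last 5 years) − mean(first 5 years), with the two 5-year
standard deviations combined in quadrature as the uncertainty. Gaps of up
to 2 consecutive months are linearly interpolated; a year touched by a
longer gap is dropped, and a window with more than 10% missing months is
rejected. If the derivative minimum does not fall in a consistent summer
season the function warns and proceeds on the global minimum.

The seasonal-cycle *amplitude* is provided only as a convenience
diagnostic (`cycle_amplitude()`): the annual maximum is contaminated by
wintertime respiration variability, which is why the drawdown slope is the
preferred GPP proxy.

## What the synthetic generators emulate — and what they do not

`sim_ensemble()` reproduces the statistical structure of the
ensemble-constraint setting: seven members by default, latent sensitivities
uniform on 0.022–0.075 m² m⁻² per unit ω (uniform, not Gaussian, to mimic
an ensemble spread across its range rather than clustered), a true
emergent line (default: ΔGPP = 0.7 + 60·sensitivity Pg C yr⁻¹, placing the
constrained estimate near 3.4 Pg C yr⁻¹ for an observation at 0.045) with
Gaussian residual sd 0.25 Pg C yr⁻¹, per-member 35-year driver series
(smooth CO2 ramp; GDD0 ramp with 25 degree-day interannual variability),
LAI noise sd 0.05 m² m⁻², and a pseudo-observation with true sensitivity
0.045. All noise is white Gaussian; there is no autocorrelation, no
nonlinearity in the emergent mapping, and no structural model error —
passing tests therefore demonstrate the *statistical machinery* is
correct, not that real ensembles satisfy its assumptions.

`sim_station()` generates baseline + trend·t + A(t)·sin(2π(month −
phase)/12) + noise with linearly deepening amplitude A(t). Defaults
(baseline 330 ppm, trend 1.7 ppm yr⁻¹, amplitude 8 ppm, deepening
0.045 ppm yr⁻¹, noise 0.2 ppm, 1974–2005) give a drawdown-slope change
around −0.7 ppm month⁻¹ over 30 years, the order observed at Arctic
stations. The phase default (12) puts the steepest monthly decline in
June–July, where high-latitude drawdown actually occurs; an integer phase
aligned differently would make two monthly differences exactly tie at the
minimum, a degenerate configuration that inflates noise-selection effects.
The truth record exposes the analytic drawdown change obtained by exact
differencing of the noiseless generator. Real records differ in having
synoptic autocorrelated variability, non-sinusoidal (sawtooth-like)
cycles, and drift in the phase itself; none of these are emulated.

`sim_temperature()` provides latitude-graded sinusoidal climatology with
an optional linear warming, chosen so GDD0 has closed-form values (3650
degree-days for a constant 10 °C 365-day year; trend 365·τ under uniform
warming τ with all months above freezing) against which the reduction
chain is tested.

Problem sizes in the test-suite replicate studies (500 bootstrap-coverage
ensembles, 200 end-to-end replicates, 40 drawdown replicates, 10⁶
Monte-Carlo draws) were chosen to make the statistical acceptance bands
sharp relative to the quantities checked.

## Known limitations

* The error model assumes i.i.d. residuals; autocorrelated LAI or CO2
  noise would make σ_b anti-conservative.
* The bootstrap percentile band at n = 7 is known to under-cover slightly;
  the coverage test asserts the 58–78% band around the nominal 68%.
* The constraint assumes the emergent relationship is linear with
  x-independent conditional shape; curvature in the true mapping would
  bias the posterior mean.
* The drawdown-change estimator's minimum-selection step has a small
  noise-dependent bias that largely cancels between record ends; its
  residual is well below the statistic's own sampling uncertainty.
* NetCDF handling targets CF monthly lat/lon/time layouts; rotated-pole or
  curvilinear grids are out of scope, as is any regridding beyond band
  masking.
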