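# greenec

Emergent constraints on northern-high-latitude (NHL, 60–90°N) gross primary
production (GPP) from the observed sensitivity of vegetation greening to a
combined CO2/warming driver — for carbon-cycle scientists who want to narrow
divergent multi-model projections with the satellite greening record, and for
anyone who needs the supporting diagnostics (growing degree days, driver PCA,
Mann–Kendall greening maps, CO2 seasonal-cycle drawdown statistics) as tested,
composable R functions.

## The method

Earth-system models disagree widely on how much NHL photosynthesis increases
when atmospheric CO2 doubles. But across an ensemble, the projected GPP
enhancement ΔGPP at 2×CO2 varies almost linearly with a quantity each model
also simulates for the *historical* period: the sensitivity of annual maximum
leaf area index (LAI_max) to the dominant driver of high-latitude plant
growth. That emergent relationship, anchored by the *observed* historical
sensitivity, constrains the projection.

The pipeline:

1. **Proxy driver ω.** Annual CO2 concentration and growing degree days above
   0 °C (GDD0 = Σ months days × monthly-mean T, T > 0 °C) are nearly collinear
   in the NHL. Each series is standardized (divisor *n*), the 2×2 covariance
   **C** = **XᵀX**/n is eigendecomposed, and ω = **X u₁** — the first
   principal component — is the common driver. ω is oriented so rising CO2
   means rising ω.
2. **Greening sensitivity.** LAI_max is regressed on ω: *f* = *a* + *b*ω,
   with residual variance *s*² = Σ(y−f)²/(N−2) and slope standard error
   σ_b = *s*/(σ_x√N). The best-fit slope *b′* is the sensitivity
   (m² m⁻² per unit ω), computed the same way for observations and for every
   ensemble member from its own simulated drivers.
3. **Emergent constraint.** Across members, ΔGPP at 2×CO2 is regressed on
   historical sensitivity (unweighted OLS). Bootstrap resampling of the
   members (resamples the size of the ensemble, continued past *m* = 100
   until the median line stabilizes to <1%) yields 68% confidence contours
   σ_f(x) — half the 16–84 percentile spread of the bootstrap lines at each
   x. With the observation PDF P(x) = N(b′, σ_b²) and the conditional
   P(y|x) = N(f(x), σ_f(x)²), the constrained projection is
   P(y) = ∫ P(y|x) P(x) dx, evaluated by trapezoidal quadrature.
4. **NPP scaling.** ΔF_NPP = b · (Δ[CO2]/[CO2]_pi) · ΔF_GPP with b = 0.5
   (±10%) and [CO2]_pi = 284 ppm, for comparison with atmospheric-inversion
   net-flux trends.
5. **Independent diagnostic.** At high-latitude stations the summertime CO2
   drawdown slope — the annual minimum of the month-to-month first
   difference — deepens as GPP grows. `drawdown_change()` computes its change
   over a record (2-year smoothing, difference of first and last 5-year
   means) without any detrending.

Every stage runs on synthetic data with known ground truth
(`sim_ensemble()`, `sim_station()`, `sim_temperature()`), so the whole
chain is validated end to end without any downloads.

## Worked example

```r
library(greenec)

run <- run_pipeline(list(seed = 7, station = list()))
print(run)
#> Emergent-constraint pipeline run
#>   ensemble: n = 7 members, mean 3.2 +/- 1.28 Pg C yr-1
#>   emergent fit: r = 0.984 (p = 6.1e-05), bootstrap m = 100
#>   observation: 0.04985 +/- 0.00633
#>   constrained Delta-GPP: 3.41 +/- 0.322 Pg C yr-1
#>   NPP enhancement: 0.363 +/- 0.05 Pg C yr-1
#>   drawdown change: -0.638 +/- 0.212 ppm/month
#>   provenance: seed 7, config ee548a4d
```

A seven-member synthetic ensemble (historical sensitivities spanning
0.022–0.075 m² m⁻² per unit ω) projects 3.2 ± 1.28 Pg C yr⁻¹ as the
unweighted ensemble mean; the emergent relationship (r = 0.98) combined with
a synthetic observation of 0.050 ± 0.006 narrows this to **3.41 ± 0.32
Pg C yr⁻¹** — the constrained estimate is both shifted and roughly four times
sharper than the raw ensemble spread. Scaled by the CO2 rise over the
inversion era, that corresponds to an NPP enhancement of 0.36 ± 0.05
Pg C yr⁻¹.

The pieces compose individually:

```r
fit <- fit_greening(tibble::tibble(x = 0:2, y = c(0, 1, 3)))
tidy(fit)
#> # A tibble: 2 × 3
#>   term      estimate std.error
#> 1 intercept   -0.167     0.373
#> 2 slope        1.5       0.289

rec <- read_noaa_monthly(system.file("extdata", "co2_station_synthetic.txt",
                                     package = "greenec"))
drawdown_change(rec)
#> CO2 drawdown-slope change 1974-2005: -0.521 +/- 0.152 ppm/month

gpp_to_npp(3.4, 0.2, dco2 = 60.5)
#> # A tibble: 1 × 2
#>    dnpp dnpp_sd
#> 1 0.362  0.0420
```

`autoplot()` methods draw the standard figures: the ensemble scatter with
its bootstrap band (`autoplot(run$relation)`), the constrained versus
ensemble PDFs (`autoplot(run$posterior, ensemble = run$ensemble)`), and the
yearly drawdown slopes (`autoplot(run$drawdown)`).

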