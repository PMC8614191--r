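# thermosens

Multi-scale environmental drivers of stream thermal sensitivity around
summer extreme events.

## The problem

Stream water temperature (WT) rises with air temperature, and short
extreme thermal events are especially harmful to cold-water species.
Managers who want to damp those events need to know *which* environmental
factors control a stream's thermal response and *at what spatial scale*
they act — the whole catchment, a 1–2 km neighbourhood, or a 50 m
riparian corridor.

`thermosens` implements that analysis end to end for users working with
daily monitoring data (or with no data at all, via its synthetic-study
generator):

1. **Thermal dynamics.** Around each extreme date, a 15-day window of the
   day maximum WT is fitted to
   `dT_w/dt = [a (T_aM − T_w) + b (T_am − T_w)] / Q + c`,
   giving per site × event the day thermal sensitivity `a`, night thermal
   sensitivity `b` and non-convective flux `c`.  The fit is an OLS
   regression of the daily forward difference on the two convective
   regressors; `thermal_model()` returns a classed object with `print`,
   `summary`, `coef`, `predict`, `residuals`, `simulate`, `plot` methods.
2. **Landscape metrics.** Fifteen environmental variables — median
   solar-incidence shade on the water surface (hillshading with cast
   shadows), reach-length-weighted sinuosity, eight land-cover
   percentages, watershed area, channel slope, elevation, water level and
   the smoothed-minima baseflow index — at six nested spatial scales
   (`CA`, `buff_1`, `buff_2`, `ripa`, `buff_1_ripa`, `buff_2_ripa`).
3. **Scale-wise regressions.** Per response and scale, stepwise-AIC
   multiple linear regression on the standardized predictors, reported as
   an 18-row matrix of estimates, significance stars and adjusted R².
4. **Synthetic study.** `sim_config()` / `simulate_study()` generate a
   full seeded study — river network, terrain, land cover, climate with
   scheduled heat waves, discharge, water temperature — whose true
   `(a, b, c)` are known linear functions of the computed landscape
   covariates, so every stage above is testable with exact ground truth.

## Worked example

A small synthetic study (20 sites, 2 years, 3 summer heat waves), run end
to end:

```r
library(thermosens)

hw  <- data.frame(date = as.Date(c("2014-07-10", "2014-08-05", "2015-07-20")),
                  amplitude = 8, duration = 5)
cfg <- sim_config(n_sites = 20, n_years = 2, start_year = 2014,
                  heat_wave_schedule = hw, catchment_km2 = c(1, 2),
                  cellsize = 25, seed = 42)
res <- run_pipeline(cfg)

# one site x event fit
w <- extract_window(res$study$series[["W001"]], hw$date[1])
thermal_model(w)
#> Thermal-dynamics fit (derivative), site W001, event 2014-07-10
#>   a (day sensitivity)     2.4685
#>   b (night sensitivity)   1.3872
#>   c (non-convective)      0.3003 degC/day
#>   n = 14 daily steps, RSS = 0.5061, window R2 = 0.976
```

`a = 2.47` means this site's WT chases the day maximum air temperature
strongly (convective gain 2.47/Q per day); the window R² of 0.98 says the
three-parameter model explains nearly all day-to-day WT change around
this event.

```r
res$models[["a.CA"]]
#> Stepwise-AIC MLR: a ~ . (scale CA, n = 20)
#>   SHADE      -0.301***  (p = 7.85e-05)
#>   ...
#>   AREA        0.541***  (p = 3.64e-08)
#>   LEVEL       0.249***  (p = 0.000159)
#>   ...
#>   Adj. R2 = 97.5%, AIC = -25.24, 5 step(s)
```

The generator planted `a = 2.0 + 0.4·AREA + 0.3·LEVEL − 0.3·SHADE`
(standardized covariates) plus noise; the selection recovers the planted
drivers with the right signs and magnitudes — shaded streams are less
thermally sensitive, larger/deeper ones more so.  `res$report` holds the
full 3-response × 6-scale matrix with blank cells for unselected
predictors.

A shell entry point for the same stages (simulate, detect-extremes,
fit-thermal, landscape, regress, all) lives at
`inst/cli/thermosens.R`:

```sh
Rscript inst/cli/thermosens.R all --n-sites 20 --n-years 2 --seed 42 --out-dir out/
```

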