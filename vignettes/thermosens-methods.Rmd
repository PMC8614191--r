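---
title: "Methods: stream thermal sensitivity and its multi-scale environmental drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stream thermal sensitivity and its multi-scale environmental drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Stream water temperature (WT) rises with climate change, and short *extreme
thermal events* — days on which WT leaves its seasonal range — are
particularly damaging to cold-water ectotherms.  River managers want to know
which environmental factors damp the response of WT to such events, and at
which spatial scale those factors act, because that determines where (and
how widely) restoration measures such as riparian planting pay off.

`thermosens` implements that analysis as a tested pipeline with three
stages, plus a synthetic-study generator with known ground truth so every
stage is verifiable without any external data.

## The thermal-dynamics model

Around each extreme date the evolution of the day maximum WT, $T_w$, is
described by a daily first-order model driven by air temperature and
streamflow:

$$\frac{dT_w}{dt} \;=\; \frac{a\,(T_{aM}-T_w) \;+\; b\,(T_{am}-T_w)}{Q} \;+\; c,$$

where $T_{aM}$ and $T_{am}$ are the day maximum and minimum air
temperatures, $Q$ is streamflow, $a$ is the **day thermal sensitivity**
(response of WT to daytime convective forcing), $b$ the **night thermal
sensitivity**, and $c$ a **non-convective flux** term (°C day⁻¹) absorbing
processes such as advection that are not explicitly modelled.  Dividing by
$Q$ encodes thermal inertia: the same convective forcing moves a large
river less than a small one.

The model is fitted independently to each site × extreme-event window of
15 days (7 days on each side of the event date).

**Discretisation.**  We use the daily forward difference with regressors
evaluated at day $t$:
$$\Delta T_w[t] \;=\; a\,x_1[t] + b\,x_2[t] + c, \qquad
x_1[t] = \frac{T_{aM}[t]-T_w[t]}{Q[t]},\;
x_2[t] = \frac{T_{am}[t]-T_w[t]}{Q[t]},$$
estimated by OLS on the 14 daily steps of a window.  The synthetic
generator steps the same forward-Euler scheme, so in the noise-free limit
the estimator inverts the generator exactly (the tests verify recovery to
below $10^{-9}$).  A trajectory-matching mode (`mode = "trajectory"`,
least squares on the forward-integrated trajectory) is provided because it
is the other defensible reading of a continuous-time model statement;
derivative matching is the default because it is exact, fast and convex.
A window with any missing day is refused rather than imputed: with 14
observations and 3 parameters there is no room for imputation artefacts.
Sensitivities are not sign-constrained; negative estimates are returned
and flagged.

The per-window fit is exposed in the classic R modelling idiom:
`thermal_model()` returns a classed object with `print`, `summary`,
`coef`, `predict` (forward-integrated trajectory), `residuals`,
`simulate` and `plot` methods.

**Stability.**  The explicit daily step is contractive only while
$(a+b)/Q \le 2$; the generator validates this and rejects configurations
beyond it instead of silently blowing up.

## Extreme dates and seasons

The event dates of the original monitoring campaign are identified
regionally from WT anomalies.  The package ships the printed list of the
17 regional summer dates (2012–2018) via `summer_extreme_dates()` and also
implements a documented detector, since the upstream procedure is not
fully specified:

1. per site, a *seasonal baseline* — a cyclic penalized regression spline
   on day-of-year (mgcv, GCV smoothing) — yields daily anomalies;
2. a date qualifies when the anomaly exceeds the site's $q$-quantile
   (default $q = 0.97$) **and** an absolute floor of 4 °C at a minimum
   fraction of sites (default 0.5); the floor prevents ordinary synoptic
   noise, or the numerically tiny residuals of a clean seasonal cycle,
   from qualifying;
3. runs of consecutive qualifying days collapse to their peak day, since
   regional events are catalogued as single dates.

Seasons follow the meteorological convention (summer = June–August).  An
externally supplied event list always bypasses detection.  The default
operating point was chosen so that, under the generator's default
conditions, the detector recovers exactly the injected summer waves; on
real data the detected dates are approximate and bypass mode is the
recommended route.

## The fifteen environmental variables and six spatial scales

For each site the package computes SHADE, SINUO, eight land-cover
percentages (AGRI, ARTI, BROAD, HERBA, FORESTS, NEEDLE, OTHER, WATER),
AREA, SLOP, LEVEL, ELEV and BFI, at six nested footprints: the upstream
catchment (`CA`), its intersections with 1 km and 2 km discs around the
site (`buff_1`, `buff_2`), a 50 m-per-side riparian corridor along the
upstream network (`ripa`), and the corridor clipped to the discs
(`buff_1_ripa`, `buff_2_ripa`).  Footprints are boolean rasters (zonal
statistics by mask) rather than exact polygon overlays; the resolution is
configurable and the mask invariants (`ripa ⊆ CA`, `buff_1 ⊆ buff_2`,
`buff_k_ripa = ripa ∩ buff_k`) are enforced by construction and tested
against analytic areas.

* **BFI** — baseflow index by the smoothed-minima separation: 5-day block
  minima; an interior minimum $m_i$ is a turning point when
  $0.9\,m_i \le m_{i-1}$ and $0.9\,m_i \le m_{i+1}$; the baseflow line
  interpolates linearly between turning points (first and last block
  minima anchor the ends), is capped at the observed flow, and BFI is the
  ratio of baseflow to total flow volume over the covered days.  BFI ∈
  [0, 1] and is invariant to rescaling the flow; the tests pin it to a
  hand-executed worked example.
* **SHADE** — solar-incidence hillshading of the surface model at solar
  noon of each event date: declination from the Spencer day-of-year
  expansion, noon elevation $90° - \text{latitude} + \delta$, azimuth
  180°; per cell, the angle between the Horn finite-difference surface
  normal and the sun direction, clamped to [0, 90] (90 = in shadow), with
  an optional (default on) ray-march toward the sun marking cast shadows.
  Shade is evaluated on the water surface only: mapped corridors whose
  width grows with drainage area above 50 km², a fixed 2 m line buffer for
  reaches between 1 and 50 km² (at coarse working resolutions the
  generator widens this to half a cell so the channel line is resolved),
  and nothing below 1 km².  The median over water cells in the footprint
  is taken per event date and averaged over the summer dates.
* **SINUO** — per-reach channel length over the straight distance between
  reach endpoints ("mean axis" read as the straight chord, the simplest
  defensible interpretation), aggregated as the reach-length-weighted mean
  over upstream reaches intersecting the footprint.
* **SLOP** — elevation drop over about 4 km of channel upstream of the
  site (truncated with a warning when less channel exists), in percent.
* **AREA, ELEV, LEVEL, BFI** — station-scale quantities, replicated across
  the six scales, matching the published variables table; SHADE and SINUO
  are computed on the watercourse and are therefore identical within the
  CA/ripa, buff_1/buff_1_ripa and buff_2/buff_2_ripa pairs.

## The regression stage

Per spatial scale, the 15 predictors are standardized to zero mean and
unit variance and each response ($a$, $b$, $c$; site-level summer means)
is regressed by **bidirectional stepwise-AIC** selection: start from the
full model, take the single add-or-drop move with the lowest Gaussian AIC
($k = 2$), stop when no move lowers it, refit the endpoint by OLS.  Ties
break on the fixed variables-table order.  Two numerical guards matter:

* the eight cover percentages sum to 100, so the literal full model is
  singular; the start set is the maximal non-aliased subset (QR pivoting),
  which is what a rank-reduced full fit effectively uses;
* the RSS entering the AIC is floored at $10^{-12}$ of the TSS so exact
  fits compare by the parameter penalty rather than by floating-point
  noise in $\log(\mathrm{RSS})$.

The direction and starting point of the original stepwise procedure are
not documented; full-model bidirectional stepping is the convention of the
workflow the study cites, and the tests show the endpoint coincides with
exhaustive best-subset AIC on orthogonal designs and with `stats::step`
on generic ones.  p-values of the final OLS fit are reported with the
conventional star codes (`***` ≤ 0.001, `**` ≤ 0.01, `*` ≤ 0.05, `#` ≤
0.1) and are deliberately not multiplicity-adjusted, matching the original
convention of a per-coefficient 0.05 threshold.  Model quality is the
adjusted R², reported in percent, in an 18-row (3 responses × 6 scales)
report matrix.  Missing rows are dropped listwise per model with a logged
count.

## The synthetic study and what it does (not) show

`sim_config()` defaults describe the emulated study conditions: 92 sites
observed daily over 2012–2018 at latitude 50° N, with the 17 printed
regional summer dates injected as 8 °C, 5-day triangular heat waves.
Choices a field scientist would recognise, made once:

* **Climate** — seasonal sinusoid (mean 10 °C, amplitude 9 °C, peak late
  July) plus regional AR(1) noise (marginal sd 1.5 °C, lag-1 0.7) shared
  across sites, small per-site noise (0.3 °C), and a stochastic positive
  diurnal range (mean 8 °C) so `ta_min ≤ ta_max` holds by construction.
  Scheduled waves *replace* the free-running synoptic anomaly of their
  days (triangular cross-fade) rather than stacking on it, and storm
  arrivals are suppressed around wave dates (heat waves are dry
  anticyclonic spells); both choices make the injected events observable
  in the water series, which is what defines an extreme event in the
  first place.
* **Hydrology** — constant per-site baseflow (3–8 flow units) plus
  exponentially-recessing storm pulses on shared storm days; the
  `quickflow_share` dial moves the computed BFI monotonically, and
  `level = k Q^{0.4}` stands in for the stage rating (any monotone map
  suffices, since level enters the analysis only as a covariate).
* **Geometry** — one dendritic stem per catchment on disjoint rectangular
  tiles (20 m cells; catchments 2–8 km², a scaled-down version of the
  real size range chosen to keep the default run in tens of seconds),
  sinusoidal meanders whose amplitude dial controls sinuosity, a constant
  along-valley gradient per catchment (0.5–3 %), and drainage areas that
  equal the summed cell area of the catchment masks exactly.
* **Canopy and shade** — a riparian gallery on the west bank whose
  surface-model height is `tree_height × density` (a partly vegetated
  cell's photogrammetric surface rises by its fractional cover).  The
  single-bank layout keeps the canopy-induced tilt of the water cells
  one-signed so the median shade responds monotonically to the density
  dial; symmetric banks cancel each other's Horn gradient at coarse
  cells.
* **Ground truth** — the true $(a, b, c)$ of each site are linear
  functions of its *computed* standardized CA-scale covariates
  (`default_coefficient_truth()`: area, level and shade drive $a$; BFI,
  open cover and sinuosity drive $b$; $c$ is small and weakly linked)
  plus site-level noise, then water temperature is generated forward with
  0.2 °C observation noise.  With all noise at zero the full pipeline —
  generator → fit → landscape → regression — returns the planted slopes
  with adjusted R² of 100 %, which is the package's strongest end-to-end
  correctness check.

What passing tests on this world do **not** show: realism of
rainfall-runoff dynamics, hyporheic processes, sub-daily dynamics, LiDAR
canopy structure, or the actual Walloon covariate distributions.  The
synthetic study validates the *computations*, not the ecological
conclusions.

## Numerical choices and degenerate inputs

Windows with missing days, series with date gaps, non-positive discharge,
rank-deficient fit designs, constant columns under standardization,
unmapped land-cover codes, polar latitudes, and closed-loop reaches all
raise named errors rather than producing silent zeros.  Batch fitting
logs and skips per-pair failures without aborting.  Raster borders use
edge-clamped Horn differences; footprints with no water cells yield a
missing SHADE with a warning and the row survives to the listwise stage.

## Problem sizes

The test suite exercises the full 92-site default study once (about a
minute) and otherwise uses 2–20-site configurations; the acceptance
script regenerates the default study, the 1,564 window fits, the
552-row landscape table, the 18 stepwise models and a 100-replicate
support-recovery experiment from a single seed.

## Known limitations

* The extreme-date detector is a documented stand-in for the original
  (unpublished) GAM-based procedure; on real data, supply the event list.
* "Mean axis" sinuosity uses the straight chord between reach endpoints;
  a smoothed valley axis would give slightly different values for long,
  strongly curved reaches.
* Whether the original shade maps included cast shadows is unknown; both
  modes are available (`cast_shadows`), default on, because vegetation
  shading of water physically requires occlusion.
* The station LEVEL and the model variables are aggregated over summer
  events by the mean; the source analysis states the mean explicitly only
  for shade and level, and the same rule is applied to $a$, $b$, $c$ for
  symmetry.
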