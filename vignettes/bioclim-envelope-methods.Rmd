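---
title: "Bioclimatic envelopes under climate change: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioclimatic envelopes under climate change: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioclimenv)
```

`bioclimenv` chains four models: a deterministic index layer (the
Rivas-Martínez bioclimatic classification), a statistical layer (robust
linear trends per station-month), a geostatistical layer (station-to-grid
interpolation) and a rectilinear niche model (the climate envelope with
Boolean map algebra). This vignette explains each layer's assumptions,
the tunable parameters that matter, and the choices made where the
design was genuinely open.

## The index layer

All indices are functions of a 12-month climatology (monthly mean
temperature in °C, monthly precipitation totals in mm). The annual
parameters are `Tavg` (mean of the 12 monthly means), `Pavg` (annual
precipitation sum), and the *positive* sums `Tp = 10 Σ{Tᵢ : Tᵢ > 0}`
(tenths of °C) and `Pp = Σ{Pᵢ : Tᵢ > 0}`; months at or below 0 °C
contribute to neither. Continentality is `Ic = Tmax − Tmin` over monthly
means; thermicity is `It = 10 (Tavg + 2 Tmin)`, and the compensated form
adds a piecewise-linear correction `Itc = It + C(Ic)` that is zero on
`Ic ∈ [9, 18]` (both boundaries included), `−10·(9 − Ic)` on the
hyperoceanic side, and accumulates `+5, +10, +20, +30` units per degree
above the knots 18, 21, 28 and 46. The annual ombrothermic index is
`Io = 10 Pp / Tp`; the summer indices `Ios1–Ios4` are `ΣP / ΣT` over the
warmest summer month, the two hottest summer months, the summer quarter,
and the quarter plus its preceding month.

Open points decided here:

* **Summer quarter.** Defined as the warmest three *consecutive*
  calendar months of the climatology (ties broken toward the earliest
  window), which generalises to both hemispheres; a fixed calendar
  summer (Jun–Aug / Dec–Feb) is available via `summer_mode = "fixed"`.
  The two hottest months within the quarter are chosen by temperature,
  ties by calendar order.
* **`Tp = 0`.** A climate with no month above freezing has no defined
  ombrothermic ratio; `Io` (and any `Ios` whose window's temperature sum
  is not positive) becomes `NA`, which the envelope layer treats as
  absence — such cells can never be suitable. This is a marker, not an
  error: the vector as a whole is still produced.
* **Arithmetic.** All index arithmetic is double precision; rounding to
  one decimal happens only in report renderers.

## The qualitative diagnosis

The macrobioclimate test is the classification's summer-drought rule:
Mediterranean iff two consecutive summer-quarter months each satisfy
`P < 2T`. The prose of the rule admits a second reading — the *average*
of the two hottest months satisfying `P < 2T` — and both are
implemented (`rule = "two-hottest-mean"`); the consecutive-months form
is the default because it is the stricter, month-resolved reading. Only
the Mediterranean/Temperate distinction is diagnosed; tropical climates
are out of scope.

Thermotype, ombrotype, continentality and bioclimate bands ship as an
editable CSV (`inst/extdata/rm_thresholds.csv`) with values from the
worldwide classification; the tables are validated on load (contiguous,
disjoint, ordered intervals). Conventions: intervals are lower-closed
and upper-open everywhere, so a value exactly on a boundary belongs to
the upper interval; each class splits into horizons at its arithmetic
midpoint, with thermotype horizons named so that "lower" is the warmer
half (matching field usage, where *lower mesomediterranean* is the hot
end); values outside a table's span yield an explicit `<beyond-table>`
marker rather than silence. The thermotype is assigned from `Itc`,
falling back to `Tp` when `Itc` is below the thermicity scale's floor
(the lower end of the Itc table, 150 Mediterranean / 100 Temperate) —
at high elevations thermicity loses discrimination and the positive
temperature scale takes over. The submediterranean variant is flagged
for Temperate diagnoses with `Ios3 < 2.0`, a configurable cut chosen to
represent a summer-dry tendency inside an otherwise temperate regime.

## The trend layer

Each station contributes 24 yearly series (12 calendar months × two
variables). Five estimators of `value = a + b·year` are fitted:
ordinary least squares, Theil–Sen (median of all pairwise slopes),
Siegel repeated medians (median over points of each point's median
pairwise slope; breakdown point near 50 %), a Huber M-estimator
(tuning constant 1.345 scale units), and an MM-estimator
(high-breakdown S-initialisation followed by a bisquare M-step; its
internal subsampling runs under a fixed seed so fits are reproducible).
Theil–Sen and Siegel intercepts are `median(y − b·x)`. When the data
lie exactly on a line every estimator returns that line; M/MM fits that
fail to converge fall back to least squares with a warning.

**Model selection** defaults to the *median absolute residual*, not the
root-mean-square residual. The RMSE criterion is degenerate for this
ensemble: least squares minimises the in-sample RMSE among linear fits
by construction, so under RMSE the "selection" can only ever return
OLS and the robust estimators would be dead code. The median absolute
residual scores fits by how well they describe the bulk of years,
letting robust fits win exactly when gross outliers distort the least
squares line; `criterion = "rmse"` remains available. Ties (within
1e-12) resolve in the declared order
`ols, theil_sen, siegel, m_estimator, mm_estimator`.

Projection evaluates each month's selected fit at the target year;
projected precipitation is floored at 0 mm, temperature is not clamped.
Future indices are recomputed from the projected monthly climatology,
never trended directly — this preserves inter-index identities such as
`Ic = Tmax − Tmin` that independent extrapolation would break.

## Surfaces

Station index values are interpolated to a grid by inverse-distance
weighting (power 2, exact at stations within the snap distance) or
ordinary kriging. Kriging fits a variogram to the pairwise cloud —
`linear` (default), `power` (`b·hᵃ`, exponent fitted in (0, 2) on the
log-log cloud) or `spherical` — solves one kriging system per layer,
and is exact at the data points (zero nugget by default). The power
family is there because smooth, trend-dominated fields such as index
surfaces have semivariances growing faster than linearly, and ordinary
kriging weights are invariant to a linear variogram's slope, so only
the model's *shape* can adapt; with the power model a noiseless linear
field is reproduced to a fraction of a percent of its range. Any
failure in the variogram fit or the kriging solve falls back to IDW
with a warning. Geometry: lon/lat (or any planar tag), cell-centre
registration, half-open cells, row 1 at the north; sampling is
nearest-cell with `NA` outside the grid. On disk, rasters are
plain-text ESRI ASCII grids, a format every GIS reads.

Limitations: interpolation is purely two-dimensional — elevation enters
the suitability analysis as its own layer, not as an interpolation
covariate — so index surfaces between sparse mountain stations are
smoother than the real fields; statements about individual high-relief
cells inherit that smoothing.

## The envelope model

A species' envelope is fitted from the variable values at its
occurrence points: per variable the minimum, first and third quartile
and maximum, quantiles by linear interpolation of order statistics
(`stats::quantile` type 7, pinned in `quantile_type`), plus the set of
soil orders observed at occurrences. At least four complete points are
required; rows with missing values are dropped with a warning.
*Suitable* cells satisfy every `[min, max]` interval (CON bounds
inclusive at both ends, missing cells are absence); *optimal* cells
satisfy every `[Q1, Q3]`, hence optimal ⊆ suitable always. The
conjunction across all variables — the 13 indices, elevation, and soil
membership when a soil layer is supplied — follows from applying the
CON operator per variable and multiplying the masks. Change maps code
each cell `never/gain/unstable/stable` from the (current, future)
binary pair, and percentages are reported relative to the *current*
area: stable% + unstable% = 100 by construction, and gain% may in
principle exceed 100. Whole-domain denominators would be the obvious
alternative; current-area denominators are used because they answer
the conservation question "how much of where the species now lives
survives".

`Ios1` is computed but excluded from the default envelope variable set:
the single-month ratio is the noisiest of the four summer indices and
adds no constraint beyond `Ios2` in practice; it can be included by
passing `vars` explicitly.

## The synthetic scenario

`scenario_config()` fixes the study conditions: a 40-year (1980–2019)
monthly record over a coastal-ridge landscape on a lon/lat grid, with a
−6.5 °C/km lapse rate, a latitudinal cooling gradient (−0.7 °C per
degree north), a July-peaking seasonal cycle whose amplitude grows
inland (+12 % per degree east of the coast, so continentality rises
away from the sea), winter-peaked precipitation (amplitude 0.9, drier
inland, wetter with elevation), independent Gaussian noise
(0.5 °C / 8 mm by default), optional linear trends, gross-outlier
contamination (±8 °C, +150 mm) and missingness masks. Soils are
elevation bands, as real soil catenas broadly are. The generator
asserts its own promise that low-elevation cells are Mediterranean
under the `P < 2T` rule. Everything is a deterministic function of
`(seed, config)`.

What it deliberately does not emulate: temporal autocorrelation (the
in-scope trend models are linear, so noise is independent across months
and years; an autocorrelated option was considered and left out to keep
the trend-recovery oracle transparent), spatially correlated noise
fields, non-Gaussian precipitation (noise is truncated at zero instead),
and circulation-driven change patterns. Passing tests therefore
demonstrate correctness of the machinery and recoverability of known
signals, not skill on real archives.

Problem sizes used by the test-suite and the acceptance script — chosen
as the smallest networks at which every stage is well conditioned —
are 15–200 stations on 20×20 to 30×30 grids over 30–40 years, with
100–200 replicate series for estimator checks; a `scenario_statewide()`
preset (177 stations, 80×90 cells) is provided for larger
demonstrations.

## Known limitations

* The geostatistical layer is a generic ordinary-kriging/IDW
  interpolator; proprietary ensemble-variogram methods used in
  GIS-based studies are intentionally not imitated, and their absence
  is the pipeline's main deviation from such workflows.
* Threshold tables are shipped as reconstructed constants of the
  worldwide classification; users matching a specific regional variant
  should edit the CSV.
* Envelopes are rectilinear and unweighted: no kernel densities, no
  dispersal, no interspecific competition, no significance testing on
  area changes.
* Quantitative characterisations printed for real species depend on
  occurrence cleaning and on interpolation fidelity at the occurrence
  cells; with sparse mountain networks the envelope's outer bounds are
  the most fragile statistics.
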