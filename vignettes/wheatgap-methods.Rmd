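---
title: "Designing wheat ideotypes and estimating yield gaps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing wheat ideotypes and estimating yield gaps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatgap)
```

`wheatgap` estimates the *genetic* yield gap of winter wheat: the difference
between the yield potential of a virtual cultivar (an *ideotype*) whose
traits are optimized for a local environment, and the management-optimal
yield of an existing locally adapted cultivar. It does this for six
wheat-growing sites — Edinburgh, Leeds and Rothamsted in the UK; Gore,
Lincoln and Pukekohe in New Zealand — under rainfed (water-limited) and
irrigated (potential) conditions. Three components are involved: a
stochastic daily weather generator, a process-based daily wheat simulator,
and an evolutionary trait optimizer. This vignette describes each model,
its assumptions, and the design decisions behind them.

## The weather generator

No daily weather records ship with the package; a seeded generator
(`generate_weather()`) produces arbitrarily long daily series whose
long-run statistics match each site's climate normals (annual mean
temperature, annual precipitation, mean daily global radiation — see
`builtin_sites()`).

* **Temperature.** Daily mean = annual mean + an annual cosine (amplitude
  6.5 degC at UK sites, 5.0 degC at NZ sites; warmest near 19 July in the
  north and 17 January in the south) + a semi-annual cosine (default
  0.8 degC) + an AR(1) Gaussian residual (sd 2.5 degC, lag-1 correlation
  0.7). The semi-annual term warms both solstices and cools the equinoxes
  relative to a single sinusoid; maritime temperate climates have exactly
  this broad summer plateau (July at Rothamsted averages about 1 degC above
  the best-fitting single sinusoid), and grain-fill temperature controls
  grain-fill duration, so the term matters. It leaves the annual mean
  unchanged. Tmin/Tmax are the mean -/+ half an 8 degC diurnal range.
* **Precipitation.** A two-state Markov chain (unconditional wet-day
  probability 0.45, wet-day persistence 0.65) with exponentially
  distributed wet-day amounts whose mean is scaled so the *expected* annual
  total equals the site normal. There is no seasonal precipitation cycle:
  only annual totals are published for these sites, so the generator
  declares, rather than fits, sub-annual structure.
* **Radiation.** An annual cosine (relative amplitude 0.8) peaking at the
  summer solstice, damped 25% on wet days, rescaled to preserve the annual
  mean, and capped at 95% of the extraterrestrial radiation for the
  latitude and day (`extraterrestrial_radiation()`, standard FAO-56
  geometry). Radiation has no day-to-day noise beyond the wet/dry
  alternation.
* **Calendar.** 365-day years; the phase arithmetic is exact and the bias
  of dropping leap days is negligible at this scale.

Generated series are rounded to 2 decimals — the precision of the
plain-text weather file format (`write_weather()` / `read_weather()`) — so
file round trips are bit-exact. A 100-year series recovers the target
statistics to well within 0.3 degC and 3%.

What the generator does *not* emulate: seasonal rainfall structure, dry/wet
year persistence (ENSO-like variability), radiation anomalies independent
of rain, and trends. Tests passing under this generator therefore
demonstrate correct model behaviour under a stationary, seasonally smooth
climate, not robustness to realistic extremes.

## The crop simulator

`simulate_season()` runs a daily time-step winter wheat model, a compact
process model in the Sirius family. The state comprises phenological
clocks, a cohort-based canopy, above-ground biomass and grain pools, and a
30-layer soil water profile.

**Phenology.** All clocks run on thermal time `max(0, (tmin+tmax)/2)`
(base 0 degC). Emergence needs 150 degC day from sowing. Mainstem leaves
appear every phyllochron `P_h` (a cultivar trait). The final leaf number
is committed the first day the appeared-leaf count overtakes the current
provisional target

> FLN = 11 + P_p x max(0, 15 h - daylength) + 8 x (1 - vernalisation),

clamped to [11, 24], where `P_p` is the daylength response (leaves per
hour of shortfall) and vernalisation accrues per day with full credit
between -1 and 8 degC, declining linearly to zero at 13 degC, over 75
effective days. Anthesis follows two phyllochrons after commitment; grain
fill ends when post-anthesis thermal time reaches `G_f` (a trait) or the
canopy is exhausted, whichever comes first.

The smooth vernalisation ramp matters at exactly one site: Pukekohe's mild
winters (9.5 degC mean) vernalise slowly and with large inter-annual
spread under a hard temperature window, which made simulated flowering
dates erratic; the ramp delays mean flowering to mid-October and brings
the inter-annual yield CV to ~8%, in line with the cooler sites.

**Canopy.** Each leaf rank forms a cohort whose potential area is
`A_max x 220 x max(0.5, rank/FLN)` (m2 m-2); the 220 shoots m-2 scaling
and the 0.5 floor stand in for tillers accompanying early mainstem leaves.
A cohort expands over one phyllochron, stays fully green for 630 degC day,
then declines linearly over 210 degC day. After anthesis the senescence
clock runs at `(1 + 0.5)/(1 + S_G)` of the thermal rate — the stay-green
trait `S_G` delays *post-anthesis* senescence (0.5 is the reference
cultivar's value, making it neutral), which is how the trait is defined
agronomically. Under water stress the senescence clock accelerates by a
factor interpolating from 1 (no stress) to `W_ss` (full stress).

**Growth.** Intercepted PAR is `0.5 x radiation x (1 - exp(-0.55 LAI))`;
daily biomass is intercepted PAR x RUE (3.5 g DM MJ-1 PAR) x an LUE
multiplier (1.10 for ideotype design, 1.00 for the reference) x a
temperature factor (piecewise linear: 0 at 0 degC, 1 between 10 and 20,
0 at 37) x the water stress factor. Pre-anthesis, 10% goes below ground;
post-anthesis everything is above-ground and available to grain.

**Grain.** At anthesis a stem-reserve pool of 18% of above-ground biomass
forms; during fill it translocates to grain at up to 2.5% of the initial
pool per day alongside current assimilate. Grain is sink-limited:
grain number and potential kernel weight are set by crop size at
flowering, and they scale *sub-linearly* with it — the cap is
`0.74 x 2000 x (b_anth/2000)^0.6` g m-2, where `b_anth` is above-ground
biomass at anthesis. Without any cap the source-driven model converts New
Zealand's 48% radiation advantage almost linearly into yield and pushes
harvest indices toward 0.6; with a *linear* cap, optimized ideotypes that
delay flowering into mid-summer build enormous anthesis biomass and carry
a proportionally enormous sink, inflating their advantage over the
reference far beyond the published range. The concavity (a diminishing
grain number per unit of crop biomass, standard wheat sink physiology) is
what keeps both the reference calibration and the optimizer's headroom
realistic. Around
flowering (200 degC day before to 100 after anthesis), days above 32 degC
or with severe water stress multiply grain set down; under the baseline
climates this changes mean yield by well under 1% (and can be toggled
off), but it responds to synthetic heat waves.

**Soil water.** A cascade of 30 x 5-cm layers (210 mm total available
water in the UK profile, 270 mm in the NZ profile). Rain fills layers
top-down; overflow is drainage; soil evaporation draws on the top two
layers. Daily extraction from layer *i* is capped at
`lambda_i x (R_u / 3) x available_i`, with the extraction-efficiency
profile `lambda` declining from 0.10 to 0.04 with depth: the profile
applies as published at the reference cultivar's uptake rate (`R_u` = 3%),
and the trait scales it. Transpiration demand is Priestley-Taylor
(alpha = 1.26, net radiation approximated as `0.75 Rs - 2`) times canopy
cover. Roots descend 1.2 cm per day. Potential (irrigated) mode refills
the profile daily and reports the water added as irrigation, so the water
balance closes exactly in both modes (tested to 1e-6 mm over 1000 days).
Under these baseline climates both countries' crops largely escape
drought — the crop matures before the summer moisture peak — which is why
the drought-senescence trait `W_ss` turns out unimportant and why rainfed
and irrigated reference yields nearly coincide.

**Units.** Biomass is tracked in g DM m-2 and reported as t ha-1
(dry-matter basis). Yield CV uses the sample standard deviation; the
harvest-index filter below applies to the mean HI across years.

### Calibration

The published description of the original simulator is qualitative, so the
free constants here (RUE, extinction coefficient, shoot-density scaling,
cohort green/decline durations, base leaf number, daylength cap,
vernalisation parameters, reserve pool, sink ratio) were fixed once by
calibrating the reference cultivar — cv. Claire: `P_h` 110, `P_p` 0.565,
`G_f` 650, `A_max` 0.007, `S_G` 0.5, `R_u` 3.0, `W_ss` 1.27 — against
three published anchors under 100-year potential-mode runs: country-mean
yield 10.8 t ha-1 (UK) and 13.2 t ha-1 (NZ), and a cross-site mean
grain-fill duration of 38 days. The shipped defaults give 10.9, 14.0 and
40.5 days. They live in one block (`crop_constants()`), are documented
there, and are not re-tuned per site or cultivar. Exact reproduction of
the original simulator's internals (and hence of its absolute optimized
trait values) is not attempted.

## The ideotype optimizer

`run_easa()` implements an evolutionary search algorithm with
self-adaptation: eight independent elitist (1+16) evolution-strategy
lineages. Lineage 1 starts from the reference cultivar; the other seven
start uniformly at random inside the trait bounds (phyllochron 80-140
degC day, daylength response 0.065-0.900 leaves h-1, grain fill 500-900
degC day, flag-leaf area 0.005-0.010 m2 m-2, stay-green 0-1.5, root
uptake 1-5%, drought senescence 1.0-1.7; the last is dropped from the
genome under irrigation, where it has no effect). Each offspring rescales
its per-trait mutation steps log-normally (global factor `1/sqrt(2n)`,
coordinate factor `1/sqrt(2 sqrt n)`) before perturbing the traits and
clipping to bounds.

Every candidate is evaluated on the *same* 100-year weather realisation
(common random numbers, reducing selection noise) with the 10% LUE uplift.
Candidates with yield CV above 10% or mean HI above 0.64 are removed from
selection — both thresholds inclusive, since the published rule removes
candidates *exceeding* them. The next parent is the highest-yielding
feasible member of the parent-plus-offspring set; keeping the parent
eligible (plus-selection) guarantees per-lineage monotone improvement and
that the returned ideotype never falls below the seeded reference. Whether
the original algorithm used plus- or comma-selection is not stated; plus
was chosen for exactly that guarantee. A lineage stops after 15
generations without relative improvement above 1e-3, or at 200
generations. The best feasible candidate across lineages is the site
ideotype. On analytic concave test surfaces the optimizer recovers the
known optimum to within 2% of each trait's range.

## The yield-gap pipeline

For each site and mode, `run_full_analysis()` simulates the reference
cultivar (LUE multiplier 1.00) and designs an ideotype (LUE 1.10) on the
same weather series, then reports

> Y_G = Y_GP - Y_M,  and  Y_G as a percentage of Y_GP,

with unweighted three-site country means and between-site sample
variances. Note the design consequence inherited from the study setup:
part of the reported gap is the 10% LUE uplift itself, which is attached
to ideotype design, not to the reference. Report tables round yields and
gaps to one decimal and percentages to integers; all identities hold
exactly pre-rounding. Because published gap percentages were evidently
computed from per-site-rounded figures in places, `gap_percent()` exposes
the alternative order of operations, and `climate_contrasts()` reports the
photothermal-quotient contrast under both averaging orders (ratio of
country means, and mean of site ratios) rather than asserting either.

Every run is driven by one master seed; per-stage seeds are derived
deterministically and recorded in a JSON manifest that suffices to replay
the analysis bit-identically (`replay_manifest()`).

## Problem sizes used in the shipped checks

The packaged tests run the full pipeline at 25 evaluation years and 30
generations (all 6 sites x 2 modes), the calibration checks at 100 years,
the conservation properties over 1000 random soil days and 200 random
cultivar-weather draws, and the optimizer oracle at 3 seeds; these sizes
give stable statistics for every quantity checked while keeping a complete
run on one core comfortably short. The acceptance script
(`scripts/acceptance.R`) recomputes the published arithmetic and the
100-year grain-fill duration at all six sites.

## Known limitations

* The simulator is a compact re-design in the Sirius family, not a port:
  absolute optimized trait values and absolute ideotype yields are not
  comparable one-to-one with the original; calibration bands and
  directional/structural results are.
* Nitrogen is assumed non-limiting and pests/diseases absent (as in the
  study design); there is no CO2 response.
* The weather generator's sub-annual structure is declared, not fitted
  (no seasonal rainfall cycle, no radiation noise); drought stress is
  correspondingly rare at these sites.
* Once the grain sink is full, further grain-fill duration adds biomass
  but no yield, so the optimizer is close to indifferent among long `G_f`
  / high `S_G` combinations; optimized phenology traits should be read as
  representatives of a near-optimal set, not unique values.
* Published trait tables report some optimized values outside the stated
  optimization ranges (daylength response below 0.065; root uptake above
  5). The bounds are enforced strictly here, so those rows are treated as
  illustrative rather than as reproduction targets.
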