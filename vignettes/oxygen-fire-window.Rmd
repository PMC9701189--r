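---
title: "Oxygen, fire and the persistence of forests: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oxygen, fire and the persistence of forests: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxfire)
library(ggplot2)
```

## The scientific question

Atmospheric oxygen has varied over Earth history, and a long-standing
argument bounds its upper levels by fire: if oxygen rose too high, wildfires
would become so frequent and intense that forests could not regenerate, yet
forests have existed continuously for hundreds of millions of years.
Combustion experiments show three oxygen dependences that matter for this
argument: the probability that an ignition succeeds rises steeply with
oxygen, the fuel moisture above which a fire cannot spread (the *moisture of
extinction*) rises linearly with oxygen, and the heat released per unit fuel
burned rises toward its complete-combustion value. `oxfire` implements these
dependences as pure functions, routes them through a reduced-complexity
daily fire engine coupled to a minimal vegetation layer, and sweeps
atmospheric oxygen from the present level (20.95% by volume, "PAL") to 35%
against a fire-off baseline, on a synthetic gridded world. The question the
experiment addresses is qualitative: as oxygen rises, do fires multiply
faster than area burns, and does fuel moisture protect enough forest for
woody vegetation to persist?

## The oxygen pathways

Three empirical relationships carry all oxygen dependence.

**Probability of ignition.** An empirical combustion-experiment fit gives a
rating (in %) for the likelihood that a lightning strike ignites fine dead
fuel, cubic in oxygen $O_x$ (% vol) for both the $\ln$-moisture slope and
the intercept:

$$\mathrm{PI}(O_x, M) = \left[308.02 - 27.406\,O_x + 0.634\,O_x^2 -
0.0044\,O_x^3\right]\ln M - 633.54 + 42.327\,O_x - 0.2194\,O_x^2 -
0.0075\,O_x^3$$

with $M$ the fuel moisture (% of dry mass). Being an empirical fit the
rating can stray outside $[0, 100]$; `ignition_probability()` clamps it to
that interval, because it is used as a probability rating and no guidance
exists for out-of-range values. The fit is only trusted over the
experimental range $O_x \in [16, 35]$; the package refuses to extrapolate.
The engine uses the *normalised* form `ignition_scaling()`,
$\mathrm{PI}(O_x, \omega)/\mathrm{PI}(20.95, \omega)$, evaluated separately
with the 1-h/live-grass moisture $\omega_{nl}$ (for grass fuels) and the
woody fuel moisture $\omega_{o}$ (for tree fuels); the scaled per-PFT
efficiencies are combined into a grid-cell value by a foliar-projective-cover
(FPC) weighted average, and the overall ignition efficiency is the product
of that average, the fire danger index, and a burned-area attenuation
factor.

At PAL the rating crosses zero near 22.3% moisture, so the naive ratio
diverges for wet fuels. The package floors the PAL denominator at
`pi_floor` rating points (default 1, roughly the resolution of the
underlying rating) by evaluating both numerator and denominator at the
corresponding moisture cap (~21.5%). Wetter fuels therefore receive the
largest *finite* scaling (~64 at 35% O2) instead of an unbounded one. This
is the one place the package deviates from treating the fit literally; the
alternative (normalising at the exact zero crossing) is ill-posed.

**Moisture of extinction.** $M_e = 8\,O_x - 128$ (% dry mass), zero at 16%
vol — consistent with experiments in which dry fuel cannot ignite below
about 17% vol oxygen — and 152% at 35% vol. Moisture on a dry-mass basis can
exceed 100%, so values above 100 are meaningful. The engine multiplies each
fuel class's *native* (PAL-calibrated) extinction constant by the scaling
$M_e(O_x)/M_e(20.95)$, which is exactly 1 at PAL and reaches 380/99 ≈ 3.84
at 35%.

**Heat of combustion.** Per PFT, $h = \alpha/O_x + \beta$ (kJ kg⁻¹), with
$\beta$ the complete-combustion (bomb-calorimeter-like) asymptote and
$\alpha < 0$ so that heat released rises toward $\beta$ as oxygen becomes
abundant. No authoritative per-PFT table is available, so the defaults set
$\beta$ per growth form (trees 20,000; grasses 18,500 kJ kg⁻¹) and anchor
the present-day value $h(20.95)$ at 17,500 (trees) and 16,500 (grasses)
kJ kg⁻¹ via $\alpha = (h_{PAL} - \beta)\cdot 20.95$. All heats are carried
in kJ kg⁻¹ (a legacy fixed value of "18,000" is interpreted at this
magnitude); the grid-cell average replaces that single constant through the
same FPC weighting as ignition efficiency.

All three scalings equal exactly 1 at PAL, and the simulator run at
`o2 = 20.95` is bit-for-bit identical to a run with the oxygen feature
disabled (`oxygen = FALSE` takes a separate code path that skips the
scalings entirely, so the equivalence is a real regression check, not a
tautology).

## The fire engine

The engine is a deliberately small, single-day SPITFIRE-style model: each
day, each cell can ignite and burn fires that last a fixed `duration` (240
minutes); there is no multi-day burning or fire coalescence. This keeps the
oxygen pathways — which are the point — inspectable and testable at desk
scale.

* **Fire danger** (`fire_danger_index()`) is a Nesterov-style cumulative
  dryness index: each dry day adds $\max(T,0)(1-rh)$, a day with more than
  `rain_reset` (3 mm) of rain resets it, and the danger on day $t$ is
  $1-\exp(-N_{t-1}/\mathrm{ref})$ with `nesterov_ref = 300` °C·days, so the
  day after heavy rain has zero danger.
* **Ignitions** (`expected_ignitions()`) are lightning strikes times a
  ground-strike fraction (0.35) times cell area times the overall ignition
  efficiency. The burned-area attenuation is `1 - (fraction of the cell
  already burned this calendar year)`, floored at zero and reset annually —
  a simple monotone stand-in for fuel exhaustion within a season.
* **Rate of spread** (`rate_of_spread()`) is a Rothermel-flavoured product:
  a base scale (`ros_max`, 18 m min⁻¹) times a linear wind response, reduced
  by fuel-bed bulk density and sparse fuel, damped by moisture in two ways:
  a damping term $(1 - \omega/M_e^{\mathrm{eff}})^3$ that is exactly zero at
  and beyond the effective (oxygen-scaled) moisture of extinction, and an
  ignition heat sink $1/(1+\omega/28)$ representing the energy spent heating
  and evaporating fuel water well below extinction. The damping exponent 3
  is steeper than the classic cubic damping curve; with the shallow classic
  form, fuels near extinction still spread at half speed, which makes the
  moisture protection of wet forests far weaker than the experiments the
  extinction concept comes from suggest. The two native extinction
  constants default to 16% (fine dead + live grass) and 15% (woody), at the
  dry end of the conventional range: they anchor the *PAL* fire regime in
  the semi-arid grasslands, and the oxygen sweep then widens the burnable
  moisture window from there (see "why the bands order themselves" below).
* **Burned area** (`burned_area()`) treats each fire as an ellipse of length
  `ros × duration` with a wind-driven length-to-breadth ratio; the day's
  newly burned fraction is capped by the cell fraction still unburned this
  year, so the cumulative annual burned fraction can never exceed 1.
* **Fireline intensity** (`fireline_intensity()`) is Byram's product
  $I = h\,w\,r/60$ (kW m⁻¹) with $h$ the FPC-weighted heat of combustion and
  $w$ the fuel consumed.
* **Mortality** (`fire_mortality()`) is a saturating function of intensity,
  $\mathrm{susc}\cdot I/(I+i_{1/2})$ with $i_{1/2}=150$ kW m⁻¹, applied to
  the burned fraction of the cell. Grasses carry high susceptibility but
  regrow within a season; trees lose cover durably.

A consequence worth knowing: *realized* fire counts in fuel-limited
grasslands can fall as oxygen rises, because the season's area burns out in
its first fires and the attenuation then suppresses later ignitions.
Expected ignitions at fixed cell state are monotone in oxygen; the counts
that survive the attenuation need not be, and globally the rise is carried
increasingly by moist cells where fires ignite but stay small.

## Vegetation

Nine plant functional types (2 tropical, 3 temperate and 2 boreal trees,
plus C3 and C4 grasses) carry LPJ-family bioclimatic limits (coldest-month
temperature window, minimum growing degree days). Inside their limits,
PFTs grow logistically toward a climate-set carrying capacity using the
*exact* annual step of the continuous logistic (so constant-climate
trajectories match the closed form); outside, they decay at 20% per year.
Carrying capacities come from a moisture index (annual precipitation over a
crude evaporative demand of 0.17 mm per positive degree-day): trees ramp in
over MI 0.28–0.75, grasses over 0.04–0.25, and trees pre-empt space, with
grasses filling the remainder up to a total cover of 0.95. Fire mortality
multiplies cover by $1 - \mathrm{kill}\times\mathrm{burned\ fraction}$ and
transfers killed canopy to the woody fuel pool. Fuel pools are annual:
litter production proportional to cover, first-order decomposition, and
combustion removal.

Two vegetation choices matter for the oxygen experiment and are worth
defending explicitly. C3 grass ignition efficiency is set much lower (0.15)
than C4 (0.55): cool-climate grass fuels are the kindling of the model's
temperate zone, and with equal efficiencies every mid-latitude forest sits
on a hair-trigger grass-fire feedback that flips it to savanna the moment
cover thins — a bistability that is real in the model but would dominate
every diagnostic. Susceptibilities distinguish fire-sensitive mediterranean
broadleaf evergreens (0.85) from thicker-skinned conifers (0.30–0.45);
combined with slow canopy recovery (0.04–0.06 yr⁻¹) this produces the
experiment's central behaviour: seasonally dry mid-latitude woodland is lost
as oxygen rises, while conifer belts thin but persist.

Tree cover above 0.60 defines *forest*; the **suppression metric** is
$100\,(1 - F(O_x)/F_{\text{no fire}})$, the percentage decrease of forest
area relative to an otherwise identical simulation with fire disabled
(`simulate_world(fire = FALSE)`), floored at zero, and undefined (an error)
if the no-fire world has no forest at all.

## The synthetic world

No external forcing is used. `generate_forcing()` builds daily temperature,
precipitation, humidity proxy, wind and lightning on a latitude–longitude
grid from smooth zonal normals: wet, warm, convectively active low
latitudes; arid subtropics; a low-seasonality semi-arid shrub belt near
35°; moist mid-latitudes; cold high latitudes whose low evaporative demand
keeps fuels damp; and a calm subtropical wind belt between trade winds and
westerlies. Precipitation occurrence is a two-state Markov chain
parameterised by its stationary wet-day probability and a persistence of
0.2 (so the chain's stationary distribution is exactly the configured
probability — the property the calibration test checks against the closed
form), with gamma-distributed amounts targeting the zonal annual total.
Temperature adds AR(1) noise to a seasonal cycle; the humidity proxy is a
30-day memory of wet-day occurrence plus a cold-climate bonus; lightning
follows warm, moist convective conditions. Everything is deterministic
given the seed.

Fuel moistures relax linearly toward a daily equilibrium — 70% of dry mass
on rain days, a humidity-driven value between 4% and ~110% otherwise — with
time constants of 7 days (fine + live grass) and 25 days (woody), kept
symmetric so the recursion is a linear filter. The 30-day humidity memory
deliberately separates *climate* wetness from *weather* dryness: without
it, every dry spell anywhere crashes fuel moisture to desert values within
a week and the latitudinal moisture structure cannot protect anything.

The default experiment grid is the 6 × 3 "mini world" (latitude rows at 5°,
20°, 35°, 50°, 65°, 80°; dry, average and wet longitudes at 0.7×, 1.0× and
1.4× zonal wetness), spun up for 200 years with the final 10 years averaged
— a desk-scale reduction of the full protocol (a 10° global grid and a much
longer spin-up), sized so that the complete 16-run sweep takes well under a
minute. An equilibrium check warns when area-weighted tree cover still
drifts by more than 0.02 between the last two decades. The full-size grid
is available through `world_config()`; note a 10° global grid over 200
years holds several gigabytes of daily fields in memory.

What the generator does *not* emulate: orography, land–sea contrast, ENSO-
scale interannual persistence, realistic lightning climatologies, human
ignition and suppression, or any real-world geography. Passing tests on
this world show that the oxygen pathways interact with moisture, fuel and
vegetation structure in the documented directions; they do not validate
absolute magnitudes for the real Earth, and the experiment's absolute fire
counts and areas have no real-world calibration.

## The experiment and its diagnostics

`run_experiment()` sweeps oxygen over {20.95, 21, 22, …, 35}% vol under
identical seeded forcing, plus the fire-off baseline, and summarises each
run over its final decade: total fires per year, burned area (cell
fractions times spherical cell areas, i.e. cosine-of-latitude weighting),
global tree cover, forest area, the suppression metric, and the
moisture-band spread analysis. `tidy()`, `glance()` and `autoplot()` expose
the results; `write_sweep_outputs()` writes CSVs (gridded maps as
long-format latitude/longitude tables — the package deliberately has no
binary-format dependencies).

**Moisture bands.** Cells are binned by their 10-year-mean fuel moisture
(the plain mean of the two fuel-class moistures, which depends only on the
forcing, so every cell keeps one band across all oxygen levels) into <20,
20–40, 40–60 and >60% — conventional edges, config-exposed. A cell's rate
of spread is that of the fires that actually burned it (burned-area
weighted); cells that never burn report zero, as gridded fire-model output
does. Because a band whose fuels cannot carry fire at PAL has nothing of
its own to normalise by, the per-band change across the sweep is expressed
relative to the *global* PAL mean rate of spread (a common denominator).
Empty bands are reported as missing, never zero.

**Why the bands order themselves.** For any monotone moisture-damping
curve, the *relative* gain in spread rate between two oxygen levels grows
with fuel moisture right up to the extinction point — wetter fuel always
gains more, proportionally, from a rising extinction threshold. A
decreasing band ordering therefore cannot come from the damping function
alone; it is a property of where the burnable-moisture window sits relative
to the landscape's moisture distribution. The native extinction constants
place that window just below the dry band's typical fuel moisture: at PAL
only the driest fuels carry fire, and as oxygen raises the window the dry
band unlocks fully (large gain), the semi-arid band unlocks partially (its
wetter days remain damped by the heat sink and the steep damping), the
moist mid-latitudes barely unlock (slow, creeping fires), and the wet
tropics and high latitudes stay above the window entirely. The ordering is
then a statement about the landscape, which is exactly what it is in the
underlying science.

## Numerical and design notes

* Oxygen outside [16, 35]% vol raises an error everywhere (no
  extrapolation of the combustion fits); sweeps are further restricted to
  [20.95, 35].
* The ignition rating is clamped to [0, 100] after evaluation; the
  normalisation cap (`pi_floor`) is the only smoothing applied to it.
* Bare ground (zero total FPC) yields `NA` from `fpc_weighted_average()`;
  the simulator treats such cells as non-flammable rather than propagating
  the missing value.
* All within-year fire arithmetic is vectorised over (day × cell) matrices;
  the burned-area attenuation uses the exact closed form
  $1-b_t = \prod_{s\le t}(1-\min(q_s,1))$, so no daily loop is needed.
* Fuel-moisture and humidity recursions are linear filters
  (`stats::filter`); the wet/dry chain is the only sequential simulation.
* Determinism: all randomness lives in `generate_forcing()` under one seed;
  two runs with the same configuration are bit-identical, and the RNG state
  of the calling session is restored afterwards.
* Ties and degenerate inputs: zero-length guilds keep their cover; logistic
  steps with zero carrying capacity decay exponentially; cells with no
  unburned area left simply stop burning (and stop igniting, through the
  attenuation).

## Limitations

The engine is a single-day fire model without multi-day burning,
coalescence, crown fire or spotting; burned areas at high oxygen are
cap-limited rather than spread-limited in the driest cells. The vegetation
layer has no carbon cycle, allometry, soil hydrology or dispersal; its
bistable grass–forest feedback is tamed by construction (see above) rather
than resolved ecologically. The 18-cell mini world makes global series
lumpy: single-cell regime shifts are visible as steps in the suppression
series. Oxygen effects on plant physiology (photorespiration under high
O2) are deliberately out of scope, as are real climate forcing and any
reproduction of absolute global numbers.

## A worked sweep

```{r sweep, fig.width = 6, fig.height = 4}
sweep <- run_experiment(
  mini_world_config(),
  o2_levels = c(20.95, 23, 26, 29, 32, 35),
  spinup_years = 200
)
tidy(sweep)
glance(sweep)
autoplot(sweep, type = "sweep")
autoplot(sweep, type = "suppression")
autoplot(sweep, type = "bands")
```
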