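---
title: "A diel metabolic model of phototrophic subaerial biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A diel metabolic model of phototrophic subaerial biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabsim)
```

## The system

Subaerial biofilms (SABs) are thin (tens of micrometers) mixed layers of
microbes and liquid water on stone surfaces exposed to the atmosphere —
monument roofs are a classic habitat. Two functional guilds dominate:
cyanobacteria, the primary producers, and heterotrophic bacteria that live
off cyanobacterial byproducts (secreted polysaccharides, non-volatile
organic acids from photorespiration, and decayed biomass). Because the film
is so thin, it is taken as spatially homogeneous: volatile compounds (CO2,
O2, N2) equilibrate with the atmosphere essentially instantaneously, while
non-volatile byproducts are trapped and accumulate.

The film's master variable is **water activity** `a_w` — the ratio of the
film's vapor pressure to that of pure water. It is driven by the diel cycle
of air temperature, stone temperature and humidity, and gates every
metabolic process: below a minimum viable value (default 0.6, consistent
with experimental viability limits) all metabolism stops, and as `a_w`
falls the ATP cost of osmotic homeostasis rises. The model's central
prediction is a diel activity pattern: a burst of photosynthesis and
biosynthesis in the humid early morning, full metabolic suppression over
the hot dry midday, and a second window of respiration and nutrient
scavenging after sunset.

## State variables and equations

The model is a stiff ODE system over 15 extensive states: cyanobacterial
functional biomass `M_C` [mol C] with quota pools for stored organic carbon,
bound nitrogen, ATP and NADPH (Droop formalism: each pool is integrated as
an extensive amount `E = M * Q` and the quota `Q` recovered afterwards);
heterotroph biomass `M_H` with carbon, nitrogen and ATP quotas;
extracellular polysaccharides, carbon- and nitrogen-decayed biomass; and
dissolved amounts of total organic acid, its anion, and bicarbonate
(`A = V * S`, with `V = M / rho` the film volume tied to total solid mass
by the constant film density and thickness). Integrating extensive
variables keeps elemental audits exact and absorbs volume change without an
explicit dilution term.

Every biological rate has the law-of-the-minimum form

    r_i = k_i * M_i * min(phi_1, ..., phi_k)

with each limitation factor `phi` in [0, 1]; a single factor limits at any
instant. The derivative is `dy/dt = K r`, with `K` a stoichiometric matrix
whose columns are closed in carbon and nitrogen against three *virtual gas
rows* (CO2, O2, N2) that are not integrated but solved at build time from
the biological entries of each column. Cumulative gas-exchange trackers
(`G_CO2`, `G_O2`, `G_N2`) are integrated alongside the state so trajectory
conservation can be asserted: total tracked carbon plus `G_CO2` is constant
to solver tolerance, and likewise for nitrogen against `G_N2`.

### Limitation factors

* `aw_ramp`: linear from 0 at `a_w_min` to 1 at pure water — the default
  water gate on photosynthesis, fixation, growth, respiration, uptake and
  scavenging.
* `aw_tent`: 0 at `a_w_min`, peak 1 at `a_w_peak` (default 0.8), back to 0
  at pure water — the osmotic-stress response shaping the extra cyclic
  electron transport and polysaccharide secretion, processes that intensify
  under moderate stress and cease both in desiccation and in pure water.
* `light_response`: Monod in light intensity, or normalized Haldane
  (photoinhibition, PSII damage) for the non-cyclic chain only.
* `ph_window`: parabolic bump over a viable pH window (default [4.5, 9.5]),
  applied to carbon fixation.
* Quota factors: Monod factors on stored ATP/NADPH where a process consumes
  them, Droop subsistence factors `1 - Q_min/Q` where a reserve fuels
  growth or respiration, and capacity ("room") factors `1 - Q/Q_max` that
  throttle production of a pool as it fills.

### Energy budget, maintenance and decay

The light phase runs two electron-transport chains: the non-cyclic chain
produces NADPH and some ATP (and O2, on the virtual row), the cyclic chain
ATP only, with a basal term plus a stress increment shaped by the tent
factor. Carbon fixation competes with photorespiration through the
branching function `g_fix = 1 / (1 + gamma * S_O2 / S_DIC)`; the two rates
share one limitation evaluation, so their sum is exactly the limited
fixation capacity. Photorespired carbon leaves the cell as (undissociated)
organic acid; finite-rate acid–base kinetics then set its speciation.

Maintenance demand per unit biomass is `m0 + m1 * (1 - a_w)`. When the
instantaneous specific ATP production `omega` (gated by the stored-ATP
Monod factor) covers the demand, maintenance is paid in full and no decay
occurs; otherwise all produced ATP goes to maintenance and decay proceeds
at `k_d * (1 - s)` with `s` the met fraction. Decay routes functional
carbon and the cell's current stored-carbon quota to the decayed-carbon
pool and its nitrogen (bound plus structural, `q_N_bio` per mol C) to the
decayed-nitrogen pool.

### Chemistry and pH

Dissolved CO2 and O2 are held at Henry's-law saturation at the interface
temperature (van 't Hoff temperature dependence; warm stone holds less
CO2). Bicarbonate relaxes toward `S_H * S_HCO3 = Ka_CO2 * CO2_sat` with
fast first-order kinetics, and the organic acid toward its dissociation
equilibrium. H+ is algebraic: at every evaluation the charge balance
`S_H + S_Cat = Kw/S_H + S_HCO3 + S_OA- + S_An` is solved in closed form and
pH reported on the molar scale. Bicarbonate–carbonate dissociation is
neglected (relevant only near pH 10.3). With the default dissociation
constant the pH at which saturated CO2 and bicarbonate are equimolar is the
pKa, 6.36; glycolic acid (pKa 3.83) is the organic-acid default.

### Microclimate

The film–air interface temperature is the flux-matching weighted mean
`T* = (T_a k_a lambda + T_s delta k_b) / (lambda k_a + delta k_b)`; with
the default 15 um film under a 1 mm boundary layer it is dominated by the
stone. Water activity follows the Magnus form
`a_w = RH_a * e_sat(T_a) / e_sat(T*)`, clipped to [0, 1] (condensation),
and is evaluated quasi-statically — evaporation/condensation is assumed
fast relative to biology. The transport coefficients are labelled as
effective; only the ratio `k_a/k_b` (with the two thicknesses) matters.

## Synthetic forcing

Field forcing records for this kind of site are not redistributable, so the
package generates idealized 24 h-periodic days from seasonal presets:
sinusoidal air temperature (minimum one hour before sunrise), half-sine
light, stone temperature blending a sun-driven warm offset with a night
cool offset in proportion to instantaneous insolation, and relative
humidity derived from a fixed dewpoint through the same Magnus expression
used by the microclimate module. A measured day can be supplied as CSV
instead; piecewise-linear interpolation with a periodic wrap deliberately
tolerates the step discontinuity at the wrap point that periodically
extending a measured day introduces.

The four presets (summer 20–33 degC / dewpoint 17 / 2000 uE; spring 10–24 /
10 / 1600; autumn 8–18 / 6 / 1000; winter 0–8 / 4 / 700) were chosen once as
climatologically plausible mid-latitude values whose mean water activity
increases monotonically from summer to winter; the dewpoints are humid-side
realistic (a humid continental summer) rather than arid. They are defaults
of the generator, not claims about any particular site.

What the generator does **not** emulate: weather-to-weather variability,
rain, wind, multi-day autocorrelation, and the asymmetries of real
temperature records. Passing the scenario tests under these idealized days
shows the model mechanisms behave as intended; it does not validate the
model against field data.

## Parameter defaults

Kinetic and stoichiometric defaults are order-of-magnitude choices that
produce day-scale dynamics (`k_fix` 0.2 h-1, `k_growth_C` 0.08 h-1,
maximum decay 0.003 h-1, maintenance 0.002–0.022 mol ATP (mol C)-1 h-1
across the water-activity range); none is a measured value, and all are
exposed in the configuration. Several deserve comment:

* **Energy yields.** The non-cyclic chain yields 0.5 ATP per NADPH and
  fixation costs 2.5 ATP + 2 NADPH per carbon, so fixation is a *net ATP
  drain*; the cyclic chain balances the ledger. An earlier symmetric choice
  (1 ATP per NADPH) let the ATP pool saturate, and its capacity factor then
  froze the non-cyclic chain — an ATP-rich, NADPH-starved deadlock with no
  biological counterpart.
* **Darkness gate.** Respiration and cyanobacterial acid reuptake switch on
  via `K_I_dark / (K_I_dark + I)` with `K_I_dark` = 1 uE m-2 s-1, distinct
  from the photosynthetic half-saturation (150 uE). With a shared constant,
  enough reuptake leaked into daylight to consume the photorespired acids
  as fast as they appeared, erasing the morning acid pulse and the pH
  dynamics that the heterotroph-ablation study probes.
* **Inorganic-carbon split.** Fixation (and photorespiration) draw
  bicarbonate and gaseous CO2 in proportion to their instantaneous
  concentrations. This keeps the bicarbonate pool non-negative by
  construction and reproduces the morning pH rise from bicarbonate
  consumption; cyanobacterial respiration returns its carbon as
  bicarbonate, the charge counterpart of night-time anion reuptake.
  Heterotroph respiration vents CO2 directly.
* **Organic-acid uptake speciation.** Uptake removes the anion in its
  current dissociated fraction, preserving `S_OA- <= S_TOA` exactly; the
  stoichiometric entry is state-dependent but carries no elemental weight,
  so column closure is unaffected.
* **Heterotroph decay mass.** The heterotroph decay rate is scaled by
  heterotroph biomass; `strict_hetero_decay_mass` instead scales it by
  cyanobacterial biomass, an alternative convention retained for
  comparison. Similarly `strict_decay_gamma` switches decay to be
  proportional to the met (rather than unmet) maintenance fraction.

## Numerics

The system is stiff (acid–base relaxation in seconds against biology in
hours), so it is integrated with an adaptive implicit BDF/Adams switching
solver (deSolve's `lsodar`), rtol
1e-6, per-state atol scaled to pool size (1e-16 for the tiny dissolved
amounts), and forcing evaluated inside the right-hand side — no operator
splitting. The right-hand side exists twice: an exported R reference
implementation built from the documented rate functions, and a compiled C
mirror used by default (a multi-day run evaluates the derivative on the
order of 1e4–1e5 times); a property test pins the two together at ~1e-12
on random states. Solver undershoots below zero are clipped for rate
evaluation; quotas are recovered as `E/M` with a 1e-12 mass guard.
Integration stops with an extinction flag when *living* biomass (functional
plus stored carbon) falls below 1e-6 of the initial mass — decay conserves
total solid mass by design, so a total-mass threshold could never fire.

The periodic state is detected by comparing consecutive daily profiles of
all intensive variables (quotas, dissolved concentrations, pH) in relative
supremum norm; biomasses are excluded because at the periodic state they
change by a constant daily factor, reported separately as the daily growth
factor.

## Scenario studies and problem sizes

Three runners mirror the natural numerical experiments. `single_day`
integrates one forcing until the diel orbit settles; under the summer
preset the final day shows cyanobacterial biosynthesis confined to the
early-morning window (free water and light), exact zero biosynthesis over
11:00–15:00, and respiration/uptake reactivating after sunset. `ablation`
repeats the run with the heterotroph seed removed: photorespired acids then
accumulate through the morning (mean daily acid load orders of magnitude
higher), the pH floor drops toward 4.5 where the viable-pH window throttles
fixation, and polysaccharides plus decayed biomass dominate the final
composition. `seasons` runs the four presets; the daily growth factor is
maximal in winter and minimal in summer, tracking the monotone increase of
mean water activity from the warmest to the coldest preset.

The test suite runs these at 40 simulated days (diel, ablation) and 60 days
(seasons) on a 6-minute output grid — sizes chosen so the orbit is settled
well past the transient while a full check completes in well under a
minute per scenario.

Under the synthetic defaults the summer day sits slightly *below*
break-even (daily growth factor ~0.98): the film persists through the
40–60 day horizon but would slowly retreat, which we read as the marginal
end of the regime the presets aim at. Two further caveats: without
heterotrophs the *total* solid mass can still grow because uneaten decayed
biomass accumulates and counts toward mass, so the ecosystem-level benefit
of heterotrophs appears here in the living composition rather than in
total mass; and heterotrophs equilibrate at a larger share of the living
biomass than confocal observations of real films suggest. Both trace to
the free defaults, not to the model structure.

## Known limitations

No spatial structure (thick films with diffusion gradients are out of
scope), no direct temperature dependence of the metabolic rates (the water
activity channel is the only temperature pathway), no photoacclimation or
explicit PSII damage–repair kinetics, no transient water retention by the
polysaccharide matrix or the stone, no carbonate-mineral chemistry, and no
prediction of film thickness. Inert ions `S_An`/`S_Cat` default to zero;
nonzero values shift the charge balance and are accepted in the
configuration but unexplored here.
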