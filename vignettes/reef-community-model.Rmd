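---
title: "An individual-based model of benthic space competition on a coral reef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of benthic space competition on a coral reef}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefsim)
```

## The model

`reefsim` simulates a virtual benthic reef community on a continuous
40 x 40 m arena. Four scleractinian coral species — the massive *Porites
lobata* and *P. lutea* and the branching *Acropora muricata* and
*Pocillopora damicornis* — compete for space with fleshy macroalgae
(*Sargassum*-like) and an algal turf layer. Community composition is not
prescribed anywhere: it emerges from individual life histories (growth,
reproduction, mortality), pairwise spatial interactions, and three
environmental processes — temperature-driven coral bleaching, mechanical
disturbance events, and density-dependent herbivory. The time step is one
month; published annual lateral-extension rates (mm/yr) convert to radial
growth per step as `mm / 10 / 12` cm.

### Coral colonies

A colony is a 24-point star: 24 axis lengths anchored at a fixed centre,
one per 15 degrees. Massive colonies connect the endpoints into a polygonal
footprint; branching colonies use the star itself, with containment decided
by linear interpolation of the two bracketing axes. The mean of the 24 axes
(`mean_radius()`) defines the colony's planar cover `pi * rbar^2` and its
surface area `2 * pi * rbar^2 * surface_factor`, where the species-specific
surface factor captures how much live tissue a morphology packs above a
unit of substrate (1–1.5 for massive domes, 3–5 for branching thickets).

Each month every axis extends by the species' base rate multiplied by a
per-axis competition modifier: the minimum, over all organisms whose
footprint the axis's next endpoint would enter, of the interaction-table
multiplier. The table encodes a slight competitive edge for massive
morphologies (a larger massive reduces a smaller one to a standstill, while
branching colonies merely slow each other), one species-specific
competition index (*P. lobata* keeps 30 % of its growth against a larger
*P. lutea* less than 25 % bigger in diameter — *P. lutea* wins the community
through growth rate, not contact superiority), and mild suppression of
corals by larger macroalgae. Ties in the size comparison count as inferior.
Axes are clamped at the species' maximum radius (3 m for massive species,
50 and 30 cm for the branching ones), and an axis whose endpoint would
cross the arena border is held at the colony's mean radius, which removes
the growth advantage an edge position would otherwise confer.

A colony dies when it is overgrown (more than 75 % of a massive colony's
size, more than 50 % of a branching colony's — measured by the fraction of
its 24 axis endpoints lying inside other living footprints, a cheap proxy
for areal overlap that we validate against rasterized geometry in the test
suite), when a mechanical disturbance hits it, through post-bleaching
mortality, or — for branching colonies — by mechanical breakage: an
unsheltered branching colony (fewer than two neighbours of at least its
size within contact distance) is lost with 0.5 % probability per month.

### Bleaching

Thermal stress is summarized by a 20-day statistic: the hottest 20-day
window mean among windows ending in the focal month. (The windows are
expressed as means rather than sums so that the statistic lives on the same
degC scale as the species thresholds.) A healthy colony bleaches with
probability rising linearly from 0.30 at its species' minimum bleaching
temperature to 1.0 at the all-bleach temperature; a colony that bleaches
dies in the same step with probability interpolated between its death
thresholds. Survivors recover over six months, during which growth,
competitive strength and fecundity scale linearly from 0 to 100 %
(`recovery_performance()`), recruits can settle on their tissue with a
complementary survival probability, and a second bleaching trigger is
ignored — the recovery trajectory is defined from a single onset.

The threshold table gives the four species distinct characters: massive
*Porites* (onset 29.9 degC) never bleaches in ordinary years;
*A. muricata* (onset 29.4) is the only species that bleaches occasionally
in normal summers; *P. damicornis* (onset 30.0) bleaches only in extreme
years but then nearly always dies (its death range saturates at 30.4).

### Temperature forcing

Daily sea-surface temperatures come either from a two-column CSV
(`read_sst_csv()`) or from the built-in generator `synth_sst()`, which
emulates a Zanzibar-like climate: a sinusoidal seasonal cycle (annual mean
27.4 degC, half-range 1.9, peak in mid-March) plus AR(1) daily noise
(sd 0.2, lag-1 correlation 0.5). Every k-th year is a "hot year" carrying a
Gaussian-in-time anomaly pulse centred on 15 March with a +2 degC peak and
a 4-day temporal sd.

Two generator constants were calibrated, once, against the qualitative
anchors above rather than against any output statistic: the seasonal mean
is set so the normal-year March statistic (about 29.35 degC) crosses the
*A. muricata* onset in roughly a quarter of years while staying safely
below 29.9; and the pulse duration is set so a hot-year March statistic
lands just above 30 degC — every species bleaches, bleached *P. damicornis*
virtually always dies, and whole-colony mortality of massive *Porites* is
roughly 15–20 % per event, consistent with the comparatively moderate
*Porites* losses observed in the 1998 East African bleaching while
branching species bear the brunt. A broad anomaly (weeks at
+2 degC on the 20-day mean) would instead kill the majority of massive
colonies at every event and no community structure above a few percent
cover would survive a 15-year regime — dynamics incompatible with reefs
that demonstrably retain *Porites* dominance under such regimes.

### Reproduction and recruitment

Mature colonies (mean diameter above the species' maturity size) produce
`eggs_per_cm2 x surface_area` gametes or larvae per event — annual spawning
in March for the three broadcast spawners, monthly larval release for the
brooding *P. damicornis*. The expected recruit pool of an event is

```
internal * (1 + connectivity) * retention + fixed_input * arena_m2
```

where `internal` is the summed colony output, `connectivity` (default 1)
scales the variable external supply from statistically similar neighbour
reefs, `retention` collapses fertilization mode, predation, larval
retention and early mortality into recruits-per-larva, and `fixed_input`
(0.01 recruits m^-2 event^-1) is a constant rescue term of already-settled
recruits that does not depend on the local stock — without it a species
that loses its last colony could never return, and the brooding
*P. damicornis*, which is nearly eliminated by every extreme year, would
not persist. The realized count is a Poisson draw; each recruit settles at
a uniform random position, dies on contact with a healthy coral or a
macroalgal zone, survives on a bleached coral with the recovery-dependent
probability, and on free ground dies with probability equal to the local
turf cover ("reciprocal" turf mortality read as
proportional-to-cover — turf occupies settling ground, so more turf means
fewer surviving spat). Survivors enter the arena at spat size (1–2 mm).
This stock–recruitment loop is the model's central positive feedback:
abundant species recruit more, rare species fade unless rescued from
outside.

### Macroalgae and turf

A macroalga grows 30 cm per month, split equally between height and
diameter until the 45 cm diameter cap, then all into height up to 60 cm.
Its diameter defines a zone of influence (shading and abrasion reach beyond
the thallus). Above 30 cm height it fragments — one fragment per 5 cm of
excess, 5 cm height lost per fragment — with fragments landing within 2 m
of the parent (a 10 m margin around the arena keeps edge densities
unbiased; margin organisms are excluded from every metric). Each fragment
establishes with probability 0.05; algae die of old age at 24 months; the
smaller of two algae whose zones share at least half of the smaller zone
dies; and between an alga and a coral whose footprints overgrow one
another, the smaller-diameter individual is removed once its centre lies
inside the other's footprint. Yearly recruitment adds a Poisson realization
of 0.5 recruits m^-2 on the core arena.

The fragment establishment probability is the one closed-form calibration
in the package. At the herbivory threshold (5 % cover, grazing probability
0.25 per month) the stationary age structure gives 56 % adults producing
about six fragments per month each; balancing recruitment plus fragment
establishment against grazing removal at exactly 5 % cover yields an
establishment probability of 0.05. The test suite verifies the resulting
homeostasis empirically in an algae-only arena.

Turf is a 1 x 1 m grid of cover fractions: ungrazed cells grow 20 % per
month (from a 1 % recolonization floor, so disturbance scars can regrow —
a purely multiplicative rule would lock a scoured cell at zero forever),
grazed cells are halved.

### Herbivory

Grazing pressure is density-dependent through an increasing logistic in
macroalgal percent cover, anchored at 0.25 at the 5 % threshold with bounds
0.2–0.3 and slope 2. The probability computed from one month's cover is
applied in the next month (a one-step lag): each macroalga is removed with
that probability, and each turf cell is independently grazed with it.
Grazing removes whole algae — herbivory controls algal population density
rather than pruning individuals.

### Disturbance

Mechanical disturbances are circles that kill every organism whose centre
they contain and reset the turf beneath them: small events (2–4 m diameter,
anchor or small-boat damage) and large events (5–10 m, anchor chains, net
damage), each on its own interval (standard: 12 and 60 months). Event
centres are drawn uniformly on the arena *extended by the event radius*, so
interior cells are hit with equal probability — the test suite checks this
equal-area property with a chi-squared test.

### The monthly schedule

Each month executes, in a fixed, config-independent order: (1) thermal
check and bleaching draws; (2) scheduled disturbances; (3) per-axis
competition modifiers from the start-of-month configuration; (4) growth;
(5) interaction mortality — overgrowth, branch breakage, alga–coral
displacement; (6) macroalgal aging, growth, fragmentation, self-thinning
and (yearly) recruitment; (7) herbivory on algae and turf; (8)
reproduction and settlement; (9) the cover record. Each concern draws from
its own RNG stream, so disabling one process leaves every other process's
draws — and hence its trajectory — unchanged; the test suite exploits this
for differential tests.

## Outputs and metrics

`relative_cover()` reports, per month, each species' summed planar cover as
a percentage of the arena, counting overlapping colonies in full — the
total across groups can therefore exceed 100 %. `total_benthic` is the sum
over all simulated benthic components: the four corals, the macroalgae and
the mean turf cover. Including turf is a deliberate reading of "the sum of
the relative cover of all species": turf is a simulated benthic group, and
the reported long-run totals around 117 % under a standard disturbance
regime decompose naturally into roughly 86 % coral + 0.5 % macroalgae +
30 % turf, while coral-plus-macroalgae alone cannot exceed its geometric
packing ceiling of about 110 %.

## Study conditions and problem sizes

The full study protocol initializes every coral species at 10 % cover
(colonies drawn between spat size and 25 cm radius), macroalgae at 5 %, and
turf at 50 %, runs 1000 years and analyses the last 500, pooling 10
replicates. The package defaults mirror those conditions. The shipped
acceptance script (`scripts/acceptance.R`) runs a desk-scale version — 500
simulated years per replicate (300 for the rapid-collapse scenarios), the
last half analysed, 3 replicates with fixed seeds — which keeps a full
four-scenario reproduction under half an hour on one core; the test suite
uses 20 x 20 m arenas and 100–300 year horizons for the emergent-property
checks. Since initial-condition influence fades within the first 50–100
years, the truncation widens replicate scatter but does not move the
long-run means materially.

## What the generator does and does not emulate

The synthetic SST generator reproduces the seasonal cycle, modest
autocorrelated variability, and recurrent discrete extreme years of a
Western Indian Ocean fringing reef. It does not model multi-year trends,
ENSO-like irregular spacing, or within-reef thermal microhabitats; hot
years are strictly periodic, which makes scenario axes clean but removes
the stochastic clustering of real extreme events. Passing tests therefore
demonstrate the community model's response to a controlled forcing, not a
forecast for any real reef. Similarly, grazing is held quasi-constant
(herbivore populations are not modelled), so phase-shift dynamics that run
through herbivore collapse are outside this model's scope.

## Numerical and design notes

* Containment tests use an inscribed-circle accept / bounding-circle
  reject shortcut, falling back to exact polygon or star tests only in the
  rim annulus; the compiled kernels are deterministic and all randomness
  stays in R.
* Overgrowth and shelter are evaluated on the start-of-month configuration
  (one kernel pass per month); the one-month lag this introduces is far
  below the monthly growth scale.
* Ties in every size comparison resolve to the inferior branch; equal-size
  algal pairs remove the later-indexed individual, keeping runs
  deterministic.
* The fixed external input enters after retention, as recruits: published
  retention factors (1e-8 to 1.5e-7) would otherwise annihilate any
  plausible fixed larval count and disable the rescue pathway entirely.
* `sum / 20` window means (not raw sums) make the 20-day statistic
  commensurable with the threshold table.
* Initial colonies may overlap; the overgrowth rule prunes these within
  the first months, part of the discarded transient.

## Known limitations

Whole-colony mortality only (no partial mortality or fission); 2-D
geometry without structural complexity; a single macroalgal functional
type; periodic hot years; no acidification, nutrients, sedimentation or
disease. The split of cover between the two *Porites* species is sensitive
to the competition-index parameters and to the hot-year pulse shape;
between-scenario contrasts (rank order along perturbation axes, the
interior evenness maximum) are far more robust than any single species'
absolute cover.
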