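---
title: "Ediacaran oxygenation from rising tectonic degassing: the copsebox model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ediacaran oxygenation from rising tectonic degassing: the copsebox model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`copsebox` implements a COPSE-style global biogeochemical box model: a small
set of coupled ocean-atmosphere reservoirs (phosphate P, nitrate N, oxygen O,
carbon A, sulphate S, plus an ocean-sediment strontium pair) driven by
tectonic forcings and closed by nutrient-limited marine productivity,
weathering feedbacks and sediment burial. The crustal reservoirs (carbonate,
organic carbon, pyrite, gypsum) are held at their relative present-day size
throughout: over the ~100 Myr horizons considered here their fractional
change is negligible, and freezing them avoids coupling the model to the
mantle.

The science question the package is built around is whether a step increase
in tectonic CO~2~ and sulphur degassing between the late Neoproterozoic and
the early Phanerozoic, combined with an increase in uplift and erosion, can
raise atmospheric O~2~ enough to matter for early animal evolution — without
leaving a step in the carbonate carbon-isotope record. The mechanism is mass
balance: a larger carbon throughput forces a larger total burial flux, and if
the organic fraction of burial (`f_org`) stays roughly constant, O~2~
production rises while carbonate delta13C barely moves. The sulphur cycle
contributes in parallel through pyrite burial (2 mol O~2~ per mol S).

### Flux laws

All fluxes are written as a present-day constant times a dimensionless shape
factor normalised to 1 at the reference point (all relative reservoirs and
forcings at 1, present-day solar luminosity). The main laws:

* climate: `RCO2 = a^2` (a = relative atmosphere-ocean carbon), `deltaT =
  k_c ln(RCO2) - k_l t/570` with `k_c` set so one CO~2~ doubling yields the
  sampled climate sensitivity exactly;
* marine new production limited by the scarcer of N and P in Redfield
  proportion; organic carbon burial `mocb = k2 U newp'^2` (an optional
  direct O~2~ dependence `2.1276 exp(-0.755 o)` is off by default);
* the ocean anoxic fraction is a logistic in `0.5 newp' - o`
  (steepness 12), giving ~0.25% anoxia today and near-total anoxia in the
  nutrient-rich, low-O~2~ Ediacaran configuration;
* continental weathering of granite (erosion-dependent), basalt
  (erosion-independent), carbonate and gypsum, each scaled by
  temperature/runoff laws and a biota factor; oxidative weathering
  `oxidw = k17 U o^kappa` with the exponent kappa sampled in [0, 0.5];
* seafloor weathering `sfw = k_sfw D exp(k_T^sfw deltaT)`, with
  `k_T^sfw = E_sfw / (R T0^2)` from the sampled activation energy — the same
  linearised-Arrhenius convention is applied to granite and basalt so that
  the three sampled activation energies are commensurable;
* carbonate burial closes the alkalinity budget identically:
  `mccb = silw + carbw + mpsb - pyrw - pyrdeg` (clamped at zero and flagged
  under pathological draws);
* pyrite burial `mpsb = k_mpsb (s/o) mocb'`, gypsum burial `mgsb = k_mgsb s`;
  degassing of all four crustal reservoirs, and the reduced gas flux
  `rgf = k_rgf D` (H~2~, consuming 1 mol O~2~ per mol by default,
  configurable), are linear in the degassing forcing D.

Carbon and sulphur isotopes are tracked as moments (reservoir times delta),
with organic burial fractionated by `Delta_C = 27` permil and pyrite by
`Delta_S = 35` permil. The strontium system follows the ocean and sediment
inventories and their ^87^Sr/^86^Sr moments; crustal end-member ratios grow
by explicit ^87^Rb decay, calibrated so each rock type reaches its
present-day ratio exactly after 4.5 Gyr, and the sedimentary reservoir
additionally accumulates radiogenic Sr during a run with its Rb/Sr set by
the average crustal ratio 0.73.

### The biota factor and the pre-vegetation regime

All runs here are pre-vegetation (`V = 0`): land-plant weathering
enhancement and land organic burial are absent. We model the biota factor as
`V + (1 - V) * 0.15 * sqrt(RCO2)`: at the vegetated present it is 1 (so the
reference closure below holds), while with vegetation off continental
weathering carries an absolute abiotic deficit with a direct CO~2~
dependence. The equilibrium consequence is the expected one: Ediacaran CO~2~
sits at ~10-25 times present and the surface is several degrees warmer
despite a fainter sun. Land P routing and land organic burial are held at
zero at any V — the vegetation switch here affects weathering only.

### Closure construction

The sampled present-day fluxes are not mutually consistent, so each
parameter draw is completed by a closure that makes the present-day
reference point an exact steady state: total outgassing is split
carbonate:organic in the baseline 6.65:1.25 proportion; oxidative weathering
is derived from the O~2~ balance; silicate weathering is the residual of the
carbon balance given the seafloor-weathering baseline (1.75e12 mol/yr),
split basalt/granite by the sampled basaltic fraction; the sulphur residual
is absorbed into the effective gypsum-burial constant; and the
phosphorus/nitrogen cycles are closed against reactive-P weathering and
denitrification, with the non-organic P residual split Ca-bound : Fe-sorbed
as 1.5 : 0.6. Draws with a non-positive derived flux are rejected and
redrawn (logged); the dominant rejection mode is organic P burial exceeding
reactive P weathering (large sampled organic burial against the narrow P
weathering interval), which truncates the effective organic-burial marginal
at about 250 times the P weathering draw.

Because closure pins the non-organic P burial to a (usually small) residual,
the Ca-bound and Fe-sorbed pathways are weaker here than in the parent
model's fixed constants; essentially all reactive P ends up in organic
burial. This choice guarantees every ensemble member starts from a
physically consistent present day — the alternative (fixed burial constants,
inconsistent reference point absorbed by a long spin-up) matches the parent
model's procedure but leaves the closure identities untestable.

### Reactive-phosphorus weathering weights

Reactive-P delivery blends the silicate, carbonate and oxidative channels.
We weight them 2/12 : 5/12 : 5/12, the parent COPSE formulation. This is the
single most consequential structural choice in the package: with
silicate-dominated weights the P supply is insensitive to uplift while the
oxidative O~2~ sink scales linearly with it, and the 0.5 to 2 uplift ramp
then collapses O~2~ across the Ediacaran — the opposite of the behaviour the
experiment is designed to capture. With the carbonate/oxidative-weighted
blend, P supply tracks uplift and the uplift effect on O~2~ becomes mildly
positive here (slightly negative in the source model). The weights are
exposed in `copse_constants()$phosw_weights`.

## Numerical choices

* **State and solver.** The 7 mole inventories are integrated in log space
  (positivity by construction) alongside 4 linear isotope moments, with the
  adaptive stiff solvers of `deSolve` (`lsoda`, relative tolerance 1e-6,
  per-component absolute tolerances scaled to present reservoir sizes).
  Runs are split at forcing discontinuities, with output on a uniform 1-Myr
  grid. Halving the tolerance changes end-state O~2~ by well under 0.1%.
* **Spin-up.** Steady states are found by chunked integration (up to 10 Gyr)
  under frozen forcing and frozen solar term, declared converged when the
  largest relative rate of change falls below 1e-10 per year; non-converged
  results are flagged, never silently returned.
* **Sedimentary Rb decay.** The in-run decay term uses time elapsed since
  the start of the transient and is frozen during spin-up, so equilibration
  horizons do not inject spurious radiogenic growth.
* **Degenerate inputs.** A zero-width degassing window reproduces its
  midline for any seed; degenerate sampling intervals make the ensemble
  deterministic; the carbonate-burial clamp marks a run invalid once it has
  been active for more than 1 Myr cumulative.

## The synthetic forcings and what they do (and do not) represent

The degassing forcing emulates a reconstruction of global subduction-zone
length that is not available as a printed table. The default window rises
from 1.0-1.2 at 650 Ma to 1.4-1.6 at the Precambrian-Cambrian boundary
(midline 1.1 to 1.5, half-width 0.1), resampled uniformly every 10 Myr per
run; runs start at 650 Ma so the 640-620 Ma averaging window is covered.
Uplift ramps linearly from 0.5 to 2 (the constant-uplift variant sets both
ends equal). The absolute calibration of this window is the single largest
reproduction uncertainty in the package and should be treated as such when
comparing against published curves; a digitised node table can be supplied
as a CSV.

The pseudo-proxy generator produces scattered-age series with a linear
secular trend, Gaussian noise and boxcar excursions. It emulates the
*structure* of isotope compilations, not their sampling biases, diagenesis
or age-model error — trend-recovery tests on it validate the regression
machinery, not the geological interpretation of any real compilation.

## Reduced ensemble and what the tests show

The full experiment uses 10,000 Monte-Carlo members; the package's tests and
the acceptance script run 300 (about 2.5 minutes on one core), which is
ample for window means of ensemble means and for fractions-of-runs
statistics (binomial standard error about 1-3 percentage points). Runs are
seeded by a counter-based substream per run index, so results are
bit-identical regardless of execution order and adding members never
perturbs existing ones.

With the default configuration the model reproduces the qualitative
experiment faithfully: a low-O~2~ (~0.2-0.3 PAL), high-CO~2~, largely anoxic
early Ediacaran ocean; a monotonic degassing-driven O~2~ rise in every
ensemble member; near-flat carbonate delta13C; rising pyrite and gypsum
burial with little change in their ratio; and an ocean ^87^Sr/^86^Sr rise of
about 0.0015 driven by the uplift ramp. Quantitatively, the package's
uplift response of P delivery makes organic burial (and hence the O~2~ rise)
overshoot the source experiment by roughly a factor of two, and the larger
O~2~ rise feeds back to suppress the late-run pyrite-burial increase (the
`s/o` factor) below its reported ~1e12 mol S/yr. These deviations trace to
structural constants that are not printed anywhere in the source chain
(pre-plant weathering baseline, P-channel weights, P-burial partition), are
documented above, and are deliberately not re-tuned against the target
numbers; the corresponding acceptance checks are left failing rather than
widened.

## Limitations

* Global box model: no spatial redox structure; the anoxic fraction is a
  single logistic diagnostic.
* Pre-vegetation configuration only; the Phanerozoic forcing set of the
  parent model is not reproduced.
* Fixed crustal reservoirs; no mantle-crust coupling.
* The C:P ratio of buried organic matter is constant (250); anoxia-dependent
  P recycling variants would strengthen low-O~2~ regulation.
* Command-line orchestration is intentionally thin: the exported functions,
  the YAML config loader and `scripts/acceptance.R` are the interface.
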