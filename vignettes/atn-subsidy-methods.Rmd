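---
title: "Methods: non-autonomous ATN dynamics with a pulsed phytoplankton subsidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-autonomous ATN dynamics with a pulsed phytoplankton subsidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, and the numerical and design
choices that were genuinely open.

## The bioenergetic model

Allometric trophic network (ATN) models track biomass densities (g/m²)
through a pair of mass-balance equations. Producers grow logistically and
lose biomass to predation; consumers assimilate what they eat, pay a
metabolic cost proportional to their biomass, and are themselves eaten:

$$\frac{dB_i}{dt} = r_i B_i G(\mathbf B)
  - \sum_j \frac{x_j\, y_{ji}\, B_j\, F_{ji}(\mathbf B)}{e_{ji}}
  \qquad\text{(producers)}$$

$$\frac{dB_i}{dt} = f_a x_i B_i \sum_j y_{ij} F_{ij}(\mathbf B)
  - f_m x_i B_i
  - \sum_j \frac{x_j\, y_{ji}\, B_j\, F_{ji}(\mathbf B)}{e_{ji}}
  \qquad\text{(consumers)}$$

Two structural choices do most of the ecological work:

* **A community-level carrying capacity.** All producers share one logistic
  factor $G = 1 - \sum_{j \in \mathrm{producers}} B_j / K$. Producers
  therefore compete for a common resource pool (space, light, nutrients):
  when phytoplankton surges, every alga's realized growth rate drops. This
  single term is what transmits bloom damage to herbivores.
* **An intermediate Holling response.**
  $F_{ij} = \omega_{ij} B_j^q / (B0_i^q + d_i B_i B0_i +
  \sum_l \omega_{il} B_l^q)$ with $q = 1.2$, between Type II ($q=1$) and
  Type III ($q=2$). The interference term $d_i B_i B0_i$ makes crowded
  consumers less efficient, which is the only intraspecific density
  dependence consumers have.

All rates are per hour at run time. They are assembled per day from
allometric power laws of body mass ($r_i$, $x_i \propto m^{-1/4}$; the
maximum consumption multiple $y$ mass-independent) and divided by 24 in a
single explicit, guarded unit-conversion step — converting twice is an
error, not a silent no-op.

## The subsidy: three phytoplankton nodes and one-way mixing

The phytoplankton node of the input web is split into three:

* **OP** carries the scaled empirical (or synthetic) series $B_{op}(t)$.
  It has no differential equation and never appears in a functional
  response; it touches the web only through mixing.
* **FP** keeps the original node's consumers and its producer equation and
  receives $k_{mixing}(B_{op} - B_{fp})$ whenever $B_{op} \ge B_{fp}$, and
  nothing otherwise. The piecewise form makes the subsidy a one-way valve:
  intertidal phytoplankton is never exported. Both branches vanish at
  $B_{op} = B_{fp}$, so assigning the boundary to the flux branch is
  continuity-neutral.
* **Baseline detritus** is a constant pool (default 3,750 g/m²) with
  exactly FP's consumer set. It stands for particulate organic matter that
  the model does not otherwise track, and it is the floor that keeps
  filter feeders alive between blooms. It enters functional-response sums
  as an ordinary resource, but has no equation of its own, does not count
  toward the producer sum in $G$, and predation losses on it are simply
  discarded — it is a boundary condition, not a population.

### Scaling chlorophyll to biomass

The chlorophyll record arrives as a volumetric density (g/m³). The chain
from chlorophyll density to areal phytoplankton biomass — cells per unit
chlorophyll, mass per cell, water-column depth — collapses into one factor
$\alpha$ (metres) that is fixed by a conservation argument: over the whole
record, the subsidy potential must equal that of a reference model
delivering a constant 7,355 g/(m² day). Hence

$$\alpha = \frac{7355 \times 365 \times n_{years}}
               {\sum_{daily} \delta_{chloro}},$$

and none of the individual physical constituents is ever needed. On a
constant unit-density series $\alpha$ is exactly the daily subsidy — a
useful identity test.

The daily biomass samples are interpolated by a cubic spline and the
interpolant is evaluated directly wherever the integrator needs
$B_{op}(t)$ (hours). Evaluating the spline beats integrating its
derivative — mathematically the same curve, but immune to re-integration
drift. Negative spline excursions (inevitable near sharp pulses) are
clipped to zero; evaluation outside the record holds the boundary value.
Years are 365 days for the subsidy total; within a record, hours are
computed from true date offsets, so leap days are kept, not dropped. Gaps
are bridged by the spline, with a warning beyond 30 days.

## Simulation protocol

Each forcing year runs from an equilibrated start so that transients
reflect the forcing, not the initial condition. Strategy 1 equilibrates the
autonomous system (mixing off) for ten 365-day years; strategy 2 instead
runs against ten periodic copies of the year's forcing. On the built-in
fixtures both land in the same regime (tested), matching the expectation
that the protocol choice is not load-bearing; strategy 1 is the default.

Integration uses `deSolve`'s `lsoda` (adaptive, stiff-capable) with
relative tolerance 1e-8 and absolute tolerance 1e-10, sampled hourly. The
hourly clock in the model's units is a reporting and rate-unit convention,
not a mandate for fixed-step integration; pulses make the system stiff and
an adaptive method is the right tool. Fidelity is guarded by an
independent cross-check: a 10-species web run 30 days by `lsoda` agrees
with a fixed-step 4th-order Runge-Kutta oracle at dt = 0.01 h to a maximum
relative deviation below 1e-4 (observed ~1e-7).

**Extirpation.** A species whose biomass falls below 1e-6 g/m² cannot
plausibly recover without immigration. Crossings are caught by the
solver's root detection (biomass minus threshold), logged with their first
crossing time, and the species is clamped to exactly zero thereafter —
preventing numerical "resurrection" from sub-threshold values. Clamping is
switchable (`atn_scenario(clamp = FALSE)` logs without clamping), and the
binary survived/extirpated outcome is insensitive to the choice because
the clamp only binds after the threshold is reached. The FP node is exempt
from clamping: unlike a population, it has an external input (mixing) that
can legitimately rebuild it from nothing. Nodes already below threshold at
the start of a run are pinned at zero silently rather than logged as new
extirpations of that run.

## Summary statistics

* **Truncated, normalized CV.** Fluctuation sensitivity per species is the
  coefficient of variation (population convention, $\sigma_n / \mu$; at
  ~8,760 hourly samples the $n$ vs $n-1$ distinction is noise) computed on
  the series up to its terminal collapse — trailing sub-threshold samples
  are cut, a dip-with-recovery is not — and divided by the CV of the
  offshore series over the same window. Under clamping every crossing is
  permanent, so the two readings of "trailing zeroes" coincide. CVs are
  computed on hourly output by default; the report function accepts any
  OP series covering the window, so daily resampling is a caller-side
  choice.
* **Guild grouping.** Every node gets exactly one of: algae (producers),
  filter feeders (consumers of FP or the baseline pool), herbivores
  (plant-only diets), carnivores (animal-only), omnivores (mixed), plus
  phytoplankton and detritus labels for the special nodes. These rules are
  a reproducible default inferred from diet composition; a
  `guild_override` column in the species table wins where natural history
  says otherwise (e.g. scavengers).
* **Biomass ranges** summarize the envelope (min, max of group-summed
  biomass) over a window, and the extirpation scan tabulates focal-species
  status in a years-by-mixing-rates grid.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `a_r` | 1.0 | 1/d | producer growth at 1 g reference mass |
| `a_x` | 0.314 | 1/d | invertebrate metabolic constant (classic bioenergetic value) |
| `y` | 8 | – | maximum consumption as a multiple of `x` |
| mass exponent | -0.25 | – | quarter-power metabolic scaling |
| `e` plant / animal | 0.45 / 0.85 | – | assimilation efficiencies; detritus uses the plant value |
| `f_a`, `f_m` | 1, 1 | – | recover the standard bioenergetic consumer equation |
| `q` | 1.2 | – | intermediate Holling shape |
| `B0` | 1500 | g/m² | half-saturation density |
| `d` | 0.01 | 1/(g/m²) · (g/m²) scale | interference; see below |
| baseline | 3750 | g/m² | detrital floor for filter feeders |
| threshold | 1e-6 | g/m² | extirpation cutoff |
| `k_mixing` grid | 0.1, 1, 10 | 1/h | slow / intermediate / rapid surf-zone flushing |

The exact rate table of the empirical Las Cruces parameterisation is not
distributed with the package, so the defaults above are taken from the
bioenergetic food-web literature and are all config-driven
(`atn_default_config()`, YAML overlays via `read_config()`); the
structural tests are deliberately parameter-robust. Two defaults deserve
their rationale spelled out:

* **Interference `d = 0.01`.** With `d = 0` a consumer feeding on the
  constant detritus pool has no density dependence at all and grows without
  bound. The natural magnitude follows from the denominator of $F$:
  interference is comparable to resource saturation when
  $d\,B\,B0 \approx B0^q$, i.e. $d \approx B0^{q-2} \approx 0.003$ for
  biomasses near $B0$; 0.01 is moderate interference on that scale.
  Dimensionless-unit ATN studies use $d$ of order 0.1–1, which translates
  to this range once biomasses are measured in g/m².
* **Carrying capacity `K`.** A community property, estimated (when group
  data exist) as the species-count-weighted sum of the fastest-growing
  member's biomass per producer functional group, ties broken
  lexicographically for determinism. Fixtures set `K` explicitly.

## The synthetic generators

The package must be fully testable without the empirical record, so it
generates both sides of the problem:

* **Niche-model webs** (standard one-dimensional niche topology at target
  connectance) with validity enforcement: at least one basal species,
  every consumer fed and connected to a basal resource, no isolates, no
  self-links. The most-consumed basal species is designated phytoplankton.
  Body masses are where the ecology enters: macroalgae default to 10 g
  (intrinsic growth ~0.6/d — slow, so bloom suppression accumulates over
  days), phytoplankton to 1e-3 g (~5.6/d — an order of magnitude faster,
  so blooms are self-limited by the shared logistic term rather than
  passively tracking the ocean), and consumers climb a mass-ratio ladder
  from a 0.1 g grazer anchor (fast enough metabolically to pin
  phytoplankton at a grazed equilibrium). Without this fast-phytoplankton /
  slow-algae / small-grazer structure the mixing rate loses its biological
  role: the subsidy either tracks the ocean at any `k` or none.
* **Pulsed forcing series**: a baseline plus Gaussian-in-time bloom pulses
  with optional multiplicative lognormal noise, floored at zero. Real
  bloom records are irregular, multi-scale and skewed; only amplitude,
  duration and timing matter to the properties under test, and Gaussian
  pulses make those analytically controllable. Consequently, passing
  tests say the *mechanisms* (dose dependence, one-way valve, guild
  ordering) behave correctly — they do not certify reproduction of any
  specific empirical year.
* **The fixture suite** (`make_fixture_suite()`): `producer_only` (logistic
  limit: total biomass must reach `K`), `chain3` (an interior fixed point
  checkable by an independent Newton solve), `flat_forcing` (constant
  subsidy, for reduction-identity regressions), and `niche50_pulse` — a
  50-species web, fixed seed, with a designated focal herbivore and a
  three-peak pulse family (20,000 / 30,000 / 120,000 g/m²) spanning quiet,
  marginal and extreme bloom years. The marginal amplitude was chosen
  during fixture design so the focal herbivore survives slow mixing
  (k = 0.1/h) and dies under rapid mixing — the dose-dependence motif —
  and is fixed thereafter.

Why a mixing-rate effect needs those scales: during a bloom the food-web
phytoplankton settles where influx balances self-limitation,
$r_{fp} B_{fp}^2 / K \approx k B_{op}$, so its effective peak scales like
$\sqrt{k\,B_{op}\,K / r_{fp}}$ — a tenfold mixing difference is a
~threefold dose difference. The damage pathway is indirect: FP overshoot
drives $G$ negative, slow algae decay for days, and the herbivore starves
while its shared predators (fed by booming filter feeders) press harder.

## Numerical choices and degenerate inputs

* States are clipped at zero inside the right-hand side (`B^q` of a tiny
  negative solver excursion would be NaN); non-finite states abort with
  the offending index.
* The right-hand side exists twice: a per-node, loop-based reference
  (`producer_rhs`, `consumer_rhs`, `full_rhs`) and a vectorized
  matrix-product path used by the integrator (`build_sim_context`); their
  equality on random states is a standing test, so the fast path can never
  silently drift from the written equations.
* Trophic levels solve the linear system $TL = 1 + \bar{TL}_{resources}$
  directly, which handles feeding loops; self-links (cannibalism) are
  rejected at validation, a stricter stance than leaving their
  trophic-level treatment ambiguous.
* A web with no links at all is accepted only if it is producer-only (the
  logistic-limit fixture); any consumer in a linkless web is an error.
* Zero-duration equilibration returns the initial state unchanged; an
  empty mixing grid or year list yields an empty scan, not an error.

## Problem sizes

The test suite and the acceptance script run, by design, on: a 3-species
chain and 3-producer web (analytic cases), a 10-species web for the
integrator cross-check (30 days, fixed-step oracle at dt = 0.01 h), and the
50-species niche web for the scanning and guild analyses (10-year
equilibration + 1-year runs at three mixing rates and three bloom
amplitudes). These sizes keep the full suite around a minute on one CPU
while exercising every code path at the community scale the model targets
(~100 nodes is well within the same machinery).

## Known limitations

* No temperature or nutrient dependence of rates; no adaptive foraging
  (preferences $\omega$ fixed); no demographic stochasticity; no spatial
  structure within the shore.
* The guild rules are diet-composition heuristics; real assemblages need
  the override column for edge cases.
* The generator's masses and the global rate constants are literature
  defaults, not a fitted parameterisation of any real web; quantitative
  outputs (biomasses, CV magnitudes) are regime-level, not predictions for
  a named site.
* The one-way valve means the model cannot represent export of intertidal
  production to the ocean, which is a real (if usually secondary) flux.
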