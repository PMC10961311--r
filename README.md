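# atnsubsidy

Bioenergetic food-web simulation for intertidal communities fed by a
time-varying offshore phytoplankton subsidy.

Rocky-shore ecosystems in upwelling regions depend on pelagic phytoplankton
delivered by waves, tides and currents. That subsidy is anything but
constant: it arrives as pulses, varying over days to years. `atnsubsidy`
implements an allometric trophic network (ATN) model in which a daily
chlorophyll-a record (empirical or synthetic) drives the intertidal food web
through a one-way pelagic–intertidal mixing term, making the dynamics
non-autonomous. The package is aimed at community ecologists who want to ask
how subsidy variability and mixing rates reshape biomass fluctuations,
which species are pushed to local extirpation, and how sensitivity differs
across guilds.

## The model

Each producer and consumer population carries a biomass density `B_i`
(g/m²) obeying

    producers:  dB_i/dt = r_i B_i G(B)  - sum_j x_j y_ji B_j F_ji / e_ji
    consumers:  dB_i/dt = f_a x_i B_i sum_j y_ij F_ij  - f_m x_i B_i
                          - sum_j x_j y_ji B_j F_ji / e_ji

with a community-level logistic factor shared by all producers,

    G(B) = 1 - (sum of producer biomass) / K,

and a Holling functional response intermediate between Type II and III,

    F_ij = omega_ij B_j^q / (B0_i^q + d_i B_i B0_i + sum_l omega_il B_l^q),
    q = 1.2.

Rates scale allometrically with body mass (`r_i`, `x_i` as mass^-1/4 power
laws; `y` a fixed multiple of `x_i`), and the model runs on an hourly clock.

The phytoplankton node is split three ways:

* **OP (offshore phytoplankton)** — biomass prescribed by the scaled
  chlorophyll series `B_op(t)`; not a dynamic state, connected to the web
  only by water-borne exchange;
* **FP (food-web phytoplankton)** — keeps the original trophic links and its
  producer equation, plus the subsidy term

      + k_mixing (B_op - B_fp)   when B_op >= B_fp   (0 otherwise),

  so mixing is strictly one-way (nothing is exported off-shore);
* **baseline detritus** — a constant 3,750 g/m² particulate-organic-matter
  pool with exactly FP's consumer set, which keeps filter feeders alive
  through low-subsidy spells.

The chlorophyll record (g/m³) becomes areal biomass (g/m²) through a single
scaling factor `alpha` (metres) chosen so the record's total subsidy
potential matches a reference model that delivers a constant 7,355
g/(m² day): `alpha = 7355 * 365 * n_years / sum(daily chlorophyll)`.
A species whose biomass falls below 10⁻⁶ g/m² is considered locally
extirpated and clamped to zero.

## Worked example

The built-in fixture suite carries a 50-species niche-model web (seeded, so
always identical) with a split phytoplankton node, a designated focal
herbivore, and a family of bloom-pulse forcing series whose peaks span quiet
to extreme years:

```r
library(atnsubsidy)

nf <- make_fixture_suite()$niche50_pulse
forcings <- lapply(nf$peak_family, nf$make_forcing)
names(forcings) <- paste0("peak", nf$peak_family)

scan <- scan_mixing(nf$web, nf$params, forcings,
                    k_grid = c(0.1, 1, 10), init = nf$init)
extirpation_table(scan, nf$focal)
#> # A tibble: 3 × 5
#>   year       peak_op k10   k1    k0.1
#>   <chr>        <dbl> <chr> <chr> <chr>
#> 1 peak120000  120500 "e"   "e"   "e"
#> 2 peak20000    20500 ""    ""    ""
#> 3 peak30000    30500 "e"   "e"   ""
```

Each row is one simulated year (labelled by its bloom peak, in g/m²); an
`"e"` marks a run in which the focal herbivore was extirpated. Survival is
dose-dependent: quiet years are safe at any mixing rate, the moderate bloom
kills only under intermediate-to-fast mixing, and the extreme bloom kills
everywhere. Slow exchange (`k = 0.1` h⁻¹) buffers the shore from all but the
most extreme blooms.

Per-species fluctuation sensitivity, normalized to the offshore signal:

```r
eq <- equilibrate(nf$web, nf$params, atn_scenario(), nf$init)
tr <- run_year(nf$web, nf$params, nf$forcing, eq,
               atn_scenario(k_mixing = 1))
op <- evaluate_forcing(nf$forcing, tr$times)
cv <- normalized_cv_report(tr, op, nf$guilds)
dplyr::summarise(dplyr::group_by(cv, guild),
                 median_cv = median(cv_norm, na.rm = TRUE))
```

At every mixing rate the carnivore guild shows the highest normalized CV
(0.54–0.68 across `k`) and algae the lowest (0.14–0.19): top predators
amplify subsidy fluctuations, massive algal stocks damp them.
`autoplot(tr, guilds = nf$guilds)`, `autoplot(nf$forcing)` and
`autoplot(cv)` give quick ggplot views of trajectories, forcing and CV
distributions; `tidy()`/`glance()` return long-form and one-row summaries.

A thin command-line wrapper covering the same workflow (synthesize a web and
a forcing series, simulate, scan, analyze) lives at `inst/cli/atn.R`:

```sh
Rscript inst/cli/atn.R synth-web --s 50 --c 0.12 --seed 7 --out-prefix web
Rscript inst/cli/atn.R synth-forcing --days 365 --baseline 3 \
    --pulse 300:15:120 --seed 7 --out chloro.csv
Rscript inst/cli/atn.R simulate --web web_species.csv --edges web_edges.csv \
    --chloro chloro.csv --kmix 1.0 --out traj.csv
```

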