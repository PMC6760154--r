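---
title: "Metabolic model control: model-driven nutrient feeding for algal cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic model control: model-driven nutrient feeding for algal cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcontrol)
```

## The control problem

Fed-batch microalgal cultures (the motivating organism is *Chlorella
vulgaris*) are usually either bulk-charged with nutrients up front or fed on
fixed empirical rules. Both overfeed: nitrate and glucose are significant
cost drivers, and surplus nitrogen ends up as pollution. Metabolic model
control (MMC) replaces the empirical rule with a constraint-based metabolic
model of the cell. The loop at each feeding time point is:

1. estimate the specific growth rate from the last two optical-density
   readings, `mu = ln(OD_t / OD_(t-1)) / dt`;
2. fix the model's biomass flux to that rate (`lb = ub = mu` on the biomass
   pseudo-reaction);
3. invert the usual FBA objective: instead of maximizing growth, *minimize*
   the uptake flux of the nutrient being controlled (nitrate under
   autotrophy; glucose then nitrate lexicographically under heterotrophy);
4. convert the minimized flux into a mass of nutrient to add for the next
   interval, and feed it.

Because the biomass reaction consumes precursors in proportions fixed by the
cell's macromolecular composition, the minimized uptake is exactly the
stoichiometric requirement of the observed growth — no more. Feeding that
amount (scale factor 1.0) should match bulk-fed growth on strictly less
nutrient; feeding 80% of it should starve the culture; feeding 120% should
buy nothing. That three-way ordering is the package's main closed-loop
correctness check.

## The model layer

`metabolic_network` holds the stoichiometric matrix `S` (metabolites x
reactions), flux bounds, a tagged biomass reaction, and a nutrient-name to
uptake-reaction map — everything the controller reads. Models come from
three sources: the built-in toy network (`build_toy_model()`), the JSON
model dialect (`model_from_json()`), or SBML (`load_sbml()`, FBC v2 bounds
with a legacy kineticLaw fallback).

The genome-scale models used in the motivating work have thousands of
reactions and are not redistributable here; the controller, however, only
ever consumes two numbers per solve (the growth flux and an uptake flux), so
it is model-agnostic. The toy network preserves exactly the quantities MMC
reads while staying small enough to verify by hand:

* uptake reactions for nitrate, glucose, photons and CO2;
* nitrogen and carbon assimilation into abstract `Nunit`/`Cunit`
  bookkeeping metabolites (1 mmol N per mmol nitrate; 6 mmol C per mmol
  glucose; CO2 fixation consumes 2 photons per C so that heterotrophic
  variants — photon bound 0 — cannot fix carbon);
* an ATP pseudo-metabolite (photon-driven under autotrophy; glucose
  respiration yields 30 ATP and releases 6 CO2 under heterotrophy);
* one synthesis reaction per macromolecule class (amino acid, carbohydrate,
  lipid, chlorophyll, nucleotide, other), each consuming its nitrogen and
  carbon content plus 0.5 ATP per gram;
* a biomass reaction consuming `fractions[m]` gram of each class per gDW.

The biomass nitrogen demand is therefore `sum(fractions * n_content)` mmol
N/gDW, and nitrate minimization at fixed `mu` returns `demand * mu` exactly
when nitrate is the sole N source — the identity the unit tests pin down.
Internal reactions balance N and C exactly (`validate_mass_balance()`);
exchange and biomass columns exchange mass with the environment and are
exempt.

### Composition defaults and composition editing

The built-in compositions (`default_composition()`) describe a
nitrogen-replete autotrophic cell ("PAT1"-like, 45% amino acid), a replete
heterotrophic cell ("HT1"-like, 40%), and a nitrogen-starved cell
("PAT5"-like, 16% amino acid). Only the 16% figure is anchored in the
motivating study's model family; the other fractions are this package's own
realistic defaults and are documented as placeholders — the original
composition vectors live in that study's supplementary material and are not
transcribed here. Two deliberate simplifications: all cellular nitrogen is
bookkept in the amino-acid pool (11.1 mmol N/g protein, i.e. ~16% N by
mass), so nitrate demand scales directly with protein content; and carbon
contents are generic literature-scale values.

`set_amino_acid_fraction()` derives reduced-protein variants (16% to 10% or
2%) for nitrogen-limited operation: the amino-acid fraction is set to the
target and every other fraction is rescaled by `(1 - target)/(1 - old)` so
the composition stays normalized; the biomass column is rebuilt. The edit is
involutive to round-off, which the property tests check.

## The LP engine

`solve_fba()` optimizes one flux subject to `S v = 0` and bounds. No
installed LP package proved usable, so the package carries a dense two-phase
primal simplex with Bland's anti-cycling rule. Design notes:

* variables are shifted by their lower bounds and upper bounds become slack
  rows, so every variable is bounded and phase-2 pivots cannot be unbounded;
* pivot tolerance 1e-9; phase-1 feasibility accepted below 1e-7; optimal
  solutions are checked to satisfy `max |S v| < 1e-7` in the tests;
* non-finite bounds are clipped to +/-1000 (the convention genome-scale
  models themselves use); if an optimum lands on a clipped bound of the
  objective reaction the status is reported `"unbounded"`;
* degenerate alternate optima are accepted: the controller consumes the
  objective *value*, which is unique, and no flux-uniqueness post-processing
  (pFBA-style) is attempted.

The engine is verified against an independent oracle: exhaustive vertex
enumeration of the feasible polytope on random networks of up to six
reactions (an LP optimum is always attained at a vertex of a bounded,
nonempty polytope).

`lexicographic_minimize()` implements the heterotrophic two-stage
minimization: glucose first, then nitrate with glucose fixed at its optimum.
Fixing uses an equality window of 1e-12 — wide enough to absorb float noise,
narrow enough that later stages provably cannot degrade earlier optima by
more than that (the stability tests require drift below 1e-9).

`minimize_uptake_at_growth()` fixes growth as a hard equality, matching the
procedure the loop describes; when the requested rate is infeasible (for
example under a binding glucose cap) the controller falls back to
`feasible_growth()`, i.e. `min(mu_target, max achievable mu)`.

## The glucose-uptake cap

At high cell density, observed glucose consumption decouples from model
predictions — cultures take up less than growth demand predicts, whether
through oxygen-transfer limits or transporter saturation (the package
deliberately does not model which; only the phenomenological cap matters to
control). `fit_uptake_cap()` fits an ordinary least-squares polynomial of
uptake flux against accumulated biomass. Defaults and rationale:

* degree 2 — the lowest degree that captures saturation followed by
  decline; configurable because the original fit's degree and coefficients
  were never published (its quality, R^2 = 0.947, is known, so property
  tests substitute for coefficient checks: exact recovery on noiseless
  quadratics, OLS-oracle agreement under noise, nested-model R^2 ordering);
* regressor `integrated_biomass` (gDW/L x h) following the construction the
  source describes, with plain biomass concentration as the simpler option;
* evaluation clips at zero — uptake capacity cannot be negative;
* volumetric rates (mg/L/h) are converted to specific fluxes with the mean
  biomass of each interval before fitting (`uptake_series()`).

`apply_uptake_cap()` writes the evaluated cap into the glucose uptake upper
bound. A binding cap makes the OD-estimated growth rate infeasible; the
controller then predicts at the capped feasible rate, which simultaneously
lowers the nitrate feed — both restrictions propagate through one
`feasible_growth()` call.

## Flux to feed mass

A flux is per gram dry weight per hour; a feed is mg/L. The conversion
integrates demand over the upcoming interval assuming exponential biomass at
the estimated rate:

`mass = flux * MW * X0 * (exp(mu dt) - 1) / mu`,

with the limit `flux * MW * X0 * dt` below `|mu| = 1e-9`. The exponential
assumption is the minimal one consistent with having constrained FBA to `mu`
over the interval; a constant-biomass variant is available
(`method = "constant"`). The closed form is tested against high-resolution
numerical quadrature across a grid of `mu` (including signs and the zero
limit), `dt` and `X0` to 1e-6 relative.

Biomass concentration comes from OD750 via `od_to_gdw`, default 0.4 gDW/L
per OD unit — an approximate pairing of late-culture OD ~1.3 with ~520 mg/L
dry biomass; it is a config value and should be overridden per instrument.
Molecular weights default to 62.00 (nitrate anion) and 180.16 mg/mmol
(glucose). Feed volumes are treated as negligible (feeds are assumed to come
from concentrated stocks); the package does not bookkeep volume changes.

Policy decisions: a non-positive growth estimate feeds nothing (cultures
that shrink are never fed; the prediction is flagged `mu_floor`), and the
controller takes explicit feed times — deciding *when* to feed (e.g. when a
measured concentration hits zero) is left to measurements or the simulator,
not to the model.

## The virtual culture

`sim_step()`/`run_closed_loop()` implement a discrete-time quota
(Droop-flavored) cell, not a dynamic-FBA culture. The quota form is the
point: nitrogen can be taken up faster than growth incorporates it (luxury
uptake into the protein pool) and growth is driven by the internal protein
fraction, which is exactly the storage phenomenology a pure FBA cell cannot
show and the failure mode the controller must tolerate. Rules:

* growth rate `mu_max * (p - p_min)/(p_target - p_min)` clipped to [0, 1],
  gated to zero below `p_min` (default 0.10 — the observed protein fraction
  below which growth stops);
* nitrogen uptake replenishes protein toward `p_target`, bounded by an
  uptake capacity (`v_n_max`) and by the medium pool; with feeds matching
  demand the pool returns to ~0 by interval end, reproducing the
  near-zero residual nitrate measured in controlled cultures;
* with an empty pool, protein is diluted by growth and additionally
  degraded at `k_deg` (default 0.005 1/h, recycling into storage products),
  which drives the quota through the 10% threshold in finite time — the
  starvation plateau;
* heterotrophic growth is additionally limited by the glucose pool and by
  the same uptake-cap curve the controller uses;
* biomass updates exponentially within a step, so a replete culture grows by
  exactly `exp(mu_max dt)` and pool bookkeeping is exact
  (`pool_out = pool_in + feed - uptake`, asserted identically in tests).

The internal step is 0.5 h regardless of feed cadence, keeping the
discretization error of the nutrient coupling far below the quantities the
closed-loop tests compare. Observation noise is multiplicative lognormal on
OD (truncated Gaussian on concentrations), always under an explicit seed.

What the simulator does *not* emulate: absolute OD curves of real cultures,
light-field effects, pigment/lipid synthesis kinetics (product yields enter
only as ledger arithmetic), or volume changes. Passing closed-loop tests
therefore demonstrate controller correctness against the stated
phenomenology — not predictive accuracy for a particular wet culture.

### Study conditions used in the closed-loop tests

The closed-loop checks run the conditions of the motivating experiments at
desk scale: initial biomass 0.032 gDW/L (OD 0.08), `mu_max` 0.018 1/h,
25 mg/L initial nitrate for controlled cultures vs a 250 mg/L bulk charge,
feeds every 24 h over a 168 h horizon, feed scales 0.8/1.0/1.2. The
starvation comparison runs 549 h with `mu_max` 0.006, starting from a
nitrogen-starved composition (protein fraction 0.16) and a 10%-amino-acid
controller model. These sizes keep every simulation in seconds on one CPU.

## Feed accounting

`feed_ledger()` tracks initial charges and feed events; totals use
compensated (Kahan) summation so thousand-event schedules stay exact to
1e-9. `savings_percent()`, `percent_increase()` and `average_feed_rate()`
implement the comparative arithmetic used to evaluate strategies; all return
unrounded values, with `report_percent()` providing the integer-rounded
reporting form. Whether an initial charge counts toward "total supply" is
ambiguous in practice, so `cumulative_total()` exposes `include_initial` and
both variants are reported. Note one standing rounding quirk in the
reference comparisons: 36 mg/L over 549 h is 0.0656 mg/L/h, commonly quoted
as 0.06 — the package reports unrounded.

## Known limitations

* The toy network is a bookkeeping model: it reproduces stoichiometric
  demands, not pathway structure; shadow prices and flux distributions are
  not meaningful beyond the controlled uptakes.
* SBML support covers the FBC v2 / legacy-bounds subset used by
  constraint-based models, not full SBML semantics (no rules, events, or
  compartment volumes); composition editing is unavailable for SBML-loaded
  models because their biomass coefficients are opaque.
* The simplex is dense and intended for networks up to a few hundred
  reactions; genome-scale models will solve, but slowly.
* The uptake cap is phenomenological; it does not distinguish oxygen
  limitation from transporter saturation and should be refit per strain and
  reactor.
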