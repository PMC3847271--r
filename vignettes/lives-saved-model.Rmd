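---
title: "The lives-saved projection model: assumptions, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lives-saved projection model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livesaved)
```

# The model and its assumptions

`livesaved` implements a linear, deterministic intervention-impact model.
The overarching assumption is that mortality rates and cause-of-death
structures do not change dynamically: every difference between scenarios is
driven solely by intervention coverage. Distal drivers (income growth,
maternal education) are assumed to act *through* coverage and are not
modeled. Identical inputs always yield identical outputs.

Three mechanisms make up the engine.

**1. Impact terms.** Each intervention holds cause-specific efficacies
$E_{c,b}$: the fraction of cause-$c$ deaths in band $b$ removed by a full
(100-point) coverage change. In a scenario year its impact term is
$I = \Delta C \times E$, with $\Delta C$ the signed coverage change from
baseline. Defining efficacy against *cause-specific* rather than all-cause
mortality is what makes multi-intervention combination possible.

**2. Residual-deaths combination.** Interventions acting on the same
(cause, band) apply sequentially to the deaths remaining after earlier
ones, which collapses to the product

$$D_{\text{residual}} = D_{\text{base}} \prod_i (1 - I_i).$$

This cannot double count: with impacts of 0.25 and 0.25 on 10,000 deaths
the residual is $10{,}000 \times 0.75 \times 0.75 = 5{,}625$, not
$10{,}000 \times 0.5 = 5{,}000$. The product is invariant to the order of
application (a property the test suite verifies over randomized impact
sets); bounded below by the additive bound $D(1-\sum I_i)$ and by zero; and
monotone, in that strengthening any one impact never increases the
residual. Negative $\Delta C$ (coverage decline) yields factors above 1 and
deaths rise — the natural extension of the same formula, which we permit
and document rather than forbid.

**3. The age cascade.** Outcomes are tracked in seven bands: stillbirths,
maternal deaths, and the child chain 0–1, 1–5, 6–11, 12–23 and 24–59
months. Within a projection year, each child band's survivors are the next
band's entrants, so upstream mortality gains raise downstream *counts*
while leaving downstream *rates* (deaths/entrants) exactly unchanged. Both
halves of that statement are asserted to 1e-12 in the tests. The maternal
band runs in parallel on live births and has no cascade descendant —
maternal deaths do not feed back into births, since fertility modeling is
out of scope.

# Inputs and their units

| Input | Units | Notes |
|---|---|---|
| `neonatal_mortality` | deaths / 1,000 live births | |
| `child_1_59m_mortality` | deaths / 1,000 live births | whole 1–59 m window |
| `stillbirth_rate` | / 1,000 **total** births | see denominators below |
| `maternal_mortality_ratio` | / 100,000 live births | |
| cause structures | fractions summing to 1 per band | frozen at base year |
| coverages, efficacies | decimal fractions in [0, 1] | never percentage points |
| `live_births` | count per year | exogenous; no demography module |

Machine inputs and outputs are always decimal fractions; percentages appear
only in human-readable summaries. This is deliberate — keeping one unit
convention across every file format eliminates the %-versus-fraction bug
class entirely.

Causes are free tokens, not a fixed list: the intervention catalog is
user-supplied configuration, and whatever causes it references (plus those
in the profile's structures) define the cause vocabulary. HIV/AIDS can only
appear as an ordinary user-defined cause; there are no epidemic dynamics.

# Tunable parameters and defaults

**Sub-band weights.** The 1–59 month mortality input is a single rate, but
deaths are modeled in four sub-bands with higher risk at younger ages. The
shipped split — `M1_5` 0.45, `M6_11` 0.25, `M12_23` 0.18, `M24_59` 0.12 —
is an illustrative, front-loaded default, *not* an empirical estimate;
override it with country-specific weights whenever you have them. Weights
must be non-negative and sum to 1.

**Trajectory interpolation.** Scenario files may give explicit per-year
coverages, or anchor pairs expanded with `expand_trajectory()`, which
interpolates *linearly* between endpoints (50% in 2013 to 95% in 2015 gives
72.5% in 2014) and holds the target constant afterwards. Linearity is the
simplest defensible default for a scale-up path; step changes are available
by listing per-year values explicitly.

**Stillbirth denominators.** Stillbirth rates are conventionally expressed
per total births, while the demographic input is live births. We back-derive
total births as $\text{live} / (1 - \text{SBR}/1000)$ and apply the rate to
that; the stillbirth band's "survivors" are the live births. Stillbirth
survivors do not cascade into the neonatal band — neonatal entrants are the
exogenous live-birth count — so a stillbirth-prevention scale-up does not
inflate later cohorts.

# The period approximation

All bands in projection year $t$ experience year-$t$ coverage, and the
cascade (survivors feeding the next band) is resolved *within* the same
projection year, rather than tracking lagged birth cohorts across calendar
years. A child born in 2013 does not, in reality, pass through the 24–59
month band in 2013; the period form treats each year as a synthetic cohort
experiencing all bands at that year's coverage. We chose it because it is
simpler, reproduces every qualitative property the model is specified by
(cascade direction, rate invariance, frozen structure, linearity in
births), and keeps year-by-year output interpretable as steady-state rates.
A cohort-lagged mode is explicitly a non-goal; results for fast-changing
trajectories will differ from a lagged implementation during the transition
years.

# Attribution rules

Attribution answers "who gets credit" for each cell's averted deaths:

1. **Preventive first.** The preventive block's combined effect
   $D(1 - \prod(1-I_i))$ is computed on the full pre-intervention pool.
2. **Curative on the residual.** The curative block acts on
   $D\prod(1-I_i^{\text{prev}})$.
3. **Proportional within block.** Within each block, shares are
   $I_i / \sum_j I_j$. Impacts 0.08 and 0.05 share 61.5% / 38.5%.

By construction the attributed counts sum exactly to the total deaths
averted by all impacts combined — no leakage, no double counting — which
the suite property-tests over randomized catalogs. Within-block delivery
stage ordering is retained in the output for readability but does not
affect the allocation: the within-block rule is purely proportional. (An
alternative reading would sub-sequence within blocks by stage; we follow
the proportional rule, which matches the canonical two-intervention worked
example, and note the ambiguity here.)

Two documented extensions where the basic rules are silent:

* **Mixed-sign blocks.** Shares use signed impacts. If a block's impacts
  sum to exactly zero while individual terms are nonzero, the block
  attributes zero to every member and a warning is emitted — there is no
  principled way to split a net-zero effect.
* **Cohort effects.** Downstream death *increases* caused by upstream
  survival are reported as separate `cohort_effect` rows in the
  attribution table, never charged to (or credited against) interventions.
  Attributed rows plus cohort rows reconcile exactly with total lives
  saved.

The baseline-coverage normalization used by fuller production models
(discounting efficacy for the coverage already embedded in baseline
mortality) is intentionally not implemented: this engine uses the plain
$\Delta C \times E$ form throughout. Likewise no herd effects, affected
fractions, or coverage-interaction terms: impacts are independent
multiplicative factors, and the product form is the only cap on combined
impact.

# Numerical choices

* Deaths are carried as real numbers end to end; rounding happens only at
  report formatting (CSV floats at 6 decimals). The canonical worked
  examples (7,500; 5,625) are exact under real arithmetic.
* Validation tolerances: cause-structure and weight sums to 1e-9; ledger
  conservation (entrants = deaths + survivors) to 1e-9 relative; rate
  invariance under the cascade to 1e-12.
* Degenerate inputs: zero rates give zero deaths; a zero-entrant band gives
  zero deaths and survivors; an empty impact set is the identity;
  `base_entrants = 0` short-circuits the scaling ratio to 0.
* Ties in impact ordering (same category and stage) break lexicographically
  by intervention id, so output ordering is deterministic.
* Result CSVs use a fixed column order and fixed 6-decimal float format, so
  identical inputs produce byte-identical files.

# What the synthetic generator emulates — and what it does not

`fixture_spec()` / `make_profile()` / `make_catalog()` / `make_scenario()`
generate deterministic, structurally valid input sets: rates drawn
uniformly from high-burden-setting bounds (neonatal 15–40 per 1,000, 1–59 m
20–80 per 1,000, stillbirth 10–30 per 1,000, maternal 100–800 per 100,000;
500,000 births/year over a five-year horizon), cause proportions drawn then
normalized, coverages uniform in [0, 1]. All randomness flows from one
explicit seed and the global RNG state is left untouched.

These fixtures emulate the *structure* of national input sets, not their
content: real cause structures are correlated with rate levels, real
coverage trajectories are autocorrelated and policy-driven, real efficacy
values come from systematic evidence review, and real births vary by year.
Passing tests therefore demonstrate that the engine's arithmetic,
invariants and interfaces are correct on any valid input — not that any
particular projection for a real country is accurate, which depends
entirely on the quality of user-supplied rates, structures and efficacies.
`demo_fixtures()` is the exception: its numbers are chosen so the base-year
1–5 month band carries exactly 10,000 diarrhea deaths and the pneumonia
pair reproduces the canonical impact terms 0.08/0.05, making the desk
examples executable end to end.

Problem sizes in the test suite — 1,000 random impact sets, 500 random
attribution cells, 100 randomized two-year projections, 1,000 generator
seeds — were chosen as comfortable coverage for property testing on a
single CPU.

# Known limitations

* No demographic projection: births are an exogenous map, with no
  fertility, migration or population-structure feedback, and maternal
  deaths do not reduce subsequent births.
* No risk-factor mediation (stunting, wasting, birth outcomes) and no
  birth-risk-category redistribution; efficacy acts directly on
  cause-specific deaths.
* The period approximation (above) is not a lagged-cohort model.
* The shipped intervention catalog is a small illustrative fixture; the
  engine is agnostic to the catalog's content and ships no empirical
  effectiveness database.
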