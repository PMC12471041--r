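---
title: "Age-stage two-sex life tables: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twosexlt)
```

## The problem

Classical female-only life tables mis-state the demography of species in
which males are numerous, sexes develop at different rates, or treatments
shift the sex ratio — all of which happen in sublethal-toxicology assays
on holometabolous pests such as the tomato leafminer. The age-stage,
two-sex framework avoids this by indexing survival and fecundity by age
*and* stage, with the adult stage split by sex, so every individual of the
initial cohort stays in the accounting from oviposition to death.

`twosexlt` implements that framework from raw individual records (one row
per insect: stage durations in days, sex, fate, daily egg counts), with an
individual-resampling bootstrap for uncertainty, a calibrated synthetic
data generator, the accompanying endpoint statistics, and a reproducible
pipeline.

## Data model and day-counting conventions

These conventions are fixed and every formula below depends on them:

* **Age origin.** Age `x = 0` is the day the individual was laid as an
  egg. Total pre-oviposition period (TPOP) is therefore measured from the
  egg, while the adult pre-oviposition period (APOP) is measured from
  emergence; `TPOP ≈ preadult duration + APOP` by construction.
* **Daily census.** All durations are whole days; there is no sub-day
  resolution. An individual's lifespan is the number of age-days on which
  it was alive.
* **Half-open stage boundaries.** An individual with `egg_d = 3` is in the
  egg stage on ages 0, 1, 2 and in the larval stage on age 3: stage
  transitions are credited to the later stage on the transition day.
* **Deaths mid-stage.** The recorded duration of the fatal stage is the
  number of days actually survived in it. Preadult deaths are unsexed
  (`sex = "undetermined"`); consequently the stage ladder egg → larva →
  pupa → {female, male} has five states plus death.
* **Fecundity attribution.** Eggs are credited to the mother's age-day of
  laying, not to the offspring's birth cohort.
* **Missing values.** In the CSV interchange format a stage never entered
  is an empty field; a literal `NA` token is rejected to keep the dialect
  unambiguous.

## Life-table quantities

With `n` the initial cohort size, `s_xj` is the observed fraction of the
cohort alive in stage `j` at age `x`. Then `l_x = Σ_j s_xj`, and with
`f_x,female` the eggs laid at age `x` per living female adult,
`m_x = Σ_j s_xj f_xj / Σ_j s_xj`. Two identities are exact by
construction, and the test suite asserts them for arbitrary cohorts:

* `l_x m_x` equals (eggs laid at age `x`)/`n`, so
  `R0 = Σ_x l_x m_x = total eggs / n`, which also equals mean eggs per
  emerged female times the female fraction of the cohort
  (`R0 = F · Fn/n`): offspring conservation.
* `e` at `(0, egg)` equals the cohort mean lifespan.

### The Euler-Lotka root

`r` solves `Σ_x e^{-r(x+1)} l_x m_x = 1`. The `(x+1)` exponent is the
convention of the age-stage literature with age indexed from 0 (a
newborn's first reproduction can occur no earlier than its first full
day); `λ = e^r` and `T = ln(R0)/r` follow from the same convention. The
left side is strictly decreasing in `r`, so the root is unique whenever
`R0 > 0`.

Numerics: bisection on `[-1, 2]` (widened adaptively for pathological
schedules), 100 halvings, then a short Newton polish; the residual at the
returned root is required to be below `1e-10` and is reported in the
output. Degenerate cases are flagged rather than silently patched:
`R0 = 0` leaves `r`, `λ`, `T` undefined; `R0 = 1` gives `r = 0` exactly
and `T` is then reported by the limit convention `Σ_x x · l_x m_x / R0`.

### Life expectancy and reproductive value

`e_xj` and `v_xj` are computed by the hypothetical-cohort construction
that is standard for age-stage tables: a unit of survival is placed at
`(x, j)` and propagated forward with the empirical daily transition
probabilities estimated from the observed records (stay, advance — with
the pupa branching by sex — or die). `e_xj` is the propagated mass summed
over all later ages and stages; `v_xj` discounts the propagated cohort's
per-capita fecundity at rate `r`:
`v_xj = e^{r(x+1)} Σ_{i≥x} e^{-r(i+1)} Σ_y s'_iy f'_iy`. The printed
formulas for these two quantities circulate in several typographically
mangled variants; the package states its convention in the output
metadata (`exj_vxj_convention`) so results are interpretable without
guessing. This construction requires record-level transition counts, which
is why `life_expectancy()` and `reproductive_value()` take the cohort
rather than the marginal `s_xj` matrix.

Two facts about `e_xj` that users should expect: under the day-counting
convention every occupied cell has `e ≥ 1` (the current day counts), and
the empirical curves *fluctuate* near the tail of each stage, because
terminal cells hold few individuals and their estimated hazards are
noisy. Strict monotonicity in age within a stage is **not** an invariant
of the empirical estimator and is not asserted; the tests check the
guaranteed bound (remaining life cannot fall by more than one day per day
of age) and a strongly negative trend over the adult stage instead.

### Bootstrap

The resampling unit is the whole individual with its complete history: a
replicate draws `n` ids with replacement and recomputes everything. This
choice is validated by a closed form — for the 20-individual control
design with preadult survival 0.95 the bootstrap SE of `Sa` must converge
to `√(0.95·0.05/20) = 0.0487`, and the SD of the female count to
`√(20·0.45·0.55) = 2.22` — which the acceptance tests check at
`B = 100,000`. The reported SE is the bootstrap SD (not a percentile
half-width); 95% percentile intervals are reported alongside. Replicates
in which a parameter is undefined (no reproducing female drawn, so
`R0 = 0`) are excluded from that parameter's aggregation and counted in
`valid_B`. `R0` itself is defined (0) in every replicate.

Replicate index matrices are drawn from one seeded stream in fixed blocks
of 10,000, so results are bit-for-bit reproducible in `(cohort, B, seed)`
regardless of machine. The conventional published `B` is 100,000 (about
six seconds for an n = 20 cohort with the vectorised implementation);
tests use 2,000–10,000 with Monte-Carlo tolerances stated inline.

## The synthetic generator

`default_params()` carries one calibrated parameter set per dose group
(0, 3, 30, 300 mg L⁻¹) whose expectations match the reported treatment
summaries: stage durations (e.g. larva 7.4 d control → 11.8 d high dose),
preadult survivorship (0.95 → 0.40), cohort female fraction (0.45 → 0.15),
per-female fecundity (208.22 → 47.33 eggs), APOP and oviposition days.
Design choices, fixed once:

* **Discretised gamma durations** (continuous gamma rounded up, floor one
  day), shape 50 for stage durations — positive skew is typical of
  development times and the sources report only means ± SE. The continuous
  mean is calibrated numerically so the *discretised* expectation hits the
  target exactly.
* **Mortality allocation.** All preadult mortality sits in the larval
  stage by default (egg and pupal survival 1): bioassays start from newly
  hatched larvae and only the overall `Sa` is reported. The death day is
  uniform within the fatal stage.
* **Sex at emergence.** `p(female)` applies to emergers and equals the
  target cohort female fraction divided by `Sa`, so both bookkeeping
  conventions come out right.
* **Fecundity.** Total eggs per female are gamma-distributed (CV 0.12)
  about the dose mean, spread over the oviposition window with a
  triangular daily profile peaking a third of the way in (only peaks and
  windows are reported in the sources, not daily shapes), with at least
  one egg per laying day. Female longevity is floored at APOP +
  oviposition days so every female's laying window is feasible; at the
  calibrated values this floor binds with negligible probability.
* **Endpoints.** Replicate endpoint values are Normal(mean, SD) truncated
  at zero, three replicates per treatment. Means/SDs printed in the
  sources are used as-is (SD = SE·√3); panel values never printed (some
  3 mg L⁻¹ cells; the digestive/detox enzymes) are fixed synthetic choices
  consistent with the described hormetic dose profiles.

What the generator does *not* emulate: egg-viability of offspring,
between-replicate (block) variance in the cohort assays, within-day timing,
density or maternal effects, and any mechanistic dose-response — dose acts
only through the calibrated parameter sets. Passing tests therefore show
that the pipeline recovers known parameters from data with this structure,
not that real cohorts satisfy the distributional choices.

## Group statistics and correlation

Endpoint tables (replicate-level, typically n = 3 per treatment) run
through a fixed decision tree: screen (Shapiro-Wilk on residuals —
per-group testing is powerless at n = 3 — and median-centred Levene, both
at α = 0.05); on failure apply the configured transform (ln(x+1) for
measurements, arcsine-square-root for proportions) and re-screen; then
one-way ANOVA with Tukey's HSD if the screen passes, else Kruskal-Wallis
with Dunn's rank-based post hocs under Holm adjustment. The branch taken
is recorded in the output rather than presumed. Letters come from an
insert-and-absorb compact letter display on adjusted pairwise p-values,
ties broken alphabetically. Dunn's test and the letter display are
implemented in the package (standard formulas, tie-corrected) since no
installed dependency provides them. All-constant inputs are reported as
non-assessable with omnibus p = 1 and a single shared letter.

Pearson correlations are computed on treatment-wise means — four points
per variable in the standard design. At n = 4 such coefficients are
exploratory descriptions of monotone association, so the matrix carries an
`n` attribute, no significance stars are attached (deliberately), and
zero-variance variables yield flagged `NA`s rather than silent zeros.
Heatmaps fix the colour scale at [-1, 1] regardless of the data range.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → life table → bootstrap → comparisons →
correlation with per-stage seeds derived from one master seed
(`seed · 131 + offset`, mod 2³¹−1), writes only plain-text outputs, and
finishes with a manifest of every file and its MD5 checksum; identical
configurations reproduce identical checksums. In the YAML configuration
the cohort size key is `cohort_size` (a bare `n:` key is a YAML 1.1
boolean and cannot be used reliably). The CLI (`inst/cli/twosexlt`) is a
thin wrapper over the same functions; a missing `--seed` is a usage error
(exit 2), never silently defaulted.

## Problem sizes and tolerances used by the tests

Calibration and property tests use cohorts of 150–5,000 individuals and
bootstrap counts of 2,000–100,000, chosen so each statistical assertion
sits at ≥3 Monte-Carlo σ from its pass boundary while the whole suite
stays interactive (under a minute). Every stochastic tolerance is derived
from a stated closed form (binomial SEs, SD-of-SD error ≈ `1/√(2B)`)
rather than tuned.

## Known limitations

* Larval instars are not resolved; the stage ladder is fixed at
  egg → larva → pupa → adult.
* No stable-age-distribution projection or forecasting beyond the
  reported parameters.
* The paired bootstrap reports difference CIs, not hypothesis tests.
* Offspring are counts only; their viability is out of scope.
* `e_xj`/`v_xj` for cells never occupied in the observed cohort are `NA`
  by design — the empirical transition probabilities are undefined there.
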