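---
title: "Modelling the health impact of a sugar-sweetened beverage duty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impact of a sugar-sweetened beverage duty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbduty)
```

## The model

`ssbduty` implements a comparative-risk-assessment style policy model of an
ad valorem duty on sugar-sweetened beverages (SSBs) in England. The causal
chain is deliberately simple and linear:

1. **Duty → consumption.** A duty of rate $\tau$ raises prices; demand
   falls according to the price elasticity of SSBs. In the default
   `ng_lookup` mode the package uses empirical demand-response anchors — a
   10% price rise cuts consumption by 4.6% and a 20% rise by 9.1% — with
   linear interpolation through the origin and linear extrapolation beyond
   20%. A `linear_elasticity` mode ($|\varepsilon|\tau$, capped at 1) is
   available for arbitrary rates and for the Monte Carlo, where the
   elasticity is sampled. The two modes differ slightly by design: 9.1% is
   an empirical estimate, not exactly $0.46 \times 20\%$, and the lookup
   mode reproduces the published per-group arithmetic exactly.

2. **Consumption → calories.** Per-group SSB calorie intake (NDNS survey
   estimates for eight age/gender groups) is multiplied by the reduction
   fraction. Survey intake is known to understate true consumption
   substantially: manufacturer sales data imply about 3.1 times the
   surveyed volume. Both a *low* (survey) and *high* (survey × 3.1)
   estimate are therefore carried. The 3.1 factor is applied exactly
   rather than recomputed from the rounded volume figures, because the
   published high-estimate reductions back-calculate to exactly
   $\text{kcal} \times 3.1 \times 0.091$.

3. **Calories → outcomes.** A reference obesity model projects 20-year UK
   changes in diabetes, CHD/stroke and cancer incidence and in QALYs for a
   sustained 20 kcal/person/day reduction (−179,000 diabetes cases,
   −122,000 CHD/stroke, −32,000 cancer, +3,011,000 QALYs over 2010–2030).
   A net reduction of $x$ kcal/day scales these pro rata by $x/20$,
   rescales from UK to England by a population factor, and annualises by
   dividing by the 20-year horizon. Disease-case changes are valued at
   average annual treatment costs (£1,371 diabetes, £4,614 CHD/stroke,
   £8,808 bowel cancer); QALYs are not monetised.

4. **National → local.** The England result is disaggregated to lower-tier
   local authorities in proportion to each area's demographic structure
   (see below).

### Assumptions worth stating plainly

* Effects are **linear** in both the calorie change and the duty rate
  within policy-relevant ranges; a 30% duty produces exactly 1.5 times the
  20% impacts, and `run_national(duty_rate = ...)` exploits this by
  rescaling the canonical 20% simulation. Substitution is treated as
  duty-induced, so it scales with the duty too — which is what makes a
  zero duty produce an exactly null result.
* One elasticity applies to **all age and gender groups**; evidence for
  income-stratified elasticities exists but matching consumption data does
  not. Cross-price substitution into diet drinks is excluded (the
  cross-price elasticity, about −0.026, is negligible, and diet drinks
  carry almost no calories).
* The three uncertain parameters are **independent untruncated normals**.
  Crossing-zero probabilities are negligible for consumption and
  elasticity at the fitted parameters; substitution legitimately goes
  negative.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `duty_rate` | 0.20 | fraction of price | the policy base case |
| consumption | Normal(301, 91) | ml/person/day | fitted population distribution |
| elasticity | Normal(−0.691, 0.12) | — | fitted simulation distribution (SD stored as magnitude) |
| substitution | Normal(1.78, 0.91) | kcal/person/day | calories regained from other foods |
| `energy_density` | 0.199 | kcal/ml | calibration, see below |
| `population_factor` | 0.836 | fraction | England share of UK reference outcomes, see below |
| `reference_kcal` | 20 | kcal/day | reference reduction behind the outcome deltas |
| `horizon_years` | 20 | years | horizon of the reference projection (2010–2030) |
| `n_sims` | 10,000 | draws | prediction-interval stability |

The deterministic lookup's elasticity (−0.46) and the simulation centre
(−0.691) come from different fitting exercises and are deliberately both
kept: the lookup replicates the per-group table, the distribution drives
the probabilistic analysis. Pass `elasticity_mean = -0.46` to
`ssb_uncertainty_params()` to centre the simulation on the narrative value
instead.

### Two calibrated constants

**Energy density, 0.199 kcal/ml.** The published model never states the
equation combining its three sampled parameters. This package adopts
$\text{net} = C \cdot d \cdot |\varepsilon| \cdot \tau - S$ (gross calorie
reduction minus substitution) and calibrates the density $d$ so the
mean-parameter scenario reproduces the published mean net reduction of
6.5 kcal/day: $d = (6.5 + 1.78)/(301 \times 0.691 \times 0.20) = 0.199$.
Users should note NDNS intake tables imply a higher density (about
0.31 kcal/g); 0.199 is a model calibration, not a beverage property, and
it is exposed as an ordinary configurable parameter.

**Population factor, 0.836.** The reference outcome deltas are UK-level;
the published England results never state the rescaling used.
Back-calculating from all four England-level annual outcome rows yields a
consistent factor of 0.836 ± 0.001, which matches the England/UK mid-2010
total-population ratio (≈ 0.84). Whether the original study scaled by
total or adult population is not recoverable; 0.836 is consistent with
total population and is adopted as an explicit config value.

## The Monte Carlo

`run_simulation()` draws each parameter independently, computes the net
calorie reduction per draw, and summarises the mean and empirical
2.5%/97.5% percentiles (linear interpolation between order statistics,
`quantile()` type 7 — the estimator is a documented choice since the
source model does not state one). Negative net draws are *not* clamped;
they are legitimate tail scenarios in which substitution outweighs a weak
gross reduction.

The scenario report (`scenario_table()`) presents lowest/highest-impact
columns at the net-impact percentiles, and since outcome scaling is
linear, those columns are *exact* rescalings of the mean column by
$p_{2.5}/\text{mean}$ and $p_{97.5}/\text{mean}$. An alternative
"aligned-parameter" construction — lining each parameter up at the
interval bound pushing the same way — is provided as a diagnostic
(`aligned_impact_scenarios()`), but it is not used for reporting: its
lowest-impact scenario goes negative under any sensible calibration,
whereas the published outcome columns are exactly the linear rescalings
above. Presentation quirks are preserved deliberately: the elasticity row
shows its weakest response (closest to zero) in the lowest-impact column,
while the substitution row keeps plain numeric percentile order.

## Local disaggregation

Each area's **consumption weight** is its population-composition-weighted
mean SSB calorie intake, using the national per-group intake (low
estimate) as relative weights — the low/high distinction is a national
scaling and cancels in the ratio. Per-person calorie reductions scale the
national value by the area weight over the pooled all-England weight;
totals (cases, QALYs, costs) are allocated proportionally to adult
population × relative weight and normalised so area sums equal national
totals exactly (conservation is exact by construction, and tested).

Children contribute to the consumption weight — they drive the young-area
gradient — but totals are allocated over adults only, matching the
41-million-adult modelled population. Areas are treated independently; no
spatial smoothing is applied. Ranking on disease-case columns note:
those are negative (cases averted), so a descending sort places the
least-impacted areas first; the default ranking metric is QALYs gained.

## The synthetic population generator

There is no bundled download of real area denominators, so the generator
produces populations with the statistical structure the analysis assumes:

* **326 areas, 41,000,000 adults** by default, the modelled England
  population. Adult totals are conserved *exactly* under any seed via
  largest-remainder integer rounding.
* **Log-normal area sizes** (`size_dispersion = 0.8` on the log scale),
  giving a max/min size ratio on the order of 100 — England's lower-tier
  authorities range from Birmingham (over a million) to the Isles of
  Scilly (about two thousand).
* **A young↔old composition tilt** per area,
  $t \sim \mathcal{N}(0, \texttt{age\_gradient})$, multiplying the 19–64
  shares by $e^{t}$ and 65+ shares by $e^{-t}$ before renormalising (a
  simplex-safe perturbation). Children ride at fixed ratios to adults,
  with the 11–18 ratio also tilted by $e^{t}$. The default gradient of
  0.3 produces a per-person impact spread of roughly ±15% around the
  national value, a plausible analogue of the published urban/rural
  contrast. With `age_gradient = 0` every area has the identical
  composition and inherits the national per-person reduction exactly (up
  to integer rounding of counts).

What the generator does **not** emulate: real spatial correlation,
deprivation gradients, ethnicity, or any named authority's demographics.
Passing tests on synthetic populations therefore demonstrates the
*structural* correctness of the disaggregation (conservation, refinement
invariance, monotonicity in age structure), not agreement with any real
area's published figure — the real-data area values require the original
official denominators and are out of scope here.

## Numerical choices and degenerate inputs

* Reductions are computed from unrounded intermediates; rounding (kcal to
  2 dp, cases/QALYs to whole numbers, £ to whole pounds) happens only at
  reporting.
* `n_sims < 100` warns (percentiles unstable); all-zero SDs are legal and
  collapse every draw to the analytic value — useful for testing.
* A non-positive mean net impact makes the percentile-ratio columns
  undefined; `scenario_table()` then reports absolute values at the
  percentiles, with a warning.
* Zero reference kcal, negative duties, all-zero area populations,
  duplicate area codes, unknown age-band labels and missing cost entries
  are rejected with informative errors.
* Ties in area ranking break by area code, making sorts stable and
  reproducible.

## Problem sizes used in the test suite

The bundled tests run the simulation at 10,000 draws (matching the model's
own design) where percentile recovery is asserted, and at 500–2,000 draws
for plumbing checks; disaggregation properties use synthetic populations
of 20–60 areas plus one full 326-area generation. These sizes keep the
whole suite to a few seconds while leaving the statistical assertions
well-powered (tolerances are 3 Monte-Carlo standard errors).

## Worked example

```{r example, eval = FALSE}
library(ssbduty)

# national result under a 20% duty
nat <- run_national(seed = 42)
nat$net_kcal      # mean and 95% prediction interval, kcal/person/day
nat$table         # full scenario report

# disaggregate over a synthetic England
pop <- generate_population(synth_config(seed = 7))
local <- run_local(nat, pop, out_path = "local_results.csv")
head(local)
```

## Known limitations

The model inherits every limitation of its inputs: survey under-reporting
(addressed only via the blunt 3.1 scaling), no producer cost-absorption,
no wastage adjustment, no behavioural/perception effects of a tax beyond
the price mechanism, sugar calories treated like any other calories, no
dental outcomes, and no discounting of QALYs or costs. The energy density
and population factor are calibrations (above), so absolute national
results should be read as reproductions of the source model's arithmetic,
not as independent epidemiological estimates.
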