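---
title: "An energy-balance microsimulation of sex disparities in youth physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-balance microsimulation of sex disparities in youth physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paequity)
```

## The question the model answers

US girls are, on average, less physically active than US boys: fewer days
per week with at least 60 minutes of activity (3.07 vs 3.68 for
12-17-year-olds; 3.97 vs 4.16 for 6-11-year-olds), lower exercise
intensity (4.3 vs 5.3 METs), and lower sports participation (34.5% vs
40.2%). `paequity` is an agent-based microsimulation that asks: if some
fraction *r* of each of those gaps were closed, how many overweight and
obesity cases would be averted by age 18, how many weight-related disease
cases and deaths over the cohort's lifetime, and what would that be worth
in quality-adjusted life-years (QALYs) and dollars?

The model has three stages:

1. **Childhood (entry to 18, daily steps).** Each agent carries fat mass
   and fat-free mass and a weekly stochastic activity schedule. Activity
   burns `(MET - 1) * c * mass * minutes` net of rest
   (`c = 3.5/200 = 0.0175` kcal/kg/min). Daily caloric surplus or deficit
   is partitioned between the fat and fat-free compartments
   (Forbes-style fat-free share `p = C/(C + fat mass)`) and converted to
   mass at the compartment energy densities (9441 and 1807 kcal/kg).
2. **Adulthood (18 to at most 100, annual steps).** An annual-cycle
   Markov model over semi-independent condition hazards — stroke,
   coronary heart disease, type 2 diabetes with neuropathy, retinopathy
   and nephropathy as diabetes-gated complications, and cancers — with
   baseline incidence multiplied by a relative risk for the agent's
   age-18 weight category, plus background mortality and per-condition
   excess mortality.
3. **Economics.** Per year alive: QALYs at the product of active-condition
   utility weights, direct medical costs (third-party payer perspective),
   and presenteeism valued as `daily wage x (1 - utility) x days`
   (societal perspective = direct + presenteeism), all discounted at 3%
   per year to the agent's entry.

The causal pathway is the **maintenance-intake rule**: each agent eats
exactly enough to hold its BMI-for-age percentile constant *given its
baseline activity*. When a scenario raises activity, intake stays at the
baseline schedule, so the extra expenditure becomes a sustained caloric
deficit and weight loss. Scenarios are applied only to female agents:
`female <- female + r * (male - female)` on the selected dimensions.

## Paired counterfactuals with common random numbers

Each replicate builds one cohort and simulates it twice — baseline and
scenario — with identical random streams. All stochastic draws are
inverse-CDF transforms of uniforms, so raising a parameter mean moves
every coupled draw in the same direction: a given agent's weekly active
days under the scenario are never below its baseline days. Paired
per-agent differences therefore isolate the intervention with far less
Monte-Carlo noise than independent runs, and scenario effects are
monotone in `r` replicate by replicate, not just in expectation.
Replicates differ by seed; summaries report replicate means with
percentile 95% intervals (assumption-free, conservative for the mean;
the default is 25 replicates, and the checked-in analyses use 10-20
replicates of roughly 10^4 agents, with counts rescaled to the 8 299 353
national population).

## The synthetic population

Agents are instantiated in four strata (sex x ages 6-11/12-17) by
largest-remainder apportionment of `scale` x the census counts, with ages
uniform within each band (the inputs are 6-year aggregates). Fat-free
and fat mass are drawn from truncated normals (lower bound 0) with the
published stratum means/SDs. Two deliberate departures from naive
marginal sampling:

* **Age coupling.** Within a stratum, body-composition draws are tied to
  age rank through a Gaussian copula (rank correlation 0.85 by default).
  The printed marginal mean/SD is preserved exactly, but younger agents
  get systematically smaller masses. Without this, a 6-year-old can draw
  the stratum-mean fat-free mass of an 11-year-old and is then classified
  overweight no matter how little fat it carries, which makes the
  prevalence calibration below infeasible.
* **Prevalence calibration.** After sampling, fat mass is passed through
  a stratum-wise monotone affine map (floored at a physiologic minimum)
  chosen so that classified overweight and obesity fractions match the
  survey targets. For one stratum (girls 6-11) the published fat-free
  marginal (mean 32.42 kg, SD 10.82 — larger than the boys' 26.12) is so
  heavy that no non-negative fat mass can reach the targets at realistic
  heights; there, and only there, fat-free mass is additionally shrunk by
  the smallest single factor that restores feasibility. Both maps are
  monotone, so within-stratum fat-mass rank order is preserved, and the
  calibration is idempotent up to Monte-Carlo noise.

The printed "fat tissue and fat mass ratio" rows are stored exactly as
published with an interpretation flag (`kg`, the default, or
`ratio_pct`); flipping the flag requires no code change.

## Growth reference and weight classification

BMI-for-age percentiles come from a smooth LMS surface
(`z = ((bmi/M)^L - 1)/(L*S)`) with a median-height-by-age curve per sex.
The packaged reference is **synthetic** — shaped to resemble national
CDC-type curves but not measured data — and ships as a plain TSV
(`sex, age, L, M, S, height_m`) so a genuine LMS table drops in
unchanged. Heights are deterministic medians: BMI variation comes from
mass alone, which is the quantity the energy-balance model evolves.
Youths are classified overweight at the 85th and obese at the 95th
percentile; adults (18+) at BMI 25 and 30. Because the adult cut points
sit slightly below the synthetic 85th/95th percentile at age 18,
end-of-childhood prevalence under the adult convention runs a little
above the youth-classified entry prevalence; paired scenario contrasts
are unaffected since both arms are classified identically.

## Behavioral model choices

* Weekly active days are drawn from a truncated normal on [0, 7] and
  stochastically rounded (`floor + Bernoulli(frac)`), so weeks have whole
  active days but the long-run mean equals the drawn value. The draw is
  refreshed every week with no autocorrelation.
* The printed SDs of PA days (0.07-0.08) are treated as between-draw
  SDs. They are small, so essentially all week-to-week variation in
  expenditure comes from the stochastic rounding and the intensity draw.
* Intensity is truncated-normal with lower bound 1 MET; sports intensity
  is triangular(min, mode = mean, max), honoring all three published
  numbers.
* Sports participation is a per-agent persistent uniform compared to the
  sex-specific probability, so scenario increases in the probability
  recruit new participants without reshuffling existing ones. Sports
  MVPA (418.49/320.59 min/week) is spread evenly over the week and is
  strictly additive to non-sport activity.
* Activity parameters follow the agent's *entry* age group for its whole
  childhood, matching the cross-sectional inputs; this also reproduces
  the finding that 12-17-year-olds, who start with the largest gap (0.61
  days/week), gain the largest per-capita benefit.

## Numerical choices

* Maintenance intake is solved by bisection (range 0-12000, 14
  iterations, ~1 kcal/day) against a deterministic forward integration of
  the expected energy balance in 14-day steps; expectations of the
  truncated-normal and triangular draws are closed-form, so the solve is
  unbiased for the stochastic engine. It is re-solved every 52 simulated
  weeks under *baseline* activity — a single lifetime constant cannot
  track a growing child — and the recorded schedule is reused verbatim in
  scenario runs ("frozen at baseline"). Under maintenance, stratum mean
  BMI percentile drifts by well under 1 percentile point per year.
* Masses are floored at 0.2 kg fat and 5 kg fat-free; floored steps are
  flagged and excluded from energy-conservation accounting. Away from
  the floors, compartment energies balance cumulative net intake to
  better than 1e-6 kcal over 1000-day runs.
* Calibration bisections run to ~1e-4 in the adjusted fractions; the
  feasibility shrink factor is found on a 0.02-step grid because
  empirical feasibility is not monotone in it at small cohort sizes.
* Within a Markov year the order is onsets, then diabetes complications
  (same-year diabetes counts), then mortality combined as
  `1 - prod(1 - q_i)`; one uniform per agent-condition-year is consumed
  whether used or not, keeping paired runs aligned. Death is forced at
  age 100. Deaths are attributed to background or a specific active
  condition proportionally to the competing hazards.
* Comorbid utilities combine multiplicatively (stays in [0, 1]);
  childhood years accrue healthy-utility QALYs and no disease cost.

## Placeholder tables

The behavioral, anthropometric and demographic blocks of
`inst/extdata/default_params.yaml` carry published survey values, each
block with a `source` string. The disease incidence/relative-risk/
mortality tables and the cost/utility tables are **order-of-magnitude
placeholders**, clearly labeled in the file: the registry-calibrated
tables behind the original estimates are not public. The engine treats
them as data; replacing the YAML block is the supported calibration
path. Consequently the package's national dollar and case figures are
structurally comparable to published figures (same sign, same ordering
across scenarios, similar magnitude) but are not reproductions of them,
and the analysis scripts should be read accordingly.

## What passing tests do and do not show

The test suite verifies the input arithmetic exactly (census totals,
scenario transforms, presenteeism and discounting closed forms), the
mechanics (energy conservation, maintenance stationarity, calibration
recovery, binomial/geometric behavior of the Markov engine, the
societal = direct + productivity identity), and the direction of the
scenario responses (non-negative, monotone in `r`, larger per capita for
12-17-year-olds, shrinking as non-PA-day minutes rise 0 to 45). Because
the synthetic population matches survey marginals rather than individual
survey records, and the adult tables are placeholders, passing tests
validate the model's structure and mechanisms — not the clinical accuracy
of any particular national estimate.

## Known limitations

* No race/ethnicity or socioeconomic stratification; sex is binary —
  both limits inherited from the input data.
* Adult BMI category is fixed at its age-18 value; adult weight dynamics
  are out of scope.
* No underweight category, disease remission, treatment effects,
  absenteeism, or caregiver costs.
* Replicate-percentile CIs reflect Monte-Carlo variation only, not
  parameter uncertainty.

## A minimal run

```{r example, eval = FALSE}
params <- load_params()
ref <- load_growth_reference()

scenario <- apply_disparity_reduction(params, scenario_spec("pa_days", 1))
scenario$activity$days_per_week$female_12_17$mean  # 3.07 -> 3.68

rep1 <- run_replicate(params, list(eliminate = scenario),
                      scale = 0.0012, seed = 42, ref = ref)
```

The numbered drivers under `analysis/` run the full experiment grids and
write the summary tables under `results/`.
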