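# paequity

An agent-based microsimulation of the health and economic consequences of
sex disparities in US youth physical activity and sports participation.

US girls get fewer days per week of ≥60-minute physical activity than boys
(3.07 vs 3.68 among 12-17-year-olds, 3.97 vs 4.16 among 6-11-year-olds),
exercise at lower intensity (4.3 vs 5.3 METs), and participate less in
sports (34.5% vs 40.2%). `paequity` simulates a synthetic cohort of the
8 299 353 US children aged 6-17 and asks what happens if a fraction
*r* ∈ [0, 1] of each gap is closed for girls
(`female ← female + r·(male − female)`):

* **Childhood, daily timesteps to age 18** — each agent holds fat mass and
  fat-free mass; weekly stochastic activity burns
  `(MET − 1) · c · mass · minutes` net of rest; daily surplus/deficit is
  split between compartments (Forbes partition `p = C/(C + FM)`) at
  energy densities ρ_F = 9441, ρ_L = 1807 kcal/kg. Each agent eats the
  *maintenance* intake that holds its BMI-for-age percentile constant
  under **baseline** activity — so scenario activity, with intake frozen,
  becomes weight loss.
* **Adulthood, annual timesteps to 100** — a Markov model of stroke,
  coronary heart disease, type 2 diabetes (with neuropathy, retinopathy,
  nephropathy), and cancers: incidence × relative risk of the age-18
  weight category, plus background and per-condition excess mortality.
* **Economics** — QALYs (multiplicative comorbid utilities), direct
  medical costs (third-party payer perspective), and presenteeism valued
  as `daily wage × (1 − utility) × days` (societal perspective = direct +
  presenteeism), discounted at 3%/year.

Baseline and counterfactual share one cohort and identical random streams
(common random numbers), so paired per-agent differences isolate the
intervention; results are replicate means with percentile 95% CIs, scaled
to national counts.

The published survey inputs (census counts, activity distributions,
sports participation, body-composition marginals, prevalence targets)
ship as packaged YAML defaults with per-block provenance. The adult
disease and cost/utility tables are clearly labeled **placeholders** —
the registry-calibrated originals are not public — so national dollar and
case outputs are structurally comparable to published figures, not
reproductions of them. See the methods vignette
(`vignettes/disparity-microsimulation.Rmd`) for every modeling choice.

## Worked example

```r
library(paequity)

params <- load_params()            # packaged survey defaults
ref    <- load_growth_reference()  # synthetic LMS growth reference

# eliminate the PA-days gap for girls
sc <- apply_disparity_reduction(params, scenario_spec("pa_days", 1))
sc$activity$days_per_week$female_12_17$mean
#> [1] 3.68

# one paired replicate: ~2500 agents, childhood + lifetime + economics
rr  <- run_replicate(params, list(eliminate = sc), scale = 3e-4, seed = 42)
out <- replicate_outcomes(rr, "eliminate", 3e-4)
out[out$group == "total",
    c("cases_averted", "prevalence_change_pp", "societal_savings_usd")]
#>   cases_averted prevalence_change_pp societal_savings_usd
#> 3         40000            0.4819277           2768560608
```

Read: under this single replicate, eliminating the PA-days disparity
averts ~40 000 female overweight/obesity cases at age 18 nationally,
lowers all-population overweight/obesity prevalence at 18 by ~0.48
percentage points, and saves ~$2.8B (2024 USD, discounted) in lifetime
societal costs under the placeholder cost tables — a single ~2500-agent
replicate is noisy, which is why reported results average 10-25
replicates with percentile CIs. Replicate-averaged
versions with 95% CIs come from `run_experiment_grid()`; the numbered
drivers in `analysis/` (01 population calibration, 02 PA-days grid,
03 sports-participation grid, 04 non-PA-day-minutes sensitivity) write
those tables under `results/`:

```sh
Rscript analysis/01_population.R
Rscript analysis/02_pa_disparity.R
```

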