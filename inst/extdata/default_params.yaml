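# Default parameter bundle for the paequity microsimulation.
#
# Behavioral and anthropometric blocks carry the published survey-derived
# input values (see each block's `source`).  The disease, background-
# mortality and cost/utility blocks are PLACEHOLDERS of realistic magnitude:
# the original model's registry-calibrated tables are not public, so these
# values should be calibrated or replaced before any substantive use.  The
# engine is agnostic to the values; only the structure is contractual.
meta:
  description: "Youth physical-activity sex-disparity microsimulation defaults"
  currency_year: 2024
demography:
  source: "US Census 2022 single-year-of-age counts aggregated to sex x age-group strata"
  counts:
    male_6_11: 2078664
    female_6_11: 1992402
    male_12_17: 2161455
    female_12_17: 2066832
activity:
  source: "National Survey of Children's Health 2016-2020 weighted means (days/week with >=60 min PA); Harrell et al. 2003 (MET intensities)"
  days_per_week:
    male_6_11: {mean: 4.16, sd: 0.08}
    female_6_11: {mean: 3.97, sd: 0.07}
    male_12_17: {mean: 3.68, sd: 0.08}
    female_12_17: {mean: 3.07, sd: 0.07}
  intensity_met:
    male: {mean: 5.3, sd: 1.6}
    female: {mean: 4.3, sd: 1.56}
  active_day_minutes: {male: 60.0, female: 60.0}
  non_pa_day_minutes: {male: 30.0, female: 30.0}
sports:
  source: "Project Play 2023 (participation %); Kanters et al. / Sports and Fitness Industry Association 2024 (MVPA min/week and MET mean/range)"
  participation_pct: {male: 40.2, female: 34.5}
  mvpa_min_week: {male: 418.49, female: 320.59}
  intensity_met:
    male: {mean: 3.95, min: 3.02, max: 4.84}
    female: {mean: 3.55, min: 2.41, max: 4.35}
body_composition:
  source: "NHANES 2017-2020 body-composition means (SDs) by sex x age group"
  # fat_mass rows are stored exactly as printed in the source table
  # ("fat tissue and fat mass ratio"); interpretation is switchable:
  # "kg" treats them as fat mass in kilograms (default), "ratio_pct"
  # as percent body fat applied to fat-free mass.
  fat_mass_interpretation: kg
  # Gaussian-copula rank correlation between age and each body-composition
  # draw within a stratum (0 = marginal sampling); preserves the printed
  # marginal mean/SD exactly while giving younger agents smaller masses.
  age_rank_correlation: 0.85
  fat_free_mass_kg:
    male_6_11: {mean: 26.12, sd: 6.45}
    female_6_11: {mean: 32.42, sd: 10.82}
    male_12_17: {mean: 52.94, sd: 11.41}
    female_12_17: {mean: 40.92, sd: 6.73}
  fat_mass:
    male_6_11: {mean: 7.35, sd: 3.66}
    female_6_11: {mean: 15.20, sd: 7.84}
    male_12_17: {mean: 13.11, sd: 5.18}
    female_12_17: {mean: 20.21, sd: 6.90}
prevalence_targets:
  source: "NHANES 2017-2020 overweight and obesity prevalence, percent (95% CI)"
  overweight_pct:
    male_6_11: {mean: 12.79, lo: 9.83, hi: 15.74}
    female_6_11: {mean: 13.58, lo: 10.35, hi: 16.80}
    male_12_17: {mean: 14.45, lo: 10.86, hi: 18.03}
    female_12_17: {mean: 18.21, lo: 14.39, hi: 22.03}
  obesity_pct:
    male_6_11: {mean: 23.72, lo: 19.79, hi: 27.66}
    female_6_11: {mean: 17.58, lo: 13.72, hi: 20.98}
    male_12_17: {mean: 21.77, lo: 17.95, hi: 25.58}
    female_12_17: {mean: 20.23, lo: 16.54, hi: 23.91}
metabolic:
  source: "placeholder - calibrate or replace; energy densities and Forbes partition from the Hall energy-balance literature, resting energy of Katch-McArdle form, 1 MET = 3.5 ml O2/kg/min => 0.0175 kcal/kg/min"
  rho_fat_kcal_per_kg: 9441.0
  rho_lean_kcal_per_kg: 1807.0
  kcal_per_met_min_per_kg: 0.0175
  rmr_intercept_kcal: {male: 370.0, female: 370.0}
  rmr_kcal_per_kg_ffm: 21.6
  rmr_kcal_per_kg_fm: 4.5
  growth_kcal_per_day_minor: 30.0
  forbes_c_kg: 10.4
  min_fat_mass_kg: 0.2
  min_fat_free_mass_kg: 5.0
disease:
  source: "placeholder - calibrate or replace; annual incidence, relative risks by adult weight category, and excess mortality are order-of-magnitude stand-ins for unavailable registry-derived tables"
  max_age: 100
  conditions:
    diabetes:
      incidence:
        - {min_age: 18, max_age: 39, male: 0.0020, female: 0.0018}
        - {min_age: 40, max_age: 59, male: 0.0080, female: 0.0070}
        - {min_age: 60, max_age: 79, male: 0.0120, female: 0.0100}
        - {min_age: 80, max_age: 99, male: 0.0100, female: 0.0090}
      rr: {healthy: 1.0, overweight: 1.8, obesity: 3.5}
      excess_mortality: 0.005
      annual_cost_usd: 6000.0
      utility: 0.88
    chd:
      incidence:
        - {min_age: 18, max_age: 39, male: 0.0010, female: 0.0006}
        - {min_age: 40, max_age: 59, male: 0.0050, female: 0.0035}
        - {min_age: 60, max_age: 79, male: 0.0120, female: 0.0090}
        - {min_age: 80, max_age: 99, male: 0.0200, female: 0.0170}
      rr: {healthy: 1.0, overweight: 1.3, obesity: 1.9}
      excess_mortality: 0.020
      annual_cost_usd: 8000.0
      utility: 0.82
    stroke:
      incidence:
        - {min_age: 18, max_age: 39, male: 0.0005, female: 0.0004}
        - {min_age: 40, max_age: 59, male: 0.0020, female: 0.0016}
        - {min_age: 60, max_age: 79, male: 0.0080, female: 0.0070}
        - {min_age: 80, max_age: 99, male: 0.0200, female: 0.0190}
      rr: {healthy: 1.0, overweight: 1.2, obesity: 1.6}
      excess_mortality: 0.030
      annual_cost_usd: 10000.0
      utility: 0.70
    cancer:
      incidence:
        - {min_age: 18, max_age: 39, male: 0.0020, female: 0.0022}
        - {min_age: 40, max_age: 59, male: 0.0060, female: 0.0062}
        - {min_age: 60, max_age: 79, male: 0.0140, female: 0.0120}
        - {min_age: 80, max_age: 99, male: 0.0200, female: 0.0170}
      rr: {healthy: 1.0, overweight: 1.1, obesity: 1.4}
      excess_mortality: 0.050
      annual_cost_usd: 20000.0
      utility: 0.78
    neuropathy:
      requires: diabetes
      incidence:
        - {min_age: 18, max_age: 59, male: 0.030, female: 0.030}
        - {min_age: 60, max_age: 99, male: 0.050, female: 0.050}
      rr: {healthy: 1.0, overweight: 1.0, obesity: 1.0}
      excess_mortality: 0.002
      annual_cost_usd: 2000.0
      utility: 0.85
    retinopathy:
      requires: diabetes
      incidence:
        - {min_age: 18, max_age: 59, male: 0.020, female: 0.020}
        - {min_age: 60, max_age: 99, male: 0.040, female: 0.040}
      rr: {healthy: 1.0, overweight: 1.0, obesity: 1.0}
      excess_mortality: 0.000
      annual_cost_usd: 1500.0
      utility: 0.85
    nephropathy:
      requires: diabetes
      incidence:
        - {min_age: 18, max_age: 59, male: 0.010, female: 0.010}
        - {min_age: 60, max_age: 99, male: 0.020, female: 0.020}
      rr: {healthy: 1.0, overweight: 1.0, obesity: 1.0}
      excess_mortality: 0.010
      annual_cost_usd: 8000.0
      utility: 0.75
  background_mortality:
    # annual probability of death from causes other than the modeled
    # conditions; forced to 1 at max_age
    - {min_age: 18, max_age: 39, male: 0.0013, female: 0.0006}
    - {min_age: 40, max_age: 59, male: 0.0040, female: 0.0025}
    - {min_age: 60, max_age: 79, male: 0.0150, female: 0.0100}
    - {min_age: 80, max_age: 99, male: 0.0800, female: 0.0600}
economics:
  source: "placeholder - calibrate or replace; 3% annual discounting per cost-effectiveness panel recommendations; daily wage is a mean-across-occupations proxy"
  discount_rate: 0.03
  daily_wage_usd: 231.0
  healthy_utility: 1.0
  work_days_per_year: 365.0
  perspective: societal
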