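test_that("a zero surplus leaves the state unchanged", {
  st <- step_day(list(ffm = 40, fm = 12), 2000, 500, 1500, tp$metabolic)
  expect_equal(st$ffm, 40)
  expect_equal(st$fm, 12)
  expect_false(st$clipped)
})

test_that("surplus converts to fat mass at the fat energy density", {
  # with the fat-free share driven to ~0, a 944.1 kcal surplus at
  # rho_F = 9441 kcal/kg deposits exactly 0.1 kg of fat
  mc <- tp$metabolic
  mc$forbes_c_kg <- 1e-9
  st <- step_day(list(ffm = 40, fm = 12), 944.1, 0, 0, mc)
  expect_equal(st$fm - 12, 0.1, tolerance = 1e-6)
  expect_equal(st$ffm, 40, tolerance = 1e-6)
})

test_that("a +S then -S step pair is reversible at fixed partition", {
  st1 <- step_day(list(ffm = 40, fm = 12), 1, 0, 0, tp$metabolic)
  st2 <- step_day(st1, -1, 0, 0, tp$metabolic)
  expect_lt(abs(st2$ffm - 40) + abs(st2$fm - 12), 1e-9)
})

test_that("maintenance intake holds the BMI percentile over a year", {
  a <- test_agent(sex = "male", age_group = "6-11", age = 8,
                  ffm = 22, fm = 6)
  intake <- maintenance_intake(a, tp, ref = tref)
  pr <- paequity:::activity_profile(
    as.data.frame(a, stringsAsFactors = FALSE), tp)
  k <- paequity:::expected_activity_kcal_per_kg(pr, tp$metabolic)
  rmr0 <- tp$metabolic$rmr_intercept_kcal$male +
    tp$metabolic$growth_kcal_per_day_minor
  st <- paequity:::forward_expected(a$ffm, a$fm, rmr0, intake, k,
                                    tp$metabolic, 52, 7)
  p0 <- bmi_percentile(a$age, a$sex, (a$ffm + a$fm) /
                         median_height(a$age, a$sex, tref)^2, tref)
  h1 <- median_height(a$age + 364 / 365, a$sex, tref)
  p1 <- bmi_percentile(a$age + 364 / 365, a$sex,
                       (st$ffm + st$fm) / h1^2, tref)
  expect_lt(abs(p1 - p0), 0.005)
  # doubling expected activity strictly raises the required intake
  p2 <- tp
  p2$activity$non_pa_day_minutes$male <- 60
  p2$activity$days_per_week$male_6_11$mean <- 7
  expect_gt(maintenance_intake(a, p2, ref = tref), intake)
})

test_that("with no growth and no activity, maintenance equals resting energy", {
  fref <- flat_reference()
  p0 <- tp
  for (s in paequity:::STRATA) {
    p0$activity$days_per_week[[s]] <- list(mean = 0, sd = 0)
  }
  p0$activity$non_pa_day_minutes <- list(male = 0, female = 0)
  p0$sports$participation_pct <- list(male = 0, female = 0)
  a <- test_agent(sex = "female", age_group = "12-17", age = 13,
                  ffm = 40, fm = 12)
  intake <- maintenance_intake(a, p0, ref = fref)
  expected <- resting_energy(40, 12, 13, "female", p0$metabolic)
  expect_equal(intake, expected, tolerance = 1.5 / expected)
})

test_that("energy bookkeeping balances over a multi-year simulation", {
  co <- build_cohort(tp, 3e-5, seed = 9, ref = tref)
  sim <- simulate_childhood_cohort(co, tp, seed = 10, ref = tref,
                                   max_weeks = 150)
  mc <- tp$metabolic
  lhs <- mc$rho_fat_kcal_per_kg * (sim$cohort$fm - co$fm) +
    mc$rho_lean_kcal_per_kg * (sim$cohort$ffm - co$ffm)
  rhs <- sim$energy$cum_intake_kcal - sim$energy$cum_expenditure_kcal
  ok <- !sim$clipped
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(lhs - rhs)[ok]), 1e-6)
})

test_that("the null scenario reproduces the baseline and added activity lowers BMI", {
  co <- build_cohort(tp, 1e-4, seed = 21, ref = tref)
  base <- simulate_childhood_cohort(co, tp, seed = 22, ref = tref)
  null_sc <- apply_disparity_reduction(tp, scenario_spec("pa_days", 0))
  again <- simulate_childhood_cohort(co, null_sc, seed = 22, ref = tref,
                                     intake_schedule = base$intakes)
  expect_identical(base$cohort$fm, again$cohort$fm)
  # eliminating the activity gap with intake frozen lowers female BMI
  sc <- apply_disparity_reduction(tp, scenario_spec("pa_days", 1))
  lower <- simulate_childhood_cohort(co, sc, seed = 22, ref = tref,
                                     intake_schedule = base$intakes)
  fem <- co$sex == "female"
  expect_lt(mean(lower$cohort$fm[fem]), mean(base$cohort$fm[fem]))
  expect_identical(lower$cohort$fm[!fem], base$cohort$fm[!fem])
})

test_that("single-agent childhood simulation matches the cohort engine", {
  a <- test_agent(age = 17.5)
  s1 <- simulate_childhood(a, tp, seed = 4, ref = tref)
  expect_equal(s1$cohort$age, 18)
  expect_equal(nrow(s1$cohort), 1L)
  expect_true(all(s1$cohort$ffm > 0 & s1$cohort$fm > 0))
})
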