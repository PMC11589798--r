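test_that("largest-remainder apportionment conserves scaled totals", {
  # hand-derived from the four census counts at scale 1e-3: floors give
  # 2078+1992+2161+2066 = 8297, round(8299.353) = 8299, and the two
  # largest remainders (.832, .664) get the extra agents
  n <- apportion_counts(tp, 1e-3)
  expect_equal(unname(n), c(2079L, 1992L, 2161L, 2067L))
  expect_equal(sum(n), 8299L)
  # property: totals conserved within rounding across many scales
  for (sc in c(0.5, 0.123, 3e-4, 1e-5)) {
    n <- apportion_counts(tp, sc)
    expect_lte(abs(sum(n) - sc * 8299353), 1)
  }
  expect_error(apportion_counts(tp, 0), "scale")
  expect_error(apportion_counts(tp, -1), "scale")
})

test_that("body-composition marginals match the published mean/SD", {
  set.seed(421)
  bc <- sample_body_composition("male", "12-17", tp, 1e5)
  expect_equal(mean(bc$ffm), 52.94, tolerance = 0.2 / 52.94)
  expect_equal(sd(bc$ffm), 11.41, tolerance = 0.02)
  # age coupling preserves the marginal exactly
  set.seed(421)
  bc2 <- sample_body_composition("female", "6-11", tp, 1e5,
                                 u_age = runif(1e5))
  expect_equal(mean(bc2$ffm), 32.42, tolerance = 0.3 / 32.42)
  expect_true(all(bc2$ffm > 0) && all(bc2$fm > 0))
  # zero-SD draws collapse to the mean
  p0 <- tp
  p0$body_composition$fat_free_mass_kg$male_6_11$sd <- 0
  set.seed(1)
  bc0 <- sample_body_composition("male", "6-11", p0, 100)
  expect_true(all(bc0$ffm == 26.12))
})

test_that("all draws are strictly positive under heavy left tails", {
  set.seed(99)
  bc <- sample_body_composition("male", "6-11", tp, 1e6)
  expect_true(all(bc$ffm > 0))
  expect_true(all(bc$fm > 0))
})

test_that("cohorts are deterministic given seed and proportional to strata", {
  c1 <- build_cohort(tp, 2e-4, seed = 31, ref = tref)
  c2 <- build_cohort(tp, 2e-4, seed = 31, ref = tref)
  expect_identical(c1, c2)
  c3 <- build_cohort(tp, 2e-4, seed = 32, ref = tref)
  expect_false(identical(c1$ffm, c3$ffm))
  n <- table(paste(c1$sex, c1$age_group))
  expect_equal(unname(n[["male 6-11"]]), 416)   # round(2e-4 * 2078664)
  expect_true(all(c1$age >= 6 & c1$age < 18))
  expect_true(all(c1$ffm > 0 & c1$fm > 0))
})

test_that("calibration recovers the prevalence targets and preserves rank", {
  set.seed(5)
  co <- build_cohort(tp, 2e-3, seed = 77, calibrate = FALSE, ref = tref)
  cal <- calibrate_to_prevalence(co, tp, tref)
  prev <- measure_prevalence(cal, tref)
  for (s in paequity:::STRATA) {
    expect_equal(prev$overweight_pct[prev$stratum == s],
                 tp$prevalence_targets$overweight_pct[[s]]$mean,
                 tolerance = 1.2 / 15, label = paste("overweight", s))
    expect_equal(prev$obesity_pct[prev$stratum == s],
                 tp$prevalence_targets$obesity_pct[[s]]$mean,
                 tolerance = 1.2 / 20, label = paste("obesity", s))
  }
  # monotone map: fat-mass rank order preserved within stratum
  i <- co$sex == "male" & co$age_group == "12-17"
  expect_true(all(diff(cal$fm[i][order(co$fm[i])]) >= 0))
  # second pass is idempotent within tolerance
  cal2 <- calibrate_to_prevalence(cal, tp, tref)
  expect_lt(max(abs(cal2$fm - cal$fm)), 0.25)
})

test_that("zero targets empty both categories and infeasible targets error", {
  p0 <- tp
  for (s in paequity:::STRATA) {
    p0$prevalence_targets$overweight_pct[[s]]$mean <- 0
    p0$prevalence_targets$obesity_pct[[s]]$mean <- 0
  }
  co <- build_cohort(p0, 1e-4, seed = 3, calibrate = FALSE, ref = tref)
  cal <- calibrate_to_prevalence(co, p0, tref)
  prev <- measure_prevalence(cal, tref)
  expect_true(all(prev$overweight_pct == 0 & prev$obesity_pct == 0))

  pbad <- tp
  pbad$prevalence_targets$overweight_pct$male_6_11$mean <- 60
  pbad$prevalence_targets$obesity_pct$male_6_11$mean <- 50
  expect_error(calibrate_to_prevalence(co, pbad, tref), "infeasible")
})

test_that("cohorts round-trip through CSV", {
  co <- build_cohort(tp, 5e-5, seed = 12, ref = tref)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$ffm, co$ffm, tolerance = 1e-12)
  expect_equal(back$sex, co$sex)
  expect_equal(back$sports, co$sports)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = 1, sex = "male"), f2, row.names = FALSE)
  expect_error(read_cohort(f2), "columns")
})
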