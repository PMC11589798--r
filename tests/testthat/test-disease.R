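test_that("with zero hazards nothing happens except aging", {
  ds <- one_condition_disease(0)
  st <- list(active = matrix(FALSE, 10, 7,
                             dimnames = list(NULL, paequity:::CONDITIONS)),
             alive = rep(TRUE, 10), age = 30)
  nxt <- annual_transition(st, rep("healthy", 10), rep("male", 10), ds)
  expect_equal(nxt$age, 31)
  expect_true(all(nxt$alive))
  expect_false(any(nxt$active))
})

test_that("certain incidence produces onset in one step", {
  ds <- one_condition_disease(1)
  st <- list(active = matrix(FALSE, 5, 7,
                             dimnames = list(NULL, paequity:::CONDITIONS)),
             alive = rep(TRUE, 5), age = 40)
  nxt <- annual_transition(st, rep("healthy", 5), rep("female", 5), ds)
  expect_true(all(nxt$active[, "diabetes"]))
})

test_that("onset frequency matches incidence x relative risk", {
  ds <- one_condition_disease(0.02, rr_obesity = 2)
  n <- 1e5
  st <- list(active = matrix(FALSE, n, 7,
                             dimnames = list(NULL, paequity:::CONDITIONS)),
             alive = rep(TRUE, n), age = 50)
  set.seed(14)
  nxt <- annual_transition(st, rep("obesity", n), rep("male", n), ds)
  expect_equal(mean(nxt$active[, "diabetes"]), 0.04, tolerance = 0.002 / 0.04)
  set.seed(14)
  nxt_h <- annual_transition(st, rep("healthy", n), rep("male", n), ds)
  expect_equal(mean(nxt_h$active[, "diabetes"]), 0.02,
               tolerance = 0.002 / 0.02)
})

test_that("diabetes complications require active diabetes", {
  co <- build_cohort(tp, 1e-4, seed = 61, ref = tref)
  h <- simulate_adult_cohort(rep("obesity", nrow(co)), co$sex,
                             tp$disease, seed = 62)
  for (cmp in c("neuropathy", "retinopathy", "nephropathy")) {
    has_cmp <- !is.na(h$onset_age[, cmp])
    expect_true(all(!is.na(h$onset_age[has_cmp, "diabetes"])))
    expect_true(all(h$onset_age[has_cmp, cmp] >=
                      h$onset_age[has_cmp, "diabetes"]))
  }
  # absorption: onsets never postdate death; at most one onset each
  expect_true(all(h$onset_age <= h$death_age, na.rm = TRUE))
  expect_true(all(h$death_age <= tp$disease$max_age))
})

test_that("death is certain by the configured maximum age", {
  ds <- one_condition_disease(0, max_age = 100)
  h <- simulate_adult_cohort(rep("healthy", 50), rep("female", 50), ds,
                             seed = 8)
  expect_true(all(h$death_age == 100))
  expect_true(all(is.na(h$onset_age)))
  expect_true(all(h$death_cause == "background"))
})

test_that("with all relative risks 1 weight category has no effect", {
  ds <- tp$disease
  for (cn in names(ds$conditions)) {
    ds$conditions[[cn]]$rr <- list(healthy = 1, overweight = 1, obesity = 1)
  }
  sexes <- rep(c("male", "female"), 500)
  h1 <- simulate_adult_cohort(rep("healthy", 1000), sexes, ds, seed = 90)
  h2 <- simulate_adult_cohort(rep("obesity", 1000), sexes, ds, seed = 90)
  expect_identical(h1$onset_age, h2$onset_age)
  expect_identical(h1$death_age, h2$death_age)
})

test_that("lifetime onsets are monotone in relative risk under coupling", {
  # condition-independent mortality so coupled lifespans are identical
  counts <- sapply(c(1, 1.5, 2.5), function(rr) {
    ds <- one_condition_disease(0.01, rr_obesity = rr, excess = 0,
                                background = 0.01)
    h <- simulate_adult_cohort(rep("obesity", 2000), rep("male", 2000),
                               ds, seed = 33)
    sum(!is.na(h$onset_age[, "diabetes"]))
  })
  expect_true(all(diff(counts) > 0))
})

test_that("constant-hazard onset ages follow the geometric law", {
  hzd <- 0.05
  n <- 2e4
  ds <- one_condition_disease(hzd, background = 0)
  h <- simulate_adult_cohort(rep("healthy", n), rep("female", n), ds,
                             seed = 51)
  onset <- h$onset_age[, "diabetes"]
  # empirical CDF of onset vs geometric closed form, all ages; DKW-style
  # bound at n = 2e4 is ~0.010 at the 1% level
  ages <- 18:99
  emp <- vapply(ages, function(a) mean(!is.na(onset) & onset <= a),
                numeric(1))
  theo <- 1 - (1 - hzd)^(ages - 17)
  expect_lt(max(abs(emp - theo)), 0.015)
})
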