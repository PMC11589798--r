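# Daily energy-balance weight dynamics to age 18.
#
# Each day an agent's caloric surplus S = intake - resting - growth -
# activity is partitioned between the fat and fat-free compartments with a
# Forbes-style fat-free share p = C / (C + fat mass), and converted to
# mass change through the compartment energy densities (rho_F, rho_L).
# Intake is the *maintenance* intake: the amount that holds the agent's
# BMI-for-age percentile constant over the coming year under baseline
# expected activity (solved by bisection).  Scenarios that raise activity
# keep the baseline intake, so added expenditure becomes caloric deficit
# and weight loss - the model's causal pathway.

#' Resting plus growth energy expenditure
#'
#' Linear in fat-free and fat mass (Katch-McArdle form) with a constant
#' growth-energy term for minors.
#'
#' @param ffm,fm Fat-free and fat mass (kg), vectorized.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param constants The `metabolic` block of a `model_params` bundle.
#' @return kcal/day.
#' @export
resting_energy <- function(ffm, fm, age, sex, constants) {
  intercept <- ifelse(sex == "male",
                      constants$rmr_intercept_kcal$male,
                      constants$rmr_intercept_kcal$female)
  intercept + constants$rmr_kcal_per_kg_ffm * ffm +
    constants$rmr_kcal_per_kg_fm * fm +
    ifelse(age < 18, constants$growth_kcal_per_day_minor, 0)
}

# Forbes-style fat-free share of the energy surplus
partition_fraction <- function(fm, constants) {
  constants$forbes_c_kg / (constants$forbes_c_kg + fm)
}

#' One daily energy-balance step
#'
#' Converts the day's caloric surplus `S = intake - resting - activity`
#' into compartment mass changes: a fraction `p = C/(C + fm)` of `S` goes
#' to the fat-free compartment at energy density `rho_L`, the rest to fat
#' at `rho_F`.  Masses are floored at the configured physiologic minima;
#' a step that hits a floor is flagged in the result.
#'
#' @param state List with `ffm` and `fm` (kg); vectorized.
#' @param intake_kcal,activity_kcal,resting_kcal Day's energy terms
#'   (kcal).  `resting_kcal` should include any growth term.
#' @param constants The `metabolic` block.
#' @return List with updated `ffm`, `fm`, the surplus `surplus_kcal`, and
#'   logical `clipped`.
#' @export
step_day <- function(state, intake_kcal, activity_kcal, resting_kcal,
                     constants) {
  stopifnot(all(is.finite(intake_kcal)), all(is.finite(activity_kcal)),
            all(is.finite(resting_kcal)))
  s <- intake_kcal - resting_kcal - activity_kcal
  p <- partition_fraction(state$fm, constants)
  ffm <- state$ffm + p * s / constants$rho_lean_kcal_per_kg
  fm <- state$fm + (1 - p) * s / constants$rho_fat_kcal_per_kg
  clipped <- fm < constants$min_fat_mass_kg |
    ffm < constants$min_fat_free_mass_kg
  if (any(clipped)) {
    fm <- pmax(fm, constants$min_fat_mass_kg)
    ffm <- pmax(ffm, constants$min_fat_free_mass_kg)
  }
  list(ffm = ffm, fm = fm, surplus_kcal = s, clipped = clipped)
}

# Deterministic forward model used by the maintenance solver: integrates
# the expected-energy dynamics in `step_days`-day steps (the expected
# daily balance held constant within a step) and returns the
# end-of-horizon state.  `k` is the expected daily activity kcal per kg
# of body mass; `rmr0` the mass-independent part of daily expenditure.
forward_expected <- function(ffm, fm, rmr0, intake, k, constants,
                             n_steps, step_days) {
  cff <- constants$rmr_kcal_per_kg_ffm
  cfm <- constants$rmr_kcal_per_kg_fm
  cforbes <- constants$forbes_c_kg
  rl <- constants$rho_lean_kcal_per_kg
  rf <- constants$rho_fat_kcal_per_kg
  for (w in seq_len(n_steps)) {
    s <- step_days * (intake - rmr0 - cff * ffm - cfm * fm -
                        k * (ffm + fm))
    p <- cforbes / (cforbes + fm)
    ffm <- pmax(ffm + p * s / rl, constants$min_fat_free_mass_kg)
    fm <- pmax(fm + (1 - p) * s / rf, constants$min_fat_mass_kg)
  }
  list(ffm = ffm, fm = fm)
}

# Vectorized maintenance-intake solver: bisection on daily intake so that
# the BMI-for-age percentile after `horizon_days` of expected-activity
# dynamics equals today's percentile (intake bracketed to ~1 kcal/day).
solve_maintenance <- function(ffm, fm, age, sex, k, ref, constants,
                              horizon_days = 364, iters = 14L,
                              step_days = 14) {
  h0 <- median_height(age, sex, ref)
  p0 <- bmi_percentile(age, sex, (ffm + fm) / h0^2, ref)
  n_steps <- max(1L, round(horizon_days / step_days))
  rmr0 <- ifelse(sex == "male", constants$rmr_intercept_kcal$male,
                 constants$rmr_intercept_kcal$female) +
    constants$growth_kcal_per_day_minor
  age_end <- pmin(age + n_steps * step_days / 365, ref$age_range[2])
  h1 <- median_height(age_end, sex, ref)
  t1 <- lms_terms(age_end, sex, ref)
  lo <- rep(0, length(ffm))
  hi <- rep(12000, length(ffm))
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    st <- forward_expected(ffm, fm, rmr0, mid, k, constants,
                           n_steps, step_days)
    bmi1 <- (st$ffm + st$fm) / h1^2
    p1 <- stats::pnorm(((bmi1 / t1$M)^t1$L - 1) / (t1$L * t1$S))
    over <- p1 > p0
    hi[over] <- mid[over]
    lo[!over] <- mid[!over]
  }
  (lo + hi) / 2
}

#' Maintenance caloric intake for an agent
#'
#' The daily intake that holds the agent's BMI-for-age percentile constant
#' over `horizon_days` under its expected baseline activity expenditure
#' (height growth per the reference is included, so absolute BMI changes
#' while the percentile does not).  Solved by bisection to about 1
#' kcal/day.
#'
#' @param agent A one-row cohort data frame or list with `sex`,
#'   `age_group`, `age`, `ffm`, `fm`, `u_sport`.
#' @param params A `model_params` bundle (activity + sports define the
#'   expected activity; `metabolic` supplies the constants).
#' @param ref A `growth_reference`.
#' @param horizon_days Solve horizon (default 365).
#' @return kcal/day.
#' @export
maintenance_intake <- function(agent, params, ref = load_growth_reference(),
                               horizon_days = 365) {
  cohort <- as.data.frame(
    agent[c("sex", "age_group", "age", "ffm", "fm", "u_sport")],
    stringsAsFactors = FALSE)
  if (any(cohort$age >= 18)) stop("maintenance intake is defined for minors")
  pr <- activity_profile(cohort, params)
  k <- expected_activity_kcal_per_kg(pr, params$metabolic)
  solve_maintenance(cohort$ffm, cohort$fm, cohort$age, cohort$sex, k, ref,
                    params$metabolic, horizon_days = horizon_days)
}

#' Simulate a cohort's childhood in daily timesteps
#'
#' Runs every agent from its entry age to 18 in 1-day steps grouped into
#' weeks: at each week a fresh activity schedule is drawn
#' ([draw_weekly_schedule()] semantics, vectorized), and each day the
#' energy balance is stepped ([step_day()]).  Maintenance intake is
#' re-solved every 52 simulated weeks under *baseline* expected activity;
#' passing a previously recorded `intake_schedule` (from the baseline run)
#' freezes intake for a counterfactual scenario run, which is what turns
#' added activity into weight loss.  With the same `seed`, the same
#' cohort, and the same number of agents, the stream of random draws is
#' identical across runs (common random numbers), and scenario parameter
#' changes couple monotonically through the inverse-CDF draws.
#'
#' @param cohort A cohort data frame from [build_cohort()].
#' @param params A `model_params` bundle; its `activity`/`sports` blocks
#'   define the (possibly scenario-transformed) behavior.
#' @param seed Integer seed for the weekly behavioral draws.
#' @param ref A `growth_reference`.
#' @param intake_schedule Optional matrix (agents x years) of daily intakes
#'   recorded by a previous (baseline) run.  If `NULL`, maintenance intake
#'   is solved per year from the agents' current state.
#' @param baseline_params Bundle used for the maintenance solve (defaults
#'   to `params`); scenarios pass the baseline bundle here or an explicit
#'   `intake_schedule`.
#' @param max_weeks Optional cap on simulated weeks (e.g., 52 for a
#'   one-year stationarity check).
#' @return A list: `cohort` (final state, age capped at 18), `intakes`
#'   (agents x years matrix), `energy` (per-agent cumulative intake and
#'   expenditure, kcal), `clipped` (logical per agent: a mass floor was
#'   hit), `days` (per-agent days simulated).
#' @export
simulate_childhood_cohort <- function(cohort, params, seed,
                                      ref = load_growth_reference(),
                                      intake_schedule = NULL,
                                      baseline_params = params,
                                      max_weeks = Inf) {
  n <- nrow(cohort)
  constants <- params$metabolic
  pr <- activity_profile(cohort, params)
  pr_base <- activity_profile(cohort, baseline_params)
  k_base <- expected_activity_kcal_per_kg(pr_base, constants)
  cc <- constants$kcal_per_met_min_per_kg
  cff <- constants$rmr_kcal_per_kg_ffm
  cfm <- constants$rmr_kcal_per_kg_fm
  cforbes <- constants$forbes_c_kg
  rl <- constants$rho_lean_kcal_per_kg
  rf <- constants$rho_fat_kcal_per_kg
  fm_floor <- constants$min_fat_mass_kg
  ffm_floor <- constants$min_fat_free_mass_kg
  rmr0 <- ifelse(cohort$sex == "male", constants$rmr_intercept_kcal$male,
                 constants$rmr_intercept_kcal$female) +
    constants$growth_kcal_per_day_minor
  # truncation probabilities of the weekly draws, fixed per agent
  d_plo <- stats::pnorm(0, pr$days_mean, pr$days_sd)
  d_pspan <- stats::pnorm(7, pr$days_mean, pr$days_sd) - d_plo
  m_plo <- stats::pnorm(1, pr$met_mean, pr$met_sd)

  sex <- cohort$sex
  age <- cohort$age
  ffm <- cohort$ffm
  fm <- cohort$fm
  days_left <- pmax(0L, as.integer(round((18 - age) * 365)))
  n_years <- ceiling(max(days_left) / 364) + 1L
  intakes <- matrix(NA_real_, n, n_years)
  intake <- numeric(n)
  cum_in <- cum_out <- numeric(n)
  clipped <- logical(n)
  days_done <- integer(n)
  sports_min_daily <- pr$sports_min / 7 * pr$sports

  set.seed(seed)
  week <- 0L
  while (any(days_left > 0L) && week < max_weeks) {
    if (week %% 52L == 0L) {
      yi <- week %/% 52L + 1L
      act <- days_left > 0L
      if (!is.null(intake_schedule)) {
        intake[act] <- intake_schedule[act, yi]
      } else {
        intake[act] <- solve_maintenance(
          ffm[act], fm[act], age[act], sex[act], k_base[act], ref,
          constants)
      }
      intakes[act, yi] <- intake[act]
    }
    act <- days_left > 0L
    na <- sum(act)
    # weekly behavioral draws (inverse-CDF, identical stream layout to
    # draw_weekly_schedules) are taken for the full active set so that
    # paired runs consume identical random streams
    u_days <- stats::runif(na)
    u_round <- stats::runif(na)
    u_met <- stats::runif(na)
    u_smet <- stats::runif(na)
    x <- stats::qnorm(d_plo[act] + u_days * d_pspan[act],
                      pr$days_mean[act], pr$days_sd[act])
    x <- pmin(pmax(x, 0), 7)
    dw_days <- floor(x) + (u_round < (x - floor(x)))
    met <- stats::qnorm(m_plo[act] + u_met * (1 - m_plo[act]),
                        pr$met_mean[act], pr$met_sd[act])
    met <- pmax(met, 1)
    met[!is.finite(met)] <- pr$met_mean[act][!is.finite(met)]
    smet <- qtriangular(u_smet, pr$smet_min[act], pr$smet_mode[act],
                        pr$smet_max[act])
    dw <- list(days = dw_days, met = met, smet = smet)
    a_ffm <- ffm[act]; a_fm <- fm[act]
    a_int <- intake[act]
    a_left <- days_left[act]
    a_left_start <- a_left
    a_in <- cum_in[act]; a_out <- cum_out[act]; a_clip <- clipped[act]
    met1 <- (dw$met - 1) * cc
    smet_kcal_per_kg <- (dw$smet - 1) * cc * sports_min_daily[act]
    amin <- pr$active_min[act]; npmin <- pr$non_pa_min[act]
    a_rmr0 <- rmr0[act]
    for (d in 1:7) {
      live <- a_left > 0L
      if (!all(live)) {
        if (!any(live)) break
        # partial final week: freeze finished agents
        minutes <- npmin + (amin - npmin) * (d <= dw$days)
        mass <- a_ffm + a_fm
        act_kcal <- (met1 * minutes + smet_kcal_per_kg) * mass
        rmr <- a_rmr0 + cff * a_ffm + cfm * a_fm
        s <- a_int - rmr - act_kcal
        p <- cforbes / (cforbes + a_fm)
        nffm <- a_ffm + p * s / rl
        nfm <- a_fm + (1 - p) * s / rf
        cl <- nfm < fm_floor | nffm < ffm_floor
        a_ffm[live] <- pmax(nffm, ffm_floor)[live]
        a_fm[live] <- pmax(nfm, fm_floor)[live]
        a_clip <- a_clip | (cl & live)
        a_in[live] <- a_in[live] + a_int[live]
        a_out[live] <- a_out[live] + (rmr + act_kcal)[live]
        a_left[live] <- a_left[live] - 1L
      } else {
        minutes <- npmin + (amin - npmin) * (d <= dw$days)
        mass <- a_ffm + a_fm
        act_kcal <- (met1 * minutes + smet_kcal_per_kg) * mass
        rmr <- a_rmr0 + cff * a_ffm + cfm * a_fm
        s <- a_int - rmr - act_kcal
        p <- cforbes / (cforbes + a_fm)
        nffm <- a_ffm + p * s / rl
        nfm <- a_fm + (1 - p) * s / rf
        cl <- nfm < fm_floor | nffm < ffm_floor
        if (any(cl)) {
          a_clip <- a_clip | cl
          nffm <- pmax(nffm, ffm_floor)
          nfm <- pmax(nfm, fm_floor)
        }
        a_ffm <- nffm
        a_fm <- nfm
        a_in <- a_in + a_int
        a_out <- a_out + rmr + act_kcal
        a_left <- a_left - 1L
      }
    }
    ffm[act] <- a_ffm; fm[act] <- a_fm
    age[act] <- age[act] + pmin(7L, a_left_start) / 365
    days_left[act] <- a_left
    cum_in[act] <- a_in; cum_out[act] <- a_out; clipped[act] <- a_clip
    days_done[act] <- days_done[act] + pmin(7L, a_left_start)
    week <- week + 1L
  }

  out <- cohort
  out$ffm <- ffm
  out$fm <- fm
  out$age <- age
  finished <- days_left == 0L
  out$age[finished] <- 18
  list(cohort = out, intakes = intakes,
       energy = data.frame(cum_intake_kcal = cum_in,
                           cum_expenditure_kcal = cum_out),
       clipped = clipped, days = days_done)
}

#' Simulate one agent's childhood
#'
#' Single-agent wrapper around [simulate_childhood_cohort()].
#'
#' @inheritParams maintenance_intake
#' @param seed Integer seed.
#' @param ... Passed to [simulate_childhood_cohort()].
#' @return The result list of [simulate_childhood_cohort()] for a cohort
#'   of one.
#' @export
simulate_childhood <- function(agent, params, seed,
                               ref = load_growth_reference(), ...) {
  cohort <- as.data.frame(
    agent[c("sex", "age_group", "age", "ffm", "fm", "u_sport")],
    stringsAsFactors = FALSE)
  simulate_childhood_cohort(cohort, params, seed, ref, ...)
}
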