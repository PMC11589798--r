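# Weekly stochastic physical-activity behavior and its conversion into
# daily net (above-resting) caloric expenditure.
#
# Each simulated week an agent draws (i) a mean number of days with >= 60
# minutes of activity from its stratum's truncated-normal distribution on
# [0, 7], stochastically rounded to an integer so the long-run mean equals
# the drawn value; (ii) an activity intensity in METs, truncated below at
# 1 (resting); and, for sports participants, (iii) a sports intensity from
# a triangular distribution honoring the published mean and range.  All
# draws are inverse-CDF transforms of uniforms, so under common random
# numbers every draw is monotone in the underlying mean - the property the
# paired scenario comparisons rely on.

# triangular(min, mode, max) by inverse CDF
qtriangular <- function(u, min, mode, max) {
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

# per-agent activity parameter vectors for a cohort under a given bundle
activity_profile <- function(cohort, params) {
  s_key <- stratum_key(cohort$sex, cohort$age_group)
  act <- params$activity
  sp <- params$sports
  male <- cohort$sex == "male"
  pick <- function(block, field) {
    vapply(STRATA, function(k) block[[k]][[field]], numeric(1))[s_key]
  }
  sexpick <- function(block, field = NULL) {
    m <- if (is.null(field)) block$male else block$male[[field]]
    f <- if (is.null(field)) block$female else block$female[[field]]
    ifelse(male, m, f)
  }
  p_sport <- sexpick(sp$participation_pct) / 100
  list(
    days_mean = unname(pick(act$days_per_week, "mean")),
    days_sd = unname(pick(act$days_per_week, "sd")),
    met_mean = sexpick(act$intensity_met, "mean"),
    met_sd = sexpick(act$intensity_met, "sd"),
    active_min = sexpick(act$active_day_minutes),
    non_pa_min = sexpick(act$non_pa_day_minutes),
    sports = cohort$u_sport < p_sport,
    sports_min = sexpick(sp$mvpa_min_week),
    smet_min = sexpick(sp$intensity_met, "min"),
    smet_mode = sexpick(sp$intensity_met, "mean"),
    smet_max = sexpick(sp$intensity_met, "max")
  )
}

# one week of draws for all agents in `profile` (vectorized); uses 4
# uniforms per agent in fixed order
draw_weekly_schedules <- function(profile, n) {
  u_days <- stats::runif(n)
  u_round <- stats::runif(n)
  u_met <- stats::runif(n)
  u_smet <- stats::runif(n)
  x <- qtruncnorm(u_days, profile$days_mean, profile$days_sd, 0, 7)
  days <- floor(x) + (u_round < (x - floor(x)))
  met <- qtruncnorm(u_met, profile$met_mean, profile$met_sd, lower = 1)
  smet <- qtriangular(u_smet, profile$smet_min, profile$smet_mode,
                      profile$smet_max)
  list(days = days, met = met, smet = smet)
}

#' Draw one weekly activity schedule for an agent
#'
#' @param agent A one-row cohort data frame or a list with fields `sex`,
#'   `age_group`, `u_sport`.
#' @param params A `model_params` bundle.
#' @return A `weekly_schedule` list: `active_days` (integer 0-7),
#'   `active_day_minutes`, `non_pa_day_minutes`, `intensity_met`,
#'   `sports_mvpa_min` (0 for non-participants), `sports_met`.
#' @export
draw_weekly_schedule <- function(agent, params) {
  cohort <- as.data.frame(agent[c("sex", "age_group", "u_sport")],
                          stringsAsFactors = FALSE)
  pr <- activity_profile(cohort, params)
  d <- draw_weekly_schedules(pr, 1L)
  structure(list(
    active_days = as.integer(d$days),
    active_day_minutes = pr$active_min,
    non_pa_day_minutes = pr$non_pa_min,
    intensity_met = d$met,
    sports_mvpa_min = if (pr$sports) pr$sports_min else 0,
    sports_met = d$smet
  ), class = "weekly_schedule")
}

#' Net caloric expenditure of one day's activity
#'
#' Energy above rest for each activity block that day:
#' `(MET - 1) * c * mass * minutes`, where `c` is the kcal-per-MET-minute
#' constant (default 3.5/200 = 0.0175 kcal/kg/min).  Days `0 ..
#' active_days - 1` of the week are active days (>= 60 min at the weekly
#' intensity); the rest are non-PA days at the configured shorter
#' duration.  Sports MVPA is spread evenly across the 7 days and added on
#' top for participants.
#'
#' @param schedule A `weekly_schedule` from [draw_weekly_schedule()].
#' @param day_index Day of the week, 0-6.
#' @param mass_kg Body mass in kg.
#' @param constants The `metabolic` block of a `model_params` bundle.
#' @return Net kcal expended above rest that day.
#' @export
daily_activity_kcal <- function(schedule, day_index, mass_kg,
                                constants = load_params()$metabolic) {
  if (day_index < 0 || day_index > 6) stop("day_index must be in 0..6")
  minutes <- if (day_index < schedule$active_days) {
    schedule$active_day_minutes
  } else {
    schedule$non_pa_day_minutes
  }
  if (minutes < 0 || schedule$sports_mvpa_min < 0) {
    stop("minutes must be >= 0")
  }
  cc <- constants$kcal_per_met_min_per_kg
  (schedule$intensity_met - 1) * cc * mass_kg * minutes +
    (schedule$sports_met - 1) * cc * mass_kg * schedule$sports_mvpa_min / 7
}

# Expected daily activity kcal PER KG of body mass for each agent
# (closed-form expectations of the truncated-normal and triangular draws;
# matches the generator exactly, so maintenance intake is unbiased).
expected_activity_kcal_per_kg <- function(profile, constants) {
  e_days <- truncnorm_mean(profile$days_mean, profile$days_sd, 0, 7)
  e_met <- truncnorm_mean(profile$met_mean, profile$met_sd, lower = 1)
  e_smet <- (profile$smet_min + profile$smet_mode + profile$smet_max) / 3
  week_min <- profile$active_min * e_days +
    profile$non_pa_min * (7 - e_days)
  cc <- constants$kcal_per_met_min_per_kg
  cc * ((e_met - 1) * week_min +
          (e_smet - 1) * profile$sports_min * profile$sports) / 7
}
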