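# Scenario construction and paired baseline/counterfactual experiments.
#
# A scenario shrinks the female-male gap in one or more behavioral
# dimensions by a fraction r: female <- female + r * (male - female); male
# parameters are untouched.  Each replicate builds ONE cohort and
# simulates it under both parameter bundles with identical random streams
# (common random numbers), so per-agent paired differences isolate the
# intervention.  Replicate summaries are scaled to national counts and
# reported as means with percentile 95% CIs.

SCENARIO_DIMENSIONS <- c("pa_days", "pa_intensity", "pa_minutes",
                         "sports_participation", "sports_mvpa")

#' Construct a scenario specification
#'
#' @param dimensions Nonempty subset of
#'   `c("pa_days", "pa_intensity", "pa_minutes", "sports_participation",
#'   "sports_mvpa")`.
#' @param fraction Disparity-reduction fraction r in `[0, 1]` (1 =
#'   eliminate the gap, 0 = no change).
#' @param non_pa_minutes Optional override of minutes of activity on
#'   non-PA days (applied to both sexes; sensitivity range 0-45).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(dimensions, fraction,
                          non_pa_minutes = NULL) {
  if (length(dimensions) == 0) stop("dimension set must be nonempty")
  unknown <- setdiff(dimensions, SCENARIO_DIMENSIONS)
  if (length(unknown) > 0) {
    stop("unknown scenario dimension(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]")
  }
  structure(list(dimensions = dimensions, fraction = fraction,
                 non_pa_minutes = non_pa_minutes),
            class = "scenario_spec")
}

#' Apply a disparity-reduction transform to a parameter bundle
#'
#' For every selected dimension (and every age group where the dimension
#' is age-group specific), the female parameter moves toward the male one:
#' `female + r * (male - female)`.  `r = 0` is the identity; `r = 1`
#' eliminates the gap (e.g., female 12-17 mean active days 3.07 -> 3.68).
#' The input bundle is not modified.
#'
#' @param params A `model_params` bundle.
#' @param spec A [scenario_spec()].
#' @return A new, transformed `model_params` bundle.
#' @export
apply_disparity_reduction <- function(params, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  r <- spec$fraction
  lerp <- function(f, m) f + r * (m - f)
  out <- params
  for (dim in spec$dimensions) {
    if (dim == "pa_days") {
      for (g in c("6_11", "12_17")) {
        f <- out$activity$days_per_week[[paste0("female_", g)]]
        m <- out$activity$days_per_week[[paste0("male_", g)]]
        f$mean <- lerp(f$mean, m$mean)
        f$sd <- lerp(f$sd, m$sd)
        out$activity$days_per_week[[paste0("female_", g)]] <- f
      }
    } else if (dim == "pa_intensity") {
      f <- out$activity$intensity_met$female
      m <- out$activity$intensity_met$male
      f$mean <- lerp(f$mean, m$mean)
      f$sd <- lerp(f$sd, m$sd)
      out$activity$intensity_met$female <- f
    } else if (dim == "pa_minutes") {
      out$activity$active_day_minutes$female <-
        lerp(out$activity$active_day_minutes$female,
             out$activity$active_day_minutes$male)
      out$activity$non_pa_day_minutes$female <-
        lerp(out$activity$non_pa_day_minutes$female,
             out$activity$non_pa_day_minutes$male)
    } else if (dim == "sports_participation") {
      out$sports$participation_pct$female <-
        lerp(out$sports$participation_pct$female,
             out$sports$participation_pct$male)
    } else if (dim == "sports_mvpa") {
      out$sports$mvpa_min_week$female <-
        lerp(out$sports$mvpa_min_week$female,
             out$sports$mvpa_min_week$male)
    }
  }
  if (!is.null(spec$non_pa_minutes)) {
    out$activity$non_pa_day_minutes$male <- spec$non_pa_minutes
    out$activity$non_pa_day_minutes$female <- spec$non_pa_minutes
  }
  out
}

# classify an end-of-childhood cohort (age 18, adult BMI cut points)
classify_at_18 <- function(sim, ref) {
  h <- median_height(rep(18, nrow(sim$cohort)), sim$cohort$sex, ref)
  bmi <- (sim$cohort$ffm + sim$cohort$fm) / h^2
  classify_weight_status(rep(18, nrow(sim$cohort)), sim$cohort$sex, bmi, ref)
}

#' Run one paired baseline/scenario replicate
#'
#' Builds one cohort from `seed`, simulates childhood under the baseline
#' and each scenario parameter bundle with identical random streams (the
#' scenario reuses the baseline maintenance-intake schedule), then -
#' unless `horizon = "childhood"` - simulates the adult Markov model and
#' cost/QALY accrual for both arms, again with shared streams.
#'
#' @param params Baseline `model_params`.
#' @param scenarios A named list of scenario `model_params` bundles (from
#'   [apply_disparity_reduction()]), or a single bundle.
#' @param scale Cohort scale fraction.
#' @param seed Integer replicate seed (sub-seeds are derived as `seed`,
#'   `seed + 1`, `seed + 2` for cohort build, childhood, adulthood).
#' @param horizon `"lifetime"` (default) or `"childhood"` (skip the adult
#'   and economic stages; weight outcomes only).
#' @param ref A `growth_reference`.
#' @return A list with `cohort`, `baseline` and per-scenario `scenarios`
#'   entries; each arm holds `category` (at 18) and, for lifetime runs,
#'   `history` and `ledger`.
#' @export
run_replicate <- function(params, scenarios, scale, seed,
                          horizon = c("lifetime", "childhood"),
                          ref = load_growth_reference()) {
  horizon <- match.arg(horizon)
  if (inherits(scenarios, "model_params")) {
    scenarios <- list(scenario = scenarios)
  }
  cohort <- build_cohort(params, scale, seed, calibrate = TRUE, ref = ref)
  base_sim <- simulate_childhood_cohort(cohort, params, seed + 1L, ref)
  arm <- function(sim) {
    out <- list(category = classify_at_18(sim, ref), clipped = sim$clipped)
    if (horizon == "lifetime") {
      out$history <- simulate_adult_cohort(out$category, cohort$sex,
                                           params$disease, seed + 2L)
      out$ledger <- accrue_lifetime_cohort(out$history, cohort$age, params)
    }
    out
  }
  res <- list(cohort = cohort, baseline = arm(base_sim))
  res$scenarios <- lapply(scenarios, function(sp) {
    sim <- simulate_childhood_cohort(cohort, sp, seed + 1L, ref,
                                     intake_schedule = base_sim$intakes)
    arm(sim)
  })
  res
}

#' Outcome deltas for one paired replicate
#'
#' Scenario-minus-baseline benefit for one [run_replicate()] result, by
#' age group and overall, scaled to national counts (divide by `scale`).
#' Count outcomes follow the reporting convention: female agents only
#' (scenarios target females; male deltas are identically zero under
#' common random numbers); prevalence change is measured over the whole
#' population in percentage points.
#'
#' @param rep_result A [run_replicate()] result.
#' @param which_scenario Name of the scenario entry to contrast.
#' @param scale The cohort scale fraction used to build the replicate.
#' @return A data frame with one row per age group plus a total row:
#'   averted overweight/obesity cases, prevalence change, and - for
#'   lifetime runs - per-condition cases and deaths averted, QALYs and
#'   life-years saved, and direct/productivity/societal savings.
#' @export
replicate_outcomes <- function(rep_result, which_scenario, scale) {
  cohort <- rep_result$cohort
  b <- rep_result$baseline
  s <- rep_result$scenarios[[which_scenario]]
  fem <- cohort$sex == "female"
  owob_b <- b$category != "healthy"
  owob_s <- s$category != "healthy"
  lifetime <- !is.null(b$history)
  groups <- list(`6-11` = cohort$age_group == "6-11",
                 `12-17` = cohort$age_group == "12-17",
                 total = rep(TRUE, nrow(cohort)))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    fi <- i & fem
    out <- data.frame(
      group = g,
      n_group = sum(i),
      cases_averted = (sum(owob_b[fi]) - sum(owob_s[fi])) / scale,
      prevalence_change_pp =
        100 * (mean(owob_b[i]) - mean(owob_s[i])),
      stringsAsFactors = FALSE)
    if (lifetime) {
      onset_b <- !is.na(b$history$onset_age[fi, , drop = FALSE])
      onset_s <- !is.na(s$history$onset_age[fi, , drop = FALSE])
      for (cn in CONDITIONS) {
        out[[paste0("cases_averted_", cn)]] <-
          (sum(onset_b[, cn]) - sum(onset_s[, cn])) / scale
        out[[paste0("deaths_averted_", cn)]] <-
          (sum(b$history$death_cause[fi] == cn, na.rm = TRUE) -
             sum(s$history$death_cause[fi] == cn, na.rm = TRUE)) / scale
      }
      out$disease_cases_averted <- sum(vapply(
        c("cancer", "chd", "diabetes", "stroke"),
        function(cn) out[[paste0("cases_averted_", cn)]], numeric(1)))
      out$qalys_saved <-
        (sum(s$ledger$qalys[fi]) - sum(b$ledger$qalys[fi])) / scale
      out$life_years_saved <-
        (sum(s$ledger$life_years[fi]) - sum(b$ledger$life_years[fi])) / scale
      out$direct_savings_usd <-
        (sum(b$ledger$direct_usd[i]) - sum(s$ledger$direct_usd[i])) / scale
      out$productivity_savings_usd <-
        (sum(b$ledger$productivity_usd[i]) -
           sum(s$ledger$productivity_usd[i])) / scale
      out$societal_savings_usd <-
        (sum(b$ledger$societal_usd[i]) - sum(s$ledger$societal_usd[i])) / scale
    }
    out
  })
  do.call(rbind, rows)
}

#' Summarize replicate outcomes
#'
#' Means and percentile-based 95% CIs across replicates for every outcome
#' column, per age group and overall.
#'
#' @param replicate_tables List (length >= 2) of per-replicate outcome
#'   tables from the grid runner.
#' @return A long data frame: `group`, `outcome`, `mean`, `lo`, `hi`.
#' @export
summarize_outcomes <- function(replicate_tables) {
  if (length(replicate_tables) < 2) stop("need >= 2 replicates")
  all_t <- do.call(rbind, replicate_tables)
  outcomes <- setdiff(names(all_t), c("group", "n_group"))
  rows <- list()
  for (g in unique(all_t$group)) {
    for (oc in outcomes) {
      v <- all_t[all_t$group == g, oc]
      qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, outcome = oc, mean = mean(v), lo = qs[1], hi = qs[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a disparity-reduction experiment grid
#'
#' For each replicate seed, builds one cohort, runs the baseline once, and
#' runs one counterfactual per reduction fraction against it with common
#' random numbers; summarizes outcomes per fraction across replicates.
#'
#' @param params Baseline `model_params`.
#' @param dimensions Scenario dimensions (see [scenario_spec()]).
#' @param fractions Reduction fractions (default `c(0.25, 0.5, 0.75, 1)`).
#' @param scale Cohort scale fraction.
#' @param n_replicates Number of replicates (default 25).
#' @param base_seed Base seed; replicate r uses `base_seed + 101 * r`.
#' @param non_pa_minutes Optional non-PA-day minutes override (both arms).
#' @param horizon `"lifetime"` or `"childhood"`.
#' @param ref A `growth_reference`.
#' @return A list with `summary` (per-fraction summaries, long format with
#'   a `fraction` column) and `replicates` (per-fraction lists of raw
#'   per-replicate outcome tables).
#' @export
run_experiment_grid <- function(params, dimensions,
                                fractions = c(0.25, 0.5, 0.75, 1),
                                scale, n_replicates = 25, base_seed = 1,
                                non_pa_minutes = NULL,
                                horizon = "lifetime",
                                ref = load_growth_reference()) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0,1]")
  base <- params
  if (!is.null(non_pa_minutes)) {
    base <- apply_disparity_reduction(
      params, scenario_spec(dimensions[1], 0, non_pa_minutes))
  }
  scens <- lapply(fractions, function(r)
    apply_disparity_reduction(base, scenario_spec(dimensions, r)))
  names(scens) <- paste0("r", fractions)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- base_seed + 101L * r
    rr <- run_replicate(base, scens, scale, seed_r, horizon = horizon,
                        ref = ref)
    reps[[r]] <- lapply(names(scens), function(nm)
      replicate_outcomes(rr, nm, scale))
    names(reps[[r]]) <- names(scens)
  }
  per_fraction <- lapply(names(scens), function(nm)
    lapply(reps, `[[`, nm))
  names(per_fraction) <- names(scens)
  summaries <- lapply(seq_along(fractions), function(j) {
    s <- summarize_outcomes(per_fraction[[j]])
    s$fraction <- fractions[j]
    s
  })
  list(summary = do.call(rbind, summaries), replicates = per_fraction)
}
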