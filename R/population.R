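# Synthetic agent cohort: stratified instantiation from census counts,
# survey-derived body-composition marginals, and prevalence calibration.

#' Truncated-normal draws by inverse-CDF
#'
#' One uniform per draw (important for common-random-number coupling:
#' the draw is monotone in `mean`, so raising the mean raises every
#' coupled draw).  `sd = 0` returns the mean.
#'
#' @param u Uniform(0,1) variates.
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @param lower,upper Truncation bounds.
#' @return Draws from Normal(mean, sd) truncated to `[lower, upper]`.
#' @keywords internal
qtruncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) stop("sd must be >= 0")
  if (all(sd == 0)) return(rep_len(mean, length(u)) + 0 * u)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  # sd == 0 elements and numerical tail overflow
  x[!is.finite(x)] <- mean[!is.finite(x)]
  pmin(pmax(x, lower), upper)
}

# mean of Normal(mean, sd) truncated to [lower, upper]
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    a <- (lower - mean[pos]) / sd[pos]
    b <- (upper - mean[pos]) / sd[pos]
    out[pos] <- mean[pos] + sd[pos] *
      (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  out
}

#' Largest-remainder apportionment of stratum counts
#'
#' Scales the four sex x age-group census counts by `scale` and rounds to
#' integers conserving the rounded total: floors first, then one extra
#' agent to the strata with the largest fractional remainders (ties broken
#' by fixed stratum order for reproducibility).
#'
#' @param params A `model_params` bundle.
#' @param scale Fraction of the national counts to instantiate, in (0, 1].
#' @return Named integer vector over the four strata.
#' @export
apportion_counts <- function(params, scale) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop("scale must be in (0, 1]")
  }
  raw <- vapply(STRATA, function(s) params$demography$counts[[s]] * scale,
                numeric(1))
  total <- round(sum(raw))
  base <- floor(raw)
  rem <- raw - base
  k <- as.integer(total - sum(base))
  if (k > 0) {
    # ties broken by position in STRATA (stable order)
    extra <- order(rem, decreasing = TRUE)[seq_len(k)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), STRATA)
}

#' Sample body composition for one stratum
#'
#' Draws fat-free mass and fat mass (kg) from independent truncated-normal
#' distributions (lower bound 0, so every draw is strictly positive) with
#' the stratum's published mean/SD.  The fat-mass rows honor the bundle's
#' `fat_mass_interpretation` flag.
#'
#' When `u_age` (each agent's age rank within the band, in (0, 1)) is
#' supplied, draws are coupled to age through a Gaussian copula with rank
#' correlation `body_composition$age_rank_correlation`: younger agents get
#' systematically smaller masses, as in any growing population, while the
#' stratum-wide marginal distribution is preserved exactly.  Without
#' `u_age` the draws are plain marginal samples.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_group `"6-11"` or `"12-17"`.
#' @param params A `model_params` bundle (its `body_composition` block is
#'   used).
#' @param n Number of draws.
#' @param u_age Optional vector of age ranks in (0, 1) for age coupling.
#' @return A list with numeric vectors `ffm` and `fm` (kg).
#' @export
sample_body_composition <- function(sex, age_group, params, n,
                                    u_age = NULL) {
  key <- stratum_key(sex, age_group)
  ffm_p <- params$body_composition$fat_free_mass_kg[[key]]
  fm_p <- fat_mass_kg_params(params, key)
  if (ffm_p$sd < 0 || fm_p$sd < 0) stop("sd must be >= 0")
  rho <- params$body_composition$age_rank_correlation
  if (is.null(rho) || is.null(u_age)) rho <- 0
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  if (rho > 0) {
    za <- stats::qnorm(pmin(pmax(u_age, 1e-12), 1 - 1e-12))
    z1 <- rho * za + sqrt(1 - rho^2) * z1
    z2 <- rho * za + sqrt(1 - rho^2) * z2
  }
  ffm <- qtruncnorm(stats::pnorm(z1), ffm_p$mean, ffm_p$sd, lower = 0)
  fm <- qtruncnorm(stats::pnorm(z2), fm_p$mean, fm_p$sd, lower = 0)
  list(ffm = ffm, fm = fm)
}

#' Build the agent cohort
#'
#' Instantiates agents stratified by sex and age group: stratum sizes by
#' largest-remainder apportionment of `scale` x census counts, ages uniform
#' within the age band, body composition from [sample_body_composition()],
#' and a persistent per-agent sports-participation uniform (`u_sport`) that
#' makes participation monotone under scenario increases of the
#' participation probability.  Deterministic given `seed`.
#'
#' @param params A `model_params` bundle.
#' @param scale Fraction of the national population, in (0, 1].
#' @param seed Integer RNG seed.
#' @param calibrate If `TRUE` (default), calibrate fat mass to the
#'   prevalence targets via [calibrate_to_prevalence()].
#' @param ref A `growth_reference` (default: packaged synthetic reference).
#' @return A data frame (one row per agent) with columns `id`, `sex`,
#'   `age_group`, `age`, `ffm`, `fm`, `u_sport`, `sports`.
#' @export
build_cohort <- function(params, scale, seed, calibrate = TRUE,
                         ref = load_growth_reference()) {
  counts <- apportion_counts(params, scale)
  set.seed(seed)
  parts <- list()
  for (s in STRATA) {
    n <- counts[[s]]
    sex <- if (startsWith(s, "male")) "male" else "female"
    age_group <- if (endsWith(s, "6_11")) "6-11" else "12-17"
    lo <- if (age_group == "6-11") 6 else 12
    u_age <- stats::runif(n)
    age <- lo + u_age * 6
    bc <- sample_body_composition(sex, age_group, params, n,
                                  u_age = u_age)
    u_sport <- stats::runif(n)
    parts[[s]] <- data.frame(
      sex = rep(sex, n), age_group = rep(age_group, n), age = age,
      ffm = bc$ffm, fm = bc$fm, u_sport = u_sport,
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  p_sport <- ifelse(cohort$sex == "male",
                    params$sports$participation_pct$male / 100,
                    params$sports$participation_pct$female / 100)
  cohort$sports <- cohort$u_sport < p_sport
  attr(cohort, "scale") <- scale
  attr(cohort, "seed") <- seed
  if (calibrate) {
    cohort <- calibrate_to_prevalence(cohort, params, ref)
  }
  cohort
}

cohort_bmi <- function(cohort, ref) {
  h <- median_height(cohort$age, cohort$sex, ref)
  (cohort$ffm + cohort$fm) / h^2
}

#' Calibrate cohort fat mass to prevalence targets
#'
#' Applies a monotone, rank-preserving stratum-wise adjustment to fat mass
#' (an affine map `a + b * fm`, floored at the physiologic minimum) so that
#' the classified overweight and obesity fractions match the stratum
#' targets.  When the printed fat-free-mass marginal alone already exceeds
#' the target prevalence at realistic heights (so no non-negative fat mass
#' can reach the target), fat-free mass is additionally shrunk by a single
#' stratum-wise factor before the affine solve; both maps are monotone, so
#' the within-stratum rank order of fat mass is preserved.
#'
#' @param cohort A cohort data frame from [build_cohort()].
#' @param params A `model_params` bundle (targets are read from its
#'   `prevalence_targets` block; the physiologic fat-mass floor from
#'   `metabolic`).
#' @param ref A `growth_reference` for BMI-percentile classification.
#' @return The calibrated cohort; calibration constants are attached as
#'   attribute `"calibration"`.
#' @export
calibrate_to_prevalence <- function(cohort, params, ref) {
  floor_fm <- params$metabolic$min_fat_mass_kg
  cal <- list()
  for (s in STRATA) {
    sex <- if (startsWith(s, "male")) "male" else "female"
    age_group <- if (endsWith(s, "6_11")) "6-11" else "12-17"
    i <- cohort$sex == sex & cohort$age_group == age_group
    if (!any(i)) next
    q_ow <- params$prevalence_targets$overweight_pct[[s]]$mean / 100
    q_ob <- params$prevalence_targets$obesity_pct[[s]]$mean / 100
    if (q_ow + q_ob >= 1) {
      stop("infeasible prevalence targets for stratum ", s,
           ": overweight + obesity >= 100%")
    }
    q_cmb <- q_ow + q_ob

    age <- cohort$age[i]
    h <- median_height(age, sex, ref)
    ffm <- cohort$ffm[i]
    fm <- cohort$fm[i]
    # mass needed to sit exactly at the classification thresholds
    m85 <- bmi_from_percentile(age, sex, 0.85, ref) * h^2
    m95 <- bmi_from_percentile(age, sex, 0.95, ref) * h^2

    # The affine fat-mass map can hit both targets only if, with fat mass
    # at its extremes, the fat-free-mass spread alone does not already
    # exceed them: (i) at the fat floor, the fractions above each
    # threshold must be below the targets; (ii) with fat mass compressed
    # to a constant (b -> 0) chosen to match the combined target, the
    # obesity fraction must not overshoot.  If the printed fat-free-mass
    # marginal violates this at realistic heights, shrink it by the
    # smallest stratum-wise factor restoring feasibility (with a little
    # slack so the bisections have room).
    feas <- function(sc) {
      f2 <- sc * ffm
      floor_85 <- mean(f2 + floor_fm >= m85)
      floor_95 <- mean(f2 + floor_fm >= m95)
      # b -> 0 limit: constant fat mass matching the combined fraction
      alo <- floor_fm
      ahi <- max(m85 - f2) + 1
      for (it in 1:40) {
        amid <- (alo + ahi) / 2
        if (mean(f2 + pmax(floor_fm, amid) >= m85) >= q_cmb) {
          ahi <- amid
        } else {
          alo <- amid
        }
      }
      flat_95 <- mean(f2 + pmax(floor_fm, ahi) >= m95)
      # floor-stuck agents in the overweight band cap the reachable
      # obesity fraction at q_cmb - (floor_85 - floor_95) even as b -> Inf
      max(floor_85 - 0.995 * q_cmb, floor_95 - 0.995 * q_ob,
          flat_95 - 0.98 * q_ob,
          1.02 * q_ob - (q_cmb - floor_85 + floor_95))
    }
    s_ffm <- 1
    if (feas(1) > 0) {
      # feasibility is not monotone in the shrink factor at small n, so
      # scan a grid for the largest feasible factor; if sampling noise
      # leaves none feasible, take the least-infeasible (best effort -
      # at such cohort sizes the Monte-Carlo tolerance is wide anyway)
      grid <- seq(0.98, 0.40, by = -0.02)
      fv <- vapply(grid, feas, numeric(1))
      s_ffm <- if (any(fv <= 0)) grid[which(fv <= 0)[1]]
               else grid[which.min(fv)]
      ffm <- s_ffm * ffm
    }

    t85 <- m85 - ffm   # fat mass at the overweight threshold
    t95 <- m95 - ffm
    frac_ge <- function(a, b, thr) {
      mean(pmax(floor_fm, a + b * fm) >= thr)
    }
    solve_a <- function(b) {
      # shift matching the combined overweight+obesity fraction
      lo <- min(t85) - b * max(fm) - 1
      hi <- max(t85) + 1
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (frac_ge(mid, b, t85) >= q_cmb) hi <- mid else lo <- mid
      }
      hi
    }
    # spread matching the obesity fraction given the combined match
    blo <- 1e-3
    bhi <- 500
    for (it in 1:40) {
      bmid <- sqrt(blo * bhi)
      a <- solve_a(bmid)
      if (frac_ge(a, bmid, t95) >= q_ob) bhi <- bmid else blo <- bmid
    }
    b <- sqrt(blo * bhi)
    a <- solve_a(b)
    cohort$ffm[i] <- ffm
    cohort$fm[i] <- pmax(floor_fm, a + b * fm)
    cal[[s]] <- c(ffm_scale = s_ffm, a = a, b = b)
  }
  attr(cohort, "calibration") <- cal
  cohort
}

#' Measured overweight/obesity prevalence by stratum
#'
#' Classifies every agent with [classify_weight_status()] and tabulates the
#' overweight and obesity fractions per sex x age-group stratum, in
#' percent (comparable to the prevalence-target block).
#'
#' @param cohort A cohort data frame.
#' @param ref A `growth_reference`.
#' @return Data frame with columns `stratum`, `overweight_pct`,
#'   `obesity_pct`.
#' @export
measure_prevalence <- function(cohort, ref) {
  cls <- classify_weight_status(cohort$age, cohort$sex,
                                cohort_bmi(cohort, ref), ref)
  out <- lapply(STRATA, function(s) {
    sex <- if (startsWith(s, "male")) "male" else "female"
    age_group <- if (endsWith(s, "6_11")) "6-11" else "12-17"
    i <- cohort$sex == sex & cohort$age_group == age_group
    data.frame(stratum = s,
               overweight_pct = 100 * mean(cls[i] == "overweight"),
               obesity_pct = 100 * mean(cls[i] == "obesity"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a cohort to CSV
#'
#' One row per agent with the documented column dictionary: `id`, `sex`,
#' `age_group`, `age` (years), `ffm`/`fm` (kg), `u_sport` (persistent
#' participation uniform), `sports` (logical).  Round-trips with
#' [read_cohort()].
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  co <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_group", "age", "ffm", "fm", "u_sport",
            "sports")
  if (!all(need %in% names(co))) {
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  }
  co
}
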