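#' @keywords internal
"_PACKAGE"

STRATA <- c("male_6_11", "female_6_11", "male_12_17", "female_12_17")
SEXES <- c("male", "female")
AGE_GROUPS <- c("6-11", "12-17")
CONDITIONS <- c("diabetes", "chd", "stroke", "cancer",
                "neuropathy", "retinopathy", "nephropathy")
WEIGHT_CATEGORIES <- c("healthy", "overweight", "obesity")

stratum_key <- function(sex, age_group) {
  paste0(sex, "_", ifelse(age_group == "6-11", "6_11", "12_17"))
}

#' Load the model parameter bundle
#'
#' Reads a structured YAML parameter file and recursively merges it over the
#' packaged defaults, so a user file needs to list only the fields it
#' overrides.  With `path = NULL` the packaged defaults are returned.  The
#' result is validated; any invariant violation aborts with a message naming
#' the offending field (see [validate_params()]).
#'
#' @param path Path to a YAML parameter file, or `NULL` for the packaged
#'   defaults.
#' @param strict If `TRUE` (default), abort on any invariant violation.
#' @return A validated `model_params` list with blocks `demography`,
#'   `activity`, `sports`, `body_composition`, `prevalence_targets`,
#'   `metabolic`, `disease`, and `economics`.  Each block carries a `source`
#'   provenance string.
#' @export
load_params <- function(path = NULL, strict = TRUE) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_params.yaml",
                                          package = "paequity"))
  if (is.null(path)) {
    params <- defaults
  } else {
    if (!file.exists(path)) {
      stop("parameter file not found: ", path)
    }
    user <- yaml::read_yaml(path)
    params <- merge_params(defaults, user)
  }
  params <- coerce_numeric_blocks(params)
  class(params) <- c("model_params", "list")
  if (strict) {
    v <- validate_params(params)
    if (nrow(v) > 0L) {
      stop("invalid parameters:\n",
           paste0("  - ", v$field, " = ", v$value, ": ", v$rule,
                  collapse = "\n"))
    }
  }
  params
}

# recursive merge: values present in `user` override `base`
merge_params <- function(base, user) {
  if (!is.list(base) || !is.list(user) || is.null(names(user))) {
    return(user)
  }
  for (nm in names(user)) {
    if (nm %in% names(base)) {
      base[[nm]] <- merge_params(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# YAML readers may hand back integers where doubles are expected
coerce_numeric_blocks <- function(x) {
  if (is.list(x)) {
    for (i in seq_along(x)) {
      if (!is.null(x[[i]])) x[[i]] <- coerce_numeric_blocks(x[[i]])
    }
    return(x)
  }
  if (is.integer(x)) return(as.numeric(x))
  x
}

#' Write a parameter bundle to YAML
#'
#' Round-trips with [load_params()]: writing and re-loading yields an equal
#' parameter bundle (numeric values are serialized at full precision).
#'
#' @param params A `model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the parameter bundle and returns the
#' violations as data, not exceptions: one row per violated rule with the
#' offending field path, its value, and the rule text.  The packaged
#' defaults validate cleanly.
#'
#' @param params A `model_params` list (see [load_params()]).
#' @return A data frame with columns `field`, `value`, `rule`; zero rows iff
#'   all invariants hold.
#' @export
validate_params <- function(params) {
  bad <- list()
  note <- function(field, value, rule) {
    bad[[length(bad) + 1L]] <<- data.frame(
      field = field, value = as.character(value)[1], rule = rule,
      stringsAsFactors = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  # demography
  cnt <- params$demography$counts
  if (!setequal(names(cnt), STRATA)) {
    note("demography.counts", paste(names(cnt), collapse = ","),
         "exactly 4 strata (male/female x 6-11/12-17)")
  }
  for (s in names(cnt)) {
    if (!num1(cnt[[s]]) || cnt[[s]] <= 0) {
      note(paste0("demography.counts.", s), cnt[[s]], "count > 0")
    }
  }

  # activity
  act <- params$activity
  for (s in STRATA) {
    d <- act$days_per_week[[s]]
    if (!num1(d$mean) || d$mean < 0 || d$mean > 7) {
      note(paste0("activity.days_per_week.", s, ".mean"), d$mean,
           "0 <= mean days <= 7")
    }
    if (!num1(d$sd) || d$sd < 0) {
      note(paste0("activity.days_per_week.", s, ".sd"), d$sd, "sd >= 0")
    }
  }
  for (sx in SEXES) {
    im <- act$intensity_met[[sx]]
    if (!num1(im$mean) || im$mean <= 1) {
      note(paste0("activity.intensity_met.", sx, ".mean"), im$mean,
           "MET mean > 1")
    }
    if (!num1(im$sd) || im$sd < 0) {
      note(paste0("activity.intensity_met.", sx, ".sd"), im$sd, "sd >= 0")
    }
    adm <- act$active_day_minutes[[sx]]
    npm <- act$non_pa_day_minutes[[sx]]
    if (!num1(adm) || adm <= 0) {
      note(paste0("activity.active_day_minutes.", sx), adm, "minutes > 0")
    }
    if (!num1(npm) || npm < 0 || npm > adm) {
      note(paste0("activity.non_pa_day_minutes.", sx), npm,
           "non-PA minutes in [0, active-day minutes]")
    }
  }

  # sports
  sp <- params$sports
  for (sx in SEXES) {
    p <- sp$participation_pct[[sx]] / 100
    if (!num1(p) || p < 0 || p > 1) {
      note(paste0("sports.participation_pct.", sx),
           sp$participation_pct[[sx]], "participation probability in [0,1]")
    }
    if (!num1(sp$mvpa_min_week[[sx]]) || sp$mvpa_min_week[[sx]] < 0) {
      note(paste0("sports.mvpa_min_week.", sx), sp$mvpa_min_week[[sx]],
           "MVPA >= 0")
    }
    sim <- sp$intensity_met[[sx]]
    if (!(sim$min <= sim$mean && sim$mean <= sim$max)) {
      note(paste0("sports.intensity_met.", sx),
           paste(sim$min, sim$mean, sim$max),
           "MET range brackets the mean")
    }
  }

  # body composition
  bc <- params$body_composition
  if (!bc$fat_mass_interpretation %in% c("kg", "ratio_pct")) {
    note("body_composition.fat_mass_interpretation",
         bc$fat_mass_interpretation, "one of 'kg', 'ratio_pct'")
  }
  for (blk in c("fat_free_mass_kg", "fat_mass")) {
    for (s in STRATA) {
      m <- bc[[blk]][[s]]
      if (!num1(m$mean) || m$mean <= 0) {
        note(paste0("body_composition.", blk, ".", s, ".mean"), m$mean,
             "mean > 0")
      }
      if (!num1(m$sd) || m$sd < 0) {
        note(paste0("body_composition.", blk, ".", s, ".sd"), m$sd,
             "sd >= 0")
      }
    }
  }

  # prevalence targets
  pt <- params$prevalence_targets
  for (s in STRATA) {
    ow <- pt$overweight_pct[[s]]
    ob <- pt$obesity_pct[[s]]
    if (ow$mean + ob$mean >= 100) {
      note(paste0("prevalence_targets.", s), ow$mean + ob$mean,
           "overweight + obesity sum < 100%")
    }
    for (nm in c("overweight_pct", "obesity_pct")) {
      v <- pt[[nm]][[s]]
      if (!(v$lo <= v$mean && v$mean <= v$hi)) {
        note(paste0("prevalence_targets.", nm, ".", s), v$mean,
             "mean within its 95% CI bounds")
      }
    }
  }

  # metabolic constants
  mc <- params$metabolic
  for (nm in c("rho_fat_kcal_per_kg", "rho_lean_kcal_per_kg",
               "kcal_per_met_min_per_kg", "rmr_kcal_per_kg_ffm",
               "forbes_c_kg", "min_fat_mass_kg", "min_fat_free_mass_kg")) {
    if (!num1(mc[[nm]]) || mc[[nm]] <= 0) {
      note(paste0("metabolic.", nm), mc[[nm]], "positive")
    }
  }
  if (mc$rho_fat_kcal_per_kg <= mc$rho_lean_kcal_per_kg) {
    note("metabolic.rho_fat_kcal_per_kg", mc$rho_fat_kcal_per_kg,
         "fat energy density > fat-free energy density")
  }

  # disease model
  ds <- params$disease
  for (cn in names(ds$conditions)) {
    cd <- ds$conditions[[cn]]
    for (band in cd$incidence) {
      for (sx in SEXES) {
        if (band[[sx]] < 0 || band[[sx]] > 1) {
          note(paste0("disease.conditions.", cn, ".incidence.", sx),
               band[[sx]], "probability in [0,1]")
        }
      }
    }
    for (wc in WEIGHT_CATEGORIES) {
      if (cd$rr[[wc]] <= 0) {
        note(paste0("disease.conditions.", cn, ".rr.", wc), cd$rr[[wc]],
             "relative risk > 0")
      }
    }
    if (cd$excess_mortality < 0 || cd$excess_mortality > 1) {
      note(paste0("disease.conditions.", cn, ".excess_mortality"),
           cd$excess_mortality, "probability in [0,1]")
    }
    if (cd$annual_cost_usd < 0) {
      note(paste0("disease.conditions.", cn, ".annual_cost_usd"),
           cd$annual_cost_usd, "cost >= 0")
    }
    if (cd$utility < 0 || cd$utility > 1) {
      note(paste0("disease.conditions.", cn, ".utility"), cd$utility,
           "utility weight in [0,1]")
    }
  }
  for (band in ds$background_mortality) {
    for (sx in SEXES) {
      if (band[[sx]] < 0 || band[[sx]] > 1) {
        note(paste0("disease.background_mortality.", sx), band[[sx]],
             "probability in [0,1]")
      }
    }
  }
  cover <- max(vapply(ds$background_mortality,
                      function(b) b$max_age, numeric(1)))
  if (cover < ds$max_age - 1) {
    note("disease.background_mortality", cover,
         "bands must cover ages up to max_age (mortality is forced to 1 there)")
  }

  # economics
  ec <- params$economics
  if (ec$discount_rate < 0 || ec$discount_rate >= 1) {
    note("economics.discount_rate", ec$discount_rate, "0 <= rate < 1")
  }
  if (ec$daily_wage_usd < 0) {
    note("economics.daily_wage_usd", ec$daily_wage_usd, "wage >= 0")
  }
  if (ec$healthy_utility < 0 || ec$healthy_utility > 1) {
    note("economics.healthy_utility", ec$healthy_utility,
         "utility in [0,1]")
  }
  if (!ec$perspective %in% c("third_party", "societal")) {
    note("economics.perspective", ec$perspective,
         "one of 'third_party', 'societal'")
  }

  if (length(bad) == 0L) {
    return(data.frame(field = character(), value = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

# -- internal accessors -------------------------------------------------------

# fat-mass mean/sd in kilograms for one stratum, honoring the
# interpretation flag for the printed fat-mass rows
fat_mass_kg_params <- function(params, key) {
  bc <- params$body_composition
  fm <- bc$fat_mass[[key]]
  if (identical(bc$fat_mass_interpretation, "kg")) {
    return(list(mean = fm$mean, sd = fm$sd))
  }
  # ratio_pct: percent body fat relative to fat-free mass
  ffm <- bc$fat_free_mass_kg[[key]]$mean
  list(mean = fm$mean / 100 * ffm, sd = fm$sd / 100 * ffm)
}

lookup_band <- function(bands, age, sex) {
  for (b in bands) {
    if (age >= b$min_age && age <= b$max_age) return(b[[sex]])
  }
  0
}
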