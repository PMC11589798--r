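# Lifetime cost and QALY accrual under two costing perspectives.
#
# Per year alive an agent contributes: a QALY increment equal to its
# combined health utility (product of active-condition utility weights;
# healthy = 1), a direct medical cost equal to the sum of active-condition
# annual costs, and a presenteeism productivity loss of
# daily wage x (1 - combined utility) x days - all discounted to the
# agent's simulation entry at the configured annual rate.  Conditions
# persist from onset to death.  The societal perspective is, for every
# agent, exactly the third-party (direct-cost) perspective plus
# productivity losses.

#' Presenteeism productivity loss
#'
#' `daily wage x (1 - utility weight) x duration in days`: a utility
#' weight of 0.6 means the agent is 40% less productive.
#'
#' @param daily_wage Wage in USD/day (>= 0).
#' @param utility_weight Health-state utility in `[0, 1]`.
#' @param duration_days Days in the state (>= 0).
#' @return USD (undiscounted).
#' @export
productivity_loss <- function(daily_wage, utility_weight, duration_days) {
  if (any(daily_wage < 0) || any(duration_days < 0)) {
    stop("wage and duration must be >= 0")
  }
  if (any(utility_weight < 0 | utility_weight > 1)) {
    stop("utility weight must be in [0, 1]")
  }
  daily_wage * (1 - utility_weight) * duration_days
}

#' Present value of a future amount
#'
#' @param amount Amount (USD, QALYs, ...).
#' @param years_from_reference Years after the discounting reference point.
#' @param rate Annual discount rate (>= 0; default 3%).
#' @return `amount / (1 + rate)^years`.
#' @export
discount_to_present <- function(amount, years_from_reference, rate = 0.03) {
  if (any(rate < 0)) stop("rate must be >= 0")
  amount / (1 + rate)^years_from_reference
}

# utilities and annual costs per condition, in CONDITIONS order
condition_utilities <- function(dparams) {
  vapply(CONDITIONS, function(cn) dparams$conditions[[cn]]$utility,
         numeric(1))
}
condition_costs <- function(dparams) {
  vapply(CONDITIONS, function(cn) dparams$conditions[[cn]]$annual_cost_usd,
         numeric(1))
}

#' Accrue lifetime costs and QALYs for a cohort
#'
#' Vectorized ledger over a [simulate_adult_cohort()] history.  Childhood
#' years (entry to 18) accrue QALYs at healthy utility with no disease
#' cost; adult years accrue per the conditions active that year.  The
#' discounting reference is each agent's simulation entry.
#'
#' @param history A `disease_history`.
#' @param entry_age Numeric vector: each agent's age at simulation entry
#'   (discounting reference).
#' @param params A `model_params` bundle (`disease` for utilities/costs,
#'   `economics` for rate, wage, perspective settings).
#' @return A data frame ledger: `qalys`, `life_years` (undiscounted),
#'   `direct_usd`, `productivity_usd`, `societal_usd`,
#'   `third_party_usd` - all discounted except `life_years`.
#' @export
accrue_lifetime_cohort <- function(history, entry_age, params) {
  dparams <- params$disease
  econ <- params$economics
  n <- length(history$death_age)
  rate <- econ$discount_rate
  wage_year <- econ$daily_wage_usd * econ$work_days_per_year
  util <- condition_utilities(dparams)
  cost <- condition_costs(dparams)
  death_age <- history$death_age
  death_age[is.na(death_age)] <- history$max_age

  qaly <- numeric(n)
  direct <- numeric(n)
  prod_loss <- numeric(n)

  # childhood: healthy utility, discounted year chunks from entry to 18
  years_child <- pmax(0, 18 - entry_age)
  full <- floor(years_child)
  max_full <- max(full, 0)
  if (max_full >= 1) {
    for (y in seq_len(max_full)) {
      has <- full >= y
      qaly[has] <- qaly[has] +
        discount_to_present(econ$healthy_utility, y - 1, rate)
    }
  }
  frac <- years_child - full
  qaly <- qaly + frac * discount_to_present(econ$healthy_utility, full, rate)

  # adulthood: annual cycles from 18 to death
  onset <- history$onset_age
  for (a in 18:(history$max_age - 1)) {
    alive <- death_age > a
    if (!any(alive)) break
    act <- !is.na(onset) & onset <= a
    u_comb <- exp(act %*% log(util))[, 1]
    c_year <- (act %*% cost)[, 1]
    t_from_entry <- a - entry_age
    disc <- (1 + rate)^-t_from_entry
    qaly[alive] <- qaly[alive] + (u_comb * disc)[alive]
    direct[alive] <- direct[alive] + (c_year * disc)[alive]
    prod_loss[alive] <- prod_loss[alive] +
      (wage_year * (1 - u_comb) * disc)[alive]
  }
  data.frame(
    qalys = qaly,
    life_years = death_age - entry_age,
    direct_usd = direct,
    productivity_usd = prod_loss,
    third_party_usd = direct,
    societal_usd = direct + prod_loss
  )
}

#' Accrue lifetime costs and QALYs for one agent
#'
#' Single-agent wrapper around [accrue_lifetime_cohort()].
#'
#' @param history A `disease_history` for one agent.
#' @param entry_age The agent's age at simulation entry.
#' @param params A `model_params` bundle.
#' @return A one-row ledger data frame.
#' @export
accrue_lifetime <- function(history, entry_age, params) {
  accrue_lifetime_cohort(history, entry_age, params)
}
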