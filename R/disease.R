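# Adult lifetime disease progression: an annual-cycle Markov model over
# semi-independent condition hazards (stroke, coronary heart disease, type
# 2 diabetes and its complications - neuropathy, retinopathy, nephropathy -
# and cancers) plus background mortality.  Conditions are absorbing flags
# (onset once, persist to death) so co-occurrence is possible; diabetes
# complications are gated on active diabetes.  Within a year the order is
# fixed: onsets, then complications, then mortality.  Weight category (the
# age-18 classification) enters through condition-specific relative risks.

rr_lookup <- function(dparams, weight_category) {
  m <- vapply(CONDITIONS, function(cn) {
    rr <- dparams$conditions[[cn]]$rr
    c(healthy = rr$healthy, overweight = rr$overweight,
      obesity = rr$obesity)[weight_category]
  }, numeric(length(weight_category)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(NULL, CONDITIONS))
  m
}

#' One annual Markov transition
#'
#' Vectorized over agents.  For each condition not yet active, onset occurs
#' with probability `baseline incidence(age, sex) x RR(weight category)`;
#' diabetes complications are evaluated only for agents with active
#' diabetes (including same-year onset); then mortality combines the
#' background hazard with each active condition's excess hazard as
#' `1 - prod(1 - q_i)`.  Random draws are consumed for every agent and
#' every condition regardless of state, so paired runs under common random
#' numbers stay aligned.
#'
#' @param state List with matrix `active` (agents x conditions, logical),
#'   logical `alive`, numeric `age` (scalar: all agents share the cycle
#'   age).
#' @param weight_category Character vector per agent
#'   (`healthy`/`overweight`/`obesity`).
#' @param sex Character vector per agent.
#' @param dparams The `disease` block of a `model_params` bundle.
#' @param draws Optional list of pre-drawn uniforms (`onset` agents x
#'   conditions, `death`, `cause`); drawn internally if `NULL`.
#' @return Updated `state`, with `death_cause` (`NA`, `"background"`, or a
#'   condition name) for agents dying this cycle and `age` incremented.
#' @export
annual_transition <- function(state, weight_category, sex, dparams,
                              draws = NULL) {
  n <- length(state$alive)
  active <- state$active
  age <- state$age
  if (is.null(draws)) {
    draws <- list(onset = matrix(stats::runif(n * length(CONDITIONS)), n),
                  death = stats::runif(n), cause = stats::runif(n))
  }
  inc <- matrix(0, n, length(CONDITIONS),
                dimnames = list(NULL, CONDITIONS))
  for (j in seq_along(CONDITIONS)) {
    cn <- CONDITIONS[j]
    inc[, j] <- ifelse(
      sex == "male",
      lookup_band(dparams$conditions[[cn]]$incidence, age, "male"),
      lookup_band(dparams$conditions[[cn]]$incidence, age, "female"))
  }
  rr <- rr_lookup(dparams, weight_category)
  p_onset <- inc * rr
  p_onset[p_onset > 1] <- 1
  new_onset <- matrix(FALSE, n, length(CONDITIONS),
                      dimnames = list(NULL, CONDITIONS))
  # onsets for primary conditions, then complications gated on diabetes
  for (j in seq_along(CONDITIONS)) {
    cn <- CONDITIONS[j]
    req <- dparams$conditions[[cn]]$requires
    eligible <- state$alive & !active[, j]
    if (!is.null(req)) {
      eligible <- eligible & (active[, req] | new_onset[, req])
    }
    new_onset[, j] <- eligible & (draws$onset[, j] < p_onset[, j])
  }
  active <- active | new_onset
  # mortality: background plus excess hazards of active conditions
  q_bg <- ifelse(sex == "male",
                 lookup_band(dparams$background_mortality, age, "male"),
                 lookup_band(dparams$background_mortality, age, "female"))
  if (age >= dparams$max_age - 1) q_bg <- rep(1, n)
  excess <- vapply(CONDITIONS, function(cn)
    dparams$conditions[[cn]]$excess_mortality, numeric(1))
  surv <- (1 - q_bg) *
    exp(rowSums(log(1 - sweep(active, 2, excess, `*`))))
  q_total <- 1 - surv
  dies <- state$alive & (draws$death < q_total)
  # attribute cause proportionally to the competing hazards
  death_cause <- rep(NA_character_, n)
  if (any(dies)) {
    haz <- cbind(background = q_bg,
                 sweep(active, 2, excess, `*`))[dies, , drop = FALSE]
    haz <- haz / rowSums(haz)
    u <- draws$cause[dies]
    pick <- rep(1L, nrow(haz))
    acc <- haz[, 1]
    for (j in 2:ncol(haz)) {
      pick[u >= acc] <- j
      acc <- acc + haz[, j]
    }
    death_cause[dies] <- colnames(haz)[pick]
  }
  list(active = active, alive = state$alive & !dies, age = age + 1,
       new_onset = new_onset, death_cause = death_cause)
}

#' Simulate a cohort's adult lifetime
#'
#' Iterates [annual_transition()] from age 18 until death or the configured
#' maximum age (where background mortality is forced to 1).  One uniform
#' per agent-condition-year is consumed whether or not it is used, so two
#' runs with the same seed (baseline vs scenario) are driven by identical
#' randomness and differ only through the weight categories.
#'
#' @param weight_category Character vector per agent (age-18 category).
#' @param sex Character vector per agent.
#' @param dparams The `disease` block of a `model_params` bundle.
#' @param seed Integer seed.
#' @return A `disease_history` list: `onset_age` (agents x conditions
#'   matrix, `NA` if never), `death_age`, `death_cause`, `max_age`.
#' @export
simulate_adult_cohort <- function(weight_category, sex, dparams, seed) {
  n <- length(weight_category)
  set.seed(seed)
  state <- list(active = matrix(FALSE, n, length(CONDITIONS),
                                dimnames = list(NULL, CONDITIONS)),
                alive = rep(TRUE, n), age = 18)
  onset_age <- matrix(NA_real_, n, length(CONDITIONS),
                      dimnames = list(NULL, CONDITIONS))
  death_age <- rep(NA_real_, n)
  death_cause <- rep(NA_character_, n)
  for (a in 18:(dparams$max_age - 1)) {
    draws <- list(onset = matrix(stats::runif(n * length(CONDITIONS)), n),
                  death = stats::runif(n), cause = stats::runif(n))
    if (!any(state$alive)) next
    nxt <- annual_transition(state, weight_category, sex, dparams, draws)
    for (j in seq_along(CONDITIONS)) {
      i <- nxt$new_onset[, j]
      onset_age[i, j] <- a
    }
    died <- state$alive & !nxt$alive
    death_age[died] <- a + 1
    death_cause[died] <- nxt$death_cause[died]
    state <- nxt
  }
  structure(list(onset_age = onset_age, death_age = death_age,
                 death_cause = death_cause, max_age = dparams$max_age),
            class = "disease_history")
}

#' Simulate one agent's adult lifetime
#'
#' Single-agent wrapper around [simulate_adult_cohort()].
#'
#' @param agent List or one-row data frame with `sex` and a weight
#'   category field `category` (or an 18-year-old cohort row plus
#'   `category`).
#' @param dparams The `disease` block.
#' @param seed Integer seed.
#' @return A `disease_history` for one agent.
#' @export
simulate_adult_life <- function(agent, dparams, seed) {
  simulate_adult_cohort(agent$category, agent$sex, dparams, seed)
}
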