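# Shared fixtures: the packaged defaults and growth reference, loaded once,
# plus small builders used across test files.

tp <- load_params()
tref <- load_growth_reference()

# a growth reference with no height growth and age-constant BMI curves:
# useful for stationarity-by-construction checks
flat_reference <- function(M = 18, S = 0.12, L = -2, height = 1.5) {
  tab <- expand.grid(sex = c("male", "female"), age = seq(2, 20, 4),
                     stringsAsFactors = FALSE)
  tab$L <- L
  tab$M <- M
  tab$S <- S
  tab$height_m <- height
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_growth_reference(f)
}

# a disease block with a single active condition and controllable hazards
one_condition_disease <- function(incidence, rr_obesity = 1,
                                  excess = 0, max_age = 100,
                                  background = 0) {
  zero <- function(cd) {
    cd$incidence <- list(list(min_age = 18, max_age = 99, male = 0,
                              female = 0))
    cd$excess_mortality <- 0
    cd
  }
  ds <- tp$disease
  ds$conditions <- lapply(ds$conditions, zero)
  ds$conditions$diabetes$incidence <- list(
    list(min_age = 18, max_age = 99, male = incidence, female = incidence))
  ds$conditions$diabetes$rr <- list(healthy = 1, overweight = 1,
                                    obesity = rr_obesity)
  ds$conditions$diabetes$excess_mortality <- excess
  ds$background_mortality <- list(
    list(min_age = 18, max_age = 99, male = background,
         female = background))
  ds$max_age <- max_age
  ds
}

# quick agent list for single-agent APIs
test_agent <- function(sex = "female", age_group = "12-17", age = 13,
                       ffm = 40, fm = 12, u_sport = 0.9) {
  list(sex = sex, age_group = age_group, age = age, ffm = ffm, fm = fm,
       u_sport = u_sport)
}
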