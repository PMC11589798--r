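# Growth reference: smooth LMS-style BMI-for-age percentile curves and a
# median-height-by-age curve per sex.  The packaged reference is SYNTHETIC:
# a smooth parametric surface shaped to resemble national (CDC-type)
# BMI-for-age references, shipped so the package has no external data
# dependency.  A genuine LMS table in the same tabular format drops in via
# `load_growth_reference()`.

# anchor knots for the synthetic reference (ages in years, heights in m)
.growth_anchors <- list(
  age = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
  male = list(
    M = c(16.5, 15.8, 15.4, 15.9, 16.8, 17.9, 19.3, 20.6, 21.7, 22.5),
    S = c(0.080, 0.095, 0.110, 0.125, 0.135, 0.140, 0.140, 0.138, 0.135, 0.133),
    L = rep(-2.2, 10),
    height = c(0.87, 1.02, 1.16, 1.28, 1.39, 1.49, 1.64, 1.73, 1.76, 1.77)
  ),
  female = list(
    M = c(16.4, 15.5, 15.2, 15.9, 16.9, 18.2, 19.6, 20.6, 21.3, 21.8),
    S = c(0.085, 0.100, 0.115, 0.130, 0.140, 0.145, 0.145, 0.142, 0.140, 0.138),
    L = rep(-2.0, 10),
    height = c(0.86, 1.01, 1.15, 1.27, 1.38, 1.51, 1.60, 1.62, 1.63, 1.63)
  )
)

#' Generate the packaged synthetic growth reference table
#'
#' Builds the synthetic LMS-style BMI-for-age reference as a plain data
#' frame (columns `sex`, `age`, `L`, `M`, `S`, `height_m`) on a half-year
#' age grid from 2 to 20 years.  This is the table shipped at
#' `inst/extdata/growth_reference_synthetic.tsv`; it is smooth and
#' monotone where a real reference is, but it is not measured data.
#'
#' @param ages Age grid in years (default `seq(2, 20, by = 0.5)`).
#' @return A data frame in the tabular growth-reference format.
#' @export
make_synthetic_growth_reference <- function(ages = seq(2, 20, by = 0.5)) {
  an <- .growth_anchors
  rows <- lapply(SEXES, function(sx) {
    a <- an[[sx]]
    data.frame(
      sex = sx,
      age = ages,
      L = stats::spline(an$age, a$L, xout = ages, method = "natural")$y,
      M = stats::spline(an$age, a$M, xout = ages, method = "natural")$y,
      S = stats::spline(an$age, a$S, xout = ages, method = "natural")$y,
      height_m = stats::splinefun(an$age, a$height,
                                  method = "monoH.FC")(ages),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Load a growth reference
#'
#' Reads a tabular growth-reference file (tab-separated columns `sex`,
#' `age`, `L`, `M`, `S`, `height_m`; one row per sex x age) and builds
#' smooth interpolating functions.  With `path = NULL` the packaged
#' synthetic reference is used.  Real LMS tables (e.g., CDC BMI-for-age)
#' written in the same format drop in unchanged.
#'
#' @param path Path to a growth-reference TSV, or `NULL` for the packaged
#'   synthetic reference.
#' @return A `growth_reference` object: per sex, functions `L(age)`,
#'   `M(age)`, `S(age)`, `height(age)`, plus the supported `age_range`.
#' @export
load_growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "growth_reference_synthetic.tsv",
                        package = "paequity")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "L", "M", "S", "height_m")
  if (!all(need %in% names(tab))) {
    stop("growth reference must have columns: ", paste(need, collapse = ", "))
  }
  ref <- list(age_range = range(tab$age))
  for (sx in SEXES) {
    d <- tab[tab$sex == sx, ]
    d <- d[order(d$age), ]
    ref[[sx]] <- list(
      L = stats::splinefun(d$age, d$L, method = "natural"),
      M = stats::splinefun(d$age, d$M, method = "natural"),
      S = stats::splinefun(d$age, d$S, method = "natural"),
      height = stats::splinefun(d$age, d$height_m, method = "monoH.FC")
    )
  }
  class(ref) <- c("growth_reference", "list")
  ref
}

check_ref_ages <- function(age, ref) {
  if (any(age < ref$age_range[1] - 1e-9 | age > ref$age_range[2] + 1e-9)) {
    stop("age outside growth-reference support [",
         ref$age_range[1], ", ", ref$age_range[2], "]")
  }
}

# vectorized over agents; sex may be scalar or vector
lms_terms <- function(age, sex, ref) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  L <- M <- S <- numeric(n)
  for (sx in SEXES) {
    i <- sex == sx
    if (any(i)) {
      L[i] <- ref[[sx]]$L(age[i])
      M[i] <- ref[[sx]]$M(age[i])
      S[i] <- ref[[sx]]$S(age[i])
    }
  }
  list(L = L, M = M, S = S)
}

#' BMI-for-age percentile
#'
#' Maps BMI to its percentile (as a fraction in (0, 1)) at a given age and
#' sex via the reference's LMS transformation
#' `z = ((bmi / M)^L - 1) / (L * S)`.  Strictly increasing in BMI at fixed
#' age; inverts with [bmi_from_percentile()].
#'
#' @param age Age in years (vectorized); must lie within the reference
#'   support (2-20 years for the packaged reference).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param bmi Body mass index in kg/m^2 (vectorized).
#' @param ref A `growth_reference`.
#' @return Percentile(s) in (0, 1).
#' @export
bmi_percentile <- function(age, sex, bmi, ref) {
  check_ref_ages(age, ref)
  t <- lms_terms(age, sex, ref)
  z <- ((bmi / t$M)^t$L - 1) / (t$L * t$S)
  stats::pnorm(z)
}

#' BMI at a given percentile (inverse of [bmi_percentile()])
#'
#' @inheritParams bmi_percentile
#' @param p Percentile(s) as fractions in (0, 1).
#' @return BMI in kg/m^2.
#' @export
bmi_from_percentile <- function(age, sex, p, ref) {
  check_ref_ages(age, ref)
  t <- lms_terms(age, sex, ref)
  z <- stats::qnorm(p)
  base <- 1 + t$L * t$S * z
  # deep tails where the LMS power transform leaves support
  base <- pmax(base, 1e-8)
  t$M * base^(1 / t$L)
}

#' Median height by age and sex
#'
#' @inheritParams bmi_percentile
#' @return Height in meters.
#' @export
median_height <- function(age, sex, ref) {
  check_ref_ages(age, ref)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  h <- numeric(n)
  for (sx in SEXES) {
    i <- sex == sx
    if (any(i)) h[i] <- ref[[sx]]$height(age[i])
  }
  h
}

#' Classify weight status
#'
#' Youth (< 18 years) are classified by BMI-for-age percentile using the
#' conventional cut points (overweight: 85th-95th percentile; obesity: at
#' or above the 95th); adults (>= 18) by fixed BMI cut points (overweight:
#' 25-30 kg/m^2; obesity: >= 30).
#'
#' @inheritParams bmi_percentile
#' @return Character vector in `c("healthy", "overweight", "obesity")`.
#' @export
classify_weight_status <- function(age, sex, bmi, ref) {
  n <- max(length(age), length(sex), length(bmi))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  bmi <- rep_len(bmi, n)
  out <- rep("healthy", n)
  youth <- age < 18
  if (any(youth)) {
    p <- bmi_percentile(age[youth], sex[youth], bmi[youth], ref)
    cls <- rep("healthy", sum(youth))
    cls[p >= 0.85] <- "overweight"
    cls[p >= 0.95] <- "obesity"
    out[youth] <- cls
  }
  if (any(!youth)) {
    b <- bmi[!youth]
    cls <- rep("healthy", sum(!youth))
    cls[b >= 25] <- "overweight"
    cls[b >= 30] <- "obesity"
    out[!youth] <- cls
  }
  out
}
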