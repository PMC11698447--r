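#' Exponential growth model with Gamma-distributed rate
#'
#' Each tumor grows exponentially from a single malignant cell; the growth
#' rate `lambda` (/year) is drawn once per tumor from a Gamma distribution
#' with shape `K` and scale `theta` and is fixed thereafter. The tumor
#' volume doubling time is `ln 2 / lambda`.
#'
#' @param K Gamma shape (> 0).
#' @param theta Gamma scale (> 0), in /year.
#' @param met_rate_factor Multiplier (>= 1) on the growth rate of metastatic
#'   compartments relative to the primary's Gamma distribution: metastatic
#'   deposits typically double faster than the primary they came from.
#' @param v_cell Single-cell volume (cm^3).
#' @return Object of class `growth_model`.
#' @export
growth_model <- function(K = 0.34, theta = 5.3, met_rate_factor = 18,
                         v_cell = .v_cell_default) {
  stopifnot(K > 0, theta > 0, met_rate_factor > 0, v_cell > 0)
  structure(
    list(
      K = K, theta = theta, met_rate_factor = met_rate_factor,
      v_cell = v_cell
    ),
    class = "growth_model"
  )
}

#' Metastatic seeding parameters
#'
#' Seeding of nodal and distant metastases is indexed by primary tumor
#' volume `S`: cells detach at a rate proportional to `S^xi` and transfer
#' and deposit at rates `mu_n` (nodal) and `mu_m` (distant), giving the
#' seeding c.d.f. `F(S) = 1 - exp(-(mu/(xi+1)) * S^(xi+1))`.
#'
#' @param xi Detachment exponent (> -1).
#' @param mu_n,mu_m Nodal and distant transfer/deposition rates (>= 0).
#' @return Object of class `metastasis_params`.
#' @export
metastasis_params <- function(xi = -0.113, mu_n = 0.0555, mu_m = 0.0888) {
  if (xi <= -1) abort("xi must exceed -1")
  stopifnot(mu_n >= 0, mu_m >= 0)
  structure(list(xi = xi, mu_n = mu_n, mu_m = mu_m),
    class = "metastasis_params"
  )
}

#' Simulation configuration: thresholds, bins and horizon
#'
#' @param v_detect_min CT-detectability threshold (cm^3); the default is the
#'   volume of a 0.618 mm sphere.
#' @param v_cell Single-cell volume (cm^3); must be below `v_detect_min`.
#' @param max_age Simulation horizon in years.
#' @param size_bins Diameter bin edges (cm) used by the reporting tables.
#' @param met_growth `"independent"`: each metastatic compartment grows with
#'   its own Gamma-drawn rate; `"shared"`: compartments reuse the primary's
#'   rate.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(v_detect_min = .v_detect_default,
                       v_cell = .v_cell_default,
                       max_age = 100,
                       size_bins = c(0.5, 1, 1.5, 2, 3),
                       met_growth = c("independent", "shared")) {
  if (v_cell >= v_detect_min) abort("v_cell must be below v_detect_min")
  structure(
    list(
      v_detect_min = v_detect_min, v_cell = v_cell, max_age = max_age,
      size_bins = size_bins, met_growth = match.arg(met_growth)
    ),
    class = "sim_config"
  )
}

#' Metastatic seeding c.d.f. in primary tumor volume
#'
#' Probability that seeding (nodal or distant, depending on `mu`) has
#' occurred by the time the primary reaches volume `S`:
#' `F(S) = 1 - exp(-(mu/(xi+1)) * S^(xi+1))`, i.e. a per-volume seeding
#' hazard `mu * S^xi` integrated in `S`.
#'
#' @param S Primary volume(s), cm^3.
#' @param mu Transfer/deposition rate.
#' @param xi Detachment exponent (> -1).
#' @return Probabilities in \[0, 1).
#' @export
metastasis_cdf <- function(S, mu, xi = 0) {
  if (xi <= -1) abort("xi must exceed -1")
  if (any(S < 0)) abort("S must be non-negative")
  -expm1(-mu / (xi + 1) * S^(xi + 1))
}

#' Inverse of the metastatic seeding c.d.f.
#'
#' @param p Probabilities in \[0, 1).
#' @inheritParams metastasis_cdf
#' @return Seeding threshold volumes (cm^3); `Inf` when `mu = 0`.
#' @export
metastasis_quantile <- function(p, mu, xi = 0) {
  if (xi <= -1) abort("xi must exceed -1")
  if (mu == 0) return(rep(Inf, length(p)))
  ((xi + 1) / mu * (-log1p(-p)))^(1 / (xi + 1))
}

#' Simulate latent tumor courses
#'
#' Given onset ages, draws the growth rate `lambda ~ Gamma(K, theta)`, the
#' nodal and distant seeding threshold volumes by inverting
#' [metastasis_cdf()], converts them to seeding ages through the exponential
#' growth law, and (under the default independent-growth mode) draws each
#' compartment's own growth rate from the same Gamma.
#'
#' Seeding ages beyond the simulation horizon are kept as numbers (they are
#' censored downstream); `Inf` marks seeding that never happens.
#'
#' @param onsets Tibble with at least `id` and `t0` (onset age); any further
#'   columns (e.g. `birth_year`, `sex`) are carried through.
#' @param growth A [growth_model()].
#' @param mets A [metastasis_params()].
#' @param config A [sim_config()].
#' @return Tibble: input columns plus `lambda`, `s_n`, `s_m` (seeding
#'   volumes), `tn`, `tm` (seeding ages), `lambda_n`, `lambda_m`.
#' @export
simulate_tumor_course <- function(onsets, growth, mets, config = sim_config()) {
  n <- nrow(onsets)
  lambda <- rgamma(n, shape = growth$K, scale = growth$theta)
  u_n <- runif(n)
  u_m <- runif(n)
  # a seeding threshold below one cell is clamped: seeding cannot precede
  # the first malignant cell, so Tn, Tm > T0 always
  s_n <- pmax(metastasis_quantile(u_n, mets$mu_n, mets$xi), growth$v_cell * 1.001)
  s_m <- pmax(metastasis_quantile(u_m, mets$mu_m, mets$xi), growth$v_cell * 1.001)
  tn <- onsets$t0 + log(s_n / growth$v_cell) / lambda
  tm <- onsets$t0 + log(s_m / growth$v_cell) / lambda
  fac <- growth$met_rate_factor
  if (config$met_growth == "independent") {
    lambda_n <- fac * rgamma(n, shape = growth$K, scale = growth$theta)
    lambda_m <- fac * rgamma(n, shape = growth$K, scale = growth$theta)
  } else {
    lambda_n <- fac * lambda
    lambda_m <- fac * lambda
  }
  onsets %>% mutate(
    lambda = lambda, s_n = s_n, s_m = s_m, tn = tn, tm = tm,
    lambda_n = lambda_n, lambda_m = lambda_m
  )
}

#' Primary tumor volume at a given age
#'
#' `V(t) = v_cell * exp(lambda * (t - t0))`; errors if queried before onset.
#'
#' @param course Tibble with `t0` and `lambda` (rows recycled against `t`).
#' @param t Age(s) in years.
#' @param v_cell Single-cell volume (cm^3).
#' @return Volume(s) in cm^3.
#' @export
primary_volume_at <- function(course, t, v_cell = .v_cell_default) {
  if (any(t < course$t0)) abort("t must not precede onset age t0")
  v_cell * exp(course$lambda * (t - course$t0))
}

#' Metastatic compartment volume at a given age
#'
#' Zero before seeding; afterwards the compartment grows exponentially from
#' one cell with its own rate (`lambda_n` / `lambda_m`).
#'
#' @param course Tumor-course tibble (see [simulate_tumor_course()]).
#' @param t Age(s).
#' @param compartment `"nodal"` or `"distant"`.
#' @param v_cell Single-cell volume (cm^3).
#' @return Volume(s) in cm^3.
#' @export
compartment_volume_at <- function(course, t, compartment = c("nodal", "distant"),
                                  v_cell = .v_cell_default) {
  compartment <- match.arg(compartment)
  seed_age <- if (compartment == "nodal") course$tn else course$tm
  rate <- if (compartment == "nodal") course$lambda_n else course$lambda_m
  ifelse(t >= seed_age & is.finite(seed_age),
    v_cell * exp(rate * (t - seed_age)), 0
  )
}

#' Classify a compartment volume as absent, occult or detectable
#'
#' A deposit no larger than a single cell is absent; between one cell and
#' the CT threshold it is occult (present but invisible to imaging and
#' clinical workup); at or above the threshold it is detectable.
#'
#' @param v Volume(s), cm^3.
#' @param config A [sim_config()] supplying the two thresholds.
#' @return Character vector in `c("absent", "occult", "detectable")`.
#' @export
classify_compartment <- function(v, config = sim_config()) {
  if (any(v < 0)) abort("volume must be non-negative")
  dplyr::case_when(
    v <= config$v_cell ~ "absent",
    v < config$v_detect_min ~ "occult",
    TRUE ~ "detectable"
  )
}

#' True disease extent at a given age
#'
#' `M1` once distant seeding has occurred (seeded means present, regardless
#' of size), else `N1M0` once nodal seeding has occurred, else `N0M0`. The
#' sequence per course is monotone.
#'
#' @param course Tumor-course tibble.
#' @param t Age(s), recycled against rows.
#' @return Character vector in `c("N0M0", "N1M0", "M1")`.
#' @export
true_stage_at <- function(course, t) {
  if (any(t < course$t0)) abort("t must not precede onset age t0")
  dplyr::case_when(
    t >= course$tm ~ "M1",
    t >= course$tn ~ "N1M0",
    TRUE ~ "N0M0"
  )
}

#' Progression timeline marks for each course
#'
#' Ages at which the primary reaches 2 mm and 5 mm diameter (analytic
#' inversion of the growth law), the cure threshold (age of first metastatic
#' seeding — beyond it local therapy can no longer be curative), and the
#' tumor volume doubling time in days. Marks never reached are `NA`
#' (`Inf` seeding) rather than errors.
#'
#' @param course Tumor-course tibble; a `t_dc` column, if present, is
#'   carried through as the detection mark.
#' @param v_cell Single-cell volume (cm^3).
#' @return Tibble: `id`, `age_2mm`, `age_5mm`, `age_cure`, `age_detect`,
#'   `tvdt_days`.
#' @export
timeline_marks <- function(course, v_cell = .v_cell_default) {
  age_at_diam <- function(d_cm) {
    course$t0 + log(diameter_to_volume(d_cm) / v_cell) / course$lambda
  }
  cure <- pmin(course$tn, course$tm)
  tibble(
    id = course$id,
    age_2mm = age_at_diam(0.2),
    age_5mm = age_at_diam(0.5),
    age_cure = ifelse(is.finite(cure), cure, NA_real_),
    age_detect = if ("t_dc" %in% names(course)) course$t_dc else NA_real_,
    tvdt_days = 365.25 * log(2) / course$lambda
  )
}

# assign diameters (cm) to the reporting size bins; left-open right-closed
# above each edge, e.g. "0.5<TS<=1"
size_bin_of <- function(d_cm, edges = c(0.5, 1, 1.5, 2, 3)) {
  labs <- c(
    paste0("<=", edges[1]),
    paste0(head(edges, -1), "-", tail(edges, -1)),
    paste0(">", edges[length(edges)])
  )
  cut(d_cm, breaks = c(-Inf, edges, Inf), labels = labs, right = TRUE)
}
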