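#' Two-stage clonal expansion (TSCE) model parameters
#'
#' The TSCE model describes carcinogenesis as initiation of normal cells
#' (Poisson rate `nu`, absorbing the number of normal cells), clonal
#' expansion of initiated cells (symmetric division rate `alpha`, death rate
#' `alpha - gamma0` at zero dose), and malignant conversion (rate `mu`).
#' Smoking acts multiplicatively on initiation, net promotion
#' (`alpha - beta`) and conversion through power-law dose-response terms
#' `1 + c * d^e` in cigarettes/day `d`, which equal 1 at zero dose.
#'
#' @param nu Initiation rate (initiated cells per year) at zero dose.
#' @param alpha Promotion division rate (/year), held fixed across doses.
#' @param gamma0 Net promotion rate `alpha - beta` (/year) at zero dose;
#'   must be below `alpha`.
#' @param mu Malignant conversion rate (/year) at zero dose.
#' @param nu_coef,nu_exp Coefficient and exponent of the initiation
#'   dose-response `1 + nu_coef * d^nu_exp`.
#' @param growth_coef,growth_exp Dose-response of net promotion.
#' @param mu_coef,mu_exp Dose-response of malignant conversion.
#' @return Object of class `tsce_params`.
#' @export
tsce_params <- function(nu = 0.3, alpha = 10, gamma0 = 0.05, mu = 1.1e-6,
                        nu_coef = 0.08, nu_exp = 1,
                        growth_coef = 0.28, growth_exp = 0.5,
                        mu_coef = 0.30, mu_exp = 0.5) {
  stopifnot(nu >= 0, alpha > 0, gamma0 >= 0, gamma0 < alpha, mu >= 0)
  structure(
    list(
      nu = nu, alpha = alpha, gamma0 = gamma0, mu = mu,
      nu_coef = nu_coef, nu_exp = nu_exp,
      growth_coef = growth_coef, growth_exp = growth_exp,
      mu_coef = mu_coef, mu_exp = mu_exp
    ),
    class = "tsce_params"
  )
}

# per-dose TSCE rates (vectorised over dose)
tsce_rates <- function(params, dose) {
  nu <- params$nu * (1 + params$nu_coef * dose^params$nu_exp)
  g <- params$gamma0 * (1 + params$growth_coef * dose^params$growth_exp)
  mu <- params$mu * (1 + params$mu_coef * dose^params$mu_exp)
  beta <- params$alpha - g
  if (any(beta < 0)) abort("dose-response drives beta below zero; lower growth_coef or raise alpha")
  list(nu = nu, alpha = rep(params$alpha, length(dose)), beta = beta, mu = mu)
}

#' Piecewise-constant exposure profile from a smoking history
#'
#' Cigarettes/day as a step function of age: 0 before initiation, the
#' recorded intensity while smoking, 0 after cessation.
#'
#' @param history Single-row data frame (or list) with `start_age`,
#'   `quit_age`, `intensity`.
#' @param max_age Upper age bound of the profile.
#' @return Tibble with columns `from`, `to`, `dose`.
#' @export
exposure_profile <- function(history, max_age = 100) {
  start <- history$start_age[1]
  quit <- history$quit_age[1]
  int <- history$intensity[1]
  if (is.na(start) || int == 0) {
    return(tibble(from = 0, to = max_age, dose = 0))
  }
  quit <- if (is.na(quit)) max_age else min(quit, max_age)
  brk <- unique(pmin(c(0, start, quit, max_age), max_age))
  brk <- sort(brk)
  dose <- ifelse(brk[-length(brk)] >= start & brk[-length(brk)] < quit, int, 0)
  out <- tibble(from = brk[-length(brk)], to = brk[-1], dose = dose)
  if (any(diff(brk) <= 0)) abort("non-monotone exposure breakpoints")
  out
}

# One backward step of the TSCE survival recursion over a constant-parameter
# segment of length dt. State: y = extinction-type probability carried from
# later segments (y = 1 at the evaluation age), lam = accumulated -log S.
# The Riccati equation y' = a y^2 - (a+b+m) y + b has roots r1 < 1 <= r2 and
# closed-form solution via w = (y - r1)/(y - r2); -log S accrues
# nu * [(1 - r1) dt + log((1 - w1)/(1 - w0)) / a].
# All arguments vectorised.
tsce_step <- function(y, lam, dt, nu, a, b, m) {
  live <- dt > 0
  if (!any(live)) return(list(y = y, lam = lam))
  A <- a + b + m
  disc <- sqrt(pmax(A^2 - 4 * a * b, 0))
  r1 <- (A - disc) / (2 * a)
  r2 <- (A + disc) / (2 * a)
  denom <- y - r2
  # y == r2 is a fixed point (arises when mu = 0 and beta < alpha)
  fixed <- abs(denom) < 1e-14
  w0 <- ifelse(fixed, 0, (y - r1) / denom)
  w1 <- w0 * exp(-disc * dt)
  y_new <- ifelse(fixed, y, (r1 - r2 * w1) / (1 - w1))
  dlam <- ifelse(
    fixed,
    nu * (1 - y) * dt,
    nu * ((1 - r1) * dt + log1p(-w1) / a - log1p(-w0) / a)
  )
  list(
    y = ifelse(live, y_new, y),
    lam = lam + ifelse(live, dlam, 0)
  )
}

# -log S(t) for one exposure profile at (a vector of) ages t, by chaining
# the closed form backward from t to 0 across exposure segments
tsce_cumhaz_profile <- function(t, params, exposure) {
  if (any(diff(exposure$from) <= 0) || any(exposure$to <= exposure$from)) {
    abort("non-monotone exposure breakpoints")
  }
  rates <- tsce_rates(params, exposure$dose)
  vapply(t, function(tt) {
    y <- 1
    lam <- 0
    for (i in rev(seq_len(nrow(exposure)))) {
      lo <- min(exposure$from[i], tt)
      hi <- min(exposure$to[i], tt)
      st <- tsce_step(
        y, lam, hi - lo,
        rates$nu[i], rates$alpha[i], rates$beta[i], rates$mu[i]
      )
      y <- st$y
      lam <- st$lam
    }
    lam
  }, numeric(1))
}

#' TSCE survival: probability of no malignant cell by age t
#'
#' Exact closed-form solution of the two-stage clonal expansion model with
#' piecewise-constant parameters, chained recursively across the exposure
#' breakpoints. `S(0) = 1` and `S` is non-increasing and continuous at
#' breakpoints.
#'
#' @param t Age(s) in years.
#' @param params A [tsce_params()].
#' @param exposure An [exposure_profile()].
#' @return Survival probabilities in (0, 1].
#' @export
tsce_survival <- function(t, params, exposure) {
  if (any(t < 0)) abort("t must be non-negative")
  exp(-tsce_cumhaz_profile(t, params, exposure))
}

# Vectorised cumulative hazard over persons: histories is a cohort tibble,
# grid an increasing age vector. Returns a length(grid) x nrow matrix-free
# representation: list of per-grid-age vectors stacked as a matrix
# (persons x grid). Each person's exposure is the 3-segment
# (pre-start, smoking, post-quit) profile.
tsce_cumhaz_cohort <- function(histories, params, grid) {
  n <- nrow(histories)
  start <- ifelse(is.na(histories$start_age), Inf, histories$start_age)
  quit <- ifelse(is.na(histories$quit_age), Inf, histories$quit_age)
  dose <- histories$intensity
  r0 <- tsce_rates(params, rep(0, n))
  rd <- tsce_rates(params, dose)
  H <- matrix(0, n, length(grid))
  for (j in seq_along(grid)) {
    tt <- grid[j]
    y <- rep(1, n)
    lam <- rep(0, n)
    # backward: [quit, t] dose 0, [start, min(quit,t)] dose d, [0, start] dose 0
    st <- tsce_step(
      y, lam, pmax(0, tt - pmin(quit, tt)),
      r0$nu, r0$alpha, r0$beta, r0$mu
    )
    st <- tsce_step(
      st$y, st$lam, pmax(0, pmin(quit, tt) - pmin(start, tt)),
      rd$nu, rd$alpha, rd$beta, rd$mu
    )
    st <- tsce_step(
      st$y, st$lam, pmax(0, pmin(start, tt)),
      r0$nu, r0$alpha, r0$beta, r0$mu
    )
    H[, j] <- st$lam
  }
  H
}

#' Sample ages at first malignant cell for a cohort
#'
#' Inverse-transform draws from `1 - tsce_survival`, truncated at `max_age`:
#' a uniform deviate per person is mapped through the person's cumulative
#' onset hazard, evaluated exactly on an age grid and interpolated linearly
#' in the cumulative hazard between grid points.
#'
#' @param params A [tsce_params()].
#' @param histories Cohort tibble (rows are persons).
#' @param max_age Censoring age; persons with no onset by `max_age` get `NA`.
#' @param grid_by Age-grid resolution in years (interpolation error shrinks
#'   with the square of this).
#' @param chunk Persons per block, bounding the grid matrix held in memory.
#' @return Numeric vector of onset ages `T0` (`NA` = no onset).
#' @export
sample_onset_age <- function(params, histories, max_age = 100,
                             grid_by = 1, chunk = 20000L) {
  n <- nrow(histories)
  u <- runif(n)
  e <- -log1p(-u) # exponential target on the cumulative-hazard scale
  grid <- seq(0, max_age, by = grid_by)
  if (grid[length(grid)] < max_age) grid <- c(grid, max_age)
  out <- rep(NA_real_, n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx) {
    H <- tsce_cumhaz_cohort(histories[ii, , drop = FALSE], params, grid)
    hit <- e[ii] <= H[, ncol(H)]
    if (!any(hit)) next
    Hh <- H[hit, , drop = FALSE]
    eh <- e[ii][hit]
    # first grid index where H >= e
    j <- rowSums(Hh < eh) # number of grid points strictly below target
    j[j == 0] <- 1L # target below H at first point (H[ ,1] = 0, e > 0 so j >= 1)
    lo <- grid[j]
    hi <- grid[j + 1]
    Hlo <- Hh[cbind(seq_along(j), j)]
    Hhi <- Hh[cbind(seq_along(j), j + 1)]
    frac <- (eh - Hlo) / pmax(Hhi - Hlo, 1e-300)
    out[ii[hit]] <- lo + frac * (hi - lo)
  }
  out
}
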