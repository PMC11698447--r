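#' Symptomatic detection parameters
#'
#' The hazard of clinical (symptomatic) detection at age `t` is linear in
#' tumor volume: `eta * (Sp + Sn + Sm) + W_k`, where `Sp`, `Sn`, `Sm` are
#' the primary, nodal and distant compartment volumes (each compartment can
#' bring the disease to clinical attention once it is big enough) and `W_k`
#' is an offset depending on the true disease extent `k` (`W0` for N0M0,
#' `W1` for N1M0, `W2` for M1). Metastatic disease makes spontaneous
#' presentation far more likely, so typically `W1, W2 >> W0`. With
#' `include_mets = FALSE` only the primary volume enters the eta term.
#'
#' @param eta Detection efficiency per unit volume (/cm^3/year).
#' @param w0,w1,w2 Stage-dependent offset hazards (/year).
#' @param include_mets Do metastatic compartment volumes contribute to the
#'   volume term?
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(eta = 0.59, w0 = 4.3e-4, w1 = 0.045, w2 = 0.046,
                             include_mets = TRUE) {
  stopifnot(eta >= 0, w0 >= 0, w1 >= 0, w2 >= 0)
  structure(
    list(
      eta = eta, w0 = w0, w1 = w1, w2 = w2,
      include_mets = isTRUE(include_mets)
    ),
    class = "detection_params"
  )
}

# offset hazard for a true stage label
stage_offset <- function(stage, params) {
  unname(c(N0M0 = params$w0, N1M0 = params$w1, M1 = params$w2)[stage])
}

#' Symptomatic detection hazard along a course
#'
#' @param course Tumor-course tibble (rows recycled against `t`).
#' @param t Age(s), at or after onset.
#' @param params A [detection_params()].
#' @param v_cell Single-cell volume (cm^3).
#' @return Hazard(s), /year.
#' @export
symptomatic_hazard <- function(course, t, params, v_cell = .v_cell_default) {
  s <- primary_volume_at(course, t, v_cell)
  if (params$include_mets) {
    s <- s + compartment_volume_at(course, t, "nodal", v_cell) +
      compartment_volume_at(course, t, "distant", v_cell)
  }
  params$eta * s + stage_offset(true_stage_at(course, t), params)
}

# Solve eta * sum_i Sa_i*(exp(lambda_i*x)-1)/lambda_i + W*x = E for
# x in [0, L]: vectorised safeguarded Newton (left side increasing,
# convex). Sa_i = 0 switches a term off.
solve_seg_time <- function(Sa1, lam1, Sa2, lam2, Sa3, lam3, W, eta, E, L) {
  term <- function(Sa, lam, x) ifelse(Sa > 0, eta * Sa * expm1(lam * x) / lam, 0)
  dterm <- function(Sa, lam, x) ifelse(Sa > 0, eta * Sa * exp(lam * x), 0)
  f <- function(x) {
    term(Sa1, lam1, x) + term(Sa2, lam2, x) + term(Sa3, lam3, x) + W * x - E
  }
  lo <- rep(0, length(E))
  hi <- L
  # initial guess: single-term inversion on the dominant volume term
  Sa_max <- pmax(Sa1, Sa2, Sa3)
  lam_max <- ifelse(Sa_max == Sa1, lam1, ifelse(Sa_max == Sa2, lam2, lam3))
  x_eta <- ifelse(eta * Sa_max > 0,
    log1p(E * lam_max / (eta * Sa_max)) / lam_max, Inf
  )
  x_w <- ifelse(W > 0, E / W, Inf)
  x <- pmin(x_eta, x_w, L)
  for (i in 1:60) {
    fx <- f(x)
    hi <- ifelse(fx > 0, pmin(hi, x), hi)
    lo <- ifelse(fx <= 0, pmax(lo, x), lo)
    fp <- dterm(Sa1, lam1, x) + dterm(Sa2, lam2, x) + dterm(Sa3, lam3, x) + W
    x_new <- x - fx / fp
    bad <- !is.finite(x_new) | x_new <= lo | x_new >= hi
    x <- ifelse(bad, (lo + hi) / 2, x_new)
  }
  x
}

#' Sample symptomatic detection ages
#'
#' Inverse-transform draw from the inhomogeneous detection hazard
#' `eta * (Sp + Sn + Sm) + W_k`. Within each true-stage segment every
#' compartment volume is a pure exponential, so the cumulative hazard has
#' the closed form `eta * sum_i (S_i(b) - S_i(a)) / lambda_i +
#' W_k * (b - a)`; an exponential deviate is walked across the (at most
#' three) segments and inverted exactly (safeguarded Newton) inside the
#' segment where it lands.
#'
#' @param course Tumor-course tibble with `t0`, `lambda`, `tn`, `tm`.
#' @param params A [detection_params()].
#' @param end_age Per-person censoring age (death from other causes or the
#'   simulation horizon); scalar or vector.
#' @param v_cell Single-cell volume (cm^3).
#' @return Numeric vector of detection ages (`NA` = never detected).
#' @export
sample_symptomatic_detection <- function(course, params, end_age = 100,
                                         v_cell = .v_cell_default) {
  n <- nrow(course)
  end <- rep(end_age, length.out = n)
  E <- rexp(n)
  t0 <- course$t0
  lam <- course$lambda
  c1 <- pmin(course$tn, course$tm)
  c2 <- pmax(course$tn, course$tm)
  w_mid <- ifelse(course$tm < course$tn, params$w2, params$w1)
  segs <- list(
    list(a = t0, b = pmin(c1, end), W = rep(params$w0, n)),
    list(a = pmin(c1, end), b = pmin(c2, end), W = w_mid),
    list(a = pmin(c2, end), b = end, W = rep(params$w2, n))
  )
  t_dc <- rep(NA_real_, n)
  open <- rep(TRUE, n)
  with_mets <- isTRUE(params$include_mets)
  # compartment volume at segment start (0 when not yet seeded / disabled)
  vol_at <- function(a, seed, rate, on) {
    ifelse(on & a >= seed & is.finite(seed),
      v_cell * exp(rate * (a - seed)), 0
    )
  }
  for (sg in segs) {
    len <- pmax(0, sg$b - sg$a)
    act <- open & len > 0
    if (!any(act)) next
    a <- sg$a[act]
    ln <- len[act]
    Sp <- v_cell * exp(lam[act] * (a - t0[act]))
    Sn <- vol_at(a, course$tn[act], course$lambda_n[act], with_mets)
    Sm <- vol_at(a, course$tm[act], course$lambda_m[act], with_mets)
    cum <- params$eta * (
      Sp * expm1(lam[act] * ln) / lam[act] +
        ifelse(Sn > 0, Sn * expm1(course$lambda_n[act] * ln) / course$lambda_n[act], 0) +
        ifelse(Sm > 0, Sm * expm1(course$lambda_m[act] * ln) / course$lambda_m[act], 0)
    ) + sg$W[act] * ln
    inside <- E[act] <= cum
    if (any(inside)) {
      k <- which(act)[inside]
      x <- solve_seg_time(
        Sp[inside], lam[k],
        Sn[inside], course$lambda_n[k],
        Sm[inside], course$lambda_m[k],
        sg$W[k], params$eta, E[k], ln[inside]
      )
      t_dc[k] <- sg$a[k] + x
      open[k] <- FALSE
    }
    rest <- which(act)[!inside]
    E[rest] <- E[rest] - cum[!inside]
  }
  t_dc
}

#' Screening schedule for one person
#'
#' CT scans at ages `start_age + j / screens_per_year` within the policy
#' window, restricted to ages at which the person is eligible
#' (pack-years accrued, quit recency) and, optionally, to a calendar window.
#'
#' @param history Single-row cohort tibble (needs `birth_year` when a
#'   calendar window is used).
#' @param policy A [screening_policy()].
#' @param calendar_window Length-2 numeric (years) or `NULL` to disable
#'   calendar clipping.
#' @return Numeric vector of scan ages (possibly empty).
#' @export
screen_schedule <- function(history, policy, calendar_window = NULL) {
  ages <- seq(policy$start_age, policy$end_age, by = 1 / policy$screens_per_year)
  keep <- is_eligible(history[rep(1, length(ages)), , drop = FALSE], ages, policy)
  if (!is.null(calendar_window)) {
    yr <- history$birth_year[1] + ages
    keep <- keep & yr >= calendar_window[1] & yr <= calendar_window[2]
  }
  ages[keep]
}

#' Apply a screening schedule to a tumor course
#'
#' Detection occurs at the first scheduled scan at which any compartment
#' (primary, nodal, distant) is at or above the CT threshold; `n_screens`
#' counts scans up to and including detection.
#'
#' @param course Single-row tumor-course tibble.
#' @param schedule Sorted scan ages from [screen_schedule()].
#' @param v_detect_min CT threshold (cm^3).
#' @param v_cell Single-cell volume (cm^3).
#' @return One-row tibble `t_dc` (`NA` if never screen-detected),
#'   `n_screens`.
#' @export
apply_screening <- function(course, schedule, v_detect_min = .v_detect_default,
                            v_cell = .v_cell_default) {
  lag <- log(v_detect_min / v_cell)
  t_star <- pmin(
    course$t0 + lag / course$lambda,
    ifelse(is.finite(course$tn), course$tn + lag / course$lambda_n, Inf),
    ifelse(is.finite(course$tm), course$tm + lag / course$lambda_m, Inf)
  )
  hit <- schedule >= t_star[1]
  if (length(schedule) == 0 || !any(hit)) {
    return(tibble(t_dc = NA_real_, n_screens = length(schedule)))
  }
  j <- which(hit)[1]
  tibble(t_dc = schedule[j], n_screens = j)
}

# Vectorised screening detection across persons whose schedules share the
# policy grid. elig: tibble from eligibility_window(); end: censoring ages.
# Returns t_dc and n_screens (screens actually received, stopping at
# detection or censoring).
screen_detect_cohort <- function(course, elig, policy, end,
                                 calendar_window = NULL,
                                 v_detect_min = .v_detect_default,
                                 v_cell = .v_cell_default) {
  f <- policy$screens_per_year
  lag <- log(v_detect_min / v_cell)
  t_star <- pmin(
    course$t0 + lag / course$lambda,
    ifelse(is.finite(course$tn), course$tn + lag / course$lambda_n, Inf),
    ifelse(is.finite(course$tm), course$tm + lag / course$lambda_m, Inf)
  )
  lo <- pmax(policy$start_age, elig$elig_lo)
  hi <- pmin(policy$end_age, elig$elig_hi)
  if (!is.null(calendar_window)) {
    lo <- pmax(lo, calendar_window[1] - course$birth_year)
    hi <- pmin(hi, calendar_window[2] - course$birth_year)
  }
  hi <- pmin(hi, end) # no scans after death
  # scan ages are policy$start_age + j/f; first index on/after an age a:
  jfirst <- function(a) ceiling((a - policy$start_age) * f - 1e-9)
  j_lo <- pmax(0, jfirst(lo))
  j_hi <- floor((hi - policy$start_age) * f + 1e-9)
  any_window <- !is.na(lo) & j_hi >= j_lo
  j_det <- pmax(j_lo, jfirst(t_star))
  detected <- any_window & j_det <= j_hi
  t_dc <- ifelse(detected, policy$start_age + j_det / f, NA_real_)
  n_screens <- ifelse(any_window,
    ifelse(detected, j_det - j_lo + 1, j_hi - j_lo + 1), 0
  )
  tibble(t_dc = t_dc, n_screens = as.integer(pmax(n_screens, 0)))
}
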