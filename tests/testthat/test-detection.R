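test_that("symptomatic hazard is linear in volume with stage offsets", {
  crs <- make_course(t0 = 60, lambda = log(2), tn = 70, tm = 80)
  p0 <- detection_params(eta = 0, w0 = 0, w1 = 0, w2 = 0)
  expect_equal(symptomatic_hazard(crs, c(61, 75, 85), p0), rep(0, 3))
  p <- detection_params(eta = 0.4, w0 = 0.001, w1 = 0.1, w2 = 0.3)
  # doubling the volume doubles the eta term exactly (one doubling = 1 year)
  h1 <- symptomatic_hazard(crs, 65, p) - p$w0
  h2 <- symptomatic_hazard(crs, 66, p) - p$w0
  expect_equal(h2, 2 * h1)
  # offsets step with true stage
  pp <- detection_params(eta = 0, w0 = 0.01, w1 = 0.1, w2 = 0.3)
  expect_equal(symptomatic_hazard(crs, 65, pp), 0.01)
  expect_equal(symptomatic_hazard(crs, 75, pp), 0.1)
  expect_equal(symptomatic_hazard(crs, 85, pp), 0.3)
})

test_that("hazard is non-decreasing along a course", {
  crs <- make_course(t0 = 60, lambda = 1.2, tn = 67, tm = 72, lambda_n = 3, lambda_m = 4)
  ages <- seq(60, 80, by = 0.1)
  h <- symptomatic_hazard(crs[rep(1, length(ages)), ], ages, detection_params())
  expect_true(all(diff(h) >= -1e-12))
})

test_that("detection sampling matches the integrated hazard (quadrature oracle)", {
  # N0M0-only course: no metastases, so the hazard is eta*S(t) + w0
  crs <- make_course(t0 = 60, lambda = 1.5, tn = Inf, tm = Inf)
  p <- detection_params(eta = 0.5, w0 = 0.02, w1 = 0, w2 = 0)
  n <- 8000
  set.seed(41)
  t_dc <- sample_symptomatic_detection(crs[rep(1, n), ], p, end_age = 110)
  det <- t_dc[!is.na(t_dc)]
  # independent oracle: numeric quadrature of the hazard
  cumhaz <- function(t) {
    vapply(t, function(tt) {
      integrate(function(u) {
        p$eta * 1e-9 * exp(crs$lambda * (u - crs$t0)) + p$w0
      }, crs$t0, tt, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  p_det <- -expm1(-cumhaz(110))
  cdf <- function(q) -expm1(-cumhaz(q)) / p_det
  ks <- suppressWarnings(ks.test(det, cdf))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(det)))
})

test_that("zero hazard never detects; huge W2 detects at distant seeding", {
  crs <- make_course(t0 = 60, lambda = 1, tn = Inf, tm = 70)
  set.seed(2)
  none <- sample_symptomatic_detection(
    crs[rep(1, 50), ], detection_params(eta = 0, w0 = 0, w1 = 0, w2 = 0), 100
  )
  expect_true(all(is.na(none)))
  p_inf <- detection_params(eta = 0, w0 = 0, w1 = 0, w2 = 1e9)
  t_dc <- sample_symptomatic_detection(crs[rep(1, 200), ], p_inf, 100)
  expect_equal(t_dc, rep(70, 200), tolerance = 1e-6)
})

test_that("screening schedules respect frequency, window and eligibility", {
  pol <- screening_policy(55, 77, 30, 15, screens_per_year = 1)
  always <- make_history(start_age = 20, quit_age = NA, intensity = 40)
  expect_equal(screen_schedule(always, pol), 55:77) # 23 annual screens
  never <- make_history(start_age = NA, intensity = 0)
  expect_length(screen_schedule(never, pol), 0)
  # quarterly gives 4x the screens of annual over the same span (+/- boundary)
  pol4 <- screening_policy(55, 77, 30, 15, screens_per_year = 4)
  n1 <- length(screen_schedule(always, pol))
  n4 <- length(screen_schedule(always, pol4))
  expect_true(abs(n4 - 4 * n1) <= 4)
  # calendar clipping
  sched <- screen_schedule(always, pol, calendar_window = c(1979, 1999))
  expect_true(all(always$birth_year + sched >= 1979))
  expect_true(all(always$birth_year + sched <= 1999))
})

test_that("screening detects at the first scan past the threshold crossing", {
  crs <- make_course(t0 = 60, lambda = 1, tn = Inf, tm = Inf)
  # primary reaches 1.24e-4 cm^3 at t0 + ln(1.24e5) = 71.73
  sched <- seq(55, 77, by = 1)
  out <- apply_screening(crs, sched)
  expect_equal(out$t_dc, 72)
  expect_equal(out$n_screens, 18)
  # onset after the last screen
  late <- make_course(t0 = 78, lambda = 1)
  expect_true(is.na(apply_screening(late, sched)$t_dc))
  # a fast nodal compartment can trigger detection before the primary
  crs2 <- make_course(t0 = 60, lambda = 0.3, tn = 62, tm = Inf, lambda_n = 6)
  out2 <- apply_screening(crs2, sched)
  expect_equal(out2$t_dc, 64) # 62 + 11.73/6 = 63.96 -> screen at 64
})

test_that("halving the screening interval never delays detection", {
  set.seed(51)
  onsets <- tibble::tibble(id = 1:1000, t0 = runif(1000, 50, 75))
  crs <- simulate_tumor_course(
    onsets, growth_model(K = 2, theta = 1), metastasis_params(), sim_config()
  )
  sched1 <- seq(55, 77, by = 1)
  sched2 <- seq(55, 77, by = 0.5)
  for (i in sample(nrow(crs), 60)) {
    t1 <- apply_screening(crs[i, ], sched1)$t_dc
    t2 <- apply_screening(crs[i, ], sched2)$t_dc
    if (!is.na(t1)) {
      expect_true(!is.na(t2) && t2 <= t1)
    }
  }
})

test_that("cohort screening detection agrees with the per-person primitive", {
  set.seed(61)
  pol <- screening_policy(55, 77, 30, 15, screens_per_year = 1)
  coh <- generate_cohort(cohort_config(1920:1930, 100))
  coh$t0 <- runif(nrow(coh), 45, 80)
  crs <- simulate_tumor_course(
    coh, growth_model(K = 2, theta = 1), metastasis_params(), sim_config()
  )
  elig <- occultsim:::eligibility_window(crs, pol)
  end <- rep(100, nrow(crs))
  fast <- occultsim:::screen_detect_cohort(crs, elig, pol, end)
  for (i in sample(nrow(crs), 50)) {
    sched <- screen_schedule(crs[i, ], pol)
    sched <- sched[sched <= end[i]]
    ref <- apply_screening(crs[i, ], sched)
    expect_equal(fast$t_dc[i], ref$t_dc)
    if (!is.na(ref$t_dc)) expect_equal(fast$n_screens[i], ref$n_screens)
  }
})
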