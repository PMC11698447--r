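test_that("diameter/volume conversion is exact and round-trips", {
  # the CT threshold: a 0.618 mm sphere
  expect_equal(diameter_to_volume(0.0618), 1.24e-4, tolerance = 5e-3)
  expect_equal(diameter_to_volume(0), 0)
  expect_equal(diameter_to_volume(1), pi / 6, tolerance = 1e-12)
  d <- c(0.0618, 0.5, 1, 2.7, 10)
  expect_equal(volume_to_diameter(diameter_to_volume(d)), d, tolerance = 1e-12)
  expect_error(diameter_to_volume(-1), "non-negative")
  expect_error(volume_to_diameter(-1), "non-negative")
})

test_that("metastasis cdf has the right form and special cases", {
  expect_equal(metastasis_cdf(0, mu = 0.1), 0)
  expect_equal(metastasis_cdf(c(1, 10, 100), mu = 0), rep(0, 3))
  # xi = 0 reduces to 1 - exp(-mu S): half-seeding volume at mu*S = ln 2
  mu <- 0.13
  expect_equal(metastasis_cdf(log(2) / mu, mu = mu, xi = 0), 0.5)
  # monotone in S
  s <- seq(0, 50, by = 0.5)
  expect_true(all(diff(metastasis_cdf(s, mu = 0.2, xi = -0.3)) >= 0))
  expect_error(metastasis_cdf(1, mu = 0.1, xi = -1), "xi")
  # quantile inverts the cdf
  p <- c(0.05, 0.5, 0.95)
  for (xi in c(-0.5, 0, 0.7)) {
    expect_equal(
      metastasis_cdf(metastasis_quantile(p, 0.2, xi), 0.2, xi), p,
      tolerance = 1e-12
    )
  }
})

test_that("primary growth is exponential from one cell", {
  crs <- make_course(t0 = 60, lambda = log(2))
  expect_equal(primary_volume_at(crs, 60), 1e-9)
  expect_equal(primary_volume_at(crs, 61), 2e-9)
  # time to reach the CT threshold is ln(ratio)/lambda
  t_star <- log(1.24e-4 / 1e-9) / crs$lambda
  expect_equal(primary_volume_at(crs, 60 + t_star), 1.24e-4, tolerance = 1e-12)
  expect_error(primary_volume_at(crs, 59), "onset")
})

test_that("sampled seeding volumes follow the metastasis cdf", {
  set.seed(21)
  onsets <- tibble::tibble(id = 1:8000, t0 = 60)
  g <- growth_model(K = 2, theta = 1)
  m <- metastasis_params(xi = -0.2, mu_n = 0.1, mu_m = 0.2)
  crs <- simulate_tumor_course(onsets, g, m, sim_config())
  ks <- suppressWarnings(
    ks.test(crs$s_m, function(s) metastasis_cdf(s, m$mu_m, m$xi))
  )
  expect_lt(unname(ks$statistic), 1.63 / sqrt(nrow(crs)))
  # seeding is the same in volume terms whatever the growth rate:
  # doubling lambda halves the seeding time but not the seeding volume
  expect_equal(
    primary_volume_at(crs, crs$tn, v_cell = 1e-9), crs$s_n,
    tolerance = 1e-9
  )
})

test_that("compartments grow from one cell at seeding and stage monotonically", {
  crs <- make_course(t0 = 60, lambda = log(2), tn = 65, tm = 70)
  expect_equal(compartment_volume_at(crs, 65, "nodal"), 1e-9)
  expect_equal(compartment_volume_at(crs, 66, "nodal"), 2e-9)
  expect_equal(compartment_volume_at(crs, 64.9, "nodal"), 0)
  expect_equal(compartment_volume_at(crs, 80, "distant"), 1e-9 * 2^10)
  no_seed <- make_course(tn = Inf, tm = Inf)
  expect_equal(compartment_volume_at(no_seed, 90, "distant"), 0)

  # stage sequence N0M0 -> N1M0 -> M1 with no reversals
  ages <- seq(60, 90, by = 0.25)
  st <- true_stage_at(crs[rep(1, length(ages)), ], ages)
  ranks <- match(st, c("N0M0", "N1M0", "M1"))
  expect_true(all(diff(ranks) >= 0))
  expect_equal(unique(st), c("N0M0", "N1M0", "M1"))
  # distant-first seeding goes straight to M1
  crs2 <- make_course(tn = 75, tm = 65)
  expect_equal(true_stage_at(crs2, 70), "M1")
  expect_equal(true_stage_at(crs2, 80), "M1")
})

test_that("occult classification thresholds are sharp", {
  cfg <- sim_config()
  expect_equal(classify_compartment(1e-9, cfg), "absent")
  expect_equal(classify_compartment(1e-6, cfg), "occult")
  expect_equal(classify_compartment(0.001, cfg), "detectable")
  expect_equal(classify_compartment(1.24e-4, cfg), "detectable")
  expect_error(sim_config(v_cell = 1, v_detect_min = 0.5), "below")
})

test_that("timeline marks invert the growth law", {
  crs <- make_course(t0 = 50, lambda = log(2), tn = 62, tm = Inf)
  mk <- timeline_marks(crs)
  expect_equal(mk$tvdt_days, 365.25)
  # 2 mm -> 5 mm takes ln((5/2)^3)/lambda years
  expect_equal(mk$age_5mm - mk$age_2mm, log((5 / 2)^3) / crs$lambda)
  expect_equal(mk$age_cure, 62)
  no_met <- make_course(tn = Inf, tm = Inf)
  expect_true(is.na(timeline_marks(no_met)$age_cure))
})

test_that("seeding probability by simulation equals the cdf at volume", {
  # the model's defining identity: P(Tn <= t) = F_n(S(t))
  set.seed(31)
  n <- 20000
  onsets <- tibble::tibble(id = seq_len(n), t0 = 0)
  g <- growth_model(K = 2, theta = 1)
  m <- metastasis_params(xi = 0, mu_n = 0.12, mu_m = 0)
  crs <- simulate_tumor_course(onsets, g, m, sim_config())
  for (s_chk in c(0.5, 3, 10)) {
    t_chk <- log(s_chk / 1e-9) / crs$lambda # per-tumor age when S = s_chk
    p_sim <- mean(crs$tn <= t_chk)
    expect_lt(abs(p_sim - metastasis_cdf(s_chk, 0.12)), 0.015)
  }
})
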