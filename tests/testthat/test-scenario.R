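test_that("scenarios are seed-deterministic and obey their detection mode", {
  cfg <- small_config(seed = 13)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$deaths, r2$deaths)
  expect_identical(glance(r1)$config_hash, glance(r2)$config_hash)

  # unperturbed: nobody is ever detected
  un <- run_scenario(small_config(scenario = "unperturbed", seed = 13))
  expect_equal(nrow(un$records), 0)
  # screening: every detection is a screen detection
  sc <- run_scenario(small_config(scenario = "screening", seed = 13))
  if (nrow(sc$records) > 0) {
    expect_true(all(sc$records$mode == "screen"))
    expect_true(all(sc$records$n_screens >= 1))
  }
})

test_that("paired arms share the natural history exactly", {
  arms <- run_paired(small_config(seed = 17))
  base <- arms$baseline_symptomatic
  scr <- arms$screening
  # the same person has identical T0, lambda, Tn, Tm across arms
  j <- dplyr::inner_join(
    base$records, scr$records,
    by = "id", suffix = c("_b", "_s")
  )
  expect_gt(nrow(j), 0)
  expect_equal(j$t0_b, j$t0_s)
  expect_equal(j$lambda_b, j$lambda_s)
  expect_equal(j$tn_b, j$tn_s)
  expect_equal(j$tm_b, j$tm_s)
  expect_equal(j$death_other_b, j$death_other_s)
  # only detection differs
  expect_identical(base$population, scr$population)
})

test_that("records are internally consistent", {
  res <- run_scenario(small_config(seed = 19))
  rec <- res$records
  expect_true(all(rec$t_dc >= rec$t0))
  # occult flags match compartment states
  expect_identical(rec$occult_nodal, rec$nms_state == "occult")
  expect_identical(rec$occult_distant, rec$dmp_state == "occult")
  # observed extent consistent with detectability
  expect_identical(rec$observed_extent == "M1", rec$dmp_state == "detectable")
  # observed stage consistent with (PTS, NMS, DMP)
  expect_identical(
    rec$observed_stage,
    observed_stage(
      rec$pts_cm, rec$nms_state == "detectable", rec$dmp_state == "detectable"
    )
  )
  # stage monotone: true stage at detection at least the extent ever observed
  rank <- function(s) match(s, c("N0M0", "N1M0", "M1"))
  expect_true(all(rank(rec$true_stage) >= rank(rec$observed_extent)))
  # deaths resolve the competing risks
  expect_true(all(rec$death_age <= pmax(rec$death_other, rec$lc_death_age)))
})

test_that("occult crosstab percentages are exact on a hand-built table", {
  rec <- tibble::tibble(
    birth_year = 1930, t_dc = 60,
    pts_cm = c(1.2, 2.5, 0.8, 4.0),
    observed_extent = "N0M0",
    true_stage = c("N0M0", "N0M0", "N1M0", "M1")
  )
  xt <- occult_crosstab(rec)
  tot <- xt[xt$size_bin == "Total", ]
  expect_equal(tot$pct[tot$true == "N0M0"], 50)
  expect_equal(tot$pct[tot$true == "N1M0"], 25)
  expect_equal(tot$pct[tot$true == "M1"], 25)
  # percentages sum to 100 in every non-empty column
  sums <- xt %>%
    dplyr::group_by(observed, size_bin) %>%
    dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("unperturbed crosstab marginals are consistent", {
  res <- run_scenario(small_config(scenario = "unperturbed", seed = 23))
  xt <- unperturbed_crosstab(res, snapshot_years = c(1988, 1998))
  # bin counts add up to the total column
  for (yy in c(1988, 1998)) {
    blk <- xt[xt$year == yy, ]
    expect_equal(
      sum(blk$n[blk$size_bin != "Total"]),
      sum(blk$n[blk$size_bin == "Total"])
    )
  }
  expect_error(unperturbed_crosstab(res, snapshot_years = 1700), "outside")
  # a cohort that never metastasizes is 100% N0M0
  cfg <- small_config(scenario = "unperturbed", seed = 23,
                      mets = metastasis_params(mu_n = 0, mu_m = 0))
  xt0 <- unperturbed_crosstab(run_scenario(cfg), snapshot_years = 1988)
  expect_true(all(xt0$true == "N0M0"))
  expect_true(all(xt0$pct == 100))
})

test_that("timeline summary is robust and additive", {
  crs <- make_course(t0 = 50, lambda = 2, tn = 58, tm = Inf)[rep(1, 5), ]
  crs$id <- 1:5
  ts <- timeline_summary(crs)
  # identical growth rates: zero-width quartiles
  expect_equal(ts$q1, ts$q3)
  win2 <- ts$median[ts$interval == "2mm_to_5mm"]
  expect_equal(win2, log((5 / 2)^3) / 2)
  # window at 2 mm = window at 5 mm + (2mm -> 5mm interval) on matched courses
  w5 <- ts$median[ts$interval == "5mm_to_cure"]
  mk <- timeline_marks(crs)
  expect_equal(mk$age_cure[1] - mk$age_2mm[1], w5 + win2)
})

test_that("mortality reduction arithmetic, bounds and scale invariance", {
  fake <- function(n_lc, years, label = "x") {
    structure(list(
      label = label,
      deaths = tibble::tibble(
        id = seq_len(n_lc), birth_year = 1900,
        death_age = years - 1900, death_cause = "LC", death_year = years
      )
    ), class = "scenario_result")
  }
  base <- fake(200, rep(1990, 200))
  scr <- fake(170, rep(1990, 170))
  mr <- mortality_reduction(base, scr, window = c(1979, 1999), boot = 50)
  expect_equal(mr$estimate, 0.15)
  # identical arms: zero reduction
  expect_equal(mortality_reduction(base, base, boot = 10)$estimate, 0)
  # all screened deaths pushed outside the window: reduction one
  late <- fake(170, rep(2005, 170))
  expect_equal(mortality_reduction(base, late, boot = 10)$estimate, 1)
  expect_error(mortality_reduction(late, base, boot = 10), "D_base")

  # on real paired arms (screening added to usual care): in (0, 1],
  # invariant to population scale
  mr_of <- function(mult, seed) {
    cfg <- run_config(
      cohort = cohort_config(1910:1940, 300 * mult),
      policy = screening_policy(55, 77, 30, 15, screens_per_year = 1),
      seed = seed
    )
    arms <- run_paired(cfg, scenarios = c("baseline_symptomatic", "combined"))
    mortality_reduction(arms[[1]], arms[[2]], boot = 100)
  }
  m1 <- mr_of(1, 29)
  m2 <- mr_of(2, 31)
  expect_gte(m1$estimate, 0)
  expect_lte(m1$estimate, 1)
  # scale invariance within joint bootstrap error
  se <- (m1$upper - m1$lower) / 3.92 + (m2$upper - m2$lower) / 3.92
  expect_lt(abs(m1$estimate - m2$estimate), 4 * se)
})

test_that("screening summary counts screens and responds to frequency", {
  cfgs <- lapply(c(0.5, 1), function(f) {
    small_config(
      scenario = "screening", seed = 37,
      policy = screening_policy(55, 77, 30, 15, screens_per_year = f)
    )
  })
  res <- lapply(cfgs, run_scenario)
  names(res) <- c("biennial", "annual")
  sm <- screening_summary(res, stage_i_only = FALSE)
  expect_equal(nrow(sm), 2)
  # shorter interval means more screens per detected cancer
  expect_gt(sm$screens_per_lc[2], sm$screens_per_lc[1])
  expect_equal(sm$total_cost, c(res[[1]]$screen_totals, res[[2]]$screen_totals) * 3074)
  # empty result set yields an explicit zero row
  empty <- res[[1]]
  empty$records <- empty$records[0, ]
  expect_equal(screening_summary(list(e = empty))$n_detected, 0)
})

test_that("tidiers return stable shapes", {
  res <- run_scenario(small_config(seed = 41))
  td <- tidy(res)
  expect_true(all(c("id", "t_dc", "observed_stage", "true_stage") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_detected, nrow(td))
})

test_that("yaml round trip builds an equivalent config", {
  path <- system.file("extdata", "default_config.yaml", package = "occultsim")
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$scenario, "baseline_symptomatic")
  expect_equal(cfg$cohort$birth_years, 1890:1984)
  expect_equal(cfg$window, c(1979, 1999))
})
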