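#' Run configuration for a simulation scenario
#'
#' Bundles every module's parameter block plus the scenario choice:
#' `"baseline_symptomatic"` (clinical detection only), `"unperturbed"`
#' (no detection at all — the substrate for screening analyses),
#' `"screening"` (periodic CT on the unperturbed population, symptomatic
#' detection switched off), or `"combined"` (CT screening layered on top
#' of usual care: each case is detected by whichever of the two routes
#' comes first — the configuration a real screening program creates, and
#' the one mortality comparisons should use, since a screening-only arm
#' lets disease that would have presented before the program's first scan
#' progress unrealistically).
#'
#' @param scenario Scenario label (see above).
#' @param cohort A [cohort_config()].
#' @param policy A [screening_policy()] (used by the screening scenario).
#' @param tsce A [tsce_params()].
#' @param growth A [growth_model()].
#' @param mets A [metastasis_params()].
#' @param detect A [detection_params()].
#' @param curves A [survival_curves()].
#' @param rules A [stage_rules()].
#' @param lifetable A [life_table()].
#' @param sim A [sim_config()].
#' @param window Calendar analysis window (mortality accounting), years.
#' @param screen_calendar_clip Clip screening schedules to the analysis
#'   window by calendar year (in addition to age)?
#' @param ct_unit_cost Cost of one CT screen, US dollars.
#' @param seed Integer seed; every stochastic phase derives its stream from
#'   it, so arms sharing a seed share natural histories.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = c("baseline_symptomatic", "unperturbed",
                                    "screening", "combined"),
                       cohort = cohort_config(),
                       policy = screening_policy(),
                       tsce = tsce_params(),
                       growth = growth_model(),
                       mets = metastasis_params(),
                       detect = detection_params(),
                       curves = survival_curves(),
                       rules = stage_rules(),
                       lifetable = life_table(),
                       sim = sim_config(),
                       window = c(1979, 1999),
                       screen_calendar_clip = TRUE,
                       ct_unit_cost = 3074,
                       seed = 1L) {
  if (window[1] >= window[2]) abort("window start must precede end")
  structure(
    list(
      scenario = match.arg(scenario), cohort = cohort, policy = policy,
      tsce = tsce, growth = growth, mets = mets, detect = detect,
      curves = curves, rules = rules, lifetable = lifetable, sim = sim,
      window = window, screen_calendar_clip = screen_calendar_clip,
      ct_unit_cost = ct_unit_cost, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Simulate the shared natural-history substrate of a scenario
#'
#' Generates the cohort, draws other-cause death ages, samples tumor onset
#' through the TSCE model, and simulates the latent tumor course (growth
#' rate, seeding ages, compartment growth rates) for every person whose
#' onset precedes death and the horizon. Also draws the per-person survival
#' uniform, so paired arms that share a seed share not only the disease but
#' the survival quantile given identical stage at diagnosis.
#'
#' @param config A [run_config()].
#' @return List of class `lc_population`: `persons` (cohort plus death
#'   ages), `courses` (tumor courses for persons with onset), `n_persons`.
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  persons <- generate_cohort(config$cohort)
  smoking <- dplyr::case_when(
    persons$intensity == 0 ~ "never",
    is.na(persons$quit_age) ~ "current",
    TRUE ~ "former"
  )
  persons$death_other <- pmin(
    sample_other_cause_death(persons$sex, config$lifetable, smoking),
    config$sim$max_age
  )
  t0 <- sample_onset_age(config$tsce, persons, max_age = config$sim$max_age)
  persons$t0 <- t0
  case <- !is.na(t0) & t0 < persons$death_other
  courses <- persons[case, , drop = FALSE] %>%
    simulate_tumor_course(config$growth, config$mets, config$sim) %>%
    mutate(u_surv = runif(sum(case)))
  structure(
    list(persons = persons, courses = as_tibble(courses), n_persons = nrow(persons)),
    class = "lc_population"
  )
}

# Build DiagnosisRecord rows for detected cases: sizes, compartment states,
# occult flags, observed and true stage.
build_records <- function(courses, t_dc, mode, n_screens, config) {
  det <- !is.na(t_dc)
  rec <- courses[det, , drop = FALSE]
  t_dc <- t_dc[det]
  v_cell <- config$sim$v_cell
  sp <- v_cell * exp(rec$lambda * (t_dc - rec$t0))
  sn <- compartment_volume_at(rec, t_dc, "nodal", v_cell)
  sm <- compartment_volume_at(rec, t_dc, "distant", v_cell)
  nms_state <- classify_compartment(sn, config$sim)
  dmp_state <- classify_compartment(sm, config$sim)
  true_st <- true_stage_at(rec, t_dc)
  obs_extent <- dplyr::case_when(
    dmp_state == "detectable" ~ "M1",
    nms_state == "detectable" ~ "N1M0",
    TRUE ~ "N0M0"
  )
  pts <- volume_to_diameter(sp)
  tibble(
    id = rec$id, birth_year = rec$birth_year, sex = rec$sex,
    t0 = rec$t0, lambda = rec$lambda, tn = rec$tn, tm = rec$tm,
    death_other = rec$death_other, u_surv = rec$u_surv,
    t_dc = t_dc, mode = mode[det], n_screens = n_screens[det],
    pts_cm = pts,
    nms_cm = ifelse(sn > 0, volume_to_diameter(sn), 0),
    nms_state = nms_state, dmp_state = dmp_state,
    observed_extent = obs_extent, true_stage = true_st,
    occult_nodal = nms_state == "occult",
    occult_distant = dmp_state == "occult",
    observed_stage = observed_stage(
      pts, nms_state == "detectable", dmp_state == "detectable", config$rules
    )
  )
}

#' Run one scenario end to end
#'
#' Pipeline composition of every module: cohort, onset, tumor course,
#' detection (per the scenario), staging, post-diagnosis survival, and
#' competing mortality. Seed-deterministic: the same config (seed included)
#' reproduces the tables bit for bit. Detection uses an RNG stream separate
#' from the natural history, so scenarios sharing a seed are counterfactual
#' arms over identical disease.
#'
#' @param config A [run_config()].
#' @param population Optional pre-simulated [simulate_population()] output
#'   (for explicit arm pairing); simulated from `config` when `NULL`.
#' @return Object of class `scenario_result`: `label`, `records`
#'   (diagnosis records), `deaths`, `screen_totals`, `n_persons`, `seed`,
#'   `config_hash`.
#' @export
run_scenario <- function(config, population = NULL) {
  if (is.null(population)) population <- simulate_population(config)
  courses <- population$courses
  end <- pmin(courses$death_other, config$sim$max_age)
  n_scr_pop <- 0L
  n <- nrow(courses)
  t_sym <- rep(NA_real_, n)
  if (config$scenario %in% c("baseline_symptomatic", "combined")) {
    set.seed(config$seed + 1000003L)
    t_sym <- sample_symptomatic_detection(
      courses, config$detect, end, config$sim$v_cell
    )
  }
  t_scr <- rep(NA_real_, n)
  n_screens <- rep(0L, n)
  if (config$scenario %in% c("screening", "combined")) {
    cal <- if (isTRUE(config$screen_calendar_clip)) config$window else NULL
    elig <- eligibility_window(courses, config$policy)
    scr <- screen_detect_cohort(
      courses, elig, config$policy, end, cal,
      config$sim$v_detect_min, config$sim$v_cell
    )
    t_scr <- scr$t_dc
    n_screens <- scr$n_screens
    # screens delivered to the whole cohort (healthy people get scanned too)
    pers <- population$persons
    elig_all <- eligibility_window(pers, config$policy)
    n_all <- screen_count_only(
      pers, elig_all, config$policy, pmin(pers$death_other, config$sim$max_age), cal
    )
    # persons detected stop screening at detection
    det <- !is.na(t_scr)
    n_all[match(courses$id[det], pers$id)] <- n_screens[det]
    n_scr_pop <- sum(n_all)
  }
  t_dc <- pmin(t_sym, t_scr, na.rm = TRUE)
  t_dc[is.infinite(t_dc)] <- NA_real_
  mode <- dplyr::case_when(
    is.na(t_dc) ~ "undetected",
    !is.na(t_scr) & (is.na(t_sym) | t_scr <= t_sym) ~ "screen",
    TRUE ~ "symptomatic"
  )
  # a symptomatic detection in the combined scenario also ends screening:
  # recount that person's scans up to the symptomatic date
  sym_first <- !is.na(t_dc) & mode == "symptomatic" &
    config$scenario == "combined"
  if (any(sym_first)) {
    n_screens[sym_first] <- screen_count_only(
      courses[sym_first, , drop = FALSE],
      eligibility_window(courses[sym_first, , drop = FALSE], config$policy),
      config$policy, pmin(end, t_dc)[sym_first],
      if (isTRUE(config$screen_calendar_clip)) config$window else NULL
    )
  }
  records <- build_records(courses, t_dc, mode, n_screens, config)

  # survival and competing mortality for detected cases
  if (nrow(records) > 0) {
    surv_years <- sample_lc_survival(records, config$curves, u = records$u_surv)
    lc_death <- records$t_dc + surv_years
    dd <- resolve_death(lc_death, records$death_other)
    records$lc_death_age <- lc_death
    records$death_age <- dd$death_age
    records$death_cause <- dd$cause
  } else {
    records$lc_death_age <- numeric(0)
    records$death_age <- numeric(0)
    records$death_cause <- character(0)
  }
  deaths <- records %>%
    select("id", "birth_year", "death_age", "death_cause") %>%
    mutate(death_year = .data$birth_year + .data$death_age)

  structure(
    list(
      label = config$scenario,
      records = records,
      deaths = deaths,
      population = population,
      screen_totals = n_scr_pop,
      n_persons = population$n_persons,
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "seed")])
    ),
    class = "scenario_result"
  )
}

# number of scans a (possibly tumor-free) person receives absent detection
screen_count_only <- function(persons, elig, policy, end, calendar_window) {
  f <- policy$screens_per_year
  lo <- pmax(policy$start_age, elig$elig_lo)
  hi <- pmin(policy$end_age, elig$elig_hi)
  if (!is.null(calendar_window)) {
    lo <- pmax(lo, calendar_window[1] - persons$birth_year)
    hi <- pmin(hi, calendar_window[2] - persons$birth_year)
  }
  hi <- pmin(hi, end)
  j_lo <- pmax(0, ceiling((lo - policy$start_age) * f - 1e-9))
  j_hi <- floor((hi - policy$start_age) * f + 1e-9)
  n <- ifelse(!is.na(lo) & j_hi >= j_lo, j_hi - j_lo + 1, 0)
  as.integer(n)
}

#' Run counterfactually paired scenario arms
#'
#' Simulates the natural history once and applies each detection mode to
#' it, so every person has identical onset age, growth rate and seeding
#' ages across arms — only detection (and therefore stage, survival and
#' cause of death) differs.
#'
#' With `match_deaths = TRUE` (the default) a person detected in both arms
#' at the same stage and size bin — i.e. drawing from the same survival
#' curve — keeps the baseline arm's death date in the screening arm:
#' earlier detection without a stage shift advances the diagnosis, not the
#' death. Without this, restarting the survival clock at an earlier
#' detection age would move deaths of stage-unchanged cases *earlier*, the
#' classic lead-time artifact that inflates (here: reverses) modelled
#' screening mortality effects. Observed survival (diagnosis to death)
#' still includes lead time, as screen-detected survival does in registry
#' data.
#'
#' @param config A [run_config()]; its `scenario` field is ignored.
#' @param scenarios Character vector of arms to run.
#' @param policies Optional named list of [screening_policy()] objects;
#'   each adds one extra arm under the last non-baseline scenario listed
#'   (e.g. several eligibility rules compared on one population).
#' @param match_deaths Carry baseline death dates over to stage-unchanged
#'   screen-detected cases?
#' @return Named list of `scenario_result`s sharing one population.
#' @export
run_paired <- function(config,
                       scenarios = c("baseline_symptomatic", "screening"),
                       policies = NULL,
                       match_deaths = TRUE) {
  population <- simulate_population(config)
  out <- lapply(scenarios, function(sc) {
    cfg <- config
    cfg$scenario <- sc
    run_scenario(cfg, population = population)
  })
  names(out) <- scenarios
  if (!is.null(policies)) {
    sc <- setdiff(scenarios, "baseline_symptomatic")
    sc <- if (length(sc)) sc[length(sc)] else "screening"
    extra <- lapply(policies, function(pol) {
      cfg <- config
      cfg$scenario <- sc
      cfg$policy <- pol
      run_scenario(cfg, population = population)
    })
    out <- c(out, extra)
  }
  ref <- out$baseline_symptomatic
  if (match_deaths && !is.null(ref)) {
    for (nm in setdiff(names(out), "baseline_symptomatic")) {
      out[[nm]] <- match_paired_deaths(ref, out[[nm]], config)
    }
  }
  out
}

# Replace the screening arm's LC death dates by the baseline arm's for
# persons detected in both arms from the same survival curve (same stage
# group and size bin): no survival benefit without a stage shift.
match_paired_deaths <- function(baseline, screened, config) {
  rec_s <- screened$records
  if (nrow(rec_s) == 0) return(screened)
  rec_b <- baseline$records
  curve_of <- function(rec) match_curve(rec$observed_stage, rec$pts_cm, config$curves)
  b_idx <- match(rec_s$id, rec_b$id)
  both <- !is.na(b_idx)
  same <- both
  same[both] <- curve_of(rec_s[both, ]) == curve_of(rec_b[b_idx[both], ])
  lc <- rec_s$lc_death_age
  lc[same] <- rec_b$lc_death_age[b_idx[same]]
  # the carried-over death cannot precede the (earlier) screen detection,
  # but guard against pathological orderings
  lc[same] <- pmax(lc[same], rec_s$t_dc[same])
  dd <- resolve_death(lc, rec_s$death_other)
  rec_s$lc_death_age <- lc
  rec_s$death_age <- dd$death_age
  rec_s$death_cause <- dd$cause
  screened$records <- rec_s
  screened$deaths <- rec_s %>%
    select("id", "birth_year", "death_age", "death_cause") %>%
    mutate(death_year = .data$birth_year + .data$death_age)
  screened
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result:", x$label, ">\n")
  cat("  persons:  ", x$n_persons, "\n")
  cat("  cases:    ", nrow(x$population$courses), " (onset before death)\n")
  cat("  detected: ", nrow(x$records), "\n")
  if (x$label == "screening") cat("  CT screens:", x$screen_totals, "\n")
  invisible(x)
}
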