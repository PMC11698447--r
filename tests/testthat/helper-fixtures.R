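# Shared fixtures: everything is built in code at test time.

# a one-row smoking history
make_history <- function(start_age = 20, quit_age = NA, intensity = 20,
                         birth_year = 1930, sex = "M") {
  tibble::tibble(
    id = 1L, birth_year = birth_year, sex = sex,
    start_age = start_age, quit_age = quit_age, intensity = intensity
  )
}

# a hand-built tumor course (volumes in cm^3, ages in years)
make_course <- function(t0 = 60, lambda = log(2), tn = Inf, tm = Inf,
                        lambda_n = lambda, lambda_m = lambda, id = 1L) {
  tibble::tibble(
    id = id, t0 = t0, lambda = lambda, tn = tn, tm = tm,
    lambda_n = lambda_n, lambda_m = lambda_m
  )
}

# a small, fast run configuration for pipeline tests
small_config <- function(scenario = "baseline_symptomatic", seed = 7, ...) {
  run_config(
    scenario = scenario,
    cohort = cohort_config(birth_years = 1910:1940, births_per_year = 150),
    seed = seed,
    ...
  )
}
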