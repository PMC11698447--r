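#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a scenario result
#'
#' One row per diagnosis record, in a stable column order.
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble of diagnosis records.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$records %>%
    select(
      "id", "t_dc", "mode", "pts_cm", "nms_state", "nms_cm", "dmp_state",
      "observed_stage", "observed_extent", "true_stage",
      "occult_nodal", "occult_distant", "n_screens",
      "death_age", "death_cause"
    )
}

#' One-row summary of a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A one-row tibble: scenario label, cohort size, case and
#'   detection counts, occult-metastasis fraction among detections, LC
#'   deaths, total CT screens, seed and config hash.
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  rec <- x$records
  tibble(
    scenario = x$label,
    n_persons = x$n_persons,
    n_cases = nrow(x$population$courses),
    n_detected = nrow(rec),
    frac_occult = if (nrow(rec)) mean(rec$occult_nodal | rec$occult_distant) else NA_real_,
    n_lc_deaths = sum(rec$death_cause == "LC"),
    n_screens = x$screen_totals,
    seed = x$seed,
    config_hash = x$config_hash
  )
}

#' Tidy a mortality-reduction estimate
#'
#' @param x A `mortality_reduction`.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `d_base`,
#'   `d_screen`.
#' @method tidy mortality_reduction
#' @export
tidy.mortality_reduction <- function(x, ...) {
  tibble(
    estimate = x$estimate, lower = x$lower, upper = x$upper,
    d_base = x$d_base, d_screen = x$d_screen
  )
}
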