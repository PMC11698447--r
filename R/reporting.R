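#' Occult-metastasis cross-tabulation of detected cases
#'
#' For each observed extent block (N0M0, N1M0, M1) tabulates the true
#' disease extent at diagnosis against the detected primary-size bin, as
#' counts and within-column percentages (per block each size column sums to
#' 100 up to rounding). The observed N1M0 block labels true M1 as `N1M1`
#' in keeping with clinical usage (nodal disease was seen, distant was not).
#'
#' @param records Diagnosis-record tibble (e.g. `result$records`).
#' @param size_bins Diameter bin edges, cm.
#' @param calendar_window Optional length-2 calendar window restricting
#'   detections by year of diagnosis.
#' @return Tibble of class `occult_crosstab`: `observed`, `true`,
#'   `size_bin` (including `"Total"`), `n`, `pct`.
#' @export
occult_crosstab <- function(records, size_bins = c(0.5, 1, 1.5, 2, 3),
                            calendar_window = NULL) {
  if (!is.null(calendar_window)) {
    yr <- records$birth_year + records$t_dc
    records <- records[yr >= calendar_window[1] & yr <= calendar_window[2], ]
  }
  rec <- records %>%
    mutate(
      size_bin = size_bin_of(.data$pts_cm, size_bins),
      true = dplyr::case_when(
        .data$observed_extent == "N1M0" & .data$true_stage == "M1" ~ "N1M1",
        TRUE ~ .data$true_stage
      )
    )
  tot <- rec %>%
    count(observed = .data$observed_extent, true = .data$true) %>%
    mutate(size_bin = "Total")
  by_bin <- rec %>%
    count(
      observed = .data$observed_extent, true = .data$true,
      size_bin = as.character(.data$size_bin)
    )
  out <- bind_rows(tot, by_bin) %>%
    group_by(.data$observed, .data$size_bin) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$observed, .data$size_bin, .data$true)
  class(out) <- c("occult_crosstab", class(out))
  out
}

#' True-stage cross-tabulation of the unperturbed population
#'
#' At each snapshot calendar year, tabulates true disease extent against
#' primary-size bin among persons with an undiagnosed tumor who are alive
#' at the snapshot (their disease is evaluated at the snapshot age).
#' Persons who already died of another cause have left the population
#' cross-section, so successive snapshots have comparable size and show no
#' secular accumulation. Percentages are within each size column of a
#' year block.
#'
#' @param result A `scenario_result` from the unperturbed scenario (or any
#'   population whose courses are undiagnosed).
#' @param snapshot_years Calendar years at which to take the cross-section.
#' @param size_bins Diameter bin edges, cm.
#' @return Tibble of class `unperturbed_crosstab`: `year`, `true`,
#'   `size_bin`, `n`, `pct`.
#' @export
unperturbed_crosstab <- function(result, snapshot_years = c(1978, 1988, 1998),
                                 size_bins = c(0.5, 1, 1.5, 2, 3)) {
  courses <- if (inherits(result, "scenario_result")) {
    result$population$courses
  } else {
    result
  }
  min_year <- min(courses$birth_year + courses$t0)
  max_year <- max(courses$birth_year + courses$death_other)
  if (any(snapshot_years < min_year | snapshot_years > max_year)) {
    abort("snapshot year outside the simulated window")
  }
  out <- purrr::map_dfr(snapshot_years, function(yy) {
    age_snap <- yy - courses$birth_year
    have <- courses$t0 <= age_snap & courses$death_other >= age_snap
    cc <- courses[have, , drop = FALSE]
    at <- age_snap[have]
    sp <- .v_cell_default * exp(cc$lambda * (at - cc$t0))
    tibble(
      year = yy,
      true = true_stage_at(cc, at),
      size_bin = size_bin_of(volume_to_diameter(sp), size_bins)
    )
  })
  tot <- out %>% count(.data$year, .data$true) %>% mutate(size_bin = "Total")
  by_bin <- out %>%
    count(.data$year, .data$true, size_bin = as.character(.data$size_bin))
  res <- bind_rows(tot, by_bin) %>%
    group_by(.data$year, .data$size_bin) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$year, .data$size_bin, .data$true)
  class(res) <- c("unperturbed_crosstab", class(res))
  res
}

#' Progression-timeline summary
#'
#' Medians and quartiles of the interval lengths onset to 2 mm, 2 to 5 mm,
#' 5 mm to the cure threshold (first metastatic seeding), and cure threshold
#' to detection, plus the tumor volume doubling time — separately for the
#' full (unperturbed) tumor population and the detected cases. The median
#' 5 mm-to-cure interval on detected cases is the "window of opportunity":
#' the time during which the tumor is large enough to find but not yet
#' metastatic. Courses missing a mark are excluded from that interval, with
#' the exclusion count reported.
#'
#' @param courses Tumor-course tibble (the unperturbed population).
#' @param records Diagnosis-record tibble (detected cases), or `NULL`.
#' @return Tibble: `population`, `interval`, `q1`, `median`, `q3`,
#'   `n`, `n_excluded`.
#' @export
timeline_summary <- function(courses, records = NULL) {
  one <- function(marks, label) {
    ivs <- list(
      "onset_to_2mm" = marks$age_2mm - marks$t0_,
      "2mm_to_5mm" = marks$age_5mm - marks$age_2mm,
      "5mm_to_cure" = marks$age_cure - marks$age_5mm,
      "cure_to_detection" = marks$age_detect - marks$age_cure,
      "tvdt_days" = marks$tvdt_days
    )
    purrr::imap_dfr(ivs, function(v, nm) {
      ok <- is.finite(v)
      qs <- if (any(ok)) quantile(v[ok], c(0.25, 0.5, 0.75)) else rep(NA_real_, 3)
      tibble(
        population = label, interval = nm,
        q1 = qs[[1]], median = qs[[2]], q3 = qs[[3]],
        n = sum(ok), n_excluded = sum(!ok)
      )
    })
  }
  mk <- timeline_marks(courses)
  mk$t0_ <- courses$t0
  out <- one(mk, "unperturbed")
  if (!is.null(records) && nrow(records) > 0) {
    mkd <- timeline_marks(records)
    mkd$t0_ <- records$t0
    out <- bind_rows(out, one(mkd, "detected"))
  }
  out
}

#' Screening-scenario comparison rows
#'
#' One row per scenario result: mean/SD and median/IQR of age at diagnosis,
#' observed survival years (diagnosis to death from any cause), and age at
#' death, plus CT screens per detected lung cancer and the implied total
#' cost. Restricted by default to observed stage I (the stage whose
#' management screening aims to enable); set `stage_i_only = FALSE` for all
#' cases.
#'
#' @param results Named list of `scenario_result`s (or a single one).
#' @param stage_i_only Restrict to observed stage IA/IB?
#' @param ct_unit_cost Dollars per CT screen.
#' @return Tibble with one row per scenario.
#' @export
screening_summary <- function(results, stage_i_only = TRUE,
                              ct_unit_cost = 3074) {
  if (inherits(results, "scenario_result")) results <- list(results)
  purrr::imap_dfr(results, function(res, nm) {
    rec <- res$records
    if (stage_i_only && nrow(rec) > 0) {
      rec <- rec[rec$observed_stage %in% c("IA", "IB"), ]
    }
    if (nrow(rec) == 0) {
      return(tibble(
        scenario = if (nzchar(nm)) nm else res$label, n_detected = 0L,
        dx_age_mean = 0, dx_age_sd = 0, dx_age_median = 0,
        surv_mean = 0, surv_median = 0, death_age_mean = 0,
        death_age_median = 0, screens_per_lc = 0, total_cost = 0
      ))
    }
    surv <- rec$death_age - rec$t_dc
    n_lc <- nrow(rec)
    screens_per_lc <- if (res$label == "screening") res$screen_totals / n_lc else 0
    tibble(
      scenario = if (nzchar(nm)) nm else res$label,
      n_detected = n_lc,
      dx_age_mean = mean(rec$t_dc), dx_age_sd = stats::sd(rec$t_dc),
      dx_age_median = median(rec$t_dc),
      surv_mean = mean(surv), surv_median = median(surv),
      death_age_mean = mean(rec$death_age),
      death_age_median = median(rec$death_age),
      screens_per_lc = screens_per_lc,
      total_cost = res$screen_totals * ct_unit_cost
    )
  })
}

#' Screening mortality reduction over a calendar window
#'
#' `(D_base - D_screen) / D_base`, where `D` counts lung-cancer deaths whose
#' calendar year of death falls inside the window, on counterfactually
#' paired arms (same persons, same tumors, different detection). The
#' confidence interval is a person-level Poisson bootstrap: each person's
#' contribution to both counts is reweighted by an independent Poisson(1)
#' weight per replicate.
#'
#' @param baseline,screened Paired `scenario_result`s.
#' @param window Length-2 calendar window (defaults to the baseline
#'   config's).
#' @param boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param by_year Also return the per-calendar-year reduction series?
#' @return List of class `mortality_reduction`: `estimate`, `lower`,
#'   `upper`, `d_base`, `d_screen`, `window`, and optionally `by_year`.
#' @export
mortality_reduction <- function(baseline, screened, window = c(1979, 1999),
                                boot = 1000, conf = 0.95, by_year = FALSE) {
  in_win <- function(res) {
    d <- res$deaths
    d[d$death_cause == "LC" & d$death_year >= window[1] &
      d$death_year <= window[2], c("id", "death_year")]
  }
  db <- in_win(baseline)
  ds <- in_win(screened)
  if (nrow(db) == 0) abort("no baseline LC deaths in window (D_base = 0)")
  ids <- union(db$id, ds$id)
  b <- as.numeric(ids %in% db$id)
  s <- as.numeric(ids %in% ds$id)
  est <- (sum(b) - sum(s)) / sum(b)
  reps <- vapply(seq_len(boot), function(i) {
    w <- rpois(length(ids), 1)
    dbw <- sum(w * b)
    if (dbw == 0) return(NA_real_)
    (dbw - sum(w * s)) / dbw
  }, numeric(1))
  alpha <- (1 - conf) / 2
  out <- list(
    estimate = est,
    lower = unname(quantile(reps, alpha, na.rm = TRUE)),
    upper = unname(quantile(reps, 1 - alpha, na.rm = TRUE)),
    d_base = sum(b), d_screen = sum(s), window = window
  )
  if (by_year) {
    yrs <- seq(window[1], window[2])
    out$by_year <- purrr::map_dfr(yrs, function(yy) {
      dby <- sum(floor(db$death_year) == yy)
      dsy <- sum(floor(ds$death_year) == yy)
      tibble(
        year = yy, d_base = dby, d_screen = dsy,
        reduction = if (dby > 0) (dby - dsy) / dby else NA_real_
      )
    })
  }
  structure(out, class = "mortality_reduction")
}

#' @export
print.mortality_reduction <- function(x, ...) {
  cat(sprintf(
    "Mortality reduction %.2f%% (%.2f%%-%.2f%%), %d vs %d LC deaths in %d-%d\n",
    100 * x$estimate, 100 * x$lower, 100 * x$upper,
    x$d_base, x$d_screen, x$window[1], x$window[2]
  ))
  invisible(x)
}
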