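#' Read a run configuration from YAML
#'
#' Each top-level block (`cohort`, `tsce`, `growth`, `mets`, `detect`,
#' `policy`, `sim`, `run`) holds arguments for the corresponding
#' constructor; omitted blocks and fields keep their defaults, so a minimal
#' file like `run: {scenario: screening, seed: 7}` is valid.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) {
    cb <- y$cohort
    if (!is.null(cb$birth_year_from)) {
      cb$birth_years <- seq(cb$birth_year_from, cb$birth_year_to)
      cb$birth_year_from <- NULL
      cb$birth_year_to <- NULL
    }
    args$cohort <- do.call(cohort_config, cb)
  }
  if (!is.null(y$tsce)) args$tsce <- do.call(tsce_params, y$tsce)
  if (!is.null(y$growth)) args$growth <- do.call(growth_model, y$growth)
  if (!is.null(y$mets)) args$mets <- do.call(metastasis_params, y$mets)
  if (!is.null(y$detect)) args$detect <- do.call(detection_params, y$detect)
  if (!is.null(y$policy)) args$policy <- do.call(screening_policy, y$policy)
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$run)) args <- c(args, y$run)
  do.call(run_config, args)
}

#' Write the standard scenario tables as CSV
#'
#' Emits `table1_occult.csv` (occult cross-tab of symptomatic detections),
#' `table2_unperturbed.csv` (snapshot cross-tab), `timeline.csv`, and the
#' per-case diagnosis records `records.csv` into `dir`.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if missing).
#' @param snapshot_years Years for the unperturbed cross-tab.
#' @return Invisibly, the vector of files written.
#' @export
write_scenario_tables <- function(result, dir,
                                  snapshot_years = c(1978, 1988, 1998)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(tidy(result), "records.csv")
  if (nrow(result$records) > 0) {
    wr(occult_crosstab(result$records), "table1_occult.csv")
    wr(
      timeline_summary(result$population$courses, result$records),
      "timeline.csv"
    )
  }
  wr(unperturbed_crosstab(result, snapshot_years), "table2_unperturbed.csv")
  invisible(files)
}
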