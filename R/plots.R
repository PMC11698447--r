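#' Plot an occult-metastasis cross-tab as stacked bars
#'
#' One panel per observed extent; bars show the true-extent composition of
#' each detected-size bin.
#'
#' @param object An [occult_crosstab()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot occult_crosstab
#' @export
autoplot.occult_crosstab <- function(object, ...) {
  df <- object[object$size_bin != "Total", ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size_bin, y = .data$pct, fill = .data$true
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~observed) +
    ggplot2::labs(
      x = "detected primary size (cm)", y = "% of detections",
      fill = "true extent"
    )
}

#' Plot an unperturbed-population cross-tab
#'
#' @param object An [unperturbed_crosstab()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot unperturbed_crosstab
#' @export
autoplot.unperturbed_crosstab <- function(object, ...) {
  df <- object[object$size_bin != "Total", ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size_bin, y = .data$pct, fill = .data$true
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(
      x = "primary size (cm)", y = "% of undiagnosed tumors",
      fill = "true extent"
    )
}

#' Progression-timeline bar chart
#'
#' Median interval lengths (onset to 2 mm, 2 to 5 mm, 5 mm to cure
#' threshold, cure threshold to detection) for the unperturbed and detected
#' populations.
#'
#' @param summary A [timeline_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_timeline <- function(summary) {
  df <- summary[summary$interval != "tvdt_days", ]
  df$interval <- factor(df$interval, levels = c(
    "onset_to_2mm", "2mm_to_5mm", "5mm_to_cure", "cure_to_detection"
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$median, y = .data$population, fill = .data$interval
  )) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE)) +
    ggplot2::labs(x = "years from first malignant cell", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
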