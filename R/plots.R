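#' Plot a hypnogram timeline
#'
#' One coloured tile per epoch along recording time.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  ep <- attr(object, "epoch_s")
  ggplot2::ggplot(object, ggplot2::aes(
    xmin = .data$start_s / 3600, xmax = (.data$start_s + ep) / 3600,
    ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot a merge-threshold sweep
#'
#' Agreement metrics and sleep bout count against the movement-merging
#' threshold; the reference bout count is the dashed line.
#'
#' @param object A `staging_sweep` from [sweep_merge_threshold()].
#' @param ... Unused.
#' @return A ggplot (patch of two panels via facets).
#' @method autoplot staging_sweep
#' @export
autoplot.staging_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("threshold_s", "sensitivity", "specificity", "accuracy")],
    -"threshold_s", names_to = "metric", values_to = "value")
  bouts <- tibble(
    threshold_s = object$threshold_s, metric = "sleep bouts / reference",
    value = object$bout_count / object$bout_count_reference)
  ggplot2::ggplot(dplyr::bind_rows(long, bouts),
                  ggplot2::aes(.data$threshold_s, .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "merge threshold (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot hourly sleep time
#'
#' Minutes of sleep per zeitgeber hour (averaged over days).
#'
#' @param object A `sleep_summary` from [sleep_time_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sleep_summary
#' @export
autoplot.sleep_summary <- function(object, ...) {
  d <- dplyr::filter(object$hourly, .data$state %in% c("Sleep", "NREM", "REM"))
  ggplot2::ggplot(d, ggplot2::aes(.data$zt_hour, .data$minutes,
                                  colour = .data$state)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "zeitgeber time (h)", y = "min / h", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot state-wise power spectra
#'
#' @param object Output of [state_power_spectra()].
#' @return A ggplot.
#' @export
plot_state_spectra <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_hz, .data$percent,
                                       colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "% of 1-30 Hz power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
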