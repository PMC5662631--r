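# ggplot2 visualisation methods.

#' Plot a network recording
#'
#' Voltage traces stacked by probe, plus a spike raster underneath.
#'
#' @param object a `bg_recording`.
#' @param populations populations to show (default all recorded).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bg_recording <- function(object, populations = NULL, ...) {
  df <- tidy(object)
  if (!is.null(populations)) {
    df <- dplyr::filter(df, .data$population %in% populations)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$v)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$probe)) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' Spike raster of a recording
#'
#' @param rec a `bg_recording`.
#' @param populations populations to show.
#' @return a ggplot object.
#' @export
plot_raster <- function(rec, populations = NULL) {
  sp <- rec$spikes
  if (!is.null(populations)) {
    sp <- dplyr::filter(sp, .data$population %in% populations)
  }
  sp <- dplyr::mutate(sp,
    cell = paste0(.data$population, "_", .data$id))
  ggplot2::ggplot(sp, ggplot2::aes(.data$time, .data$cell,
                                   colour = .data$population)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none")
}

#' Plot an EI sweep table
#'
#' Works for spine sweeps (`ns`), dendrite sweeps (`nd`) and depletion
#' scans (`fraction`): mean EI with a +/- 1 sd ribbon against the swept
#' fraction.
#'
#' @param object a sweep tibble from [run_spine_sweep()],
#'   [run_dendrite_sweep()] or [run_depletion_scan()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_ei_sweep <- function(object, ...) {
  xvar <- intersect(c("spine_loss_fraction", "degeneration_fraction",
                      "fraction"), names(object))[1]
  if (is.na(xvar)) stop("not a sweep table: no swept fraction column")
  ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$ei_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$ei_mean - .data$ei_sd,
      ymax = .data$ei_mean + .data$ei_sd), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "error index (EI)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot a GPi-thalamic phase diagram
#'
#' @param object a `bg_phase_diagram` from [phase_diagram()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bg_phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$v_gpi, .data$v_th)) +
    ggplot2::geom_point(alpha = 0.05, size = 0.3) +
    ggplot2::labs(x = "GPi membrane potential (mV)",
                  y = "TH membrane potential (mV)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Plot an EM-neuron recording
#'
#' @param object an `em_recording` from [simulate_em()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.em_recording <- function(object, ...) {
  df <- tibble::tibble(time = object$times, v = object$v)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$v)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Box-plot summary of a cortical stimulation grid
#'
#' Five-number EI summaries per grid cell, in the style of the published
#' frequency/amplitude section plots.
#'
#' @param tbl output of [run_cortical_stim_grid()].
#' @param by `"frequency"` or `"amplitude"`.
#' @return a ggplot object.
#' @export
plot_stim_grid <- function(tbl, by = c("frequency", "amplitude")) {
  by <- match.arg(by)
  tbl$x <- factor(signif(tbl[[by]], 3))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_boxplot(ggplot2::aes(
      ymin = .data$ei_min, lower = .data$ei_q1, middle = .data$ei_median,
      upper = .data$ei_q3, ymax = .data$ei_max), stat = "identity") +
    ggplot2::labs(x = by, y = "error index (EI)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
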