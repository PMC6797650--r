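#' Plot a cutoff sweep
#'
#' Accuracy (or the chosen criterion) as a function of the swept parameter,
#' with the optimum marked and, when supplied, a horizontal reference line
#' at the unprocessed baseline.
#'
#' @param object A `sweep_result` from [sweep_strategy()].
#' @param baseline Optional baseline criterion value (e.g. accuracy of the
#'   unprocessed data) drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, baseline = NULL, ...) {
  criterion <- attr(object, "criterion")
  ycol <- if (criterion == "accuracy") "accuracy" else "youden_sum"
  opt <- attr(object, "optimum")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object[object$value == opt, , drop = FALSE],
                        colour = "red", size = 3) +
    ggplot2::labs(
      x = switch(attr(object, "strategy"),
                 min_duration = "minimal duration cutoff (s)",
                 interpolate = "interpolation gap (s)",
                 triadic_closure = "triadic closure iterations"),
      y = criterion,
      title = sprintf("%s sweep (optimum at %g)", attr(object, "strategy"), opt)
    )
  if (!is.null(baseline)) {
    p <- p + ggplot2::geom_hline(yintercept = baseline, colour = "grey50",
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot dyadic durations by nomination status
#'
#' Group means with 95% confidence intervals of dyad-level contact minutes,
#' split by whether the dyad was self-reported.
#'
#' @param x Weighted contact matrix (minutes).
#' @param y Directed nomination matrix.
#' @param mode Symmetrization defining "nominated" (see [symmetrize()]).
#' @return A ggplot object.
#' @export
plot_duration_by_nomination <- function(x, y, mode = "weak") {
  ys <- symmetrize(y, mode)
  ut <- upper.tri(x)
  dat <- tibble::tibble(minutes = x[ut], nominated = ys[ut])
  dat <- dat[!is.na(dat$nominated), ]
  dat$nominated <- factor(dat$nominated, c(0, 1), c("not reported", "reported"))
  summ <- dplyr::summarise(
    dplyr::group_by(dat, .data$nominated),
    mean = mean(.data$minutes),
    ci = stats::qt(0.975, dplyr::n() - 1) * stats::sd(.data$minutes) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$nominated, y = .data$mean)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci,
                                        ymax = .data$mean + .data$ci),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "dyadic contact duration (min)")
}

#' Plot a dyad-second raster
#'
#' Timeline view of an event log: one horizontal line segment per contact
#' event, one row per dyad.
#'
#' @param log An [event_log()].
#' @return A ggplot object.
#' @export
plot_event_log <- function(log) {
  log <- as_event_log(log)
  df <- tibble::as_tibble(as.data.frame(log))
  df$dyad <- dyad_key(df$id_a, df$id_b)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$dyad, yend = .data$dyad),
                          linewidth = 2) +
    ggplot2::labs(x = "time (s)", y = "dyad")
}
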