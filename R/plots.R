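# ggplot2 views of traces, ensembles, sweeps and maps. Non-normative
# convenience plots; all numbers come from the tidied result tables.

#' @export
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_us / 1000,
                               y = .data$current_pA,
                               colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "current (pA)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synapse_ensemble <- function(object, ...) {
  if (is.null(object$mean_trace))
    abort("ensemble was run with trace = FALSE")
  ggplot2::ggplot(object$mean_trace,
                  ggplot2::aes(x = .data$time_us / 1000,
                               y = .data$current_pA,
                               colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "mean current (pA)", colour = NULL,
                  subtitle = sprintf("pointwise mean of %d trials",
                                     object$n_trials)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  cells <- object$cells
  xvar <- switch(object$family,
                 density_constant = "n_receptors",
                 fixed_n = "mean_nn",
                 cleft_size = "cleft_radius")
  xlab <- switch(object$family,
                 density_constant = "receptor number N",
                 fixed_n = "mean nearest-neighbour distance (nm)",
                 cleft_size = "cleft radius R (nm)")
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data[[xvar]], y = .data$mean_peak_pA,
                               colour = factor(.data$cleft_radius))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_peak_pA - .data$sd_peak_pA,
                                        ymax = .data$mean_peak_pA + .data$sd_peak_pA),
                           width = 0) +
    ggplot2::geom_smooth(method = "lm",
                         formula = if (object$family == "fixed_n")
                           y ~ poly(x, 2) else y ~ x,
                         se = FALSE, linetype = "dashed") +
    ggplot2::labs(x = xlab, y = "peak current (pA)", colour = "R (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.parametric_map <- function(object, ...) {
  p <- ggplot2::ggplot(object$surface,
                       ggplot2::aes(x = .data$psd_radius, y = .data$density)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mean_peak_pA)) +
    ggplot2::scale_fill_viridis_c(name = "peak (pA)") +
    ggplot2::labs(x = "PSD radius (nm)", y = "receptor density (nm^-2)") +
    ggplot2::theme_minimal()
  g <- object$gradient
  if (nrow(g) > 0) {
    g <- g[!g$flat, ]
    rr <- diff(range(object$surface$psd_radius)) * 0.08
    dd <- diff(range(object$surface$density)) * 0.08
    p <- p + ggplot2::geom_segment(
      data = g,
      ggplot2::aes(x = .data$psd_radius, y = .data$density,
                   xend = .data$psd_radius + rr * .data$dir_radius,
                   yend = .data$density + dd * .data$dir_density),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "red", linetype = "dotted")
  }
  p
}
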