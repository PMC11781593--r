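#' Plot a model potential surface
#'
#' Filled-contour map of the energy (capped for display) with optional
#' threshold guides.
#'
#' @param surface a `potential_surface`.
#' @param xlim,ylim plot ranges, Angstrom.
#' @param n grid resolution per axis.
#' @param cap energies above this value (k_BT) are clipped for display.
#' @return A ggplot object.
#' @export
plot_surface <- function(surface, xlim = c(-4.5, 4.5), ylim = c(-10, 10),
                         n = 201, cap = 15) {
  grid <- tidyr::expand_grid(x = seq(xlim[1], xlim[2], length.out = n),
                             y = seq(ylim[1], ylim[2], length.out = n))
  grid$energy <- pmin(potential_energy(surface, grid$x, grid$y), cap)
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$y, fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "U (kBT)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.fpt_ensemble <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tibble::as_tibble(object)[!object$censored, ],
                  ggplot2::aes(.data$fpt_ns)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::geom_vline(xintercept = mfpt(object), linetype = 2) +
    ggplot2::labs(x = "first-passage time (ns)", y = "count")
}

#' @exportS3Method ggplot2::autoplot
autoplot.isr_prediction <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$valid)
  df$protocol <- ifelse(is.finite(df$threshold),
                        paste0("ISR c=", df$threshold), "SR")
  ggplot2::ggplot(df, ggplot2::aes(.data$rate_ns, .data$speedup,
                                   colour = .data$protocol)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "resetting rate (1/ns)", y = "predicted speedup")
}

#' @exportS3Method ggplot2::autoplot
autoplot.isr_inference <- function(object, ...) {
  df <- tidy(object)
  rseq <- seq(0, max(df$rate_ns), length.out = 100)
  fitted <- exp(stats::predict(object$fit, newdata = data.frame(r = rseq)))
  ggplot2::ggplot(df, ggplot2::aes(.data$rate_ns, .data$mfpt_ns)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mfpt_ns - .data$se_ns,
                                        ymax = .data$mfpt_ns + .data$se_ns),
                           width = 0) +
    ggplot2::geom_line(data = data.frame(rate_ns = rseq, mfpt_ns = fitted),
                       linetype = 2, colour = "firebrick") +
    ggplot2::annotate("point", x = 0, y = object$mfpt0_ns, shape = 8,
                      size = 3) +
    ggplot2::labs(x = "resetting rate (1/ns)", y = "MFPT (ns)")
}
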