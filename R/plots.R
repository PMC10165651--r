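#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a polarized delayed-fluorescence trace
#'
#' Both polarization channels (and optionally the total) versus time.
#'
#' @param object An `oadfa_trace`.
#' @param total Also draw `I_par + I_perp`.
#' @param log_y Log-scale the count axis.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.oadfa_trace <- function(object, total = TRUE, log_y = TRUE, ...) {
  d <- tibble::tibble(
    time = rep(object$bin_start * 1e6, if (total) 3 else 2),
    counts = c(object$counts_par, object$counts_perp,
               if (total) object$counts_par + object$counts_perp),
    channel = rep(c("parallel", "perpendicular", if (total) "total"),
                  each = nrow(object))
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$counts,
                                       colour = .data$channel)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after primary pulse (µs)",
                  y = "delayed photons / bin", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an anisotropy decay (and optionally its fit)
#'
#' @param object An `oadfa_anisotropy`.
#' @param fit Optional `oadfa_fit` whose curve is overlaid.
#' @param show_masked Draw masked bins as hollow points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.oadfa_anisotropy <- function(object, fit = NULL,
                                      show_masked = FALSE, ...) {
  d <- object
  d$time_us <- d$time * 1e6
  p <- ggplot2::ggplot(
    dplyr::filter(d, !.data$mask),
    ggplot2::aes(x = .data$time_us, y = .data$r)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$r - .data$r_err,
                                          ymax = .data$r + .data$r_err),
                             size = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time after primary pulse (µs)",
                  y = "anisotropy r(t)") +
    ggplot2::theme_minimal()
  if (show_masked) {
    p <- p + ggplot2::geom_point(data = dplyr::filter(d, .data$mask),
                                 shape = 1, na.rm = TRUE)
  }
  if (!is.null(fit) && isTRUE(fit$success)) {
    tt <- seq(fit$fit_window[1], fit$fit_window[2], length.out = 200)
    curve <- tibble::tibble(time_us = tt * 1e6,
                            r = fit$r0 * exp(-tt / fit$theta))
    p <- p + ggplot2::geom_line(data = curve, colour = "red")
  }
  p
}

#' Plot integrated state populations
#'
#' @param object An `oadfa_populations` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.oadfa_populations <- function(object, ...) {
  d <- tibble::tibble(
    time = rep(object$time * 1e6, 3),
    population = c(object$S0, object$S1, object$T1),
    state = rep(c("S0", "S1", "T1"), each = nrow(object))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$population,
                                  colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after primary pulse (µs)",
                  y = "fractional population", colour = NULL) +
    ggplot2::theme_minimal()
}
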