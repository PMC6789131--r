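#' Plot a transport profile as a residue-by-time heat map
#'
#' @param object A `transport_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transport_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$residue,
                                       fill = .data$elevation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * T[B] ~ "(K)")) +
    ggplot2::scale_y_continuous(breaks = unique(object$residue)) +
    ggplot2::labs(x = "time (ps)", y = "residue",
                  title = paste0("Temperature elevation (",
                                 attr(object, "label"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot fitted rate constants against time
#'
#' @param object A `rate_fit`.
#' @param ... Unused.
#' @return A ggplot, one panel per channel.
#' @export
autoplot.rate_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rate,
                                   colour = .data$term)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = expression(k ~ (ps^-1))) +
    ggplot2::theme_minimal()
}

#' Plot binned flux against effective temperature gradient
#'
#' The flux-gradient characteristic: class-mean flux per gradient bin with
#' one-standard-error bars, optionally overlaid with regime fits.
#'
#' @param object A `gradient_bins` tibble.
#' @param regimes Optional `regime_fit` to overlay as fitted lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gradient_bins <- function(object, regimes = NULL, ...) {
  df <- tibble::as_tibble(object[object$reliable, ])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$mean_flux,
                                        colour = .data$temperature_class)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_flux - .data$sem_flux,
      ymax = .data$mean_flux + .data$sem_flux), size = 0.2) +
    ggplot2::labs(x = expression(Delta[ij] * T[eff] ~ "(K)"),
                  y = expression(J ~ (eV ~ ps^-1)),
                  colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(regimes)) {
    seg <- tibble::as_tibble(regimes[regimes$converged, ])
    if (nrow(seg)) {
      seg$x <- seg$range_lo
      seg$xend <- seg$range_hi
      seg$y <- seg$intercept + seg$kappa_eff * seg$range_lo
      seg$yend <- seg$intercept + seg$kappa_eff * seg$range_hi
      p <- p + ggplot2::geom_segment(
        data = seg, inherit.aes = FALSE, colour = "black",
        ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$yend)) +
        ggplot2::geom_vline(xintercept = unique(c(seg$range_lo, seg$range_hi)),
                            linetype = 3, alpha = 0.4)
    }
  }
  p
}

#' Plot a per-bin free-energy barrier profile
#'
#' @param barriers The tibble returned by [barrier_profile()].
#' @return A ggplot (barrier in meV against gradient-bin centre).
#' @export
plot_barrier_profile <- function(barriers) {
  ggplot2::ggplot(barriers, ggplot2::aes(x = .data$bin_center,
                                         y = 1000 * .data$barrier)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = 1000 * (.data$barrier - .data$barrier_sem),
      ymax = 1000 * (.data$barrier + .data$barrier_sem)), size = 0.2) +
    ggplot2::labs(x = expression(Delta[ij] * T[eff] ~ "(K)"),
                  y = expression(Delta * F ~ "(meV)")) +
    ggplot2::theme_minimal()
}
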