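#' Plot a confined free-energy profile
#'
#' @inheritParams free_energy_profile
#' @return A ggplot: \eqn{\beta\Delta F} against crystal size, with the
#'   stationary points marked when present.
#' @export
plot_free_energy_profile <- function(n_tot, n_tot_s, x_star, sigma_prime,
                                     n_grid = NULL) {
  prof <- free_energy_profile(n_tot, n_tot_s, x_star, sigma_prime, n_grid)
  st <- stationary_points(n_tot, n_tot_s, x_star, sigma_prime)
  pts <- tidyr::pivot_longer(st, dplyr::everything(),
                             names_to = "point", values_to = "n_xtal")
  pts <- dplyr::filter(pts, !is.na(.data$n_xtal))
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$n_xtal, .data$beta_dF)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(n[xtal] ~ "(molecules)"),
      y = expression(beta * Delta * F ~ "(" * k[B] * T * ")")
    ) +
    ggplot2::theme_minimal()
  if (nrow(pts) > 0) {
    pts$beta_dF <- confined_free_energy(pts$n_xtal, n_tot, n_tot_s,
                                        x_star, sigma_prime)
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(.data$n_xtal, .data$beta_dF, shape = .data$point),
      size = 3
    )
  }
  p
}

#' Predicted against observed steady-state sizes for a fit
#'
#' @param object A `thermo_fit`.
#' @param ... Unused.
#' @return A ggplot comparing each observation's steady-state size with the
#'   minimum of the fitted confined free-energy profile of its box; the
#'   identity line marks perfect self-consistency.
#' @method autoplot thermo_fit
#' @export
autoplot.thermo_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$n_ss, .data$.fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = expression("observed" ~ n[ss] ~ "(molecules)"),
      y = expression("predicted" ~ n[ss] ~ "(molecules)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a confined-solution stability map
#'
#' @param map A long-format tibble from [stability_map()].
#' @param log_size Use a logarithmic box-size axis.
#' @return A ggplot tiling the composition/size plane by stability label.
#' @export
plot_stability_map <- function(map, log_size = TRUE) {
  p <- ggplot2::ggplot(map, ggplot2::aes(.data$n_tot_s, .data$x0,
                                         fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(undersaturated = "grey70", confined_stabilized = "white",
                 nucleation_permitted = "#3182bd"),
      drop = FALSE
    ) +
    ggplot2::labs(x = expression(n[tot]^s ~ "(solvent molecules)"),
                  y = expression(x[0]), fill = NULL) +
    ggplot2::theme_minimal()
  if (log_size) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a metastable zone
#'
#' @param object A [metastable_limit()] result.
#' @param ... Unused.
#' @return A ggplot of the solubility curve and the limit of solution
#'   stability; the shaded band is the metastable zone.
#' @method autoplot metastable_limit
#' @export
autoplot.metastable_limit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$T_K)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$x_star,
                                      ymax = .data$x_limit),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_star)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$x_limit), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "T (K)", y = "x (mole fraction)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
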