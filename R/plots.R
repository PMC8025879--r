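# ggplot2 views of the potentials and of settling/classification results.

#' Plot the adaptive distance-restraint potential
#'
#' Draws the energy profile for one or more fall-off exponents, showing the
#' flat bottom, the harmonic core and the top-out tails.
#'
#' @param r0,kappa,c,tau Potential parameters (see [distance_energy()]).
#' @param alpha Vector of fall-off exponents, one curve each.
#' @param span Half-range of plotted distances around `r0`, Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_potential <- function(r0 = 4, kappa = 1, c = 0.5, tau = 0.1,
                                    alpha = c(2, 0, -2, -8), span = 4) {
  d <- seq(max(r0 - span, 0.01), r0 + span, length.out = 400)
  df <- purrr::map_dfr(alpha, function(a) {
    tibble(d = d, alpha = a,
           energy = distance_energy(d, r0, kappa, c, tau, a))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$d, .data$energy,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Å)", y = "energy (kJ/mol)",
                  colour = expression(alpha)) +
    ggplot2::theme_minimal()
}

#' Plot the adaptive torsion-restraint potential
#'
#' @param delta_theta0 Well width, degrees.
#' @param k Spring constant.
#' @param alpha Vector of fall-off parameters, one curve each.
#' @return A ggplot object.
#' @export
plot_torsion_potential <- function(delta_theta0 = 60, k = 1,
                                   alpha = c(0, 0.1, 0.3, 0.5)) {
  kap <- kappa_from_well_width(delta_theta0)
  th <- seq(-180, 180, length.out = 721)
  df <- purrr::map_dfr(alpha, function(a) {
    tibble(theta = th, alpha = a,
           energy = torsion_energy_adaptive(th, 0, kap, k, a))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$energy,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 60)) +
    ggplot2::labs(x = expression(theta - theta[0] ~ "(deg)"),
                  y = "energy (kJ/mol)", colour = expression(alpha)) +
    ggplot2::theme_minimal()
}

#' Energy trajectory of a settle run
#'
#' @param object A [settle()] result.
#' @param ... Unused.
#' @return A ggplot object (energy and max force vs iteration).
#' @method autoplot settle_result
#' @export
autoplot.settle_result <- function(object, ...) {
  df <- object$trajectory |>
    tidyr::pivot_longer(c("energy", "max_force"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$iterations, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "minimiser iterations", y = NULL) +
    ggplot2::theme_minimal()
}
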