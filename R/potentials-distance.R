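# Flat-bottomed adaptive distance-restraint potential.
#
# The core is the generalised robust loss
#   rho(x; alpha, c) = (|alpha - 2|/alpha) * [((x/c)^2/|alpha - 2| + 1)^(alpha/2) - 1]
# whose fall-off exponent alpha interpolates a whole family of classical
# losses: alpha = 2 is harmonic, alpha = 0 the log ("Cauchy") limit,
# alpha = -2 Geman-McClure and alpha -> -Inf the Welsch loss. alpha = 0 and
# alpha = 2 are removable singularities of the general expression and are
# dispatched to their closed forms, as are near-singular values where the
# general form would cancel catastrophically. The restraint energy is
#   E(d) = k * rho(max(|d - r0| - tau, 0); alpha, c)
# with a symmetric flat bottom of half-width tau around the target r0.

ALPHA_SINGULAR_TOL <- 1e-6

# rho and its derivative with respect to the (non-negative) effective
# deviation x. Vectorised over everything; alpha may vary per element and may
# be -Inf (Welsch sentinel).
robust_loss <- function(x, c, alpha) {
  u <- (x / c)^2
  out <- numeric(length(u))
  alpha <- rep_len(alpha, length(u))
  welsch <- is.infinite(alpha) & alpha < 0
  harm <- !welsch & abs(alpha - 2) < ALPHA_SINGULAR_TOL
  logc <- !welsch & abs(alpha) < ALPHA_SINGULAR_TOL
  gen <- !(welsch | harm | logc)
  out[harm] <- 0.5 * u[harm]
  out[logc] <- log1p(0.5 * u[logc])
  out[welsch] <- -expm1(-0.5 * u[welsch])
  if (any(gen)) {
    a <- alpha[gen]
    b <- abs(a - 2)
    out[gen] <- (b / a) * ((u[gen] / b + 1)^(a / 2) - 1)
  }
  out
}

robust_loss_deriv <- function(x, c, alpha) {
  u <- (x / c)^2
  base <- x / c^2
  out <- numeric(length(u))
  alpha <- rep_len(alpha, length(u))
  welsch <- is.infinite(alpha) & alpha < 0
  harm <- !welsch & abs(alpha - 2) < ALPHA_SINGULAR_TOL
  logc <- !welsch & abs(alpha) < ALPHA_SINGULAR_TOL
  gen <- !(welsch | harm | logc)
  out[harm] <- base[harm]
  out[logc] <- base[logc] / (0.5 * u[logc] + 1)
  out[welsch] <- base[welsch] * exp(-0.5 * u[welsch])
  if (any(gen)) {
    a <- alpha[gen]
    b <- abs(a - 2)
    out[gen] <- base[gen] * (u[gen] / b + 1)^(a / 2 - 1)
  }
  out
}

check_distance_params <- function(d, r0, c, tau, k) {
  stopifnot_finite(d, "d")
  if (any(d < 0)) abort("distances `d` must be non-negative")
  stopifnot_finite(r0, "r0")
  if (any(r0 <= 0)) abort("target distance `r0` must be positive")
  stopifnot_finite(c, "c")
  if (any(c <= 0)) abort("harmonic half-width `c` must be positive")
  stopifnot_finite(tau, "tau")
  if (any(tau < 0)) abort("flat-bottom half-width `tau` must be non-negative")
  stopifnot_finite(k, "k")
  if (any(k < 0)) abort("energy scale `k` must be non-negative")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha)) abort("`alpha` must be numeric and non-missing")
  if (any(is.infinite(alpha) & alpha > 0)) abort("`alpha` may be -Inf (Welsch) but not +Inf")
}

#' Adaptive flat-bottomed distance-restraint energy
#'
#' Energy of the top-out distance restraint: a generalised robust loss of the
#' deviation from the target distance, with a flat (zero-energy) bottom of
#' half-width `tau` around `r0`. The fall-off exponent `alpha` tunes the
#' long-range behaviour: `alpha = 2` is a plain harmonic spring, `alpha = -2`
#' the Geman-McClure loss, and `alpha = -Inf` the Welsch loss, which flattens
#' to a constant so that distant atom pairs feel essentially no bias.
#'
#' All arguments are vectorised and recycled.
#'
#' @param d Current distance(s) in Angstrom (non-negative).
#' @param r0 Target distance in Angstrom (positive).
#' @param kappa Energy scale \eqn{k} in kJ/mol (the restraint-generation
#'   protocol calls this parameter `kappa`; it is unrelated to the torsion
#'   well-shape parameter of the same name).
#' @param c Half-width of the approximately quadratic region, Angstrom.
#' @param tau Flat-bottom half-width, Angstrom (zero energy for
#'   `|d - r0| <= tau`).
#' @param alpha Fall-off exponent (dimensionless); `-Inf` selects the Welsch
#'   closed form.
#' @return Energy in kJ/mol, `>= 0`, zero iff `|d - r0| <= tau`.
#' @seealso [distance_force()]
#' @examples
#' distance_energy(4.5, r0 = 4, kappa = 1, c = 0.5, tau = 0.1, alpha = -2)
#' @export
distance_energy <- function(d, r0, kappa = 1, c = 0.5, tau = 0, alpha = 2) {
  check_distance_params(d, r0, c, tau, kappa)
  check_alpha(alpha)
  x <- pmax(abs(d - r0) - tau, 0)
  kappa * robust_loss(x, c, alpha)
}

#' Adaptive distance-restraint gradient
#'
#' Analytic derivative `dE/dd` of [distance_energy()] with respect to the
#' current distance. The restoring force on the atom pair is its negative:
#' positive gradient for `d > r0` pulls the atoms back towards the target.
#' Exactly zero inside the flat bottom.
#'
#' @inheritParams distance_energy
#' @return Gradient in kJ/mol/Angstrom.
#' @export
distance_force <- function(d, r0, kappa = 1, c = 0.5, tau = 0, alpha = 2) {
  check_distance_params(d, r0, c, tau, kappa)
  check_alpha(alpha)
  dev <- d - r0
  x <- pmax(abs(dev) - tau, 0)
  kappa * robust_loss_deriv(x, c, alpha) * sign(dev)
}
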