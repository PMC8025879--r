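# Periodic torsion-restraint potentials derived from the von Mises
# distribution.
#
# Starting from g(theta) = -exp(kappa * cos(theta - theta0)) (the negated
# numerator of the von Mises density), the gradient
# kappa * sin(dtheta) * exp(kappa * cos(dtheta)) peaks where
#   cos(dtheta_Fmax) = (sqrt(1 + 4 kappa^2) - 1) / (2 kappa).
# Dividing by the peak gradient G(kappa) = sqrt(s) * exp(s), with
# s = kappa * cos(dtheta_Fmax), renormalises the well so that the maximum
# restraining gradient is exactly the spring constant k regardless of the
# well width. Choosing the integration constant so the minimum is zero gives
# the top-out form
#   E10(dtheta) = k * (exp(kappa) - exp(kappa cos dtheta)) / G(kappa)
# evaluated here in overflow-safe form. The adaptive extension blends in a
# plain cosine term controlled by the fall-off parameter alpha,
#   E14 = (1 - alpha) * E10 + alpha * k * (1 - cos dtheta),
# which is identical to E10 at alpha = 0, keeps a restraining gradient
# outside the well for alpha > 0, becomes repulsive outside the well for
# alpha < 0, and is steeper than a plain cosine for alpha > 1.

# s = kappa * cos(dtheta_Fmax); tends to kappa - 1/2 for large kappa.
topout_s <- function(kappa) (sqrt(4 * kappa^2 + 1) - 1) / 2

check_kappa <- function(kappa, allow_zero = FALSE) {
  stopifnot_finite(kappa, "kappa")
  lo <- if (allow_zero) 0 else .Machine$double.xmin
  if (any(kappa < lo)) {
    abort(if (allow_zero) "`kappa` must be non-negative" else "`kappa` must be positive")
  }
}

#' von Mises density
#'
#' Density of the von Mises distribution, the periodic analogue of the normal
#' distribution, parameterised by a centre `theta0` and a shape parameter
#' `kappa` (roughly an inverse variance; `kappa = 0` is the uniform
#' distribution on the circle). Angles are in degrees; the density is per
#' radian so that it integrates to one over a full period.
#'
#' @param theta Angle(s), degrees.
#' @param theta0 Centre, degrees.
#' @param kappa Shape parameter, `>= 0`.
#' @return Density per radian.
#' @examples
#' vonmises_density(0, 0, 3.46)
#' @export
vonmises_density <- function(theta, theta0 = 0, kappa = 1) {
  stopifnot_finite(theta, "theta")
  stopifnot_finite(theta0, "theta0")
  check_kappa(kappa, allow_zero = TRUE)
  d <- deg2rad(wrap_angle(theta - theta0))
  exp(kappa * (cos(d) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Deviation of peak restraining force
#'
#' The angular deviation from the target at which the gradient of the
#' (unnormalised) von Mises well `kappa * sin(d) * exp(kappa * cos(d))` is
#' maximal. Twice this value defines the natural well width of the torsion
#' restraint (see [kappa_from_well_width()]); for narrow wells it corresponds
#' to two standard deviations of the matched normal distribution. Closed
#' form: `acos((sqrt(1 + 4 kappa^2) - 1) / (2 kappa))`.
#'
#' @param kappa Well-shape parameter, `> 0`.
#' @return Deviation in degrees, in `(0, 90]`; strictly decreasing in
#'   `kappa`.
#' @examples
#' max_gradient_angle(3.46) # ~30 degrees
#' @export
max_gradient_angle <- function(kappa) {
  check_kappa(kappa)
  rad2deg(acos(topout_s(kappa) / kappa))
}

#' Well-shape parameter from well width
#'
#' Inverse of `2 * max_gradient_angle(kappa)`: converts the natural well
#' width `delta_theta0` (the full angular span outside which the restraining
#' force has decayed to near zero) into the von Mises shape parameter
#' `kappa`. Closed form: with `h = delta_theta0/2`,
#' `kappa = cos(h) / sin(h)^2`. The round trip with
#' [well_width_from_kappa()] is exact to floating-point precision.
#'
#' @param delta_theta0 Well width in degrees, strictly inside `(0, 180)`.
#' @return `kappa > 0`.
#' @examples
#' kappa_from_well_width(60)  # 3.46
#' kappa_from_well_width(120) # 0.67
#' @export
kappa_from_well_width <- function(delta_theta0) {
  stopifnot_finite(delta_theta0, "delta_theta0")
  if (any(delta_theta0 <= 0 | delta_theta0 >= 180)) {
    abort("`delta_theta0` must lie strictly between 0 and 180 degrees")
  }
  h <- deg2rad(delta_theta0 / 2)
  cos(h) / sin(h)^2
}

#' Well width from well-shape parameter
#'
#' @param kappa Well-shape parameter, `> 0`.
#' @return Well width `delta_theta0 = 2 * max_gradient_angle(kappa)`,
#'   degrees.
#' @export
well_width_from_kappa <- function(kappa) 2 * max_gradient_angle(kappa)

topout_energy_rad <- function(d, kappa, k) {
  s <- topout_s(kappa)
  k * exp(kappa - s) * (-expm1(kappa * (cos(d) - 1))) / sqrt(s)
}

topout_grad_rad <- function(d, kappa, k) {
  s <- topout_s(kappa)
  k * kappa * sin(d) * exp(kappa * (cos(d) - 1) + kappa - s) / sqrt(s)
}

#' Top-out periodic torsion-restraint energy
#'
#' The renormalised von Mises well: periodic with period 360 degrees,
#' minimum zero at `theta0`, and peak gradient magnitude exactly `k`
#' whatever the well width -- decoupling the strength of the restraint from
#' its width, unlike the raw von Mises form whose steepness collapses as the
#' well broadens.
#'
#' @param theta Current torsion(s), degrees.
#' @param theta0 Target torsion, degrees.
#' @param kappa Well-shape parameter, `> 0` (see [kappa_from_well_width()]).
#' @param k Spring constant, kJ/mol (equals the peak gradient per radian).
#' @param period Wrapping period in degrees; 180 for torsions with a
#'   symmetric terminus.
#' @return Energy, kJ/mol.
#' @seealso [torsion_energy_adaptive()]
#' @export
torsion_energy_topout <- function(theta, theta0 = 0, kappa = 1, k = 1, period = 360) {
  stopifnot_finite(theta, "theta")
  stopifnot_finite(theta0, "theta0")
  check_kappa(kappa)
  d <- deg2rad(wrap_angle(theta - theta0, period))
  topout_energy_rad(d, kappa, k)
}

#' Adaptive periodic torsion-restraint energy
#'
#' Extends [torsion_energy_topout()] with a tuneable fall-off parameter
#' `alpha` blending in a plain cosine term:
#' `E = (1 - alpha) * E_topout + alpha * k * (1 - cos(theta - theta0))`.
#' At `alpha = 0` this is identical to the top-out form; values in
#' `(0, 0.5]` keep a gentle restraining gradient outside the well (the most
#' useful range in practice); negative values make the region outside the
#' well repulsive; values above 1 are steeper than a plain cosine. The peak
#' gradient is no longer exactly `k` for nonzero `alpha`, but stays within
#' about 40% of it for `alpha` in `[0, 0.5]`.
#'
#' @inheritParams torsion_energy_topout
#' @param alpha Fall-off parameter (dimensionless, any finite value).
#' @return Energy, kJ/mol.
#' @export
torsion_energy_adaptive <- function(theta, theta0 = 0, kappa = 1, k = 1, alpha = 0,
                                    period = 360) {
  stopifnot_finite(theta, "theta")
  stopifnot_finite(theta0, "theta0")
  stopifnot_finite(alpha, "alpha")
  check_kappa(kappa)
  d <- deg2rad(wrap_angle(theta - theta0, period))
  (1 - alpha) * topout_energy_rad(d, kappa, k) + alpha * k * (1 - cos(d))
}

#' Adaptive torsion-restraint gradient
#'
#' Analytic `dE/dtheta` (per radian) of [torsion_energy_adaptive()];
#' antisymmetric in the wrapped deviation and continuous across the
#' antipode.
#'
#' @inheritParams torsion_energy_adaptive
#' @return Gradient, kJ/mol/radian.
#' @export
torsion_force_adaptive <- function(theta, theta0 = 0, kappa = 1, k = 1, alpha = 0,
                                   period = 360) {
  stopifnot_finite(theta, "theta")
  stopifnot_finite(theta0, "theta0")
  stopifnot_finite(alpha, "alpha")
  check_kappa(kappa)
  d <- deg2rad(wrap_angle(theta - theta0, period))
  (1 - alpha) * topout_grad_rad(d, kappa, k) + alpha * k * sin(d)
}

OMEGA_FLAT_DEG <- 30

omega_target_angle <- function(target) {
  if (!all(target %in% c("cis", "trans"))) {
    abort('omega restraint `target` must be "cis" or "trans"')
  }
  ifelse(target == "cis", 0, 180)
}

#' Flat-bottomed cosine restraint for the peptide omega dihedral
#'
#' Peptide-bond omega dihedrals are not restrained with the adaptive
#' periodic form; instead a cosine-shaped penalty with a +/-30 degree flat
#' bottom holds them to the cis (0 degrees) or trans (180 degrees) isomer.
#' Outside the flat bottom the penalty rises smoothly (C1 at the boundary)
#' to its maximum `k` at the opposite isomer.
#'
#' @param omega Current omega dihedral(s), degrees.
#' @param target `"cis"` or `"trans"` (recycled).
#' @param k Energy scale, kJ/mol (the maximum penalty).
#' @param flat Flat-bottom half-width, degrees (default 30).
#' @return Energy, kJ/mol.
#' @export
omega_energy <- function(omega, target = "trans", k = 1, flat = OMEGA_FLAT_DEG) {
  stopifnot_finite(omega, "omega")
  t0 <- omega_target_angle(target)
  d <- abs(deg2rad(wrap_angle(omega - t0)))
  f <- deg2rad(flat)
  scale <- pi / (pi - f)
  ifelse(d <= f, 0, k / 2 * (1 - cos((d - f) * scale)))
}

#' Gradient of the omega restraint
#'
#' Analytic `dE/domega` (per radian) of [omega_energy()]; zero inside the
#' flat bottom and at the antipode.
#'
#' @inheritParams omega_energy
#' @return Gradient, kJ/mol/radian.
#' @export
omega_force <- function(omega, target = "trans", k = 1, flat = OMEGA_FLAT_DEG) {
  stopifnot_finite(omega, "omega")
  t0 <- omega_target_angle(target)
  dev <- deg2rad(wrap_angle(omega - t0))
  d <- abs(dev)
  f <- deg2rad(flat)
  scale <- pi / (pi - f)
  ifelse(d <= f, 0, k / 2 * sin((d - f) * scale) * scale * sign(dev))
}
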