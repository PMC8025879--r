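# Export of the restraint potentials as algebraic energy expressions in the
# custom-force dialect used by common MD engines (single expression followed
# by intermediate definitions, separated by semicolons; select/step encode
# the piecewise flat bottom). Together with per-restraint parameters these
# let the restraints be dropped into an external simulation as custom
# bonded forces.

#' Custom-force energy expression for a restraint potential
#'
#' Returns the energy expression string for the requested potential:
#' \describe{
#'   \item{`"distance"`}{the general adaptive flat-bottomed form with
#'     per-bond parameters `k`, `r0`, `tau`, `c`, `alpha` over the bond
#'     length `r`. The generation protocol always produces non-singular
#'     `alpha` (it is `-2 - fall_off * ln(r0)`), so the general branch is
#'     exported.}
#'   \item{`"torsion"`}{the adaptive periodic form with parameters `k`,
#'     `theta0`, `kappa`, `alpha` over the dihedral `theta`.}
#'   \item{`"omega"`}{the flat-bottomed cosine with parameters `k`,
#'     `theta0` (0 or pi for cis/trans) and flat half-width `flat` in
#'     radians.}
#' }
#'
#' @param type `"distance"`, `"torsion"` or `"omega"`.
#' @return A single expression string.
#' @export
openmm_energy_expression <- function(type = c("distance", "torsion", "omega")) {
  type <- match.arg(type)
  switch(type,
    distance = paste(
      "k*(b/alpha)*((x_eff/c)^2/b + 1)^(alpha/2) - k*(b/alpha)",
      "b = abs(alpha - 2)",
      "x_eff = select(step(dr - tau), dr - tau, 0)",
      "dr = abs(r - r0)",
      sep = "; "
    ),
    torsion = paste(
      "k*((1-alpha)*exp(kappa - s)*(1 - exp(kappa*(cos(dtheta) - 1)))/sqrt(s) + alpha*(1 - cos(dtheta)))",
      "s = (sqrt(4*kappa^2 + 1) - 1)/2",
      "dtheta = theta - theta0",
      sep = "; "
    ),
    omega = paste(
      "select(step(adev - flat), 0.5*k*(1 - cos((adev - flat)*pi_w/(pi_w - flat))), 0)",
      "adev = abs(dwrap)",
      "dwrap = dtheta - 2*pi_w*floor(dtheta/(2*pi_w) + 0.5)",
      "dtheta = theta - theta0",
      "pi_w = 3.141592653589793",
      sep = "; "
    )
  )
}
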