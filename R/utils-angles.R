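# Angle bookkeeping. Public interfaces speak degrees; internals use radians.
# Wrapping convention is (-180, 180].

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the canonical interval
#'
#' Maps angles in degrees onto `(-180, 180]` (or, more generally, onto
#' `(-period/2, period/2]`). A reduced period is used for torsions whose
#' terminal atoms are chemically indistinguishable under a 180-degree flip
#' (e.g. the ring flip of Phe/Tyr chi2), where only the minimal equivalent
#' deviation is physically meaningful.
#'
#' @param x Numeric vector of angles in degrees.
#' @param period Wrapping period in degrees (default 360).
#' @return Numeric vector of the same length, wrapped into
#'   `(-period/2, period/2]`.
#' @examples
#' wrap_angle(c(-180, 270, 361))
#' wrap_angle(170, period = 180)
#' @export
wrap_angle <- function(x, period = 360) {
  half <- rep_len(period / 2, length(x))
  y <- (x + half) %% (2 * half) - half
  edge <- y == -half
  y[edge] <- half[edge]
  y
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0("`", what, "` must be finite and non-missing"))
  }
  invisible(x)
}
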