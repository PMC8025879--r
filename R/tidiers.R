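# broom-style tidiers and summary methods.

#' Tidy a settle result
#'
#' @param x A [settle()] result.
#' @param ... Unused.
#' @return The per-step trajectory tibble (`step`, `iterations`, `energy`,
#'   `max_force`).
#' @method tidy settle_result
#' @export
tidy.settle_result <- function(x, ...) x$trajectory

#' One-row summary of a settle result
#'
#' @param x A [settle()] result.
#' @param ... Unused.
#' @return A one-row tibble: initial/final energy, max force, iterations,
#'   convergence flag.
#' @method glance settle_result
#' @export
glance.settle_result <- function(x, ...) {
  tibble(
    initial_energy = x$initial_energy, final_energy = x$final_energy,
    max_force = x$max_force, iterations = x$iterations,
    converged = x$converged
  )
}

restraint_glance <- function(x) {
  tibble(
    n = nrow(x), n_enabled = sum(x$enabled),
    mean_k = mean(x$k)
  )
}

#' One-row summary of a distance restraint set
#'
#' @param x A `distance_restraints` table.
#' @param ... Unused.
#' @return A one-row tibble with counts and parameter ranges.
#' @method glance distance_restraints
#' @export
glance.distance_restraints <- function(x, ...) {
  bind_cols(restraint_glance(x),
            tibble(min_r0 = min(x$r0), max_r0 = max(x$r0),
                   n_groups = dplyr::n_distinct(x$group)))
}

#' One-row summary of a torsion restraint set
#'
#' @param x A `torsion_restraints` table.
#' @param ... Unused.
#' @return A one-row tibble with counts per potential form.
#' @method glance torsion_restraints
#' @export
glance.torsion_restraints <- function(x, ...) {
  bind_cols(restraint_glance(x),
            tibble(n_adaptive = sum(x$form == "adaptive"),
                   n_omega = sum(x$form == "omega")))
}

#' State counts from a classified restraint set
#'
#' @param status Output of [classify_restraints()].
#' @return A tibble of `state`, `n` and `fraction` (over enabled
#'   restraints).
#' @export
summarise_states <- function(status) {
  status |>
    filter(.data$enabled) |>
    dplyr::count(.data$state, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
}
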