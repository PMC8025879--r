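# Restraint management: classification against a structure, selective
# release, parameter adjustment, and the torsion chord score.

resolve_atoms <- function(struct, keys) {
  match(keys, structure_atom_keys(struct))
}

# Display-convention boundary constants (documented, configurable): a
# distance restraint is "beyond the well" once its effective deviation
# exceeds `beyond_c * c`; an adaptive torsion restraint once its wrapped
# deviation exceeds the full well width; the satisfied band for torsions is
# one sixth of the well width.
BEYOND_WELL_C_MULTIPLE <- 2
TORSION_SATISFIED_FRACTION <- 1 / 6

#' Classify restraints against current coordinates
#'
#' Evaluates every restraint in a set against a structure and labels it
#' `satisfied` (inside the zero-force/display band), `strained` (biased but
#' within the well) or `beyond_well` (outside the harmonic/well region,
#' where the top-out potential has begun to flatten and the restraint can no
#' longer pull the model home). Distance restraints: satisfied iff
#' `|d - r0| <= tau`; beyond the well once the effective deviation exceeds
#' `2c`. Torsion restraints: satisfied iff the wrapped deviation is within
#' one sixth of the well width; beyond once it exceeds the full width.
#' Omega restraints: satisfied inside the 30-degree flat bottom; beyond
#' past 90 degrees (the isomer boundary). Restraints whose atoms cannot be
#' resolved are labelled `error` rather than failing the whole set.
#'
#' @param restraints A `distance_restraints` or `torsion_restraints` table.
#' @param struct Structure table providing current coordinates.
#' @return The restraint table with added columns `current`, `deviation`,
#'   `force` (magnitude of the applied gradient) and `state`.
#' @export
classify_restraints <- function(restraints, struct) {
  check_structure(struct)
  if (inherits(restraints, "distance_restraints")) {
    classify_distance(restraints, struct)
  } else if (inherits(restraints, "torsion_restraints")) {
    classify_torsion(restraints, struct)
  } else {
    abort("`restraints` must be a distance_restraints or torsion_restraints table")
  }
}

classify_distance <- function(restraints, struct) {
  out <- restraints
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  i1 <- resolve_atoms(struct, out$atom1)
  i2 <- resolve_atoms(struct, out$atom2)
  ok <- !is.na(i1) & !is.na(i2)
  d <- dev <- eff <- force <- rep(NA_real_, nrow(out))
  if (any(ok)) {
    d[ok] <- measure_distance(xyz[i1[ok], , drop = FALSE], xyz[i2[ok], , drop = FALSE])
    dev[ok] <- d[ok] - out$r0[ok]
    eff[ok] <- pmax(abs(dev[ok]) - out$tau[ok], 0)
    force[ok] <- abs(distance_force(d[ok], out$r0[ok], out$k[ok], out$c[ok],
                                    out$tau[ok], out$alpha[ok]))
  }
  out$current <- d
  out$deviation <- dev
  out$force <- force
  out$state <- dplyr::case_when(
    !ok ~ "error",
    abs(dev) <= out$tau ~ "satisfied",
    eff > BEYOND_WELL_C_MULTIPLE * out$c ~ "beyond_well",
    TRUE ~ "strained"
  )
  out
}

classify_torsion <- function(restraints, struct) {
  out <- restraints
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  idx <- lapply(out[, c("a1", "a2", "a3", "a4")], resolve_atoms, struct = struct)
  ok <- !Reduce(`|`, lapply(idx, is.na))
  cur <- dev <- force <- width <- rep(NA_real_, nrow(out))
  if (any(ok)) {
    cur[ok] <- measure_torsion(
      xyz[idx$a1[ok], , drop = FALSE], xyz[idx$a2[ok], , drop = FALSE],
      xyz[idx$a3[ok], , drop = FALSE], xyz[idx$a4[ok], , drop = FALSE]
    )
  }
  adaptive <- out$form == "adaptive" & ok
  omega <- out$form == "omega" & ok
  dev[ok] <- wrap_angle(cur[ok] - out$theta0[ok],
                        ifelse(is.na(out$period[ok]), 360, out$period[ok]))
  if (any(adaptive)) {
    width[adaptive] <- well_width_from_kappa(out$kappa[adaptive])
    force[adaptive] <- abs(torsion_force_adaptive(
      cur[adaptive], out$theta0[adaptive], out$kappa[adaptive],
      out$k[adaptive], out$alpha[adaptive], out$period[adaptive]
    ))
  }
  if (any(omega)) {
    force[omega] <- abs(omega_force(cur[omega], out$target[omega], out$k[omega]))
  }
  out$current <- cur
  out$deviation <- dev
  out$force <- force
  out$state <- dplyr::case_when(
    !ok ~ "error",
    out$form == "omega" & abs(dev) <= OMEGA_FLAT_DEG ~ "satisfied",
    out$form == "omega" & abs(dev) > 90 ~ "beyond_well",
    out$form == "omega" ~ "strained",
    abs(dev) <= TORSION_SATISFIED_FRACTION * width ~ "satisfied",
    abs(dev) > width ~ "beyond_well",
    TRUE ~ "strained"
  )
  out
}

restraint_atom_match <- function(restraints, atoms) {
  if (!is.character(atoms)) {
    abort("`atoms` selection must be a character vector of atom keys")
  }
  if (inherits(restraints, "distance_restraints")) {
    restraints$atom1 %in% atoms | restraints$atom2 %in% atoms
  } else {
    restraints$a1 %in% atoms | restraints$a2 %in% atoms |
      restraints$a3 %in% atoms | restraints$a4 %in% atoms
  }
}

#' Selectively release (disable) restraints
#'
#' Disables restraints matching a selection, keeping them in the table with
#' `enabled = FALSE` -- the counterpart of pruning obviously-wrong
#' restraints that disagree with the data. With no selection arguments,
#' every restraint is released. Releasing is idempotent.
#'
#' @param restraints Restraint table.
#' @param atoms Optional character vector of atom keys
#'   (`chain|resno|icode|name`); a restraint matches if any of its atoms is
#'   listed.
#' @param deviation_above Optional deviation cutoff (Angstrom or degrees):
#'   restraints whose current absolute deviation exceeds it are released.
#'   Requires `struct`.
#' @param states Optional character vector of classification states to
#'   release (e.g. `"beyond_well"`). Requires `struct`.
#' @param struct Structure supplying current coordinates when needed.
#' @return The modified restraint table (the input is never mutated).
#' @export
release_restraints <- function(restraints, atoms = NULL, deviation_above = NULL,
                               states = NULL, struct = NULL) {
  sel <- rep(TRUE, nrow(restraints))
  any_filter <- FALSE
  if (!is.null(atoms)) {
    sel <- sel & restraint_atom_match(restraints, atoms)
    any_filter <- TRUE
  }
  if (!is.null(deviation_above) || !is.null(states)) {
    if (is.null(struct)) {
      abort("`struct` is required to release by deviation or state")
    }
    st <- classify_restraints(restraints, struct)
    if (!is.null(deviation_above)) {
      sel <- sel & !is.na(st$deviation) & abs(st$deviation) > deviation_above
    }
    if (!is.null(states)) sel <- sel & st$state %in% states
    any_filter <- TRUE
  }
  if (!any_filter) sel <- rep(TRUE, nrow(restraints))
  restraints$enabled[sel] <- FALSE
  restraints
}

#' Adjust restraint parameters in place
#'
#' Recomputes the parameters of selected restraints from new protocol-level
#' values; targets (`r0`, `theta0`) are never silently altered. For distance
#' restraints, `tolerance`, `fall_off` and `well_half_width` re-derive
#' `tau`, `alpha` and `c` from each restraint's own `r0` via the generation
#' formulas; `kappa` sets the energy scale `k` directly. For torsion
#' restraints, `spring_constant` sets `k`, `angle_range` re-derives the
#' well-shape `kappa`, and `alpha` sets the fall-off (adaptive rows only).
#' Values are validated before any mutation.
#'
#' @inheritParams release_restraints
#' @param kappa,tolerance,fall_off,well_half_width New distance-restraint
#'   protocol values (NULL = leave unchanged).
#' @param spring_constant,angle_range,alpha New torsion-restraint values.
#' @return The modified restraint table.
#' @export
adjust_restraints <- function(restraints, atoms = NULL, kappa = NULL,
                              tolerance = NULL, fall_off = NULL,
                              well_half_width = NULL, spring_constant = NULL,
                              angle_range = NULL, alpha = NULL) {
  sel <- if (is.null(atoms)) rep(TRUE, nrow(restraints)) else {
    restraint_atom_match(restraints, atoms)
  }
  if (!is.null(kappa)) {
    stopifnot_finite(kappa, "kappa")
    if (kappa < 0) abort("`kappa` must be non-negative")
  }
  if (!is.null(tolerance)) {
    stopifnot_finite(tolerance, "tolerance")
    if (tolerance < 0) abort("`tolerance` must be non-negative")
  }
  if (!is.null(fall_off)) stopifnot_finite(fall_off, "fall_off")
  if (!is.null(well_half_width)) {
    stopifnot_finite(well_half_width, "well_half_width")
    if (well_half_width <= 0) abort("`well_half_width` must be positive")
  }
  if (!is.null(spring_constant)) {
    stopifnot_finite(spring_constant, "spring_constant")
    if (spring_constant < 0) abort("`spring_constant` must be non-negative")
  }
  if (!is.null(angle_range)) {
    stopifnot_finite(angle_range, "angle_range")
    if (angle_range <= 0 || angle_range >= 180) {
      abort("`angle_range` must lie strictly between 0 and 180 degrees")
    }
  }
  if (!is.null(alpha)) stopifnot_finite(alpha, "alpha")

  if (inherits(restraints, "distance_restraints")) {
    if (!is.null(kappa)) restraints$k[sel] <- kappa
    if (!is.null(tolerance)) restraints$tau[sel] <- tolerance * restraints$r0[sel]
    if (!is.null(fall_off)) {
      restraints$alpha[sel] <- -2 - fall_off * log(restraints$r0[sel])
    }
    if (!is.null(well_half_width)) {
      restraints$c[sel] <- well_half_width * restraints$r0[sel]
    }
  } else if (inherits(restraints, "torsion_restraints")) {
    adaptive <- sel & restraints$form == "adaptive"
    if (!is.null(spring_constant)) restraints$k[sel] <- spring_constant
    if (!is.null(angle_range)) {
      restraints$kappa[adaptive] <- kappa_from_well_width(angle_range)
    }
    if (!is.null(alpha)) restraints$alpha[adaptive] <- alpha
  } else {
    abort("`restraints` must be a distance_restraints or torsion_restraints table")
  }
  restraints
}

chord_term <- function(delta_deg, form) {
  d <- deg2rad(delta_deg)
  switch(form,
    half_chord_sq = sin(d / 2)^2,
    chord = 2 * abs(sin(d / 2)),
    abort('`form` must be "half_chord_sq" or "chord"')
  )
}

#' Per-residue torsion chord score
#'
#' Model-comparison score built from unit-circle chord lengths of torsion
#' deviations between two structures: for each comparable torsion the term
#' is `sin^2(delta/2)` (default; calibrated so that a uniform 45-degree
#' deviation scores just under 0.15, the conventional "incorrect residue"
#' threshold) or the raw chord `2 sin(|delta|/2)` with `form = "chord"`.
#' Backbone mode averages over phi, psi and omega; side-chain mode over
#' chi1 and chi2, optionally weighted (e.g. by burial). Torsions missing in
#' either structure are excluded from the average; residues with no
#' comparable torsion get `NA`.
#'
#' @param model,reference Structure tables; residues are matched by chain,
#'   residue number and insertion code.
#' @param mode `"backbone"` or `"sidechain"`.
#' @param form Chord functional form (see above).
#' @param weights Optional named weights for side-chain torsions, e.g.
#'   `c(chi1 = 2, chi2 = 1)`; default unweighted.
#' @param threshold Score above which a residue is flagged `incorrect`
#'   (default 0.15).
#' @return A tibble with one row per matched residue: `chain`, `resno`,
#'   `icode`, `resname`, `n_torsions`, `score`, `incorrect`.
#' @export
chord_score <- function(model, reference, mode = c("backbone", "sidechain"),
                        form = c("half_chord_sq", "chord"), weights = NULL,
                        threshold = 0.15) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  grab <- function(struct) {
    if (mode == "backbone") {
      backbone_torsions(struct) |>
        tidyr::pivot_longer(c("phi", "psi", "omega"),
                            names_to = "torsion", values_to = "value") |>
        mutate(period = 360)
    } else {
      sidechain_torsions(struct) |>
        filter(.data$chi <= 2) |>
        mutate(torsion = paste0("chi", .data$chi)) |>
        select("chain", "resno", "icode", "resname", "torsion", "value", "period")
    }
  }
  m <- grab(model)
  r <- grab(reference) |> select("chain", "resno", "icode", "torsion",
                                 ref_value = "value")
  joined <- inner_join(m, r, by = c("chain", "resno", "icode", "torsion")) |>
    filter(!is.na(.data$value), !is.na(.data$ref_value))
  if (nrow(joined) == 0) abort("no comparable torsions between the two structures")
  w <- if (is.null(weights)) NULL else weights
  joined <- joined |>
    mutate(
      delta = wrap_angle(.data$value - .data$ref_value, .data$period),
      term = chord_term(.data$delta, form),
      w = if (is.null(w)) 1 else dplyr::coalesce(unname(w[.data$torsion]), 1)
    )
  scored <- joined |>
    group_by(.data$chain, .data$resno, .data$icode, .data$resname) |>
    summarise(
      n_torsions = dplyr::n(),
      score = sum(.data$w * .data$term) / sum(.data$w),
      .groups = "drop"
    ) |>
    mutate(incorrect = .data$score > threshold)
  res <- residue_table(model) |> filter(.data$polymer == "protein")
  res |>
    select("chain", "resno", "icode", "resname") |>
    left_join(scored, by = c("chain", "resno", "icode", "resname"))
}
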