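# Reference-restraint generation: the distance-restraint protocol
# (pairing -> rigid groups -> per-group atom-pair enumeration with
# distance-dependent parameters) and torsion-restraint assignment.

#' Restraint-generation options
#'
#' Bundles every tunable of the generation protocol with its default.
#' Distance restraints: `kappa` is the energy scale k (kJ/mol; default 5,
#' not to be confused with the torsion well-shape parameter), and the
#' remaining terms set the per-restraint parameters as functions of the
#' template distance r0, on the reasoning that longer distances are
#' inherently less certain: flat bottom `tau = tolerance * r0` (default
#' tolerance 0.025), harmonic half-width `c = well_half_width * r0` (default
#' 0.05), fall-off `alpha = -2 - fall_off * ln(r0)` (default fall_off 4,
#' placing the loss between Geman-McClure and Welsch for typical
#' distances). Candidate pairs come from template atoms within
#' `distance_cutoff` (default 8 Angstrom); rigid bodies are accepted within
#' `rigid_tolerance` (default 5 Angstrom). Torsion restraints: well width
#' `angle_range` (default 60 degrees), `spring_constant` (default 250
#' kJ/mol) and fall-off `torsion_alpha` (default 0.3).
#'
#' @param kappa Distance-restraint energy scale k, kJ/mol.
#' @param tolerance Flat-bottom fraction of r0.
#' @param fall_off Distance fall-off rate (enters alpha).
#' @param well_half_width Harmonic half-width fraction of r0.
#' @param distance_cutoff Template-distance cutoff, Angstrom.
#' @param rigid_tolerance Rigid-body residual tolerance, Angstrom.
#' @param custom_atom_names Extra atom names eligible for distance
#'   restraints besides the built-in sparse set.
#' @param restrain_interfaces Restrain atom pairs across different (model)
#'   chains.
#' @param angle_range Torsion well width Delta-theta0, degrees.
#' @param spring_constant Torsion spring constant k, kJ/mol.
#' @param torsion_alpha Torsion fall-off parameter.
#' @param restrain_backbone,restrain_sidechain Toggle phi/psi/omega and chi
#'   restraints.
#' @return A named list of options (class `"restraint_options"`).
#' @export
restraint_options <- function(kappa = 5, tolerance = 0.025, fall_off = 4,
                              well_half_width = 0.05, distance_cutoff = 8,
                              rigid_tolerance = 5,
                              custom_atom_names = character(),
                              restrain_interfaces = FALSE,
                              angle_range = 60, spring_constant = 250,
                              torsion_alpha = 0.3,
                              restrain_backbone = TRUE,
                              restrain_sidechain = TRUE) {
  opts <- list(
    kappa = kappa, tolerance = tolerance, fall_off = fall_off,
    well_half_width = well_half_width, distance_cutoff = distance_cutoff,
    rigid_tolerance = rigid_tolerance,
    custom_atom_names = as.character(custom_atom_names),
    restrain_interfaces = isTRUE(restrain_interfaces),
    angle_range = angle_range, spring_constant = spring_constant,
    torsion_alpha = torsion_alpha,
    restrain_backbone = isTRUE(restrain_backbone),
    restrain_sidechain = isTRUE(restrain_sidechain)
  )
  num <- c("kappa", "tolerance", "fall_off", "well_half_width",
           "distance_cutoff", "rigid_tolerance", "angle_range",
           "spring_constant", "torsion_alpha")
  for (f in num) stopifnot_finite(opts[[f]], f)
  if (opts$kappa < 0 || opts$spring_constant < 0) {
    abort("energy scales must be non-negative")
  }
  if (opts$tolerance < 0 || opts$well_half_width <= 0 ||
      opts$distance_cutoff <= 0 || opts$rigid_tolerance <= 0) {
    abort("tolerances, widths and cutoffs must be positive")
  }
  if (opts$angle_range <= 0 || opts$angle_range >= 180) {
    abort("`angle_range` must lie strictly between 0 and 180 degrees")
  }
  structure(opts, class = "restraint_options")
}

empty_distance_restraints <- function() {
  out <- tibble(
    atom1 = character(), atom2 = character(), group = integer(),
    r0 = numeric(), k = numeric(), tau = numeric(), c = numeric(),
    alpha = numeric(), enabled = logical()
  )
  class(out) <- c("distance_restraints", class(out))
  out
}

empty_torsion_restraints <- function() {
  out <- tibble(
    res_key = character(), resname = character(), label = character(),
    form = character(), a1 = character(), a2 = character(), a3 = character(),
    a4 = character(), theta0 = numeric(), kappa = numeric(), k = numeric(),
    alpha = numeric(), period = numeric(), target = character(),
    enabled = logical()
  )
  class(out) <- c("torsion_restraints", class(out))
  out
}

# Eligible (restrainable) atoms for one rigid group: named atoms present in
# BOTH paired residues, from the default sparse set plus any custom names.
eligible_atoms <- function(model, template, pairings, custom = character()) {
  allowed <- unique(c(RESTRAINED_ATOMS_PROTEIN, RESTRAINED_ATOMS_NUCLEIC, custom))
  mres <- residue_table(model)
  tres <- residue_table(template)
  matoms <- model |>
    mutate(res_key = structure_residue_keys(model),
           key = structure_atom_keys(model)) |>
    filter(.data$atom %in% allowed) |>
    select("res_key", "atom", "key", "chain")
  tatoms <- template |>
    mutate(res_key = structure_residue_keys(template),
           key = structure_atom_keys(template)) |>
    filter(.data$atom %in% allowed) |>
    select("res_key", "atom", tkey = "key", tx = "x", ty = "y", tz = "z")
  pairings |>
    mutate(pair_id = row_number()) |>
    inner_join(matoms, by = c(model_key = "res_key"),
               relationship = "one-to-many") |>
    inner_join(tatoms, by = c(template_key = "res_key", atom = "atom")) |>
    select("pair_id", "model_key", "atom", "key", "chain",
           "tkey", "tx", "ty", "tz", "group")
}

#' Generate adaptive distance restraints from a template
#'
#' Implements the full distance-restraint protocol: residues are paired by
#' sequence alignment ([pair_residues()]), pseudo-rigid bodies detected
#' ([find_rigid_groups()]), and for every eligible template atom pair within
#' the cutoff -- different residues, same rigid group, and (unless
#' `restrain_interfaces`) the same model chain -- one restraint is emitted
#' on the corresponding model atom pair, with target `r0` equal to the
#' template distance and parameters `k = kappa`, `tau = tolerance * r0`,
#' `c = well_half_width * r0`, `alpha = -2 - fall_off * ln(r0)`.
#'
#' Restrainable atoms are the built-in sparse set (CA, CB, CG, CG1, OG, OG1
#' for protein; key base/ribose/phosphate atoms for nucleic acids) plus
#' `custom_atom_names`, and must be present in both residues of a pairing.
#' Cross-group pairs are never restrained: each rigid group was fitted
#' independently, so inter-group template distances are not meaningful in
#' the model frame.
#'
#' @param model Structure table to be restrained.
#' @param template Reference structure; defaults to `model` itself
#'   (self-restraint).
#' @param options A [restraint_options()] list.
#' @param pairings Optional precomputed pairing table with a `group` column
#'   (from [find_rigid_groups()]); computed when omitted.
#' @return A `distance_restraints` tibble: model atom keys (`atom1`,
#'   `atom2`, format `chain|resno|icode|name`), rigid `group`, parameters
#'   `r0`, `k`, `tau`, `c`, `alpha`, and an `enabled` flag.
#' @export
generate_distance_restraints <- function(model, template = NULL,
                                         options = restraint_options(),
                                         pairings = NULL) {
  check_structure(model)
  template <- template %||% model
  check_structure(template)
  if (is.null(pairings)) {
    pairings <- pair_residues(model, template)
    if (nrow(pairings) == 0) return(empty_distance_restraints())
    pairings <- find_rigid_groups(pairings, model, template,
                                  tolerance = options$rigid_tolerance)
  }
  if (!"group" %in% names(pairings)) {
    pairings <- find_rigid_groups(pairings, model, template,
                                  tolerance = options$rigid_tolerance)
  }
  pairings <- pairings |> filter(!is.na(.data$group))
  if (nrow(pairings) == 0) {
    warn("no pairings in any rigid group; no distance restraints generated")
    return(empty_distance_restraints())
  }
  atoms <- eligible_atoms(model, template, pairings, options$custom_atom_names)
  out <- list()
  for (g in sort(unique(atoms$group))) {
    ga <- atoms |> filter(.data$group == g)
    if (nrow(ga) < 2) next
    txyz <- as.matrix(ga[, c("tx", "ty", "tz")])
    dmat <- as.matrix(stats::dist(txyz))
    pair <- which(upper.tri(dmat) & dmat <= options$distance_cutoff,
                  arr.ind = TRUE)
    if (nrow(pair) == 0) next
    i <- pair[, 1]; j <- pair[, 2]
    keep <- ga$model_key[i] != ga$model_key[j]
    if (!options$restrain_interfaces) {
      keep <- keep & ga$chain[i] == ga$chain[j]
    }
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0) next
    r0 <- dmat[cbind(i, j)]
    out[[as.character(g)]] <- tibble(
      atom1 = pmin(ga$key[i], ga$key[j]),
      atom2 = pmax(ga$key[i], ga$key[j]),
      group = as.integer(g),
      r0 = r0,
      k = options$kappa,
      tau = options$tolerance * r0,
      c = options$well_half_width * r0,
      alpha = -2 - options$fall_off * log(r0),
      enabled = TRUE
    )
  }
  if (length(out) == 0) {
    warn("no template atom pairs within the cutoff; no distance restraints generated")
    return(empty_distance_restraints())
  }
  res <- bind_rows(out) |>
    distinct(.data$atom1, .data$atom2, .keep_all = TRUE) |>
    arrange(.data$atom1, .data$atom2)
  class(res) <- c("distance_restraints", class(res))
  res
}

#' Generate adaptive torsion restraints from a template
#'
#' Pairs residues by sequence alignment and, for each pairing, restrains the
#' model's backbone torsions (phi, psi) to the template values with the
#' adaptive periodic potential (`kappa` from
#' [kappa_from_well_width()]`(angle_range)`, `k = spring_constant`,
#' `alpha = torsion_alpha`), and -- for identical residues only -- the chi
#' torsions defined in both structures. Peptide omega dihedrals are instead
#' held to the template's cis/trans isomeric state by the flat-bottomed
#' cosine form ([omega_energy()]); where the template has a cis-proline but
#' the model residue is not proline, the omega target is the model's own
#' current isomer. Torsions undefined at chain termini are skipped.
#'
#' Only protein residues are supported; pairings of nucleic-acid residues
#' raise an error.
#'
#' @inheritParams generate_distance_restraints
#' @return A `torsion_restraints` tibble: owning residue, torsion `label`
#'   (phi/psi/omega/chi1..chi4), potential `form` (`"adaptive"` or
#'   `"omega"`), the four model atom keys, parameters (`theta0`, `kappa`,
#'   `k`, `alpha`, `period`, omega `target`), and an `enabled` flag.
#' @export
generate_torsion_restraints <- function(model, template = NULL,
                                        options = restraint_options(),
                                        pairings = NULL) {
  check_structure(model)
  template <- template %||% model
  check_structure(template)
  pairings <- pairings %||% pair_residues(model, template)
  if (nrow(pairings) == 0) return(empty_torsion_restraints())
  if (any(pairings$polymer == "nucleic")) {
    abort("torsion restraints are not supported for nucleic-acid residues")
  }
  mt <- torsion_table(model)
  tt <- torsion_table(template)
  joined <- pairings |>
    inner_join(mt |> select("res_key", "label", "a1", "a2", "a3", "a4",
                            "period", "value"),
               by = c(model_key = "res_key"), relationship = "one-to-many") |>
    inner_join(tt |> select("res_key", "label", template_value = "value"),
               by = c(template_key = "res_key", label = "label"))
  if (nrow(joined) == 0) return(empty_torsion_restraints())
  kap <- kappa_from_well_width(options$angle_range)

  backbone <- joined |> filter(.data$label %in% c("phi", "psi"))
  if (!options$restrain_backbone) backbone <- backbone[0, ]
  chis <- joined |> filter(grepl("^chi", .data$label), .data$identical)
  if (!options$restrain_sidechain) chis <- chis[0, ]
  adaptive <- bind_rows(backbone, chis)
  out <- list()
  if (nrow(adaptive) > 0) {
    out$adaptive <- adaptive |>
      mutate(
        form = "adaptive", theta0 = wrap_angle(.data$template_value),
        kappa = kap, k = options$spring_constant,
        alpha = options$torsion_alpha, target = NA_character_,
        enabled = TRUE
      )
  }
  omg <- joined |> filter(.data$label == "omega")
  if (options$restrain_backbone && nrow(omg) > 0) {
    template_state <- ifelse(abs(wrap_angle(omg$template_value)) < 90, "cis", "trans")
    model_state <- ifelse(abs(wrap_angle(omg$value)) < 90, "cis", "trans")
    cispro_exception <- template_state == "cis" &
      omg$template_resname == "PRO" & omg$model_resname != "PRO"
    out$omega <- omg |>
      mutate(
        form = "omega",
        target = ifelse(cispro_exception, model_state, template_state),
        theta0 = ifelse(.data$target == "cis", 0, 180),
        kappa = NA_real_, k = options$spring_constant, alpha = NA_real_,
        enabled = TRUE
      )
  }
  if (length(out) == 0) return(empty_torsion_restraints())
  res <- bind_rows(out) |>
    rename(res_key = "model_key", resname = "model_resname") |>
    select("res_key", "resname", "label", "form", "a1", "a2", "a3", "a4",
           "theta0", "kappa", "k", "alpha", "period", "target", "enabled") |>
    arrange(.data$res_key, .data$label)
  class(res) <- c("torsion_restraints", class(res))
  res
}
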