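# Total restraint energy/forces and the coordinate relaxer.
#
# The relaxer minimises the summed restraint energy (optionally plus a
# soft-sphere clash term) with chunked L-BFGS-B using the analytic
# gradient. It is a deliberately simple, deterministic stand-in for settling
# a model by simulated-annealing molecular dynamics: it makes
# restraint-driven recovery testable, and claims no equivalence with a
# force-field simulation.

normalise_restraint_sets <- function(restraints) {
  if (inherits(restraints, "distance_restraints") ||
      inherits(restraints, "torsion_restraints")) {
    restraints <- list(restraints)
  }
  if (!is.list(restraints)) abort("`restraints` must be a restraint table or a list of them")
  restraints
}

# Idealised covalent geometry of the protein backbone/CB/gamma atoms, used
# by the optional stereochemistry regulariser in settle(). The reference
# restraints are deliberately sparse (no peptide-bond atoms) because in an
# interactive MD setting the force field maintains covalent geometry; a
# pure-restraint minimiser has no such term, so without this regulariser
# the peptide-bond atoms would simply keep whatever distortion they start
# with. Atoms without a dictionary entry get no stereo terms.
STEREO_BONDS <- list(
  c("N", "CA", BOND_N_CA), c("CA", "C", BOND_CA_C), c("CA", "CB", BOND_CA_CB),
  c("C", "O", 1.231)
)
STEREO_ANGLES <- list(
  c("N", "CA", "C", ANGLE_N_CA_C), c("N", "CA", "CB", 110.33),
  c("C", "CA", "CB", ANGLE_C_CA_CB), c("CA", "C", "O", 120.8)
)

stereo_terms <- function(struct) {
  keys <- structure_atom_keys(struct)
  res <- residue_table(struct) |> filter(.data$polymer == "protein")
  bonds <- list(); angles <- list()
  idx_of <- function(i, name) {
    match(atom_key(res$chain[i], res$resno[i], res$icode[i], name), keys)
  }
  add_bond <- function(i, j, b0) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <<- c(i, j, b0)
  }
  add_angle <- function(i, j, k, a0) {
    if (!is.na(i) && !is.na(j) && !is.na(k)) {
      angles[[length(angles) + 1]] <<- c(i, j, k, a0)
    }
  }
  n <- nrow(res)
  for (i in seq_len(n)) {
    at <- function(name) idx_of(i, name)
    for (b in STEREO_BONDS) add_bond(at(b[1]), at(b[2]), as.numeric(b[3]))
    g <- GAMMA_ATOM[res$resname[i]]
    if (!is.na(g)) {
      elem <- substr(g, 1, 1)
      gb <- GAMMA_BOND[[if (elem %in% names(GAMMA_BOND)) elem else "C"]]
      add_bond(at("CB"), at(g), gb)
      add_angle(at("CA"), at("CB"), at(g), ANGLE_CA_CB_G)
    }
    for (a in STEREO_ANGLES) {
      add_angle(at(a[1]), at(a[2]), at(a[3]), as.numeric(a[4]))
    }
    if (i < n && res$chain[i + 1] == res$chain[i]) {
      nn <- idx_of(i + 1, "N")
      add_bond(at("C"), nn, BOND_C_N)
      add_angle(at("CA"), at("C"), nn, ANGLE_CA_C_N)
      add_angle(at("O"), at("C"), nn, 123.0)
      add_angle(at("C"), nn, idx_of(i + 1, "CA"), ANGLE_C_N_CA)
    }
  }
  list(
    bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
    angles = if (length(angles)) do.call(rbind, angles) else NULL
  )
}

# theta and gradients of the i-j-k bond angle (radians).
angle_gradient <- function(u, v) {
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  uh <- u / nu; vh <- v / nv
  cth <- pmin(pmax(rowSums(uh * vh), -1), 1)
  sth <- pmax(sqrt(1 - cth^2), 1e-8)
  gi <- (uh * cth - vh) / (nu * sth)
  gk <- (vh * cth - uh) / (nv * sth)
  list(theta = acos(cth), gi = gi, gk = gk)
}

# Precompiles a restraint network against a structure: resolves atom keys
# to row indices once and returns an evaluator xyz -> list(energy, grad).
prepare_energy <- function(struct, restraints, clash = FALSE,
                           clash_scale = 0.8, clash_k = 10,
                           stereo = FALSE, stereo_k_bond = 2000,
                           stereo_k_angle = 200) {
  sets <- normalise_restraint_sets(restraints)
  keys <- structure_atom_keys(struct)
  n <- nrow(struct)
  dist_parts <- list(); tors_parts <- list()
  for (set in sets) {
    enabled <- set[set$enabled, , drop = FALSE]
    if (nrow(enabled) == 0) next
    if (inherits(set, "distance_restraints")) {
      i1 <- match(enabled$atom1, keys); i2 <- match(enabled$atom2, keys)
      missing <- unique(c(enabled$atom1[is.na(i1)], enabled$atom2[is.na(i2)]))
      if (length(missing) > 0) {
        abort(paste("restrained atoms not in structure:",
                    paste(head(missing, 5), collapse = ", ")))
      }
      dist_parts[[length(dist_parts) + 1]] <- list(i1 = i1, i2 = i2, p = enabled)
    } else if (inherits(set, "torsion_restraints")) {
      idx <- lapply(enabled[, c("a1", "a2", "a3", "a4")], match, table = keys)
      bad <- Reduce(`|`, lapply(idx, is.na))
      if (any(bad)) {
        miss <- unlist(enabled[bad, c("a1", "a2", "a3", "a4")])
        miss <- miss[!miss %in% keys]
        abort(paste("restrained atoms not in structure:",
                    paste(head(unique(miss), 5), collapse = ", ")))
      }
      tors_parts[[length(tors_parts) + 1]] <- list(idx = idx, p = enabled)
    } else {
      abort("unknown restraint set type")
    }
  }
  clash_pairs <- NULL
  if (clash) {
    xyz0 <- as.matrix(struct[, c("x", "y", "z")])
    radii <- VDW_RADII[struct$element]
    radii[is.na(radii)] <- 1.7
    dmat <- as.matrix(stats::dist(xyz0))
    d0 <- clash_scale * outer(radii, radii, "+")
    rk <- structure_residue_keys(struct)
    same_res <- outer(rk, rk, "==")
    adjacent <- outer(struct$chain, struct$chain, "==") &
      abs(outer(struct$resno, struct$resno, "-")) <= 1
    cand <- which(upper.tri(dmat) & dmat < d0 + 1.5 & !same_res & !adjacent,
                  arr.ind = TRUE)
    if (nrow(cand) > 0) {
      clash_pairs <- list(i = cand[, 1], j = cand[, 2],
                          d0 = d0[cand], k = clash_k)
    }
  }
  stereo_tab <- if (stereo) stereo_terms(struct) else NULL
  function(xyz) {
    energy <- 0
    grad <- matrix(0, n, 3)
    acc_idx <- list(); acc_g <- list()
    if (!is.null(stereo_tab)) {
      bt <- stereo_tab$bonds
      if (!is.null(bt)) {
        dv <- xyz[bt[, 1], , drop = FALSE] - xyz[bt[, 2], , drop = FALSE]
        d <- sqrt(rowSums(dv^2))
        dev <- d - bt[, 3]
        energy <- energy + sum(0.5 * stereo_k_bond * dev^2)
        g <- dv / pmax(d, 1e-8) * (stereo_k_bond * dev)
        acc_idx <- c(acc_idx, list(bt[, 1], bt[, 2]))
        acc_g <- c(acc_g, list(g, -g))
      }
      at <- stereo_tab$angles
      if (!is.null(at)) {
        u <- xyz[at[, 1], , drop = FALSE] - xyz[at[, 2], , drop = FALSE]
        v <- xyz[at[, 3], , drop = FALSE] - xyz[at[, 2], , drop = FALSE]
        ag <- angle_gradient(u, v)
        dev <- ag$theta - deg2rad(at[, 4])
        energy <- energy + sum(0.5 * stereo_k_angle * dev^2)
        coef <- stereo_k_angle * dev
        gi <- ag$gi * coef; gk <- ag$gk * coef
        acc_idx <- c(acc_idx, list(at[, 1], at[, 3], at[, 2]))
        acc_g <- c(acc_g, list(gi, gk, -(gi + gk)))
      }
    }
    for (dp in dist_parts) {
      p1 <- xyz[dp$i1, , drop = FALSE]; p2 <- xyz[dp$i2, , drop = FALSE]
      dv <- p1 - p2
      d <- sqrt(rowSums(dv^2))
      energy <- energy + sum(distance_energy(d, dp$p$r0, dp$p$k, dp$p$c,
                                             dp$p$tau, dp$p$alpha))
      dEdd <- distance_force(d, dp$p$r0, dp$p$k, dp$p$c, dp$p$tau, dp$p$alpha)
      ok <- d > 1e-8
      unit <- dv * 0
      unit[ok, ] <- dv[ok, , drop = FALSE] / d[ok]
      g <- unit * dEdd
      acc_idx <- c(acc_idx, list(dp$i1, dp$i2))
      acc_g <- c(acc_g, list(g, -g))
    }
    for (tp in tors_parts) {
      ps <- lapply(tp$idx, function(i) xyz[i, , drop = FALSE])
      theta <- measure_torsion(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
      p <- tp$p
      adaptive <- p$form == "adaptive"
      e <- dEdt <- numeric(nrow(p))
      if (any(adaptive)) {
        e[adaptive] <- torsion_energy_adaptive(
          theta[adaptive], p$theta0[adaptive], p$kappa[adaptive],
          p$k[adaptive], p$alpha[adaptive], p$period[adaptive])
        dEdt[adaptive] <- torsion_force_adaptive(
          theta[adaptive], p$theta0[adaptive], p$kappa[adaptive],
          p$k[adaptive], p$alpha[adaptive], p$period[adaptive])
      }
      if (any(!adaptive)) {
        e[!adaptive] <- omega_energy(theta[!adaptive], p$target[!adaptive],
                                     p$k[!adaptive])
        dEdt[!adaptive] <- omega_force(theta[!adaptive], p$target[!adaptive],
                                       p$k[!adaptive])
      }
      energy <- energy + sum(e)
      tg <- torsion_gradient(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
      for (s in 1:4) {
        acc_idx <- c(acc_idx, list(tp$idx[[s]]))
        acc_g <- c(acc_g, list(tg[[s]] * dEdt))
      }
    }
    if (!is.null(clash_pairs)) {
      cp <- clash_pairs
      dv <- xyz[cp$i, , drop = FALSE] - xyz[cp$j, , drop = FALSE]
      d <- sqrt(rowSums(dv^2))
      viol <- d < cp$d0 & d > 1e-8
      if (any(viol)) {
        u <- (1 - d[viol] / cp$d0[viol])
        energy <- energy + sum(cp$k * u^4)
        dEdd <- -4 * cp$k * u^3 / cp$d0[viol]
        g <- dv[viol, , drop = FALSE] / d[viol] * dEdd
        acc_idx <- c(acc_idx, list(cp$i[viol], cp$j[viol]))
        acc_g <- c(acc_g, list(g, -g))
      }
    }
    if (length(acc_idx) > 0) {
      all_idx <- unlist(acc_idx)
      all_g <- do.call(rbind, acc_g)
      agg <- rowsum(all_g, group = all_idx)
      rows <- as.integer(rownames(agg))
      grad[rows, ] <- grad[rows, ] + agg
    }
    list(energy = energy, grad = grad)
  }
}

#' Total restraint energy and per-atom forces
#'
#' Sums the energies of every enabled restraint in one or more restraint
#' sets over the current coordinates and returns the exact analytic
#' per-atom forces (the negative gradient of the total energy).
#'
#' @param struct Structure table.
#' @param restraints A restraint table or a list of restraint tables
#'   (distance and torsion sets may be mixed).
#' @param clash Add a soft-sphere clash term: quartic repulsion
#'   `k (1 - d/d0)^4` below the scaled van der Waals contact distance
#'   `d0` (default off, so restraint behaviour is testable in isolation).
#' @param clash_scale Contact-distance scale factor.
#' @param clash_k Clash energy scale, kJ/mol.
#' @return A list with `energy` (kJ/mol) and `forces` (n x 3 matrix,
#'   kJ/mol/Angstrom).
#' @export
total_energy_and_forces <- function(struct, restraints, clash = FALSE,
                                    clash_scale = 0.8, clash_k = 10) {
  check_structure(struct)
  ev <- prepare_energy(struct, restraints, clash, clash_scale, clash_k)
  res <- ev(as.matrix(struct[, c("x", "y", "z")]))
  list(energy = res$energy, forces = -res$grad)
}

#' Relaxer options
#'
#' @param max_iter Maximum total minimiser iterations.
#' @param ftol Convergence threshold on the maximum per-atom force
#'   component, kJ/mol/Angstrom.
#' @param chunk Minimiser iterations per recorded trajectory step.
#' @param clash,clash_scale,clash_k Soft-sphere clash term (see
#'   [total_energy_and_forces()]).
#' @param stereo Add a stereochemistry regulariser: harmonic terms holding
#'   backbone/CB/gamma bond lengths and angles at their ideal dictionary
#'   values (default on). This stands in for the covalent terms of the
#'   force field that reference restraints normally operate alongside --
#'   the sparse restraint network deliberately carries no peptide-bond
#'   atoms, so without it those atoms would keep whatever distortion they
#'   start with.
#' @param stereo_k_bond,stereo_k_angle Regulariser force constants,
#'   kJ/mol/Angstrom^2 and kJ/mol/rad^2.
#' @param jitter SD of an optional seeded Gaussian kick applied to the
#'   starting coordinates, Angstrom (0 = none).
#' @param seed Seed for the jitter.
#' @return Options list for [settle()].
#' @export
settle_options <- function(max_iter = 2000, ftol = 0.01, chunk = 100,
                           clash = FALSE, clash_scale = 0.8, clash_k = 10,
                           stereo = TRUE, stereo_k_bond = 2000,
                           stereo_k_angle = 200, jitter = 0, seed = 1) {
  if (ftol <= 0 || max_iter < 1 || chunk < 1) {
    abort("`ftol` must be positive and iteration counts at least 1")
  }
  list(max_iter = as.integer(max_iter), ftol = ftol, chunk = as.integer(chunk),
       clash = isTRUE(clash), clash_scale = clash_scale, clash_k = clash_k,
       stereo = isTRUE(stereo), stereo_k_bond = stereo_k_bond,
       stereo_k_angle = stereo_k_angle,
       jitter = jitter, seed = seed)
}

#' Settle a model under its restraints
#'
#' Relaxes the coordinates of a structure to a local minimum of the total
#' restraint energy by chunked L-BFGS-B minimisation with analytic
#' gradients. The energy recorded at each trajectory step is non-increasing;
#' the run stops once the largest per-atom force component drops below
#' `ftol`, the energy stops improving, or `max_iter` is exhausted. The
#' input structure is returned unmodified inside a new result object.
#'
#' @param struct Structure table.
#' @param restraints Restraint table or list of restraint tables.
#' @param options A [settle_options()] list.
#' @return An object of class `"settle_result"`: list with `structure`
#'   (relaxed coordinates), `trajectory` (tibble of step, iterations,
#'   energy, max force), `initial_energy`, `final_energy`, `max_force`,
#'   `converged`, `iterations`.
#' @export
settle <- function(struct, restraints, options = settle_options()) {
  check_structure(struct)
  ev <- prepare_energy(struct, restraints, options$clash,
                       options$clash_scale, options$clash_k,
                       stereo = options$stereo,
                       stereo_k_bond = options$stereo_k_bond,
                       stereo_k_angle = options$stereo_k_angle)
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  if (options$jitter > 0) {
    with_seed(options$seed, {
      xyz <- xyz + rnorm(length(xyz), 0, options$jitter)
    })
  }
  shape <- dim(xyz)
  fn <- function(par) ev(matrix(par, shape[1], shape[2]))$energy
  gr <- function(par) as.numeric(ev(matrix(par, shape[1], shape[2]))$grad)
  cur <- as.numeric(xyz)
  state <- ev(matrix(cur, shape[1], shape[2]))
  if (!is.finite(state$energy)) {
    abort("restraint energy is non-finite at the starting coordinates")
  }
  energy <- state$energy
  max_force <- max(abs(state$grad))
  traj <- list(tibble(step = 0L, iterations = 0L, energy = energy,
                      max_force = max_force))
  iters <- 0L
  step <- 0L
  converged <- max_force <= options$ftol
  while (!converged && iters < options$max_iter) {
    budget <- min(options$chunk, options$max_iter - iters)
    fit <- stats::optim(cur, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = budget, factr = 10))
    if (!is.finite(fit$value)) {
      abort("energy diverged (non-finite) during settling")
    }
    improved <- fit$value < energy
    if (improved) {
      cur <- fit$par
      energy <- fit$value
    }
    iters <- iters + budget
    step <- step + 1L
    g <- ev(matrix(cur, shape[1], shape[2]))$grad
    max_force <- max(abs(g))
    traj[[length(traj) + 1]] <- tibble(step = step, iterations = iters,
                                       energy = energy, max_force = max_force)
    converged <- max_force <= options$ftol
    if (!improved) break
  }
  out <- struct
  relaxed <- matrix(cur, shape[1], shape[2])
  out$x <- relaxed[, 1]; out$y <- relaxed[, 2]; out$z <- relaxed[, 3]
  structure(
    list(structure = out, trajectory = bind_rows(traj),
         initial_energy = traj[[1]]$energy, final_energy = energy,
         max_force = max_force, converged = converged, iterations = iters),
    class = "settle_result"
  )
}

#' @export
print.settle_result <- function(x, ...) {
  cat("Settle result:", x$iterations, "iterations,",
      if (x$converged) "converged" else "not converged", "\n")
  cat(sprintf("  energy %.6g -> %.6g kJ/mol, max |force| %.3g kJ/mol/A\n",
              x$initial_energy, x$final_energy, x$max_force))
  invisible(x)
}
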