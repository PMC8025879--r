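# Deterministic toy-structure generator.
#
# Builds ideal-geometry peptides (helix, strand or dipeptide) from internal
# coordinates, carrying the heavy atoms that participate in restraint
# generation and torsion measurement: N, CA, C, CB and the gamma atom of
# each residue. Standard bond lengths/angles; backbone torsions are set
# exactly, so the generator doubles as its own torsion oracle.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_CA_CB <- 1.521
ANGLE_C_N_CA <- 121.7
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_CA_CB <- 110.1
ANGLE_CA_CB_G <- 113.5
IMPROPER_N_C_CA_CB <- -122.6

GAMMA_BOND <- c(C = 1.52, O = 1.42, S = 1.81)

IDEAL_TORSIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135),
  dipeptide = c(phi = -57, psi = -47)
)

DEFAULT_SEQ_POOL <- "ALVKDSTIFEQNM"

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a deterministic toy peptide
#'
#' Constructs an ideal-geometry polypeptide from internal coordinates:
#' an alpha-helix (phi = -57, psi = -47), a beta-strand (phi = -139,
#' psi = 135) or a dipeptide. Each residue carries N, CA, C, CB (except
#' glycine) and its gamma heavy atom where the residue has one, i.e. the
#' atoms that drive distance-restraint generation and backbone/chi1 torsion
#' measurement. Optional seeded perturbations: per-coordinate Gaussian noise
#' and/or Gaussian kicks to the backbone torsions.
#'
#' The construction is exactly deterministic given `(kind, length, sequence,
#' seed)` and the measured backbone torsions of the unperturbed structure
#' equal the set values to numerical precision.
#'
#' @param kind `"helix"`, `"strand"` or `"dipeptide"`.
#' @param length Number of residues (default 10; a dipeptide is always 2).
#' @param sequence One-letter amino-acid codes (string or vector); recycled
#'   from a built-in pool when omitted.
#' @param chain Chain identifier.
#' @param seed Integer seed for the perturbations.
#' @param noise_sd Per-coordinate Gaussian noise, Angstrom (0 = none).
#' @param torsion_jitter SD of Gaussian kicks on phi/psi, degrees (0 = none).
#' @param phi,psi Optional explicit backbone torsions (recycled per residue),
#'   overriding the `kind` defaults.
#' @param omega Peptide omega dihedral(s), degrees (recycled; default all
#'   trans). `omega[i]` is the dihedral preceding residue `i`; the first
#'   element is unused.
#' @param chi1 chi1 torsion used for gamma-atom placement, degrees.
#' @return A structure table (see [read_structure()]).
#' @examples
#' helix <- build_toy_structure("helix", length = 10)
#' backbone_torsions(helix)
#' @export
build_toy_structure <- function(kind = c("helix", "strand", "dipeptide"),
                                length = 10, sequence = NULL, chain = "A",
                                seed = 1, noise_sd = 0, torsion_jitter = 0,
                                phi = NULL, psi = NULL, omega = 180,
                                chi1 = -65) {
  kind <- match.arg(kind)
  if (kind == "dipeptide") length <- 2L
  length <- as.integer(length)
  if (length < 1) abort("`length` must be >= 1")
  if (is.null(sequence)) {
    pool <- strsplit(DEFAULT_SEQ_POOL, "")[[1]]
    sequence <- rep_len(pool, length)
  } else {
    if (is.character(sequence) && length(sequence) == 1 && nchar(sequence) > 1) {
      sequence <- strsplit(sequence, "")[[1]]
    }
    if (base::length(sequence) != length) {
      abort("`sequence` length must match `length`")
    }
  }
  bad <- setdiff(toupper(sequence), names(AA1))
  if (length(bad) > 0) abort(paste("unknown residue code(s):", paste(bad, collapse = ", ")))
  resnames <- unname(AA1[toupper(sequence)])

  tor <- IDEAL_TORSIONS[[kind]]
  phi <- rep_len(phi %||% tor[["phi"]], length)
  psi <- rep_len(psi %||% tor[["psi"]], length)
  omega <- rep_len(omega, length)
  chi1 <- rep_len(chi1, length)
  if (torsion_jitter > 0) {
    with_seed(seed, {
      phi <- phi + rnorm(length, 0, torsion_jitter)
      psi <- psi + rnorm(length, 0, torsion_jitter)
    })
  }

  rows <- list()
  add <- function(i, name, xyz) {
    rows[[length(rows) + 1]] <<- list(resno = i, resname = resnames[i],
                                      atom = name, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  n_prev <- ca_prev <- c_prev <- NULL
  for (i in seq_len(length)) {
    if (i == 1) {
      n_i <- c(0, 0, 0)
      ca_i <- c(BOND_N_CA, 0, 0)
      th <- deg2rad(ANGLE_N_CA_C)
      c_i <- ca_i + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)
    } else {
      n_i <- place_atom(n_prev, ca_prev, c_prev, BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      ca_i <- place_atom(ca_prev, c_prev, n_i, BOND_N_CA, ANGLE_C_N_CA, omega[i])
      c_i <- place_atom(c_prev, n_i, ca_i, BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    add(i, "N", n_i); add(i, "CA", ca_i); add(i, "C", c_i)
    if (resnames[i] != "GLY") {
      cb <- place_atom(n_i, c_i, ca_i, BOND_CA_CB, ANGLE_C_CA_CB, IMPROPER_N_C_CA_CB)
      add(i, "CB", cb)
      g <- GAMMA_ATOM[resnames[i]]
      if (!is.na(g)) {
        elem <- substr(g, 1, 1)
        gb <- GAMMA_BOND[[if (elem %in% names(GAMMA_BOND)) elem else "C"]]
        add(i, g, place_atom(n_i, ca_i, cb, gb, ANGLE_CA_CB_G, chi1[i]))
      }
    }
    n_prev <- n_i; ca_prev <- ca_i; c_prev <- c_i
  }
  tab <- bind_rows(lapply(rows, as_tibble))
  out <- new_structure(
    chain = chain, resno = tab$resno, icode = "", resname = tab$resname,
    atom = tab$atom, x = tab$x, y = tab$y, z = tab$z,
    title = paste0("toy ", kind)
  )
  if (noise_sd > 0) out <- perturb_structure(out, noise_sd, seed = seed)
  out
}

#' Add seeded Gaussian coordinate noise to a structure
#'
#' @param struct Structure table.
#' @param sigma Per-coordinate standard deviation, Angstrom.
#' @param seed Integer seed.
#' @return The perturbed structure table.
#' @export
perturb_structure <- function(struct, sigma, seed = 1) {
  check_structure(struct)
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (sigma == 0) return(struct)
  n <- nrow(struct)
  with_seed(seed, {
    struct$x <- struct$x + rnorm(n, 0, sigma)
    struct$y <- struct$y + rnorm(n, 0, sigma)
    struct$z <- struct$z + rnorm(n, 0, sigma)
  })
  struct
}
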