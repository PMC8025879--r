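# Tidy structure tables and PDB/mmCIF I/O.
#
# A structure is an ordinary tibble with one row per atom and columns
#   chain, resno, icode, resname, polymer, atom, element, x, y, z
# in file order. Residues are identified by (chain, resno, icode); atom
# names are unique within a residue. Hydrogens are dropped on read
# (restraints act on heavy atoms only).

STRUCT_COLS <- c("chain", "resno", "icode", "resname", "polymer",
                 "atom", "element", "x", "y", "z")

atom_key <- function(chain, resno, icode, atom) {
  paste(chain, resno, icode, atom, sep = "|")
}

residue_key <- function(chain, resno, icode) {
  paste(chain, resno, icode, sep = "|")
}

structure_atom_keys <- function(struct) {
  atom_key(struct$chain, struct$resno, struct$icode, struct$atom)
}

structure_residue_keys <- function(struct) {
  residue_key(struct$chain, struct$resno, struct$icode)
}

check_structure <- function(struct) {
  if (!all(STRUCT_COLS %in% names(struct))) {
    abort(paste("a structure table needs columns:", paste(STRUCT_COLS, collapse = ", ")))
  }
  if (nrow(struct) == 0) abort("structure table is empty")
  keys <- structure_atom_keys(struct)
  if (anyDuplicated(keys)) {
    abort(paste("duplicate atoms in structure:", keys[duplicated(keys)][1]))
  }
  stopifnot_finite(struct$x, "x"); stopifnot_finite(struct$y, "y")
  stopifnot_finite(struct$z, "z")
  invisible(struct)
}

# One row per residue, in file order.
residue_table <- function(struct) {
  struct |>
    mutate(.key = structure_residue_keys(struct), .row = row_number()) |>
    group_by(.data$.key) |>
    summarise(
      chain = .data$chain[1], resno = .data$resno[1], icode = .data$icode[1],
      resname = .data$resname[1], polymer = .data$polymer[1],
      .order = min(.data$.row), .groups = "drop"
    ) |>
    arrange(.data$.order) |>
    select(key = ".key", "chain", "resno", "icode", "resname", "polymer")
}

new_structure <- function(chain, resno, icode, resname, atom, x, y, z,
                          element = NULL, title = "") {
  out <- tibble(
    chain = as.character(chain), resno = as.integer(resno),
    icode = as.character(icode), resname = as.character(resname),
    polymer = polymer_class(as.character(resname)),
    atom = as.character(atom),
    element = element %||% element_from_name(as.character(atom)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  attr(out, "title") <- title
  check_structure(out)
  out
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into a tidy atom table (one row per heavy atom;
#' hydrogens and deuteriums are dropped). Alternate locations are resolved
#' to the highest-occupancy conformer (ties keep the first altloc code).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`. PDB is the
#'   canonical round-trip format; mmCIF support is read-only.
#' @return A tibble with columns `chain`, `resno`, `icode`, `resname`,
#'   `polymer`, `atom`, `element`, `x`, `y`, `z`.
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse ", path, ": ", conditionMessage(e)))
  )
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste("no atoms in", path))
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at <- at |>
    filter(!(.data$elesy %in% c("H", "D"))) |>
    mutate(.k = atom_key(.data$chain, .data$resno, .data$insert, .data$elety)) |>
    group_by(.data$.k) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$eleno)
  if (nrow(at) == 0) abort(paste("no heavy atoms in", path))
  new_structure(
    chain = at$chain, resno = at$resno, icode = at$insert,
    resname = at$resid, atom = at$elety, x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     element_from_name(at$elety), at$elesy),
    title = basename(path)
  )
}

#' Write a structure to PDB
#'
#' Writes ATOM/HETATM records (with TER records between chains, handled by
#' `bio3d`). Coordinates are stored at the PDB precision of 3 decimals.
#'
#' @param struct Structure table.
#' @param path Output file path.
#' @return The input `struct`, invisibly.
#' @export
write_structure <- function(struct, path) {
  check_structure(struct)
  xyz <- as.numeric(t(as.matrix(struct[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(struct$polymer == "other", "HETATM", "ATOM"),
    resno = struct$resno, resid = struct$resname,
    eleno = seq_len(nrow(struct)), elety = struct$atom,
    chain = ifelse(struct$chain == "", " ", struct$chain),
    insert = ifelse(struct$icode == "", "", struct$icode),
    elesy = struct$element
  )
  invisible(struct)
}
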