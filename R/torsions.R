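# Backbone and side-chain torsion measurement.
#
# Conventions: phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1);
# omega(i) = CA(i-1)-C(i-1)-N(i)-CA(i), i.e. the peptide dihedral ending at
# this residue's N. chi torsions follow the IUPAC quadruples in the built-in
# dictionary. Undefined angles (chain termini, missing atoms) are absent
# from the long table and NA in the wide tables.

# Long table of every defined torsion with its atom keys.
torsion_table <- function(struct, backbone = TRUE, sidechain = TRUE) {
  check_structure(struct)
  res <- residue_table(struct) |> filter(.data$polymer == "protein")
  empty <- tibble(
    res_key = character(), chain = character(), resno = integer(),
    icode = character(), resname = character(), label = character(),
    a1 = character(), a2 = character(), a3 = character(), a4 = character(),
    period = numeric(), value = numeric()
  )
  if (nrow(res) == 0) return(empty)
  akey <- function(i, name) atom_key(res$chain[i], res$resno[i], res$icode[i], name)
  rows <- list()
  if (backbone) {
    n <- nrow(res)
    i <- seq_len(n)
    same_chain_prev <- c(FALSE, res$chain[-1] == res$chain[-n])
    same_chain_next <- c(res$chain[-n] == res$chain[-1], FALSE)
    prev <- i - 1L; nxt <- i + 1L
    phi <- tibble(
      res_key = res$key, chain = res$chain, resno = res$resno,
      icode = res$icode, resname = res$resname, label = "phi",
      a1 = ifelse(same_chain_prev, akey(pmax(prev, 1L), "C"), NA),
      a2 = akey(i, "N"), a3 = akey(i, "CA"), a4 = akey(i, "C"),
      period = 360
    )
    psi <- tibble(
      res_key = res$key, chain = res$chain, resno = res$resno,
      icode = res$icode, resname = res$resname, label = "psi",
      a1 = akey(i, "N"), a2 = akey(i, "CA"), a3 = akey(i, "C"),
      a4 = ifelse(same_chain_next, akey(pmin(nxt, n), "N"), NA),
      period = 360
    )
    omg <- tibble(
      res_key = res$key, chain = res$chain, resno = res$resno,
      icode = res$icode, resname = res$resname, label = "omega",
      a1 = ifelse(same_chain_prev, akey(pmax(prev, 1L), "CA"), NA),
      a2 = ifelse(same_chain_prev, akey(pmax(prev, 1L), "C"), NA),
      a3 = akey(i, "N"), a4 = akey(i, "CA"),
      period = 360
    )
    rows <- c(rows, list(phi, psi, omg))
  }
  if (sidechain) {
    chi <- inner_join(
      res |> rename(res_key = "key"),
      chi_definitions(), by = "resname", relationship = "many-to-many"
    )
    if (nrow(chi) > 0) {
      chi <- chi |>
        mutate(
          label = paste0("chi", .data$chi),
          a1 = atom_key(.data$chain, .data$resno, .data$icode, .data$a1),
          a2 = atom_key(.data$chain, .data$resno, .data$icode, .data$a2),
          a3 = atom_key(.data$chain, .data$resno, .data$icode, .data$a3),
          a4 = atom_key(.data$chain, .data$resno, .data$icode, .data$a4)
        ) |>
        select("res_key", "chain", "resno", "icode", "resname", "label",
               "a1", "a2", "a3", "a4", "period")
      rows <- c(rows, list(chi))
    }
  }
  if (length(rows) == 0) return(empty)
  tab <- bind_rows(rows)
  keys <- structure_atom_keys(struct)
  idx <- function(a) match(a, keys)
  i1 <- idx(tab$a1); i2 <- idx(tab$a2); i3 <- idx(tab$a3); i4 <- idx(tab$a4)
  ok <- !is.na(i1) & !is.na(i2) & !is.na(i3) & !is.na(i4)
  tab <- tab[ok, ]
  if (nrow(tab) == 0) return(empty)
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  tab$value <- measure_torsion(xyz[i1[ok], , drop = FALSE], xyz[i2[ok], , drop = FALSE],
                               xyz[i3[ok], , drop = FALSE], xyz[i4[ok], , drop = FALSE])
  res_order <- match(tab$res_key, res$key)
  tab[order(res_order, tab$label), ]
}

#' Backbone torsions per residue
#'
#' Computes phi, psi and omega for every protein residue. Angles undefined
#' at chain termini are `NA`. The omega reported for residue *i* is the
#' peptide dihedral CA(i-1)-C(i-1)-N(i)-CA(i), i.e. the bond *preceding*
#' the residue.
#'
#' @param struct Structure table.
#' @return A tibble with one row per protein residue and columns `chain`,
#'   `resno`, `icode`, `resname`, `phi`, `psi`, `omega` (degrees).
#' @export
backbone_torsions <- function(struct) {
  tab <- torsion_table(struct, backbone = TRUE, sidechain = FALSE)
  res <- residue_table(struct) |> filter(.data$polymer == "protein")
  if (nrow(res) == 0) abort("no protein residues in structure")
  wide <- tab |>
    select("res_key", "label", "value") |>
    tidyr::pivot_wider(names_from = "label", values_from = "value")
  for (col in c("phi", "psi", "omega")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  res |>
    left_join(wide, by = c(key = "res_key")) |>
    select("chain", "resno", "icode", "resname", "phi", "psi", "omega")
}

#' Side-chain chi torsions per residue
#'
#' Computes every chi torsion defined by the built-in dictionary whose four
#' atoms are present. Torsions with a two-fold symmetric terminus (Asp chi2,
#' Glu chi3, Phe/Tyr chi2) are flagged with `period = 180`.
#'
#' @param struct Structure table.
#' @return A long tibble with columns `chain`, `resno`, `icode`, `resname`,
#'   `chi` (integer), `value` (degrees) and `period`.
#' @export
sidechain_torsions <- function(struct) {
  tab <- torsion_table(struct, backbone = FALSE, sidechain = TRUE)
  tab |>
    mutate(chi = as.integer(sub("chi", "", .data$label))) |>
    select("chain", "resno", "icode", "resname", "chi", "value", "period")
}
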