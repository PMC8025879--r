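# Built-in residue and atom dictionaries.

AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1 <- setNames(names(AA3), AA3)

NUC_RES <- c(A = "A", C = "C", G = "G", U = "U", DA = "A", DC = "C",
             DG = "G", DT = "T", DU = "U", T = "T")

#' Polymer class of a residue name
#'
#' @param resname Character vector of 3-letter (protein) or 1-2 letter
#'   (nucleic) residue codes.
#' @return `"protein"`, `"nucleic"` or `"other"` per element.
#' @export
polymer_class <- function(resname) {
  dplyr::case_when(
    resname %in% names(AA3) ~ "protein",
    resname %in% names(NUC_RES) ~ "nucleic",
    TRUE ~ "other"
  )
}

# Default restrainable atom names: a deliberately sparse set that excludes
# the peptide-bond atoms (left to torsion restraints / the force field) and
# side-chain atoms beyond the gamma position.
RESTRAINED_ATOMS_PROTEIN <- c("CA", "CB", "CG", "CG1", "OG", "OG1")
RESTRAINED_ATOMS_NUCLEIC <- c("OP1", "OP2", "C4'", "C2'", "O2", "O4", "N4",
                              "N2", "O6", "N1", "N6", "N9")

PRINCIPAL_ATOM <- c(protein = "CA", nucleic = "C4'")

# Gamma-position heavy atom per residue (terminus of chi1); used both by the
# toy-structure builder and the chi dictionary.
GAMMA_ATOM <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# chi torsion atom quadruples (IUPAC). Entries give the moving terminal atom
# of each chi; the quadruple is (prev2, prev1, axis atoms). period = 180
# marks torsions with two-fold symmetric termini.
chi_definitions <- function() {
  def <- list(
    # resname, chi, a1, a2, a3, a4, period
    c("ARG", 1, "N", "CA", "CB", "CG", 360), c("ARG", 2, "CA", "CB", "CG", "CD", 360),
    c("ARG", 3, "CB", "CG", "CD", "NE", 360), c("ARG", 4, "CG", "CD", "NE", "CZ", 360),
    c("ASN", 1, "N", "CA", "CB", "CG", 360), c("ASN", 2, "CA", "CB", "CG", "OD1", 360),
    c("ASP", 1, "N", "CA", "CB", "CG", 360), c("ASP", 2, "CA", "CB", "CG", "OD1", 180),
    c("CYS", 1, "N", "CA", "CB", "SG", 360),
    c("GLN", 1, "N", "CA", "CB", "CG", 360), c("GLN", 2, "CA", "CB", "CG", "CD", 360),
    c("GLN", 3, "CB", "CG", "CD", "OE1", 360),
    c("GLU", 1, "N", "CA", "CB", "CG", 360), c("GLU", 2, "CA", "CB", "CG", "CD", 360),
    c("GLU", 3, "CB", "CG", "CD", "OE1", 180),
    c("HIS", 1, "N", "CA", "CB", "CG", 360), c("HIS", 2, "CA", "CB", "CG", "ND1", 360),
    c("ILE", 1, "N", "CA", "CB", "CG1", 360), c("ILE", 2, "CA", "CB", "CG1", "CD1", 360),
    c("LEU", 1, "N", "CA", "CB", "CG", 360), c("LEU", 2, "CA", "CB", "CG", "CD1", 360),
    c("LYS", 1, "N", "CA", "CB", "CG", 360), c("LYS", 2, "CA", "CB", "CG", "CD", 360),
    c("LYS", 3, "CB", "CG", "CD", "CE", 360), c("LYS", 4, "CG", "CD", "CE", "NZ", 360),
    c("MET", 1, "N", "CA", "CB", "CG", 360), c("MET", 2, "CA", "CB", "CG", "SD", 360),
    c("MET", 3, "CB", "CG", "SD", "CE", 360),
    c("PHE", 1, "N", "CA", "CB", "CG", 360), c("PHE", 2, "CA", "CB", "CG", "CD1", 180),
    c("PRO", 1, "N", "CA", "CB", "CG", 360), c("PRO", 2, "CA", "CB", "CG", "CD", 360),
    c("SER", 1, "N", "CA", "CB", "OG", 360),
    c("THR", 1, "N", "CA", "CB", "OG1", 360),
    c("TRP", 1, "N", "CA", "CB", "CG", 360), c("TRP", 2, "CA", "CB", "CG", "CD1", 360),
    c("TYR", 1, "N", "CA", "CB", "CG", 360), c("TYR", 2, "CA", "CB", "CG", "CD1", 180),
    c("VAL", 1, "N", "CA", "CB", "CG1", 360)
  )
  m <- do.call(rbind, def)
  tibble(
    resname = m[, 1], chi = as.integer(m[, 2]),
    a1 = m[, 3], a2 = m[, 4], a3 = m[, 5], a4 = m[, 6],
    period = as.numeric(m[, 7])
  )
}

# Approximate van der Waals radii (Angstrom) for the optional soft-sphere
# clash term.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

element_from_name <- function(atom) {
  e <- substr(gsub("[^A-Za-z].*$", "", atom), 1, 1)
  ifelse(e %in% names(VDW_RADII), e, "C")
}
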