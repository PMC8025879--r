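# Residue pairing by global sequence alignment and iterative
# pseudo-rigid-body detection.

structure_class_sequence <- function(res) {
  if (res$polymer[1] == "protein") {
    paste(ifelse(res$resname %in% names(AA3), AA3[res$resname], "X"), collapse = "")
  } else {
    paste(ifelse(res$resname %in% names(NUC_RES), NUC_RES[res$resname], "N"),
          collapse = "")
  }
}

align_indices <- function(seq1, seq2, class) {
  if (class == "protein") {
    mat <- "BLOSUM62"
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq1), Biostrings::AAString(seq2),
      type = "global", substitutionMatrix = mat,
      gapOpening = 12, gapExtension = 1
    )
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = FALSE)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(chartr("U", "T", seq1)),
      Biostrings::DNAString(chartr("U", "T", seq2)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 8, gapExtension = 1
    )
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ip <- cumsum(p != "-")
  is <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  cbind(model = ip[keep], template = is[keep])
}

#' Pair residues of a model with a template
#'
#' Concatenates the polymer residues of each structure into per-class
#' super-sequences (protein and nucleic acid separately) and aligns them
#' globally (Needleman-Wunsch: BLOSUM62 with gap open/extend 12/1 for
#' protein, +5/-4 with 8/1 for nucleic acids). Aligned residue pairs become
#' pairing records; residues that do not align are simply absent and will
#' not be restrained. Protein residues only ever pair with protein residues,
#' nucleic with nucleic.
#'
#' @param model,template Structure tables. `template` defaults to the model
#'   itself (self-restraint).
#' @return A tibble with one row per pairing: residue keys and names on both
#'   sides, the polymer class, and `identical` (same residue name).
#' @export
pair_residues <- function(model, template = NULL) {
  check_structure(model)
  template <- template %||% model
  check_structure(template)
  mres <- residue_table(model) |> filter(.data$polymer != "other")
  tres <- residue_table(template) |> filter(.data$polymer != "other")
  if (nrow(mres) == 0 || nrow(tres) == 0) {
    abort("selection contains no polymer residues")
  }
  out <- list()
  for (cls in intersect(unique(mres$polymer), unique(tres$polymer))) {
    m <- mres |> filter(.data$polymer == cls)
    t <- tres |> filter(.data$polymer == cls)
    idx <- align_indices(structure_class_sequence(m), structure_class_sequence(t), cls)
    if (nrow(idx) == 0) next
    out[[cls]] <- tibble(
      model_key = m$key[idx[, "model"]],
      template_key = t$key[idx[, "template"]],
      model_resname = m$resname[idx[, "model"]],
      template_resname = t$resname[idx[, "template"]],
      model_chain = m$chain[idx[, "model"]],
      polymer = cls,
      identical = m$resname[idx[, "model"]] == t$resname[idx[, "template"]]
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    warn("no residues could be aligned; nothing will be restrained")
    res <- tibble(
      model_key = character(), template_key = character(),
      model_resname = character(), template_resname = character(),
      model_chain = character(), polymer = character(), identical = logical()
    )
  }
  res
}

principal_coords <- function(struct, keys) {
  res <- residue_table(struct)
  info <- res[match(keys, res$key), ]
  pa <- unname(PRINCIPAL_ATOM[info$polymer])
  akeys <- atom_key(info$chain, info$resno, info$icode, pa)
  idx <- match(akeys, structure_atom_keys(struct))
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  out <- matrix(NA_real_, length(keys), 3)
  ok <- !is.na(idx)
  out[ok, ] <- xyz[idx[ok], , drop = FALSE]
  out
}

#' Find pseudo-rigid bodies among paired residues
#'
#' Iterative superpose-and-trim search for groups of residue pairings whose
#' principal atoms (CA for protein, C4' for nucleic acids) superpose within
#' a residual tolerance. Each round least-squares fits the remaining
#' template principal atoms onto their model counterparts and drops the
#' worst 10% of pairs until every member is within tolerance; trimmed pairs
#' seed the search for the next group. The iteration stops when fewer than
#' three pairings remain (a rigid body needs at least three points).
#'
#' @param pairings Pairing table from [pair_residues()].
#' @param model,template The structures the pairings refer to.
#' @param tolerance Maximum allowed per-residue superposition residual,
#'   Angstrom (default 5).
#' @return The pairing table with an added integer `group` column (`NA` for
#'   pairings in no rigid group). Attribute `"transforms"` holds one row per
#'   group: rotation (list of 3x3 matrices), translation, member count and
#'   maximum residual.
#' @export
find_rigid_groups <- function(pairings, model, template = NULL, tolerance = 5) {
  template <- template %||% model
  if (tolerance <= 0) abort("`tolerance` must be positive")
  pairings$group <- NA_integer_
  pm <- principal_coords(model, pairings$model_key)
  pt <- principal_coords(template, pairings$template_key)
  usable <- which(stats::complete.cases(pm) & stats::complete.cases(pt))
  transforms <- list()
  if (length(usable) < 3) {
    warn("fewer than 3 usable pairings; no rigid groups found")
  } else {
    remaining <- usable
    gid <- 0L
    while (length(remaining) >= 3) {
      sel <- remaining
      fit <- NULL
      repeat {
        fit <- kabsch(pt[sel, , drop = FALSE], pm[sel, , drop = FALSE])
        if (max(fit$residuals) <= tolerance) break
        ndrop <- max(1L, ceiling(0.1 * length(sel)))
        worst <- order(fit$residuals, decreasing = TRUE)[seq_len(ndrop)]
        sel <- sel[-worst]
        if (length(sel) < 3) { fit <- NULL; break }
      }
      if (is.null(fit)) break
      gid <- gid + 1L
      pairings$group[sel] <- gid
      transforms[[gid]] <- tibble(
        group = gid, n = length(sel), max_residual = max(fit$residuals),
        rotation = list(fit$rotation), translation = list(fit$translation)
      )
      remaining <- setdiff(remaining, sel)
    }
  }
  attr(pairings, "transforms") <- bind_rows(transforms)
  pairings
}
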