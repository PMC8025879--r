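# Versioned JSON restraint files and TSV reports.

RESTRAINT_SCHEMA <- "restraintr/1"

split_atom_key <- function(key, prefix) {
  parts <- do.call(rbind, strsplit(key, "|", fixed = TRUE))
  out <- tibble(
    chain = parts[, 1], resno = as.integer(parts[, 2]),
    icode = parts[, 3], name = parts[, 4]
  )
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Write a restraint set to a versioned JSON file
#'
#' Atoms are listed by chain, residue number, insertion code and atom name;
#' parameters are stored per restraint. The write is atomic (temp file plus
#' rename).
#'
#' @param restraints Restraint table.
#' @param path Output path.
#' @param provenance Optional named list recorded verbatim (e.g. generation
#'   options, input file names).
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path, provenance = list()) {
  kind <- if (inherits(restraints, "distance_restraints")) "distance"
          else if (inherits(restraints, "torsion_restraints")) "torsion"
          else abort("`restraints` must be a restraint table")
  payload <- list(
    schema = RESTRAINT_SCHEMA,
    kind = kind,
    provenance = provenance,
    restraints = as.data.frame(restraints)
  )
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a restraint set from JSON
#'
#' @param path Path to a file written by [write_restraints()].
#' @return The restraint table with its class restored.
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, RESTRAINT_SCHEMA)) {
    abort(paste("unsupported restraint schema:",
                payload$schema %||% "<missing>"))
  }
  out <- as_tibble(payload$restraints)
  if (identical(payload$kind, "distance")) {
    out$group <- as.integer(out$group)
    class(out) <- c("distance_restraints", class(out))
  } else if (identical(payload$kind, "torsion")) {
    if (!"target" %in% names(out)) out$target <- NA_character_
    out$target <- as.character(out$target)
    out$kappa <- as.numeric(out$kappa)
    out$alpha <- as.numeric(out$alpha)
    class(out) <- c("torsion_restraints", class(out))
  } else {
    abort(paste("unknown restraint kind:", payload$kind))
  }
  out
}

#' Write a per-restraint TSV summary
#'
#' One row per restraint with readable atom fields; when `struct` is given
#' the classification columns (current value, deviation, force, state) are
#' included.
#'
#' @param restraints Restraint table.
#' @param path Output path.
#' @param struct Optional structure for classification.
#' @return `path`, invisibly.
#' @export
write_restraint_summary <- function(restraints, path, struct = NULL) {
  tab <- if (is.null(struct)) restraints else classify_restraints(restraints, struct)
  flat <- if (inherits(restraints, "distance_restraints")) {
    bind_cols(split_atom_key(tab$atom1, "atom1"), split_atom_key(tab$atom2, "atom2"),
              tab |> select(-"atom1", -"atom2"))
  } else {
    bind_cols(tab |> select("res_key", "resname", "label", "form"),
              split_atom_key(tab$a1, "a1"), split_atom_key(tab$a4, "a4"),
              tab |> select(-"res_key", -"resname", -"label", -"form",
                            -"a1", -"a2", -"a3", -"a4"))
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv.tmp")
  write.table(as.data.frame(flat), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
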