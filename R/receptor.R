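#' Read a receptor structure from a PDB file
#'
#' Retains all `ATOM` records with their chain/residue metadata; `HETATM`
#' records are retained too but flagged via the `is_het` column. For atoms
#' with alternate locations, only the first conformer encountered is kept
#' (the drop is reported with a message). Coordinates are Angstrom, as
#' stored.
#'
#' @param path Path to a PDB file.
#' @param structure_id Identity stored in the `structure_id` attribute;
#'   defaults to the file name without extension.
#' @return A tibble with one row per atom: `record`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_number`, `x`, `y`, `z`,
#'   `element`, `is_het`.
#' @export
read_receptor_pdb <- function(path, structure_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  structure_id <- structure_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines))) {
    abort(paste0("no ATOM records in ", path, ": not a PDB structure?"))
  }
  parsed <- parse_atom_lines(lines[is_atom], which(is_atom), path)
  rec <- tibble(
    record = parsed$record,
    atom_name = parsed$atom_name,
    altloc = parsed$altloc,
    residue_name = parsed$residue_name,
    chain_id = parsed$chain_id,
    residue_number = parsed$residue_number,
    x = parsed$x, y = parsed$y, z = parsed$z,
    element = parsed$element,
    is_het = parsed$record == "HETATM"
  )
  if (any(is.na(rec$residue_number))) {
    abort(paste0("missing residue number in ATOM record of ", path))
  }

  # altLoc rule: keep the first conformer of each
  # (chain, residue, atom name) group, drop the rest
  alt <- rec$altloc != " " & rec$altloc != ""
  if (any(alt)) {
    key <- paste(rec$chain_id, rec$residue_number, rec$atom_name)
    keep <- !alt | !duplicated(key)
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      inform(paste0("dropped ", n_drop,
                    " alternate-location conformer(s); first kept"))
    }
    rec <- rec[keep, ]
  }
  rec$altloc <- NULL

  grp <- paste(rec$chain_id, rec$residue_number)
  if (any(duplicated(rle(grp)$values))) {
    abort(paste0("residue records are not contiguous in ", path))
  }
  structure(rec, structure_id = structure_id)
}

#' Write a receptor structure as PDB text
#'
#' Serializes a receptor tibble (as returned by [read_receptor_pdb()] or
#' [make_toy_receptor()]) into standard fixed-column PDB records.
#'
#' @param receptor Receptor atom tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  stopifnot(nrow(receptor) > 0)
  name4 <- ifelse(nchar(receptor$atom_name) < 4,
                  sprintf(" %-3s", receptor$atom_name),
                  receptor$atom_name)
  lines <- sprintf(
    "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    receptor$record, seq_len(nrow(receptor)), name4,
    receptor$residue_name, receptor$chain_id, receptor$residue_number,
    receptor$x, receptor$y, receptor$z, 1.00, 0.00,
    toupper(receptor$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
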