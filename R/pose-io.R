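#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# One docked conformation set is represented as a "pose table": a tibble
# with one row per atom and columns
#   ligand_id  chr   ligand / file identity
#   pose_id    int   1-based order within the source file
#   energy     dbl   docking binding energy, kcal/mol (repeated per atom row)
#   atom_name  chr
#   element    chr
#   x, y, z    dbl   Angstrom, as stored (no recentering on read)

pose_table_cols <- c("ligand_id", "pose_id", "energy",
                     "atom_name", "element", "x", "y", "z")

#' Validate a pose ensemble
#'
#' Checks the pose-table contract: at least one pose, finite energies and
#' coordinates, unique strictly increasing `pose_id` within each ligand, and
#' (unless `check_atoms = FALSE`) an identical atom count and atom-name
#' sequence across all poses of a ligand — docked poses of one ligand are
#' conformers of the same molecule, so anything else indicates a corrupt or
#' mixed input file.
#'
#' @param poses A pose table (see [read_pose_table()] for the column layout).
#' @param check_atoms If `FALSE`, skip the identical-atom-sequence check
#'   (documented override for deliberately heterogeneous pools).
#' @return `poses`, invisibly, after validation; errors otherwise.
#' @export
validate_pose_ensemble <- function(poses, check_atoms = TRUE) {
  missing_cols <- setdiff(pose_table_cols, names(poses))
  if (length(missing_cols) > 0) {
    abort(paste0("pose table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(poses) == 0) abort("no poses: pose table is empty")
  if (!all(is.finite(poses$energy))) abort("non-finite pose energy")
  if (!all(is.finite(poses$x) & is.finite(poses$y) & is.finite(poses$z))) {
    abort("non-finite atom coordinate")
  }

  by_ligand <- split(poses, poses$ligand_id)
  for (lig in by_ligand) {
    ids <- rle(lig$pose_id)$values
    if (any(duplicated(ids)) || is.unsorted(ids, strictly = TRUE)) {
      # rows of one pose must be contiguous and pose ids strictly increasing
      abort(paste0("ligand '", lig$ligand_id[1],
                   "': pose_id values must be unique and strictly increasing"))
    }
    per_pose <- lapply(split(lig$atom_name, lig$pose_id), paste, collapse = "|")
    en <- vapply(split(lig$energy, lig$pose_id),
                 function(e) length(unique(e)), integer(1))
    if (any(en != 1L)) {
      abort(paste0("ligand '", lig$ligand_id[1],
                   "': conflicting energies within a single pose"))
    }
    if (check_atoms && length(unique(unlist(per_pose))) > 1L) {
      abort(paste0("ligand '", lig$ligand_id[1],
                   "': poses differ in atom count or atom-name sequence ",
                   "(use check_atoms = FALSE to override)"))
    }
  }
  invisible(poses)
}

#' Read docked poses from a multi-MODEL PDBQT file
#'
#' Parses AutoDock Vina output: each `MODEL`/`ENDMDL` block is one docked
#' pose, and its binding energy (kcal/mol) is taken as the first numeric
#' token of the block's Vina result `REMARK` line. Any `REMARK` line whose
#' text starts with `VINA RESULT` or `RESULT` is accepted, which tolerates
#' formatting drift between Vina versions. Both `ATOM` and `HETATM` records
#' are read, from fixed PDB columns. A file with no `MODEL` blocks is
#' treated as a single pose provided it carries an energy `REMARK`.
#' The energy sign is preserved verbatim (more negative = more favorable).
#'
#' @param path Path to a PDBQT file.
#' @param ligand_id Identity stamped into the `ligand_id` column; defaults
#'   to the file name without extension.
#' @return A pose table (tibble, one row per atom) ordered as in the file;
#'   `pose_id` equals the 1-based MODEL order.
#' @seealso [read_pose_table()], [write_pose_table()]
#' @export
read_pdbqt_poses <- function(path, ligand_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ligand_id <- ligand_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {
    blocks <- list(seq_along(lines))
  } else {
    if (length(ends) != length(starts)) {
      abort(paste0("unbalanced MODEL/ENDMDL in ", path))
    }
    blocks <- purrr::map2(starts, ends, seq)
  }

  parse_block <- function(idx, pose_index) {
    blk <- lines[idx]
    rem <- grep("^REMARK\\s+(VINA\\s+)?RESULT", blk,
                ignore.case = TRUE, value = TRUE)
    if (length(rem) == 0L) {
      abort(paste0("no energy REMARK in MODEL block ", pose_index,
                   " of ", path))
    }
    tokens <- regmatches(rem[1],
                         gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                  rem[1]))[[1]]
    if (length(tokens) == 0L) {
      abort(paste0("energy REMARK has no numeric field in MODEL block ",
                   pose_index, " of ", path))
    }
    is_atom <- grepl("^(ATOM|HETATM)", blk)
    if (!any(is_atom)) {
      abort(paste0("MODEL block ", pose_index, " of ", path, " has no atoms"))
    }
    atoms <- parse_atom_lines(blk[is_atom], idx[is_atom], path, pdbqt = TRUE)
    tibble(
      ligand_id = ligand_id,
      pose_id = pose_index,
      energy = as.numeric(tokens[1]),
      atom_name = atoms$atom_name,
      element = atoms$element,
      x = atoms$x, y = atoms$y, z = atoms$z
    )
  }

  poses <- purrr::imap(blocks, parse_block)
  poses <- dplyr::bind_rows(poses)
  validate_pose_ensemble(poses)
  poses
}

# Fixed-column ATOM/HETATM parsing shared by the PDBQT and PDB readers.
# line_no is used for error messages only.
parse_atom_lines <- function(lines, line_no, path, pdbqt = FALSE) {
  field <- function(from, to) trimws(substr(lines, from, to))
  xs <- field(31, 38); ys <- field(39, 46); zs <- field(47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate field at line ", line_no[bad[1]],
                 " of ", path))
  }
  atom_name <- field(13, 16)
  el_field <- field(77, 79)
  element <- if (pdbqt) {
    ifelse(el_field == "",
           standardize_element(sub("[^A-Za-z].*$", "", atom_name)),
           element_from_pdbqt_type(el_field))
  } else {
    ifelse(el_field == "",
           standardize_element(sub("[0-9'\"]*$", "",
                                   sub("^[0-9]+", "", atom_name))),
           standardize_element(substr(el_field, 1, 2)))
  }
  list(
    record = field(1, 6),
    atom_name = atom_name,
    altloc = substr(lines, 17, 17),
    residue_name = field(18, 20),
    chain_id = substr(lines, 22, 22),
    residue_number = suppressWarnings(as.integer(field(23, 26))),
    x = x, y = y, z = z,
    element = element
  )
}

#' Read a pose table
#'
#' Reads the plain-text pose dialect: TSV with `#` comment lines and columns
#' `ligand_id, pose_id, energy, atom_name, element, x, y, z`, one row per
#' atom, energy repeated on every atom row of a pose.
#'
#' @param path Path to a pose-table TSV file.
#' @return A validated pose table (tibble).
#' @export
read_pose_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # base parser (strtod) rather than readr: %.17g output must re-read
  # bit-identically, and vroom's fast double path can be off by one ulp
  tab <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) abort(paste0("no poses in ", path))
  )
  tab <- as_tibble(tab)
  if ("pose_id" %in% names(tab)) tab$pose_id <- as.integer(tab$pose_id)
  missing_cols <- setdiff(pose_table_cols, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("pose table ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) abort(paste0("no poses in ", path))
  validate_pose_ensemble(tab[pose_table_cols])
  tab[pose_table_cols]
}

#' Write a pose table
#'
#' Serializes a pose table in the dialect read by [read_pose_table()].
#' Coordinates and energies are written with full double precision
#' (`%.17g`) so that a read-back reproduces them bit-identically.
#'
#' @param poses A pose table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(poses, path) {
  validate_pose_ensemble(poses, check_atoms = FALSE)
  out <- dplyr::mutate(
    poses,
    dplyr::across(c("energy", "x", "y", "z"), ~ sprintf("%.17g", .x))
  )
  body <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
  writeLines(c("# dockrescore pose table (one row per atom)",
               paste(names(out), collapse = "\t"),
               body), path)
  invisible(path)
}
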