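#' @keywords internal
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Parse residue specifications
#'
#' Turns strings like `"V178"` or `"A:S181"` (optional chain prefix) into a
#' residue-spec tibble. The letter is the one-letter amino-acid code of the
#' expected residue identity, which [get_ca()] verifies against the
#' structure.
#'
#' @param specs Character vector, e.g. `c("V178", "A:S181")`, or a single
#'   comma-separated string `"V178,S181"`.
#' @return A tibble with columns `one_letter_code`, `residue_number`,
#'   `chain_id` (`NA` when unspecified) and `label`.
#' @examples
#' parse_residue_specs("V178,S181,Q185")
#' @export
parse_residue_specs <- function(specs) {
  if (length(specs) == 1L && grepl(",", specs)) {
    specs <- strsplit(specs, ",")[[1]]
  }
  specs <- trimws(specs)
  specs <- specs[specs != ""]
  m <- regmatches(specs, regexec("^(?:([A-Za-z0-9]):)?([A-Za-z])([0-9]+)$", specs))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    abort(paste0("cannot parse residue spec(s): ",
                 paste(specs[bad], collapse = ", ")))
  }
  out <- tibble(
    one_letter_code = toupper(vapply(m, `[`, "", 3L)),
    residue_number = as.integer(vapply(m, `[`, "", 4L)),
    chain_id = dplyr::na_if(vapply(m, `[`, "", 2L), ""),
    label = specs
  )
  unknown <- !(out$one_letter_code %in% aa_three_to_one)
  if (any(unknown)) {
    abort(paste0("not a standard amino-acid code: ",
                 paste(specs[unknown], collapse = ", ")))
  }
  if (any(out$residue_number < 1L)) abort("residue_number must be >= 1")
  out
}

#' Get the C-alpha coordinate of a residue
#'
#' Locates the atom named `CA` in the residue matching `residue_number`
#' (and `chain_id`, if given) and verifies that the residue's three-letter
#' name translates to the expected one-letter code — a guard against
#' numbering mismatches between the residue list and the deposited
#' structure.
#'
#' @param receptor Receptor tibble from [read_receptor_pdb()].
#' @param spec One row of [parse_residue_specs()] output (or a string
#'   parseable into one).
#' @return Named numeric 3-vector (`x`, `y`, `z`) in Angstrom.
#' @export
get_ca <- function(receptor, spec) {
  if (is.character(spec)) spec <- parse_residue_specs(spec)
  stopifnot(nrow(spec) == 1L)
  hit <- receptor[!receptor$is_het &
                    receptor$residue_number == spec$residue_number, ]
  if (is.na(spec$chain_id)) {
    chains <- unique(hit$chain_id)
    if (length(chains) > 1L) {
      abort(paste0("residue ", spec$residue_number, " occurs in chains ",
                   paste(chains, collapse = ", "),
                   "; specify a chain (e.g. \"", chains[1], ":",
                   spec$label, "\")"))
    }
  } else {
    hit <- hit[hit$chain_id == spec$chain_id, ]
  }
  if (nrow(hit) == 0L) {
    abort(paste0("residue not found: ", spec$label))
  }
  found_name <- hit$residue_name[1]
  found_code <- aa_three_to_one[found_name]
  if (is.na(found_code) || found_code != spec$one_letter_code) {
    abort(paste0("identity mismatch for ", spec$label, ": structure has ",
                 found_name, " ", spec$residue_number))
  }
  ca <- hit[hit$atom_name == "CA", ]
  if (nrow(ca) == 0L) {
    abort(paste0("residue ", spec$label, " has no CA atom"))
  }
  c(x = ca$x[1], y = ca$y[1], z = ca$z[1])
}

#' Build C-alpha-centered cubic site boxes
#'
#' Constructs one axis-aligned cubic box per residue spec, centered on the
#' residue's C-alpha coordinate. This mirrors the standard definition of a
#' docking search box anchored on binding-site residues; the default edge
#' of 15 Angstrom is the conventional box size for a single-residue anchor
#' (interpreted as the cube's full edge, i.e. half-width 7.5).
#'
#' @param receptor Receptor tibble from [read_receptor_pdb()].
#' @param specs Residue specs: a tibble from [parse_residue_specs()] or a
#'   character vector / comma string parseable into one.
#' @param edge Box edge length in Angstrom (> 0). Default 15.
#' @return A tibble of boxes: `label`, `center_x`, `center_y`, `center_z`,
#'   `edge`, in input order. Empty specs give an empty (0-row) tibble.
#' @export
build_site_boxes <- function(receptor, specs, edge = 15.0) {
  if (!is.numeric(edge) || length(edge) != 1L || !is.finite(edge) ||
      edge <= 0) {
    abort("edge must be a single positive number (Angstrom)")
  }
  if (is.character(specs)) specs <- parse_residue_specs(specs)
  empty <- tibble(label = character(), center_x = double(),
                  center_y = double(), center_z = double(), edge = double())
  if (is.null(specs) || nrow(specs) == 0L) return(empty)
  purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    ca <- get_ca(receptor, specs[i, ])
    tibble(label = specs$label[i], center_x = ca[["x"]],
           center_y = ca[["y"]], center_z = ca[["z"]], edge = edge)
  })
}

# closed-cube membership of points (n x 3 matrix) in the union of boxes
points_in_boxes <- function(pts, boxes) {
  stopifnot(nrow(boxes) > 0)
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(nrow(boxes))) {
    h <- boxes$edge[i] / 2
    inside <- inside |
      (abs(pts[, 1] - boxes$center_x[i]) <= h &
         abs(pts[, 2] - boxes$center_y[i]) <= h &
         abs(pts[, 3] - boxes$center_z[i]) <= h)
  }
  inside
}

#' Test whether a pose's center of mass lies in a site
#'
#' Membership is tested on the pose center of mass (consistent with the
#' COM-based clustering geometry, not any-atom overlap) against the union
#' of boxes; each box is a closed cube, so a COM exactly on a face counts
#' as inside.
#'
#' @param pose Atom rows of a single pose (a pose table restricted to one
#'   `pose_id`).
#' @param boxes Box tibble from [build_site_boxes()]; must be non-empty.
#' @param mass_weighted Use the mass-weighted COM (default) or the plain
#'   centroid.
#' @return `TRUE` iff the COM is inside the union of boxes.
#' @export
pose_in_site <- function(pose, boxes, mass_weighted = TRUE) {
  if (is.null(boxes) || nrow(boxes) == 0L) abort("boxes must be non-empty")
  com <- center_of_mass(pose, mass_weighted = mass_weighted)
  points_in_boxes(matrix(com, nrow = 1), boxes)
}

#' Filter a pose table to poses whose COM lies inside a site
#'
#' Vectorized companion of [pose_in_site()]: keeps all atom rows of every
#' pose whose center of mass falls inside the union of boxes.
#'
#' @inheritParams pose_in_site
#' @param poses A pose table (possibly several ligands).
#' @return The filtered pose table.
#' @export
filter_poses_in_site <- function(poses, boxes, mass_weighted = TRUE) {
  if (is.null(boxes) || nrow(boxes) == 0L) abort("boxes must be non-empty")
  coms <- pose_coms(poses, mass_weighted = mass_weighted)
  keep <- coms[points_in_boxes(
    as.matrix(coms[, c("com_x", "com_y", "com_z")]), boxes), ]
  dplyr::semi_join(poses, keep, by = c("ligand_id", "pose_id"))
}
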