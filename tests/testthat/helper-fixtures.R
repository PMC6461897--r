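# Shared fixtures and the independent clustering oracle.

# Independent re-implementation of the leader rule, written as plain
# step-by-step loops over a data frame so it shares no code path with
# cluster_poses(). Takes per-pose COMs and energies, returns the partition
# as a list of clusters, each with sorted member pose ids and the
# representative pose id.
naive_leader <- function(pose_id, com, energy, radius) {
  stopifnot(nrow(com) == length(pose_id), length(energy) == length(pose_id))
  processing_order <- order(energy, pose_id)
  leaders <- c()          # indices into the input vectors, creation order
  member_of <- rep(NA_integer_, length(pose_id))
  for (i in processing_order) {
    joined <- NA
    for (L in seq_along(leaders)) {
      dx <- com[i, 1] - com[leaders[L], 1]
      dy <- com[i, 2] - com[leaders[L], 2]
      dz <- com[i, 3] - com[leaders[L], 3]
      if (sqrt(dx * dx + dy * dy + dz * dz) <= radius) {
        joined <- L
        break
      }
    }
    if (is.na(joined)) {
      leaders <- c(leaders, i)
      member_of[i] <- length(leaders)
    } else {
      member_of[i] <- joined
    }
  }
  out <- list()
  for (L in seq_along(leaders)) {
    out[[L]] <- list(
      members = sort(pose_id[which(member_of == L)]),
      representative = pose_id[leaders[L]]
    )
  }
  # normalize: order clusters by representative energy then pose id,
  # mirroring the documented output order
  rep_e <- vapply(seq_along(leaders), function(L) energy[leaders[L]], 0)
  rep_p <- vapply(seq_along(leaders), function(L) pose_id[leaders[L]], 0L)
  out[order(rep_e, rep_p)]
}

# canonical form of a cluster_poses() result for comparison with the oracle
partition_of <- function(cl) {
  lapply(seq_len(nrow(cl$clusters)), function(k) {
    list(
      members = sort(cl$assignments$pose_id[
        cl$assignments$cluster == cl$clusters$cluster[k]]),
      representative = cl$clusters$representative_pose[k]
    )
  })
}

# pose table of single-carbon poses with prescribed COMs and energies;
# with one atom per pose the COM is the atom position for any weighting
pose_table_from_coms <- function(com, energy,
                                 ligand_id = "lig", pose_id = NULL) {
  com <- as.matrix(com)
  pose_id <- pose_id %||% seq_len(nrow(com))
  tibble::tibble(
    ligand_id = ligand_id, pose_id = as.integer(pose_id),
    energy = energy, atom_name = "C1", element = "C",
    x = com[, 1], y = com[, 2], z = com[, 3]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal Vina-style multi-MODEL PDBQT text
write_pdbqt_fixture <- function(path, energies, coords) {
  stopifnot(length(energies) == length(coords))
  lines <- character(0)
  for (i in seq_along(energies)) {
    lines <- c(lines, sprintf("MODEL %d", i),
               sprintf("REMARK VINA RESULT:    %8.1f      0.000      0.000",
                       energies[i]))
    xyz <- coords[[i]]
    for (a in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
        "ATOM", a, sprintf(" C%d", a), "LIG", "A", 1,
        xyz[a, 1], xyz[a, 2], xyz[a, 3], 1.00, 0.00, 0.0, "C"))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(lines, path)
  path
}

# the 11 binding-site residues used throughout the site-box tests, at
# synthetic coordinates
myr_site_residues <- function() {
  tibble::tibble(
    residue_name = c("VAL", "SER", "GLN", "ARG", "LEU", "GLY",
                     "MET", "SER", "ILE", "GLN", "ILE"),
    residue_number = c(178L, 181L, 185L, 226L, 236L, 237L,
                       252L, 256L, 259L, 345L, 346L),
    x = seq(0, 100, length.out = 11),
    y = rep(c(0, 5), length.out = 11),
    z = rep(c(0, -5), length.out = 11)
  )
}
myr_site_specs <- "V178,S181,Q185,R226,L236,G237,M252,S256,I259,Q345,I346"
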