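#' Simulate a pose ensemble with planted cluster structure
#'
#' Deterministic, seeded generator of synthetic docked-pose ensembles for
#' validating the clustering and rescoring machinery without any real
#' docking run. Each planted cluster k gets `cluster_sizes[k]` poses whose
#' centers of mass are `centers[k,]` plus a displacement drawn uniformly
#' from a ball of radius `scatter_max` (hard truncation, not a Gaussian
#' tail — so the recovery guarantee below is a theorem, not a
#' probability). Per-pose energies are `energy_base[k]` plus Gaussian
#' jitter. Atoms are a rigid all-carbon template, randomly rotated and then
#' shifted so the realized COM equals the target COM exactly (all-carbon
#' makes the mass-weighted COM coincide with the centroid).
#'
#' In guarantee mode (`guarantee = TRUE`, the default) centers must be
#' pairwise separated by at least `2 * radius_target + 0.5` Angstrom and
#' `scatter_max` must not exceed `radius_target / 2`; under those
#' conditions [cluster_poses()] at `radius_target` recovers the planted
#' partition exactly. Auto-placed centers sit on a cubic lattice with that
#' separation.
#'
#' Defaults describe a desk-scale analogue of a Vina campaign: energies in
#' the mid-negative kcal/mol range stepped by 0.5 between clusters, 0.25
#' kcal/mol within-cluster jitter, 22 heavy atoms per pose (a typical
#' drug-like ligand), scatter at half the 4-Angstrom cluster radius.
#'
#' @param cluster_sizes Integer vector, poses per planted cluster (all
#'   >= 1).
#' @param centers Optional numeric matrix (`n_clusters` x 3) of COM
#'   centers in Angstrom; auto-placed when `NULL`.
#' @param scatter_max Truncation radius (Angstrom) for within-cluster COM
#'   displacement. Default `radius_target / 2`.
#' @param energy_base Per-cluster base energy, kcal/mol; default
#'   `-8, -7.5, -7, ...`.
#' @param energy_jitter_sd Gaussian jitter SD on pose energies, kcal/mol
#'   (0 disables jitter). Default 0.25.
#' @param atoms_per_pose Atoms in the rigid template. Default 22.
#' @param radius_target Clustering radius the ensemble is built for,
#'   Angstrom. Default 4.
#' @param guarantee Enforce the exact-recovery geometry (see above).
#'   Default `TRUE`; set `FALSE` for stress tests with overlapping
#'   clusters.
#' @param ligand_id Ligand identity for the pose table.
#' @param seed Integer seed; the same seed gives bit-identical output, and
#'   the global RNG state is left untouched.
#' @return A list: `poses` (pose table; pose order is shuffled so input
#'   order carries no information about the planted structure), `truth`
#'   (tibble `pose_id`, `cluster` — the planted labels), `centers`
#'   (the centers actually used), and `params`.
#' @examples
#' sim <- simulate_ensemble(cluster_sizes = c(4, 2), seed = 42)
#' dplyr::count(sim$truth, cluster)
#' @export
simulate_ensemble <- function(cluster_sizes,
                              centers = NULL,
                              scatter_max = radius_target / 2,
                              energy_base = NULL,
                              energy_jitter_sd = 0.25,
                              atoms_per_pose = 22,
                              radius_target = 4.0,
                              guarantee = TRUE,
                              ligand_id = "synthetic",
                              seed = 1L) {
  n_clusters <- length(cluster_sizes)
  if (n_clusters < 1 || any(cluster_sizes < 1) ||
      any(cluster_sizes != round(cluster_sizes))) {
    abort("cluster_sizes must be integers >= 1")
  }
  stopifnot(radius_target > 0, scatter_max >= 0, atoms_per_pose >= 1)
  min_sep <- 2 * radius_target + 0.5
  if (guarantee && scatter_max > radius_target / 2 + 1e-12) {
    abort("guarantee mode requires scatter_max <= radius_target / 2")
  }
  if (is.null(centers)) {
    centers <- lattice_centers(n_clusters, min_sep)
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n_clusters, ncol(centers) == 3)
    if (guarantee && n_clusters > 1) {
      d <- as.matrix(stats::dist(centers))
      if (min(d[upper.tri(d)]) < min_sep - 1e-9) {
        abort(paste0("infeasible separation: centers must be >= ", min_sep,
                     " Angstrom apart in guarantee mode"))
      }
    }
  }
  if (is.null(energy_base)) {
    energy_base <- -8 + 0.5 * (seq_len(n_clusters) - 1)
  }
  stopifnot(length(energy_base) == n_clusters)

  template <- pose_template(atoms_per_pose)
  withr::with_seed(seed, {
    per_pose <- purrr::map_dfr(seq_len(n_clusters), function(k) {
      m <- cluster_sizes[k]
      disp <- runif_ball(m, scatter_max)
      tibble(
        cluster = k,
        com_x = centers[k, 1] + disp[, 1],
        com_y = centers[k, 2] + disp[, 2],
        com_z = centers[k, 3] + disp[, 3],
        energy = energy_base[k] +
          if (energy_jitter_sd > 0) stats::rnorm(m, 0, energy_jitter_sd)
          else 0
      )
    })
    shuffle <- sample.int(nrow(per_pose))
    per_pose <- per_pose[shuffle, ]
    per_pose$pose_id <- seq_len(nrow(per_pose))

    poses <- purrr::map_dfr(seq_len(nrow(per_pose)), function(i) {
      rot <- random_rotation()
      at <- template %*% t(rot)      # template is centered: COM preserved
      tibble(
        ligand_id = ligand_id,
        pose_id = per_pose$pose_id[i],
        energy = per_pose$energy[i],
        atom_name = sprintf("C%d", seq_len(atoms_per_pose)),
        element = "C",
        x = at[, 1] + per_pose$com_x[i],
        y = at[, 2] + per_pose$com_y[i],
        z = at[, 3] + per_pose$com_z[i]
      )
    })
    validate_pose_ensemble(poses)
    list(
      poses = poses,
      truth = tibble(pose_id = per_pose$pose_id,
                     cluster = per_pose$cluster),
      centers = centers,
      params = list(cluster_sizes = cluster_sizes,
                    scatter_max = scatter_max,
                    energy_base = energy_base,
                    energy_jitter_sd = energy_jitter_sd,
                    atoms_per_pose = atoms_per_pose,
                    radius_target = radius_target,
                    guarantee = guarantee, seed = seed)
    )
  })
}

# cubic lattice with the required pairwise separation
lattice_centers <- function(n, sep) {
  m <- ceiling(n^(1 / 3))
  g <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
  g <- g[order(g$i + g$j + g$k), , drop = FALSE][seq_len(n), , drop = FALSE]
  as.matrix(g) * sep
}

# n points uniform in a ball of radius r (polar method, no rejection)
runif_ball <- function(n, r) {
  if (r == 0) return(matrix(0, n, 3))
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * (r * stats::runif(n)^(1 / 3))
}

# uniform random rotation via QR of a Gaussian matrix, det fixed to +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rigid all-carbon template: a gentle helix, centered on its centroid
pose_template <- function(n_atoms) {
  t <- seq(0, by = 0.8, length.out = n_atoms)
  xyz <- cbind(1.6 * cos(t), 1.6 * sin(t), 0.4 * t)
  sweep(xyz, 2, colMeans(xyz))
}

#' Build a toy receptor structure
#'
#' Constructs a minimal synthetic protein backbone (N, CA, C, O per
#' residue) with each C-alpha at the given coordinate — enough structure
#' for site-box fixtures without downloading a real crystal structure.
#'
#' @param residues A data frame with columns `residue_name` (3-letter
#'   code), `residue_number`, `x`, `y`, `z` (the CA coordinate) and
#'   optionally `chain_id` (default `"A"`).
#' @param structure_id Identity attribute. Default `"toy"`.
#' @return A receptor tibble in the [read_receptor_pdb()] layout; pass it
#'   to [write_receptor_pdb()] to obtain valid PDB text.
#' @examples
#' rec <- make_toy_receptor(tibble::tibble(
#'   residue_name = c("SER", "ARG"), residue_number = c(181, 226),
#'   x = c(0, 10), y = 0, z = 0))
#' get_ca(rec, "S181")
#' @export
make_toy_receptor <- function(residues, structure_id = "toy") {
  residues <- as_tibble(residues)
  stopifnot(all(c("residue_name", "residue_number", "x", "y", "z") %in%
                  names(residues)))
  if (!"chain_id" %in% names(residues)) residues$chain_id <- "A"
  dup <- duplicated(residues[c("chain_id", "residue_number")])
  if (any(dup)) {
    abort(paste0("duplicate residue number in one chain: ",
                 paste(residues$residue_number[dup], collapse = ", ")))
  }
  # idealized local backbone offsets around the CA, Angstrom
  backbone <- tibble(
    atom_name = c("N", "CA", "C", "O"),
    dx = c(-1.45, 0, 1.52, 2.15),
    dy = c(0.3, 0, 0.2, 1.25),
    dz = c(0, 0, 0, 0),
    element = c("N", "C", "C", "O")
  )
  rec <- tidyr::crossing(residues, backbone) |>
    dplyr::arrange(.data$chain_id, .data$residue_number,
                   match(.data$atom_name, backbone$atom_name)) |>
    dplyr::transmute(
      record = "ATOM",
      atom_name = .data$atom_name,
      residue_name = .data$residue_name,
      chain_id = .data$chain_id,
      residue_number = as.integer(.data$residue_number),
      x = .data$x + .data$dx,
      y = .data$y + .data$dy,
      z = .data$z + .data$dz,
      element = .data$element,
      is_het = FALSE
    )
  structure(rec, structure_id = structure_id)
}
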