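#' Center of mass of a pose
#'
#' Mass-weighted mean of the atom coordinates, with masses looked up from
#' the element symbol ([atomic_mass()]). With `mass_weighted = FALSE` the
#' plain geometric centroid is returned instead — useful when the docking
#' files lack hydrogens and approximate masses would add noise rather than
#' physics.
#'
#' @param pose Atom rows of a single pose (columns `element`, `x`, `y`,
#'   `z`; extra columns ignored).
#' @param mass_weighted Weight coordinates by atomic mass (default `TRUE`).
#' @return Named numeric 3-vector (`x`, `y`, `z`) in Angstrom.
#' @examples
#' pose <- tibble::tibble(element = c("O", "C"),
#'                        x = c(0, 1), y = 0, z = 0)
#' center_of_mass(pose)                       # pulled toward the oxygen
#' center_of_mass(pose, mass_weighted = FALSE)  # plain midpoint
#' @export
center_of_mass <- function(pose, mass_weighted = TRUE) {
  if (nrow(pose) == 0L) abort("pose has no atoms")
  w <- if (mass_weighted) atomic_mass(pose$element) else rep(1, nrow(pose))
  s <- sum(w)
  c(x = sum(w * pose$x) / s,
    y = sum(w * pose$y) / s,
    z = sum(w * pose$z) / s)
}

#' Centers of mass for every pose in a table
#'
#' @param poses A pose table.
#' @inheritParams center_of_mass
#' @return A tibble with one row per pose: `ligand_id`, `pose_id`,
#'   `energy`, `com_x`, `com_y`, `com_z`.
#' @export
pose_coms <- function(poses, mass_weighted = TRUE) {
  w <- if (mass_weighted) atomic_mass(poses$element) else rep(1, nrow(poses))
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(poses, .w = w),
                    .data$ligand_id, .data$pose_id),
    energy = .data$energy[1],
    com_x = sum(.data$.w * .data$x) / sum(.data$.w),
    com_y = sum(.data$.w * .data$y) / sum(.data$.w),
    com_z = sum(.data$.w * .data$z) / sum(.data$.w),
    .groups = "drop"
  )
}

#' Cluster docked poses by center-of-mass distance
#'
#' Leader (greedy) clustering of one ligand's pose ensemble, the
#' CHARMM-style convention for post-docking pose pools: poses are processed
#' in ascending energy order (ties broken by ascending `pose_id`); each
#' pose joins the earliest-created cluster whose *representative* COM lies
#' within `radius` (Euclidean), otherwise it founds a new cluster with
#' itself as representative. Because seeding is energy-ordered, each
#' representative is automatically the lowest-energy member of its cluster
#' — the "lowest energy selected for each cluster" rule comes for free.
#' The resulting partition is disjoint and exhaustive, and the procedure is
#' fully deterministic: the input row order never matters.
#'
#' @param poses A pose table containing exactly one ligand.
#' @param radius Cluster radius in Angstrom (> 0). Default 4, the
#'   conventional COM cutoff for docked-pose clustering.
#' @param mass_weighted Passed to [center_of_mass()]. Default `TRUE`.
#' @param check_atoms Passed to [validate_pose_ensemble()].
#' @return An object of class `pose_clusters`: a list with
#'   \describe{
#'     \item{clusters}{tibble, one row per cluster sorted by `e_min`
#'       ascending: `cluster`, `n`, `representative_pose`, `e_min`,
#'       `e_mean`, `com_x`, `com_y`, `com_z` (representative COM).}
#'     \item{assignments}{tibble `pose_id` -> `cluster`.}
#'     \item{coms}{per-pose COM tibble used for the clustering.}
#'     \item{ligand_id, radius, mass_weighted}{parameters, recorded so the
#'       result is self-describing.}
#'   }
#'   Use [generics::tidy()] / [generics::glance()] to extract summaries.
#' @examples
#' poses <- simulate_ensemble(cluster_sizes = c(3, 2), seed = 1)$poses
#' cl <- cluster_poses(poses, radius = 4)
#' tidy(cl)
#' @export
cluster_poses <- function(poses, radius = 4.0, mass_weighted = TRUE,
                          check_atoms = TRUE) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    abort("radius must be a single positive number (Angstrom)")
  }
  validate_pose_ensemble(poses, check_atoms = check_atoms)
  if (length(unique(poses$ligand_id)) != 1L) {
    abort(paste0("cluster_poses() takes one ligand at a time; split by ",
                 "ligand_id (rescore_poses() does this for you)"))
  }
  coms <- pose_coms(poses, mass_weighted = mass_weighted)
  ord <- order(coms$energy, coms$pose_id)
  com_mat <- as.matrix(coms[, c("com_x", "com_y", "com_z")])

  n <- nrow(coms)
  assignment <- integer(n)          # cluster id per row of coms
  rep_row <- integer(0)             # row index of each cluster's leader
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(rep_row)) { # earliest-created cluster wins
      if (sqrt(sum((com_mat[i, ] - com_mat[rep_row[k], ])^2)) <= radius) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_row <- c(rep_row, i)
      assignment[i] <- length(rep_row)
    }
  }

  clusters <- purrr::map_dfr(seq_along(rep_row), function(k) {
    members <- which(assignment == k)
    tibble(
      cluster = k,
      n = length(members),
      representative_pose = coms$pose_id[rep_row[k]],
      e_min = coms$energy[rep_row[k]],
      e_mean = mean(coms$energy[members]),
      com_x = com_mat[rep_row[k], 1],
      com_y = com_mat[rep_row[k], 2],
      com_z = com_mat[rep_row[k], 3]
    )
  })
  # creation order is already e_min-ascending (energy-ordered seeding);
  # sort defensively with the documented tie-break and relabel 1..K
  perm <- order(clusters$e_min, clusters$representative_pose)
  clusters <- clusters[perm, ]
  new_id <- integer(length(perm))
  new_id[perm] <- seq_along(perm)
  clusters$cluster <- seq_len(nrow(clusters))

  structure(
    list(
      clusters = tibble::remove_rownames(clusters),
      assignments = tibble(pose_id = coms$pose_id,
                           cluster = new_id[assignment]),
      coms = coms,
      ligand_id = poses$ligand_id[1],
      radius = radius,
      mass_weighted = mass_weighted
    ),
    class = "pose_clusters"
  )
}

#' Verify a clustering partition
#'
#' Validation utility backing the clustering invariants: checks that the
#' clusters are disjoint and cover every pose, that each representative is
#' its cluster's minimum-energy member (with its energy recorded as
#' `e_min`), and that every member COM lies within `radius` of its
#' representative COM.
#'
#' @param cl A `pose_clusters` object from [cluster_poses()].
#' @param poses The pose table it was computed from.
#' @param radius Radius to check against; defaults to the radius recorded
#'   in `cl`.
#' @return `TRUE` if all checks pass, otherwise `FALSE` with the first
#'   failing reason attached as attribute `"reason"` (and reported via a
#'   message).
#' @export
partition_check <- function(cl, poses, radius = cl$radius) {
  fail <- function(reason) {
    inform(paste0("partition_check: ", reason))
    structure(FALSE, reason = reason)
  }
  coms <- pose_coms(poses, mass_weighted = cl$mass_weighted)
  asg <- cl$assignments
  if (anyDuplicated(asg$pose_id) > 0L) return(fail("duplicate pose assignment"))
  if (!setequal(asg$pose_id, coms$pose_id)) {
    return(fail("assignments do not cover all poses"))
  }
  for (k in seq_len(nrow(cl$clusters))) {
    row <- cl$clusters[k, ]
    members <- asg$pose_id[asg$cluster == row$cluster]
    me <- coms[match(members, coms$pose_id), ]
    if (!(row$representative_pose %in% members)) {
      return(fail(paste0("representative of cluster ", row$cluster,
                         " is not a member")))
    }
    if (abs(min(me$energy) - row$e_min) > 1e-12 ||
        abs(coms$energy[coms$pose_id == row$representative_pose] -
            row$e_min) > 1e-12) {
      return(fail(paste0("representative of cluster ", row$cluster,
                         " is not the minimum-energy member")))
    }
    d <- sqrt((me$com_x - row$com_x)^2 + (me$com_y - row$com_y)^2 +
                (me$com_z - row$com_z)^2)
    if (any(d > radius)) {
      return(fail(paste0("member COM outside radius in cluster ",
                         row$cluster)))
    }
  }
  TRUE
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat("Pose clustering of ligand '", x$ligand_id, "': ",
      nrow(x$clusters), " cluster(s) from ", nrow(x$assignments),
      " pose(s)\n", sep = "")
  cat("COM leader clustering, radius ", x$radius, " A, ",
      if (x$mass_weighted) "mass-weighted" else "geometric centroid",
      "\n\n", sep = "")
  print(x$clusters, ...)
  invisible(x)
}

#' Tidy a pose clustering
#'
#' @param x A `pose_clusters` object.
#' @param ... Unused.
#' @return One row per cluster (sorted by `e_min`): `ligand_id`, `cluster`,
#'   `n`, `representative_pose`, `e_min`, `e_mean`, representative COM.
#' @method tidy pose_clusters
#' @export
tidy.pose_clusters <- function(x, ...) {
  dplyr::bind_cols(tibble(ligand_id = x$ligand_id), x$clusters)
}

#' One-row summary of a pose clustering
#'
#' @param x A `pose_clusters` object.
#' @param ... Unused.
#' @return A one-row tibble: `ligand_id`, `n_poses`, `n_clusters`,
#'   `largest_cluster`, `e_min`, `radius`, `mass_weighted`.
#' @method glance pose_clusters
#' @export
glance.pose_clusters <- function(x, ...) {
  tibble(
    ligand_id = x$ligand_id,
    n_poses = nrow(x$assignments),
    n_clusters = nrow(x$clusters),
    largest_cluster = max(x$clusters$n),
    e_min = min(x$clusters$e_min),
    radius = x$radius,
    mass_weighted = x$mass_weighted
  )
}

#' Plot a pose clustering
#'
#' Scatter of pose centers of mass in the two requested coordinates,
#' colored by cluster, with cluster representatives emphasized.
#'
#' @param object A `pose_clusters` object.
#' @param coords Which two coordinates to plot, default `c("x", "y")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pose_clusters
#' @export
autoplot.pose_clusters <- function(object, coords = c("x", "y"), ...) {
  stopifnot(length(coords) == 2, all(coords %in% c("x", "y", "z")))
  dat <- dplyr::left_join(object$coms, object$assignments, by = "pose_id")
  dat$cluster <- factor(dat$cluster)
  reps <- object$clusters
  ax <- paste0("com_", coords)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                    colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = reps,
      ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]]),
      inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.2
    ) +
    ggplot2::labs(
      title = paste0("Pose COM clusters: ", object$ligand_id),
      subtitle = paste0("leader clustering, radius ", object$radius,
                        " Å; × = representatives"),
      x = paste0("COM ", coords[1], " (Å)"),
      y = paste0("COM ", coords[2], " (Å)")
    ) +
    ggplot2::theme_minimal()
}
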