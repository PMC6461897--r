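#' Thermal energy kT in kcal/mol
#'
#' @param temperature Absolute temperature in K (default 298.15, the room
#'   temperature convention for docking scores).
#' @param boltzmann_k Boltzmann constant in kcal/(mol K); the default
#'   0.0019872041 makes kT ~ 0.59248 kcal/mol at 298.15 K.
#' @return kT in kcal/mol.
#' @export
kT <- function(temperature = 298.15, boltzmann_k = 0.0019872041) {
  stopifnot(is.numeric(temperature), temperature > 0,
            is.numeric(boltzmann_k), boltzmann_k > 0)
  temperature * boltzmann_k
}

#' Cluster-entropy-corrected free energy
#'
#' The rescoring heuristic for a docked-pose cluster:
#' \deqn{\Delta G = E_{min} + (-kT \ln N)}
#' where \eqn{E_{min}} is the lowest binding energy in the cluster
#' (kcal/mol, signed, more negative = more favorable) and \eqn{N} the
#' cluster population. A large cluster of similar poses is read as a proxy
#' for configurational stability, so population lowers (improves) the
#' score; a singleton cluster scores exactly its own energy
#' (\eqn{\ln 1 = 0}).
#'
#' @param e_min Lowest binding energy of the cluster, kcal/mol. Vectorized.
#' @param n Cluster population (integer >= 1). Vectorized, recycled
#'   against `e_min`.
#' @inheritParams kT
#' @return Free energy in kcal/mol: `e_min - kT * log(n)`.
#' @examples
#' cluster_free_energy(-7.9, 91)   # ~ -10.57
#' cluster_free_energy(-5, 1)      # -5: entropy term vanishes
#' @export
cluster_free_energy <- function(e_min, n, temperature = 298.15,
                                boltzmann_k = 0.0019872041) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    abort("n must be integer-valued and >= 1")
  }
  if (any(!is.finite(e_min))) abort("e_min must be finite")
  e_min + (-kT(temperature, boltzmann_k) * log(n))
}

#' Score clusters with the entropy-corrected free energy
#'
#' Annotates each cluster with `delta_g = e_min - kT ln(n)`; the input
#' order is preserved.
#'
#' @param clusters A cluster tibble (columns `n` and `e_min`; e.g.
#'   `tidy()` of a [cluster_poses()] result, or the result itself).
#' @inheritParams kT
#' @return The cluster tibble with a `delta_g` column appended.
#' @export
score_clusters <- function(clusters, temperature = 298.15,
                           boltzmann_k = 0.0019872041) {
  if (inherits(clusters, "pose_clusters")) clusters <- tidy(clusters)
  stopifnot(all(c("n", "e_min") %in% names(clusters)))
  dplyr::mutate(clusters,
                delta_g = cluster_free_energy(.data$e_min, .data$n,
                                              temperature, boltzmann_k))
}

#' Assemble a ranked rescoring report
#'
#' Within each ligand, clusters are sorted by `delta_g` ascending (most
#' negative, i.e. most favorable, first) and given a `cluster_rank`;
#' ligands are then ordered by their best (lowest) `delta_g`. Ties are
#' broken by `n` descending, then `ligand_id` lexicographically — a stable,
#' fully deterministic ordering.
#'
#' @param scored A scored cluster tibble covering one or more ligands
#'   (columns `ligand_id`, `n`, `representative_pose`, `e_min`, `e_mean`,
#'   `delta_g`, `com_x`, `com_y`, `com_z`), e.g. rows of
#'   [score_clusters()] output bound together.
#' @param parameters Named list of run parameters echoed into the report
#'   (radius, mass weighting, temperature, Boltzmann constant, ...).
#' @return An object of class `rescore_report`: list with `entries` (the
#'   ranked tibble with columns `ligand_id`, `cluster_rank`, `n_poses`,
#'   `representative_pose`, `e_min`, `e_mean`, `delta_g`, `com_x`, `com_y`,
#'   `com_z`) and `parameters`.
#' @export
rank_report <- function(scored, parameters = list()) {
  if (nrow(scored) == 0) abort("empty input: nothing to rank")
  stopifnot(all(c("ligand_id", "n", "delta_g") %in% names(scored)))
  entries <- scored |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::arrange(.data$delta_g, dplyr::desc(.data$n), .by_group = TRUE) |>
    dplyr::mutate(cluster_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::mutate(.best = min(.data$delta_g),
                  .best_n = .data$n[which.min(.data$delta_g)]) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.best, dplyr::desc(.data$.best_n),
                   .data$ligand_id, .data$cluster_rank) |>
    dplyr::transmute(
      .data$ligand_id, .data$cluster_rank, n_poses = .data$n,
      .data$representative_pose, .data$e_min, .data$e_mean, .data$delta_g,
      .data$com_x, .data$com_y, .data$com_z
    )
  structure(list(entries = entries, parameters = parameters),
            class = "rescore_report")
}

#' Per-cluster and per-ligand energy summaries
#'
#' @param scored A scored cluster tibble (see [rank_report()]) or a
#'   `rescore_report`.
#' @param poses Optional pose table; when given, the per-ligand summary
#'   includes the energy spread (max - min member energy) of the largest
#'   cluster, recomputed from the member energies.
#' @return A list with `clusters` (per cluster: `ligand_id`, `n`, `e_min`,
#'   `e_mean`, `delta_g`) and `ligands` (per ligand: `n_clusters`,
#'   `largest_cluster`, and `spread_largest` when `poses` is supplied).
#' @export
cluster_energy_summary <- function(scored, poses = NULL) {
  if (inherits(scored, "rescore_report")) {
    scored <- dplyr::rename(scored$entries, n = "n_poses")
  }
  clusters <- dplyr::select(scored, dplyr::any_of(
    c("ligand_id", "cluster_rank", "n", "e_min", "e_mean", "delta_g")))
  ligands <- scored |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     largest_cluster = max(.data$n),
                     best_delta_g = min(.data$delta_g),
                     .groups = "drop")
  if (!is.null(poses)) {
    spread <- purrr::map_dfr(split(poses, poses$ligand_id), function(lig) {
      cl <- cluster_poses(lig, check_atoms = FALSE)
      big <- cl$clusters$cluster[which.max(cl$clusters$n)]
      members <- cl$assignments$pose_id[cl$assignments$cluster == big]
      en <- cl$coms$energy[cl$coms$pose_id %in% members]
      tibble(ligand_id = lig$ligand_id[1],
             spread_largest = max(en) - min(en))
    })
    ligands <- dplyr::left_join(ligands, spread, by = "ligand_id")
  }
  list(clusters = clusters, ligands = ligands)
}

#' Cluster and rescore a multi-ligand pose table end to end
#'
#' The whole post-docking pipeline in one call: split the pose table by
#' ligand, cluster each ligand's poses by COM at `radius`
#' ([cluster_poses()]), score every cluster with the entropy-corrected
#' free energy ([cluster_free_energy()]), and rank clusters and ligands
#' ([rank_report()]).
#'
#' @param poses A pose table with one or more ligands.
#' @param radius Cluster radius in Angstrom (default 4).
#' @param mass_weighted Mass-weighted COM (default `TRUE`).
#' @inheritParams kT
#' @param boxes Optional site-box tibble ([build_site_boxes()]); when
#'   given, poses whose COM falls outside the union of boxes are dropped
#'   before clustering.
#' @param check_atoms Passed to [validate_pose_ensemble()].
#' @return A `rescore_report` (see [rank_report()]); its `parameters`
#'   element records every parameter used.
#' @examples
#' poses <- simulate_ensemble(cluster_sizes = c(5, 3), seed = 7)$poses
#' rescore_poses(poses)
#' @export
rescore_poses <- function(poses, radius = 4.0, mass_weighted = TRUE,
                          temperature = 298.15,
                          boltzmann_k = 0.0019872041,
                          boxes = NULL, check_atoms = TRUE) {
  validate_pose_ensemble(poses, check_atoms = check_atoms)
  if (!is.null(boxes)) {
    poses <- filter_poses_in_site(poses, boxes, mass_weighted = mass_weighted)
    if (nrow(poses) == 0) abort("no poses remain after site filtering")
  }
  scored <- purrr::map_dfr(split(poses, poses$ligand_id), function(lig) {
    cl <- cluster_poses(lig, radius = radius, mass_weighted = mass_weighted,
                        check_atoms = check_atoms)
    score_clusters(cl, temperature = temperature, boltzmann_k = boltzmann_k)
  })
  rank_report(scored, parameters = list(
    radius = radius,
    mass_weighted = mass_weighted,
    temperature = temperature,
    boltzmann_k = boltzmann_k,
    kT = kT(temperature, boltzmann_k),
    site_filtered = !is.null(boxes)
  ))
}

#' @export
print.rescore_report <- function(x, ...) {
  p <- x$parameters
  cat("Rescoring report: ", length(unique(x$entries$ligand_id)),
      " ligand(s), ", nrow(x$entries), " cluster(s)\n", sep = "")
  if (length(p)) {
    cat("  radius = ", p$radius, " A, T = ", p$temperature,
        " K, kT = ", signif(p$kT, 6), " kcal/mol\n", sep = "")
  }
  cat("  delta_g = e_min - kT*ln(n); ligands ordered by best delta_g\n\n")
  print(x$entries, ...)
  invisible(x)
}

#' Tidy a rescoring report
#'
#' @param x A `rescore_report`.
#' @param ... Unused.
#' @return The ranked entries tibble, one row per cluster.
#' @method tidy rescore_report
#' @export
tidy.rescore_report <- function(x, ...) x$entries

#' Per-ligand summary of a rescoring report
#'
#' @param x A `rescore_report`.
#' @param ... Unused.
#' @return One row per ligand in rank order: `ligand_id`, `n_clusters`,
#'   `largest_cluster`, `best_e_min`, `best_delta_g`.
#' @method glance rescore_report
#' @export
glance.rescore_report <- function(x, ...) {
  x$entries |>
    dplyr::group_by(.data$ligand_id) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     largest_cluster = max(.data$n_poses),
                     best_e_min = min(.data$e_min),
                     best_delta_g = min(.data$delta_g),
                     .groups = "drop") |>
    dplyr::arrange(.data$best_delta_g)
}

#' Plot a rescoring report
#'
#' Dot plot of cluster free energies per ligand, sized by cluster
#' population; the entropy correction is what separates `delta_g` from
#' `e_min`, so both are shown.
#'
#' @param object A `rescore_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rescore_report
#' @export
autoplot.rescore_report <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$entries, c("e_min", "delta_g"),
                             names_to = "score", values_to = "kcal_mol")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ligand_id,
                                    y = .data$kcal_mol,
                                    colour = .data$score,
                                    size = .data$n_poses)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = NULL, y = "kcal/mol",
                  title = "Cluster energies and entropy-corrected free energies",
                  size = "cluster N", colour = NULL) +
    ggplot2::theme_minimal()
}
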