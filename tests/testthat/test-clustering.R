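test_that("center of mass: identity, symmetry, and mass weighting", {
  one <- tibble::tibble(element = "N", x = 2, y = -1, z = 0)
  expect_equal(center_of_mass(one), c(x = 2, y = -1, z = 0))
  expect_equal(center_of_mass(one, mass_weighted = FALSE),
               c(x = 2, y = -1, z = 0))

  two <- tibble::tibble(element = c("C", "C"), x = c(0, 2), y = 0, z = 0)
  expect_equal(center_of_mass(two), c(x = 1, y = 0, z = 0))

  # O at origin, C at x=1: weighted mean 12.011/(15.999+12.011)
  oc <- tibble::tibble(element = c("O", "C"), x = c(0, 1), y = 0, z = 0)
  expect_equal(center_of_mass(oc)[["x"]], 0.4288111, tolerance = 1e-6)
  expect_equal(center_of_mass(oc, mass_weighted = FALSE)[["x"]], 0.5)

  expect_warning(m <- atomic_mass(c("C", "Xq")), "unknown element")
  expect_equal(m, c(12.011, 12.011))
})

test_that("worked 5-pose example gives the hand-enumerated partition", {
  poses <- pose_table_from_coms(
    rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(11, 0, 0), c(30, 0, 0)),
    c(-9.0, -8.0, -7.5, -6.0, -5.0))
  cl <- cluster_poses(poses, radius = 4)
  expect_equal(partition_of(cl), list(
    list(members = c(1L, 2L), representative = 1L),
    list(members = c(3L, 4L), representative = 3L),
    list(members = 5L, representative = 5L)
  ))
  expect_equal(cl$clusters$e_min, c(-9.0, -7.5, -5.0))
  expect_equal(cl$clusters$e_mean, c(-8.5, -6.75, -5.0))
  expect_true(partition_check(cl, poses))
})

test_that("degenerate ensembles: single pose, coincident COMs, empty", {
  single <- pose_table_from_coms(matrix(c(1, 2, 3), 1, 3), -4.2)
  cl <- cluster_poses(single)
  expect_equal(cl$clusters$n, 1L)
  expect_equal(cl$clusters$representative_pose, 1L)

  co <- pose_table_from_coms(matrix(1, 6, 3), c(-3, -9, -5, -1, -9.5, -2))
  cl2 <- cluster_poses(co, radius = 0.5)
  expect_equal(nrow(cl2$clusters), 1L)
  expect_equal(cl2$clusters$n, 6L)
  expect_equal(cl2$clusters$e_min, -9.5)
  expect_equal(cl2$clusters$representative_pose, 5L)

  expect_error(cluster_poses(single[0, ]), "empty")
})

test_that("leader clustering matches the independent naive oracle", {
  set.seed(202)
  for (trial in 1:120) {
    n <- sample(2:12, 1)
    com <- matrix(runif(3 * n, 0, 12), n, 3)
    energy <- round(rnorm(n, -7, 1.5), 2)  # rounding forces energy ties
    radius <- runif(1, 0.5, 8)
    poses <- pose_table_from_coms(com, energy)
    cl <- cluster_poses(poses, radius = radius)
    expect_identical(partition_of(cl),
                     naive_leader(poses$pose_id, com, energy, radius))
    expect_true(partition_check(cl, poses))
  }
})

test_that("radius endpoints: all-singletons and single-cluster regimes", {
  set.seed(7)
  com <- matrix(runif(30, 0, 20), 10, 3)
  poses <- pose_table_from_coms(com, rnorm(10, -6))
  d <- dist(com)
  below <- cluster_poses(poses, radius = min(d) * 0.99)
  expect_equal(nrow(below$clusters), 10L)
  above <- cluster_poses(poses, radius = max(d) * 1.01)
  expect_equal(nrow(above$clusters), 1L)
})

test_that("cluster statistics are invariant under a common rigid motion", {
  sim <- simulate_ensemble(cluster_sizes = c(6, 4, 3), seed = 55)
  cl0 <- cluster_poses(sim$poses)
  set.seed(31)
  for (trial in 1:10) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    t3 <- rnorm(3, sd = 30)
    xyz <- as.matrix(sim$poses[, c("x", "y", "z")]) %*% t(q)
    moved <- dplyr::mutate(sim$poses,
                           x = xyz[, 1] + t3[1],
                           y = xyz[, 2] + t3[2],
                           z = xyz[, 3] + t3[3])
    cl1 <- cluster_poses(moved)
    expect_equal(cl1$clusters$n, cl0$clusters$n)
    expect_equal(cl1$clusters$representative_pose,
                 cl0$clusters$representative_pose)
    expect_equal(cl1$clusters$e_min, cl0$clusters$e_min)
    expect_equal(cl1$clusters$e_mean, cl0$clusters$e_mean)
    expect_identical(dplyr::arrange(cl1$assignments, pose_id),
                     dplyr::arrange(cl0$assignments, pose_id))
  }
})

test_that("clustering is determined by pose content, not atom row order", {
  sim <- simulate_ensemble(cluster_sizes = c(5, 5), seed = 9)
  cl0 <- cluster_poses(sim$poses)
  # reverse the atom rows inside every pose: geometry unchanged
  reversed <- sim$poses |>
    dplyr::group_by(pose_id) |>
    dplyr::slice(rev(dplyr::row_number())) |>
    dplyr::ungroup()
  cl1 <- cluster_poses(reversed)
  expect_equal(cl1$clusters, cl0$clusters)
  expect_identical(cluster_poses(sim$poses)$clusters, cl0$clusters)
})

test_that("partition_check flags corrupted partitions", {
  sim <- simulate_ensemble(cluster_sizes = c(4, 4), seed = 13)
  cl <- cluster_poses(sim$poses)
  expect_true(partition_check(cl, sim$poses))

  moved <- cl
  k1 <- moved$assignments$cluster[1]
  moved$assignments$cluster[1] <- ifelse(k1 == 1L, 2L, 1L)
  expect_message(res <- partition_check(moved, sim$poses), "partition_check")
  expect_false(as.logical(res))

  expect_false(as.logical(
    suppressMessages(partition_check(cl, sim$poses, radius = 1e-6))))
})

test_that("tidy, glance and autoplot expose the clustering", {
  sim <- simulate_ensemble(cluster_sizes = c(4, 2), seed = 2)
  cl <- cluster_poses(sim$poses)
  td <- tidy(cl)
  expect_equal(td$ligand_id, rep("synthetic", 2))
  expect_equal(td$n, c(4L, 2L))
  gl <- glance(cl)
  expect_equal(gl$n_poses, 6L)
  expect_equal(gl$n_clusters, 2L)
  expect_s3_class(autoplot(cl), "ggplot")
})
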