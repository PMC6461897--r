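test_that("multi-MODEL PDBQT parses to poses with energies in file order", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  coords <- list(
    matrix(c(1, 2, 3), 1, 3),
    matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE),
    matrix(c(5, 5, 5), 1, 3)
  )
  # heterogeneous atom counts are deliberate: only the validator's
  # check_atoms flag distinguishes this from corrupt input
  expect_error(
    read_pdbqt_poses(write_pdbqt_fixture(path, c(-7.9, -7.5, -6.0), coords)),
    "atom count"
  )

  coords <- list(matrix(c(1, 2, 3), 1, 3), matrix(c(0, 1, 0), 1, 3),
                 matrix(c(5, 5, 5), 1, 3))
  ens <- read_pdbqt_poses(
    write_pdbqt_fixture(path, c(-7.9, -7.5, -6.0), coords), "bi6015")
  expect_equal(unique(ens$ligand_id), "bi6015")
  expect_equal(ens$pose_id, 1:3)
  expect_equal(ens$energy, c(-7.9, -7.5, -6.0))
  expect_equal(unlist(ens[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(ens$element, rep("C", 3))
})

test_that("PDBQT error paths name the failing block or line", {
  path <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:   -7.0  0 0",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL 2",
    "ATOM      1  C1  LIG A   1       1.000   0.000   0.000  1.00  0.00",
    "ENDMDL"), path)
  expect_error(read_pdbqt_poses(path), "MODEL block 2")

  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:   -7.0  0 0",
    "ATOM      1  C1  LIG A   1       x.bad   0.000   0.000  1.00  0.00",
    "ENDMDL"), path)
  expect_error(read_pdbqt_poses(path), "line 3")

  # no MODEL blocks: single pose iff an energy REMARK exists
  writeLines(c(
    "REMARK VINA RESULT:   -5.5  0 0",
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00"),
    path)
  one <- read_pdbqt_poses(path)
  expect_equal(nrow(one), 1L)
  expect_equal(one$energy, -5.5)

  writeLines(
    "ATOM      1  C1  LIG A   1       1.000   2.000   3.000  1.00  0.00",
    path)
  expect_error(read_pdbqt_poses(path), "REMARK")
})

test_that("pose-table round-trip is bit-identical and equals the PDBQT parse", {
  pdbqt <- withr::local_tempfile(fileext = ".pdbqt")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  set.seed(4)
  coords <- replicate(3, matrix(rnorm(9, sd = 5), 3, 3), simplify = FALSE)
  ens <- read_pdbqt_poses(
    write_pdbqt_fixture(pdbqt, c(-8.123, -7.5, -3.001), coords))
  write_pose_table(ens, tsv)
  back <- read_pose_table(tsv)
  expect_identical(back$x, ens$x)
  expect_identical(back$energy, ens$energy)
  expect_equal(as.data.frame(back), as.data.frame(ens))
})

test_that("pose-table reader enforces the dialect contract", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ens <- pose_table_from_coms(matrix(1:6, 2, 3), c(-5, -4))
  write_pose_table(ens, tsv)
  got <- read_pose_table(tsv)
  expect_equal(nrow(got), 2L)
  expect_equal(got$energy, c(-5, -4))

  # conflicting energies within one pose id
  bad <- ens
  bad$pose_id <- 1L
  write_pose_table(pose_table_from_coms(matrix(1:6, 2, 3), c(-5, -4)), tsv)
  txt <- readLines(tsv)
  txt <- sub("^lig\t2", "lig\t1", txt)
  writeLines(txt, tsv)
  expect_error(read_pose_table(tsv), "conflicting energies")

  writeLines("ligand_id\tpose_id\tenergy", tsv)
  suppressWarnings(expect_error(read_pose_table(tsv),
                                "missing column|no poses"))

  writeLines(paste(c("ligand_id", "pose_id", "energy", "atom_name",
                     "element", "x", "y", "z"), collapse = "\t"), tsv)
  expect_error(read_pose_table(tsv), "no poses")
})

test_that("receptor PDB reading: metadata, altLoc rule, error paths", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  rec <- make_toy_receptor(tibble::tibble(
    residue_name = c("SER", "VAL", "GLY"),
    residue_number = c(181L, 178L, 237L),
    x = c(5, 0, 20), y = c(5, 0, 0), z = c(5, 0, 0)
  ))
  write_receptor_pdb(rec, pdb)
  got <- read_receptor_pdb(pdb)
  expect_equal(length(unique(paste(got$chain_id, got$residue_number))), 3L)
  expect_equal(get_ca(got, "S181"), c(x = 5, y = 5, z = 5))
  expect_false(any(got$is_het))

  # altLoc: first conformer kept
  lines <- readLines(pdb)
  idx <- grep(" CA .SER", lines)[1]
  ca_line <- lines[idx]
  a_var <- sub("^(.{16}).", "\\1A", ca_line)
  b_var <- sub("^(.{16}).", "\\1B", ca_line)
  b_var <- sub("5\\.000   5\\.000   5\\.000", "9.000   9.000   9.000", b_var)
  lines[idx] <- a_var
  writeLines(append(lines, b_var, after = idx), pdb)
  expect_message(got2 <- read_receptor_pdb(pdb), "alternate-location")
  expect_equal(sum(got2$atom_name == "CA" & got2$residue_number == 181), 1L)
  expect_equal(get_ca(got2, "S181"), c(x = 5, y = 5, z = 5))

  writeLines(c("this is", "not a PDB file"), pdb)
  expect_error(read_receptor_pdb(pdb), "no ATOM records")
})

test_that("report writing is deterministic and JSON round-trips", {
  sim <- simulate_ensemble(cluster_sizes = c(4, 2), seed = 3)
  report <- rescore_poses(sim$poses)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(report, tsv, format = "tsv")
  lines <- readLines(tsv)
  expect_equal(lines[1], paste(c("ligand_id", "cluster_rank", "n_poses",
                                 "representative_pose", "e_min", "e_mean",
                                 "delta_g", "com_x", "com_y", "com_z"),
                               collapse = "\t"))
  expect_equal(length(lines), 1L + nrow(report$entries))
  # fixed 4-decimal rendering => byte-identical rewrite
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(report, tsv2, format = "tsv")
  expect_identical(readLines(tsv2), lines)

  json <- withr::local_tempfile(fileext = ".json")
  write_report(report, json, format = "json")
  back <- read_report_json(json)
  expect_equal(back$entries$delta_g, round(report$entries$delta_g, 4))
  expect_equal(back$entries$n_poses, report$entries$n_poses)
  expect_equal(back$parameters$radius, report$parameters$radius)

  empty <- structure(list(entries = report$entries[0, ], parameters = list()),
                     class = "rescore_report")
  expect_error(write_report(empty, tsv), "empty report")
  expect_error(write_report(report, tsv, format = "xml"), "unknown")
})
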