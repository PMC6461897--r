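Package: dockrescore
Title: Clustering and Entropy-Corrected Rescoring of Docked Ligand Pose Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of ensemble molecular docking campaigns. Reads
    multi-pose AutoDock Vina PDBQT output (or a simple tabular pose dialect),
    groups poses of each ligand into disjoint clusters by center-of-mass
    distance at a fixed radius (leader clustering with energy-ordered
    seeding), selects the lowest-energy representative of each cluster, and
    scores clusters with the entropy-corrected free energy
    E_min - kT*ln(N), where N is the cluster population. Also builds
    C-alpha-anchored cubic binding-site boxes from a receptor structure and a
    residue list, ranks ligands by their best cluster free energy, and ships
    a seeded generator of synthetic pose ensembles with planted cluster
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
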