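---
title: "Clustering and entropy-corrected rescoring of docked pose ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and entropy-corrected rescoring of docked pose ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockrescore)
library(dplyr)
```

## The problem

Ensemble docking campaigns (AutoDock Vina with `num_modes` pushed into the
hundreds or thousands) return large pools of candidate ligand poses, each
with an engine-assigned binding energy in kcal/mol. The single lowest-energy
pose is a noisy statistic: scoring functions have errors of the order of the
gap between the top poses, and a pose that sits alone at a slightly lower
energy is often less trustworthy than a broad basin of near-identical poses.
A standard remedy is to group poses geometrically and reward *population*:
a basin visited by many independent docking runs is read as a proxy for
configurational (entropic) stability of that binding mode.

`dockrescore` implements that post-processing step: center-of-mass (COM)
clustering of each ligand's poses at a fixed radius, selection of the
lowest-energy pose as each cluster's representative, and cluster scoring by

$$\Delta G \;=\; E_{\min} + \left(-kT \ln N\right)$$

where $E_{\min}$ is the representative's (lowest) binding energy and $N$ the
cluster population. Ligands are then ranked by their best (lowest) cluster
$\Delta G$. The historical use case is the comparison of nitro-positional
isomers of the HNF4α inhibitor BI6015 docked into the receptor's
myristic-acid site, but every step is generic.

## The clustering rule

The algorithm is *leader clustering* on pose centers of mass:

1. Compute each pose's COM (mass-weighted by default; masses come from a
   standard-atomic-weight table keyed by element symbol).
2. Process poses in ascending energy order, ties broken by ascending pose
   index.
3. Each pose joins the earliest-created cluster whose *representative* COM
   lies within the radius (Euclidean, closed ball); otherwise it founds a
   new cluster with itself as representative.

Because seeding is energy-ordered, the representative of every cluster is
automatically its lowest-energy member, so "select the lowest-energy
structure per cluster" needs no separate pass. The partition is disjoint
and exhaustive, and the procedure is completely deterministic: input row
order never matters, and equal energies fall back to the pose index.

Two variants of radius-based pose clustering exist in the literature:
distance to the cluster *representative* (leader) versus distance to a
running *centroid*. The representative-anchored form was chosen because it
makes the lowest-energy-representative rule exact by construction and is
the common convention for docked-pose pools; the anchor choice is recorded
in every result object. Distances are on COMs, not RMSD — pose similarity
here means "same place in the site", not "same conformation".

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `radius` | 4.0 | Å | the conventional COM cutoff for docked-pose clustering |
| `mass_weighted` | `TRUE` | — | it is a center of *mass*; a geometric-centroid flag exists because docking files usually lack most hydrogens and masses are approximate |
| `temperature` | 298.15 | K | room-temperature convention for docking scores; the source protocol does not state a temperature, so it is explicit and overridable |
| `boltzmann_k` | 0.0019872041 | kcal/(mol·K) | gives $kT \approx 0.59248$ kcal/mol at 298.15 K |
| `edge` (site boxes) | 15.0 | Å | "a 15 Å box" around a residue's Cα is read as the cube's full **edge** (half-width 7.5 Å), matching how docking engines specify box sizes; the alternative half-width reading is available by passing `edge = 30` |

Unknown element symbols fall back to the mass of carbon with a warning
rather than aborting: PDBQT atom typing is nonstandard, and a run should
not die on one exotic atom type whose mass barely moves a 20-atom COM.

## Site boxes

`build_site_boxes()` anchors one axis-aligned cube on the Cα of each
residue in a binding-site list (e.g. the myristic-acid contact residues
V178, S181, Q185, R226, L236, G237, M252, S256, I259, Q345, I346 of
HNF4α). `get_ca()` verifies the residue's identity (three-letter name
versus the expected one-letter code) before trusting its coordinate, and
refuses to guess when a residue number occurs in several chains. Site
membership of a pose is tested on its COM against the closed cube — a COM
exactly on a face is inside. An any-atom overlap mode is deliberately out
of scope: membership and clustering should use the same geometry.

## The free-energy score

`cluster_free_energy(e_min, n)` is the literal formula
$E_{\min} - kT\ln N$ on signed energies (favorable = negative). Useful
identities, all tested: $\Delta G(N{=}1) = E_{\min}$ exactly;
$\Delta G(N) - \Delta G(1) = -kT\ln N$ to $10^{-9}$; $\Delta G$ is strictly
decreasing in $N$ and increasing in $E_{\min}$. With the published campaign
sizes, an $E_{\min}$ of $-7.9$ kcal/mol in a 91-pose cluster scores
$-10.57$ kcal/mol, while a 521-pose cluster needs only
$E_{\min}\approx-7.24$ to reach $-10.95$ — a larger basin can beat a deeper
single minimum, which is the point of the correction.

One reporting caveat: the study this heuristic comes from also quotes
*positive* per-cluster "average energies" (10.32/3.43/29.87 kcal/mol).
Those values cannot be reconciled with signed Vina affinities, whose means
are negative; `dockrescore` reports signed arithmetic means (`e_mean`) and
does not attempt to emulate the positive values.

Whether a campaign pools poses from all residue-centered docking boxes
before clustering, or clusters each box's pool separately, is a protocol
choice the tool stays agnostic about: it clusters whatever ensembles it is
given, and `filter_poses_in_site()` exists for explicit post-hoc pooling.

## Synthetic ensembles: what a green test establishes

`simulate_ensemble()` generates pose ensembles with *planted* cluster
structure: cluster COM centers on a lattice (or user-supplied), within-
cluster COM displacements drawn uniformly from a ball of radius
`scatter_max` (hard truncation, not a Gaussian tail), per-pose energies as
a per-cluster base plus Gaussian jitter, and atoms as a rigid all-carbon
template, randomly rotated and shifted so the realized COM equals the
target exactly. In guarantee mode (centers $\geq 2r + 0.5$ Å apart,
scatter $\leq r/2$) exact recovery of the planted partition by leader
clustering is a theorem — any two same-cluster poses are within $2\cdot
r/2 = r$ of each other and any two cross-cluster poses are at least
$r + 0.5$ apart — and the tests confirm it for 100/100 seeds, including
one ensemble with the published cluster sizes 27/91/521.

Defaults describe a desk-scale analogue of a real campaign: base energies
stepped by 0.5 kcal/mol from −8, within-cluster jitter of 0.25 kcal/mol
(the spread seen among near-duplicate Vina poses), 22 atoms per pose (a
drug-like ligand's heavy-atom count), scatter of 2 Å against the 4 Å
radius. What the generator does *not* emulate: real ligand chemistry and
torsions, Vina's energy model, correlation between geometry and energy,
and overlapping or elongated basins. A green recovery test therefore
establishes the correctness of the clustering *rule*, not the scientific
adequacy of COM clustering for any particular receptor.

The generator runs on its own RNG stream derived from `seed` (the global
RNG state is saved and restored), so identical seeds give bit-identical
ensembles anywhere.

## Numerical choices

* Ties in energy order fall back to the pose index; a pose within radius
  of several representatives joins the earliest-created cluster. Both
  rules exist purely for determinism.
* Cluster output is sorted by `e_min` ascending; ligand ranking breaks
  `delta_g` ties by larger $N$, then lexicographic ligand id.
* Pose tables serialize coordinates and energies with `%.17g` and are
  parsed with the C library's `strtod`, so write/read round-trips are
  bit-identical. Reports render numbers at fixed 4-decimal precision so
  repeated runs diff cleanly; the JSON report embeds the parameters, tool
  version and input checksums, and round-trips exactly at that precision.
* Energies are used verbatim from the input file — no sign or magnitude
  normalization anywhere.

## A worked example

```{r example}
poses <- dplyr::bind_rows(
  simulate_ensemble(c(27L, 3L), energy_base = c(-7.3, -6.0),
                    seed = 101, ligand_id = "ortho")$poses,
  simulate_ensemble(c(91L, 5L), energy_base = c(-7.9, -6.5),
                    seed = 102, ligand_id = "meta")$poses,
  simulate_ensemble(c(521L, 4L), energy_base = c(-7.25, -6.1),
                    seed = 103, ligand_id = "para")$poses
)

report <- rescore_poses(poses)
tidy(report)
glance(report)
```

The ligand with the deepest raw minimum need not win: a large cluster at a
slightly higher $E_{\min}$ can take the best $\Delta G$ through the
$-kT\ln N$ term, mirroring how a 521-pose basin outscored a deeper
91-pose one in the published campaign.

```{r plot, fig.width = 6, fig.height = 4}
autoplot(report)
```

## Limitations

* The score is exactly the stated heuristic — no MM-PBSA, FEP or other
  physical free-energy method, and no claim that $-kT\ln N$ is a
  thermodynamic entropy; $N$ depends on the docking engine's sampling
  settings.
* COM clustering cannot separate binding modes that share a center of
  mass (e.g. a ring flip), and there is no RMSD or symmetry-corrected
  option.
* PDBQT parsing covers the Vina multi-MODEL dialect; mol2/SDF, bond
  perception, protonation and charge assignment are out of scope.
* Hydrogens are used exactly as present in the file; none are added.
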