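---
title: "Assessing glycosaminoglycan mimicry from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing glycosaminoglycan mimicry from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagmimic)
library(dplyr)
```

## The problem

Glycosaminoglycans (GAGs) such as heparan sulfate are sulfated linear
polysaccharides whose protein interactions drive growth-factor signalling.
They are nearly impossible to develop as drugs — heterogeneous, hard to
synthesize — which motivates *non-saccharide GAG mimetics* (NSGMs):
homogeneous, synthetic, aromatic scaffolds carrying sulfate groups in a
GAG-like display. The design question is whether a given NSGM *structurally*
mimics a target GAG sequence, not merely whether a static overlay of sulfate
positions looks similar. Both molecule classes are highly flexible, so the
honest comparison is between *conformational ensembles*: in free solution
and in the protein-bound state.

`gagmimic` implements that comparison as a three-leg sequential decision
procedure over molecular-dynamics ensembles:

1. **Free state** — do the candidate's end-to-end distance (EED) and
   minimum-volume enclosing ellipsoid (MVEE) distributions overlap the
   reference GAG's? This is a chain-length/shape mimicry screen.
2. **Binding site** — does externally produced docking evidence place the
   candidate in the same protein site as the GAG, with a comparable fitness
   score? (Docking is ingested, never computed here.)
3. **Bound state** — in the protein-bound ensembles, do shape distributions,
   residue-level hydrogen-bond occupancy profiles, and total binding
   free-energy intervals (ingested from external MM/PB(GB)SA tables) agree?

A failed leg short-circuits the procedure; candidates are ranked by legs
passed, then by a quantitative overlap score.

## Data model and conventions

An ensemble is a topology (ordered atom table plus bonds) with a
`frames x atoms x 3` coordinate array in Angstrom and strictly increasing
frame times in picoseconds. Times default to a 1 ps spacing, the typical
save cadence of a 20 ns explicit-solvent production run; such a run saved
from 1 ps onward holds 20000 frames. Analysis windows are half-open
`(start, end]` with a stride anchored at the window start, so the canonical
MM/PB(GB)SA subsample — (10 ns, 20 ns] every 10 ps — contains exactly 1000
conformers:

```{r window}
top <- topology(tibble::tibble(atom_name = paste0("C", 1:4), element = "C",
                               residue_name = "X", residue_id = 1L))
traj <- conformer_ensemble(top, array(0, dim = c(20000, 4, 3)), times = 1:20000)
n_frames(select_frames(traj, frame_window(10000, 20000, 10)))
```

Coordinates are always Angstrom; there is no unit option. Alternate
locations in PDB input keep the first altloc (with a warning) — the format
gives no principled rule, and the first location is the conventional
highest-occupancy entry.

## Shape descriptors

**End-to-end distance.** The distance between two designated terminal
atoms, per frame. Published analyses rarely say *which* atoms; the package
therefore takes a user-specified pair and, by default, fixes the two heavy
atoms with maximum separation in the first frame (`auto_endpoints()`). The
provenance of the pair (`user_specified` / `auto_max_extent`) is carried in
the series and in every report, because the choice changes the number.

**Minimum-volume enclosing ellipsoid.** The smallest ellipsoid
`{x : (x - c)' A (x - c) <= 1}` containing the (by default heavy-atom)
point cloud, computed by Khachiyan's dual coordinate-ascent with
Wolfe–Atwood away steps. Each iteration reweights the most-violating (or
most over-weighted support) point; iteration stops when the `(1 + eps)`
enclosure factor falls below the tolerance (default `1e-6`, cap 10000
iterations — away steps give the linear convergence the plain ascent
lacks). Semi-axes are the reciprocal square roots of the shape-matrix
eigenvalues; volume is `4/3 * pi * a * b * c`. Because published tables do
not always say whether "axial length" means a semi-axis or a full axis,
`ellipsoid_descriptors()` reports both. Shape classes (spherical, prolate,
oblate, scalene) compare axes at a 2% relative equality tolerance — the
literature descriptions are qualitative, and 2% separates genuinely
distinct axes from numerical ties. Hydrogens are excluded by default
because ring and sulfate geometry, not hydrogen positions, carry molecular
shape.

```{r mvee}
cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
glance(mvee(cube))   # circumscribed sphere: radius sqrt(3), volume 4*pi*sqrt(3)
```

**Superposition and RMSD.** Optimal rigid superposition is the Kabsch SVD
construction restricted to proper rotations; `rmsd_to_average()` iterates
superposition against a running mean until the mean moves by less than
`1e-6` Angstrom RMSD, then reports per-frame RMSD to the converged mean —
the standard bound-ligand stability measure. Positional PCA removes
rigid-body motion the same way before diagonalizing the 3N x 3N
covariance, so the eigenvalues measure conformational, not diffusive,
variance.

## Conformer clustering

The clustering contract is radius-based: the smallest k such that every
frame lies within a fixed RMSD (default 2.0 Angstrom, the conventional
conformational-family cutoff) of its cluster's *medoid* frame. The medoid —
a real conformation — is reported rather than a coordinate mean, because a
mean of dissimilar conformers is not a structure. The distance space is
pairwise optimal-superposition RMSD: clustering must be rigid-motion
invariant, and a shared reference orientation misplaces frames when the
conformers are very dissimilar. k-means (10 seeded restarts per k,
incrementing k until the radius holds) runs on a classical-MDS embedding of
that distance matrix; the defining radius check is then made on the
distances themselves, and the same seed always reproduces the same
assignment bitwise.

```{r cluster}
tpl <- list(matrix(rnorm(24, sd = 8), 8), matrix(rnorm(24, sd = 8), 8) + 30)
mix <- generate_conformer_mixture(tpl, c(0.6, 0.4), jitter_sd = 0.3,
                                  n_frames = 60, seed = 2)
glance(cluster_conformers(mix$ensemble, clustering_params(radius = 2, seed = 7)))
```

## Hydrogen bonds and occupancy

Detection is geometric: donor–acceptor distance at most 3.5 Angstrom and an
angle criterion at most 60 degrees, the cutoffs trajectory-analysis tools
conventionally apply. The 60 degree figure is meaningless without saying
*which* angle, so the convention is explicit and recorded in every output:
the default reads it as the deviation of the donor–hydrogen–acceptor angle
from linearity (so angle DHA at least 120 degrees); the alternative
(`theta_DH_DA`) bounds the angle between the D→H and D→A vectors. Donors
are N/O/S atoms with a bonded hydrogen; acceptors are all N/O/S atoms, so
sulfate and phenolate oxygens qualify. Structures without hydrogens are
refused outright — a distance-only fallback would silently change the
criterion.

A receptor residue's occupancy is the percentage of window frames in which
at least one intermolecular hydrogen bond touches any of its atoms; a
residue bonding twice in a frame still counts once, since occupancy
measures the *proportion of time* a residue engages the ligand. The window
is a required, recorded parameter (default: final 50% of frames, where a
bound complex has settled), because occupancies change meaning with their
denominator.

## Energetics are ingested, not computed

Binding free energies and their per-residue decompositions come from
external MM/PB(GB)SA runs as `residue,mean,sd` tables (kcal/mol) with a
mandatory `TOTAL` row. The package ranks dominant residues (most negative
mean, ties broken by identifier) and compares total-energy intervals
(mean ± sd) between candidate and reference. No energetic model is
evaluated here.

## The decision rule made explicit

Published ensemble comparisons are box plots judged by eye. The package
operationalizes them: for each metric, `overlap_index()` computes the
Jaccard overlap of the two interquartile ranges and the standardized mean
difference (pooled-sd denominator); a metric is "similar" when IQR overlap
is at least 0.25 and |SMD| at most 2.0. The defaults are deliberately
permissive — they encode "the boxes visibly overlap and the centers are
within two pooled standard deviations", the weakest reading under which the
qualitative published comparisons come out as stated — and both thresholds
are configurable and recorded in report provenance. The bound-state leg
adds an occupancy component (Jaccard of residue sets with occupancy >= 50%,
plus the absolute difference of mean occupancies; thresholds 0.5 and 25
points) and an energy component (pass on total-ΔG interval overlap, with
the top-3 dominant-residue Jaccard contributing to the score only — two
complexes can be equally stable through partly different residues).
Quartiles use the linear-interpolation convention (position `(n-1)p`), and
standard deviations the `n-1` denominator.

The overall verdict is `mimic` only when every evaluated leg passes,
`non_mimic` as soon as any completed leg fails (later legs are marked
`not_evaluated`, never silently computed), and `inconclusive` when evidence
for a leg is absent. Ranking orders by legs passed, then overall score,
then label. When several protein targets are compared, per-target reports
are ranked separately; any cross-target weighting is the user's explicit
choice, since no principled default exists.

## Synthetic fixtures and what passing tests show

Every analysis is tested against seeded generators with recorded ground
truth rather than against re-derived values:

- `generate_chain_ensemble()` — a freely jointed chain (1.5 Angstrom
  links), rescaled per frame so the terminal distance follows a truncated
  normal with planted mean and sd: the unimodal EED distribution the
  free-state leg consumes.
- `generate_conformer_mixture()` — discrete templates plus i.i.d. Gaussian
  jitter, with frame-to-template labels recorded: clustering ground truth.
- `generate_complex_with_hbonds()` — per-residue Bernoulli bond incidence
  realized as ideal linear N–H···O geometry at 2.9 Angstrom (or a 5
  Angstrom displacement), with the realized incidence matrix recorded:
  occupancy ground truth.
- `generate_energy_table()` — a planted dominant residue separated from the
  background by at least `gap` kcal/mol. With the default `noise_sd = 0`
  the margin holds exactly; positive `noise_sd` adds observation noise to
  the reported means, emulating the scatter of an end-point energy
  estimate, so narrow gaps are sometimes lost — the behaviour the recovery
  tests quantify.

These fixtures reproduce the *statistical* structure the methods assume —
unimodal shape distributions, well-separated conformational basins,
Bernoulli bond incidence — and none of the physics: no force field, no
solvent, no correlated motions, no ring-pucker dynamics. Passing tests
therefore demonstrate that the estimators recover planted truth under the
assumed statistical model, not that any particular molecule mimics any
particular GAG.

`synthetic_hexasaccharide_helix()` deserves its own caveat: it is an
idealized two-fold helix with an axial rise of 8.7 (skew-boat pucker) or
8.0 (chair) Angstrom per disaccharide, ring pseudo-atoms near the axis and
sulfate pseudo-atoms projecting radially. It is *synthetic* — built from
helix parameters, not from any experimental coordinate set — and stands in
for a real sulfated hexasaccharide only where a worked example needs a
molecule-shaped thin-rod point cloud (terminal span near 26 Angstrom,
scalene ellipsoid). Checks that require the experimental NMR heparin
structure (PDB accession 1HPN) run only when the user supplies a local copy
of that file; the suite does not ship it.

## Numerical choices and degenerate inputs

- MVEE: tolerance `1e-6` on the enclosure factor, 10000-iteration cap;
  coplanar input and non-convergence are explicit errors. Volumes are
  stable well below 0.1%, which a constrained log-det minimization cross-
  check confirms to ~1e-10 on random clouds.
- Superposition: at least 3 non-collinear atoms; reflections are never
  used (determinant +1), so mirror images score as different conformations.
- Bond inference: covalent-radii sum + 0.4 Angstrom, the standard
  crystallographic slack; a hydrogen bonds only to its nearest heavy atom.
- Zero-width IQRs in `overlap_index()`: identical point-IQRs count as
  overlap 1, distinct ones as 0; a zero pooled sd gives SMD 0 for equal
  means and infinite otherwise.
- Clustering tie-breaks: largest cluster by size, ties to the lower cluster
  index; labels are canonical by first occurrence, so frame permutation
  permutes labels consistently.
- Energy-table ranking ties break alphabetically by residue identifier.

## Problem sizes in the test suite

The suite regenerates every fixture at run time: shape and superposition
checks use 10–40-atom clouds; occupancy recovery uses a 4-residue complex
over 2000 frames; clustering recovery uses 100 seeded trials of planted
k in {1, 2, 3, 5} mixtures (8 atoms, 10 frames per cluster, templates
separated by more than 8 Angstrom RMSD, 0.3 Angstrom jitter); PCA
properties use up to 2000 frames. These sizes give the distributional
bounds their stated power (99% binomial and CLT intervals) while keeping
the full suite in the low tens of seconds.

## Known limitations

- The package analyzes ensembles; it does not produce them. Force-field
  choice, sampling adequacy and pucker restraints are upstream decisions
  that dominate the numbers the package compares.
- Docking evidence and binding energies are ingested as given; no attempt
  is made to judge their quality.
- Similarity thresholds encode a reasonable reading of qualitative
  published comparisons; they are defaults to be examined, not calibrated
  constants.
- Hydrogen-bond detection requires explicit hydrogens; ensembles stripped
  to heavy atoms cannot be profiled.
- MVEE is a convex summary: it cannot distinguish a bent rod from a
  straight one of equal extent, which is why the procedure pairs it with
  EED and, in the bound state, with interaction profiles.
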