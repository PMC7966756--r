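---
title: "Bound-water networks at antifreeze protein ice-binding sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bound-water networks at antifreeze protein ice-binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebound)
```

## The scientific problem

Antifreeze proteins (AFPs) depress the non-equilibrium freezing point of a
solution by adsorbing irreversibly onto specific planes of a seed ice
crystal. In the widespread microbial family of beta-helical AFPs, the
ice-binding site (IBS) is a flat face of the solenoid with no repetitive
sequence motif, and the working hypothesis for how such an irregular surface
recognizes ice is *anchored clathrate water*: the IBS organizes a shell of
semi-ordered waters whose geometry already resembles an ice plane, and these
waters merge with the quasi-liquid layer at the ice surface.

Crystal structures make this hypothesis quantitative. A well-refined
structure of a ~220-residue AFP carries several hundred ordered waters; the
subset held on the IBS shows recurring geometric motifs:

* a **zigzag chain** of ~12 waters over the IBS loop sub-site, with
  nearest-neighbour spacings near 2.9 Å and inter-water angles near 116°,
  close to the chair-ring geometry of the ice basal plane;
* a **linear trough** of ~6 waters in single file along inward-facing
  hydrophobic residues of the IBS beta-sheet, repeating at ~4.6 Å like rows
  of a prism plane;
* a **hydrophobic hydration ring** of ~10 waters encircling an exposed IBS
  phenylalanine at van-der-Waals contact (~3.4 Å to the nearest aromatic
  carbon).

This package measures those motifs from coordinates, generates ideal ice Ih
oxygen lattices to compare against, rigidly docks bound-water sets onto
ice-plane patches, and provides two companion estimators used in the same
kind of study: the CD fraction-unfolded melting midpoint, and the
hydrogen-bond forward-lifetime water residence time from trajectory event
tables. Every stage has a synthetic generator with planted ground truth, so
the full pipeline is testable with no external data.

## Structures, symmetry and water selection

`read_structure()` reads PDB or mmCIF coordinates (atom records through
bio3d; cell, space group and any `REMARK 290` operators from the header).
Alternate conformers are collapsed to the highest-occupancy copy (ties go to
altloc `A`), matching the usual deposition convention. Waters are residues
named `HOH`, `WAT` or `H2O`, and since deposited waters carry no hydrogens,
*all water geometry in this package is oxygen geometry*.

A crystallographic subtlety: the asymmetric unit rarely contains all the
waters that physically surround an IBS — some belong to symmetry mates.
`expand_symmetry()` therefore applies the space-group operators combined
with ±1 unit-cell translations to the waters and keeps every image within a
radius (default 6 Å) of the IBS selection, tagging copies `op_lmn` style.
Images within 0.1 Å of an existing atom are duplicates and dropped. Built-in
operator tables cover `P 1` and `P 21 21 21` (the relevant orthorhombic
group); other groups must supply operators in the file header. Note that
pure lattice translations are applied even in `P 1`: a periodic image is a
legitimate neighbour regardless of the point group.

"Waters on the IBS" is operationalized by `select_waters_near()`: any-atom
distance ≤ 4.0 Å (configurable) to the IBS residue ranges. No convention
fixes this cutoff, which is why it is a parameter rather than a constant;
4.0 Å comfortably includes first-shell hydrogen-bonded waters (2.5–3.5 Å)
while excluding second-shell ones. The default IBS definition
(`ibs_regions()`) is the compound loop + beta-sheet site of the 223-residue
fungal AFP scaffold: positions 19–25, 38–45, 123–129, 147–153, 174–180,
192–198 and 210–216.

## The ideal ice Ih lattice

`build_ice_lattice()` generates the oxygen sublattice of hexagonal ice: a
wurtzite-type arrangement with four oxygens per hexagonal cell, default
constants a = 4.52 Å and c = 7.36 Å (ice Ih near 0 °C). The internal
coordinate is chosen ideal, with the oxygens at the 4f positions with
z = 1/16. This is the value that makes the lattice tetrahedral: the bond
along the c axis then spans (1/2 − 2·1/16)·c = (3/8)·c = 2.76 Å, equal (for
the ideal c/a ratio) to the three bonds within each puckered bilayer; each
oxygen sits (3/16)·c — half a bond — from the midplane of the *adjacent*
bilayer. Because the experimental c/a = 1.628 is slightly below the ideal
1.633, the two bond flavours differ by ~0.008 Å (2.760 vs 2.768); tests
treat the bond length as 2.76 ± 0.02 Å for this reason.

`extract_plane_patch()` slices the lattice along the three low-index faces:
`basal` (0001), `prism1` (10-10) and `prism2` (11-20). The patch is the slab
of oxygens within a half-thickness (default 1.0 Å, one puckered bilayer) of
the best-populated plane offset near the lattice centre.
`characteristic_spacings()` reports the nearest-neighbour distance plus the
lengths of translations that map the patch onto itself (detected from the
generated points, so a finite patch works); for the default constants the
prism face repeats at 4.52 Å in-plane and 7.36 / 14.72 Å along c — the
values against which measured trough intervals (≈4.6 and ≈14.5–14.7 Å) are
compared. The small discrepancy between the ideal 4.52 Å and the ~4.6 Å
measured on real structures is real and deliberately *not* absorbed into the
lattice constants.

## Water networks and the three motifs

`build_network()` connects waters within 3.7 Å (the conventional display
cutoff for proximal bound waters, closed interval). `network_stats()`
reports edge distances and the angle at the middle water of every connected
triple i–j–k; "angles between adjacent waters" is interpreted as exactly
this vertex angle, the natural graph reading. Branch count is the number of
nodes of degree ≥ 3.

`find_linear_trough()` seeks the largest subset (≥ 3) of candidate waters
whose perpendicular residuals from a total-least-squares line all stay
within a tolerance (default 1.0 Å). Candidates are waters within 3.5 Å of
any side-chain atom of the anchor residues. Up to 12 candidates the search
enumerates subsets exhaustively (4096 subsets at most — cheap and exact, and
the scale of real troughs); beyond that, every candidate pair seeds a line,
inliers are collected and refined by TLS twice, and the best consensus wins.
Ties on size resolve toward the smallest total residual, then lexicographic
water ids. An absent trough is a result (`found = FALSE`), not an error.

`find_hydration_ring()` restricts waters to those within a contact cutoff
(default 4.5 Å) of the residue's side-chain carbons, connects them at 3.5 Å,
and finds the largest simple cycle by exact depth-first enumeration for up
to 15 candidates (a canonical smallest-start rule prevents double counting;
equal-length cycles resolve toward the smallest total circumference, then
lexicographic ids). Above 15 candidates a greedy nearest-neighbour walk is
used with a warning — real hydration rings live well below that scale. When
no cycle of ≥ 4 waters exists, the longest open chain is returned flagged
`ring_closure = FALSE`.

## Rigid superposition and ice-plane docking

`kabsch()` is the closed-form least-squares fit: SVD of the cross-covariance
of the centred point sets, with the sign of the smallest singular direction
corrected so only proper rotations (det = +1) are returned — a reflected
water motif is a different chemical object, so improper fits are never
acceptable. Collinear inputs are rejected explicitly (the rotation about the
common axis is undefined).

Docking a bound-water set onto an ice-plane patch is a correspondence
problem: which lattice oxygen should each water claim? The reference
workflow fixes the correspondence by hand; `dock_waters_to_plane()`
generalizes it as multi-start iterative closest point (ICP) registration,
alternating

1. the *optimal injective assignment* of waters to distinct lattice oxygens —
   an exact bipartite assignment (Hungarian method, via clue) on the current
   distance matrix, rather than independent nearest neighbours, because at
   ice-lattice density nearest-neighbour ICP readily collapses two waters
   onto one oxygen and stalls in swapped assignments; and
2. a Kabsch refit of that assignment,

until the RMSD change drops below `tol` (default 1e-6 Å, `max_iter` 100).
Starting orientations combine plane-aligned seeds — both signs of the
waters' best-fit plane normal crossed with in-plane rotations every 15° —
with uniformly random orientations up to `n_starts` (default 64), and each
start is also tried from four in-plane translation offsets of ±1.4 Å along
the patch basis, because the hexagonal lattice has shift-equivalent local
minima about one bond apart. The run is deterministic given `seed`, which is
recorded in the result. Because the search optimizes the correspondence, it
can legitimately find an RMSD at or below a hand-assigned reference fit.

`calpha_rmsd()` pairs Cα atoms by author residue number and reports the
Kabsch RMSD — the standard whole-fold comparison for closely related
structures (isoforms of the same AFP differ by ~0.3–0.4 Å).

## CD melting curves

With ellipticity θ monitored at a fixed wavelength while heating, the
fraction unfolded is the printed two-state normalization
f(T) = (θ_T − θ_low) / (θ_high − θ_low), with reference temperatures 20 and
60 °C by default (70 °C for thermostable variants — a parameter, not a code
branch). `fraction_unfolded()` smooths each raw sample by an unweighted mean
over all samples within ±0.4 °C (the stated window read as a symmetric
half-width), resamples to a 1.0 °C grid by linear interpolation, and
normalizes using the smoothed values at the references, so f = 0 and f = 1
are pinned at the references *by construction*. Two consequences are worth
stating plainly:

* the curve is invariant to any affine rescaling of the CD units —
  including a sign flip, so a trace with swapped baselines yields the *same*
  curve, not an error;
* the ±0.4 °C window introduces a second-order smoothing bias of
  var(offsets)/2 · f″(T) ≈ 1e-3 at a 2 °C transition width; the test suite
  verifies both the ≤1.5e-3 envelope and the collapse of the residual when
  the analytic correction is applied.

`estimate_tm()` returns the first upward crossing of f = 0.5, linearly
interpolated between the bracketing grid points; first-crossing is the
two-state reading of noisy multi-crossing curves. A no-crossing error can
only arise for externally supplied curves, since the pinned normalization
guarantees a crossing on the grid.

## Hydrogen-bond forward lifetimes

Water residence on a protein surface is summarized as the *forward
lifetime* of protein–water hydrogen bonds: the duration of a maximal
contiguous bonded run, from formation to first break (a run of k frames
lasts k·dt). `detect_hbonds()` marks a bond present when the donor–acceptor
heavy-atom distance is ≤ 3.5 Å and, when hydrogens are modelled, the
hydrogen–donor–acceptor angle is ≤ 30° from linear — the standard geometric
criterion; without hydrogens the distance criterion stands alone.
`forward_lifetime()` excludes runs truncated by the trajectory ends by
default (their formation or break is unobserved; including them is a flag),
and a one-frame interruption is a real break unless a grace period is
requested — the simplest reading of a continuous-run lifetime; an
intermittent (correlation-function) definition is deliberately out of scope.
`region_residence()` pools lifetimes by residue position into IBS, non-IBS
and whole-surface groups; a region with no completed run is reported absent,
never as zero. The whole-surface value is necessarily the run-count-weighted
mean of the regional values.

The MD engine itself is out of scope: inputs are small multi-frame
coordinate sets or precomputed occupancy tables, and absolute picosecond
values from nanosecond solvated simulations are not reproducible at this
scale — the estimator is validated on telegraph processes instead (below).

## Synthetic data: what it emulates and what it does not

Each generator plants known truth and is bit-reproducible from its seed
(`with_seed` restores the caller's RNG stream):

* `gen_zigzag()` — planar chain with constant spacing and alternating turn,
  defaults 2.86 Å / 116°; `angle = 180` degenerates to the trough fixture.
* `gen_ring()` — regular polygon of waters (default decagon, edge 2.74 Å)
  around a benzene-like carbon hexagon, offset out of plane so the mean
  nearest-carbon distance hits its target (default 3.4 Å, solved
  numerically).
* `gen_transformed_patch()` — compact subset of an ice patch under a known
  rigid transform plus noise, for docking recovery.
* `gen_cd_trace()` — logistic two-state melt, default midpoint 47.5 °C and
  width 2 °C on a 0.2 °C grid from 20 to 60 °C (the standard scan).
* `gen_telegraph_hbonds()` — two-state Markov occupancy with geometric run
  lengths; mean bonded run = planted lifetime, default 80 ps (with 68 ps as
  the contrasting region in two-region tests, mirroring the scale of
  IBS/non-IBS contrasts), unbonded gaps mean 5 frames.
* `gen_toy_structure()` — writable miniature crystal: poly-alanine scaffold
  (3.8 Å/residue along x with a small deterministic wiggle so the Cα trace
  is never collinear), planted waters as HOH, a unit cell and space group.

Positional noise is isotropic Gaussian in Cartesian coordinates, the
B-factor-style model of coordinate uncertainty. The *study-condition* noise
used by the replication tests is σ = 0.05 Å, the coordinate-precision scale
of well-ordered waters in a ~1.5 Å-resolution structure. This choice
matters: the mean nearest-neighbour distance estimator carries a known
positive bias of about 2σ²/d (transverse noise only lengthens distances), so
an "unbiased within 3 standard errors over 100 replicates" check is a
statement about σ as much as about the code — at σ = 0.05 Å the bias is
~0.8 standard errors of the replicate mean, at σ = 0.2 Å it would dominate.

What passing these tests shows: the estimators recover planted geometry,
lifetimes and midpoints without systematic error at crystallographic noise
levels, and the search algorithms agree with exhaustive oracles at the
motif scale. What they do not show: robustness to the structural
irregularity of real hydration shells (real spacings spread 2.6–3.7 Å
because the *sites* differ, not because of measurement noise), to partial
occupancy, or to selection ambiguity at the IBS boundary — those need real
structures, which is exactly what the deposited-structure reproduction
checks in the test suite are for (they run whenever the corresponding PDB
entries are placed under `tests/testthat/deposited/`).

## Numerical choices and degenerate inputs

* Distance comparisons use a closed interval with a 1e-9 Å guard, so a pair
  at exactly the cutoff is connected.
* The cross-product distance formula loses ~1e-7 Å at coordinate magnitudes
  of tens of Å; coincidence tests therefore use 1e-5-level tolerances, and
  the 0.1 Å symmetry-duplicate threshold is far above round-off.
* Kabsch degeneracy is declared when the second singular value falls below
  1e-8 of the first.
* Exhaustive searches (trough subsets ≤ 12 candidates, cycles ≤ 15) are
  exact by enumeration; both have deterministic tie-breaks (total residual /
  total circumference, then lexicographic ids) so reports are reproducible
  to the byte.
* ICP convergence is declared on an RMSD change < 1e-6 Å; non-convergence
  returns the best-so-far flagged and warned, never an exception.
* The pipeline (`run_analysis()`) records a failed stage as an error entry
  in the report and continues with independent stages; identical
  config + seed gives byte-identical JSON.

## Problem sizes

The test-suite and acceptance computations run at the scale of the study
itself: motifs of 6–12 waters, lattices of a few hundred oxygens, docking
with ≤ 64 starts, 100-replicate parameter-recovery batches, 50-replicate
melting batches, and ~10⁵ hydrogen-bond runs for the lifetime estimator —
each component completes in seconds on a single core.

## Known limitations

* Only oxygen positions are modelled: no hydrogen placement, proton
  disorder, or water orientation inference.
* Built-in symmetry covers `P 1` and `P 21 21 21`; other groups rely on the
  file's own operator records.
* The ice lattice is ideal and unrelaxed — no surface reconstruction or
  quasi-liquid layer.
* Hydrogen-bond energetics are not scored; the geometric criterion is a
  binary gate.
* The docking search may return an RMSD below a published hand-assigned
  fit for the same inputs, because it optimizes the correspondence; both
  behaviours are reported rather than reconciled.
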