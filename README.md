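# icebound

Bound-water network analysis at antifreeze protein ice-binding sites.

## What this package is for

Antifreeze proteins (AFPs) stop ice crystals from growing by adsorbing onto
specific ice planes. For the widespread microbial family of beta-helical
AFPs the leading explanation is *anchored clathrate water*: the flat
ice-binding site (IBS) organizes a shell of semi-ordered waters whose
geometry already looks like an ice plane, and this pre-formed lattice
fragment merges with the ice surface. Crystal structures let you test that
idea quantitatively — if you can measure the bound-water geometry carefully.

`icebound` is for structural biologists doing exactly that. Given a crystal
structure it:

* reads PDB/mmCIF coordinates, applies crystallographic symmetry so the IBS
  is surrounded by all its equivalent waters, and selects the waters "on"
  the IBS (any-atom cutoff, default 4.0 Å);
* builds the water proximity network (3.7 Å) and extracts the three motifs
  recurring on these sites — the **zigzag chain** (spacing/angle
  statistics), the **linear trough** along hydrophobic residues
  (total-least-squares collinear subset, exhaustive at motif scale), and
  the **hydrophobic hydration ring** around an IBS phenylalanine (largest
  simple cycle, exact at motif scale);
* generates ideal **ice Ih oxygen lattices** (a = 4.52 Å, c = 7.36 Å) with
  basal/prism plane patches and their characteristic repeats (2.76 Å bond,
  4.52 Å and 14.72 Å prism repeats);
* **docks** a bound-water set onto an ice-plane patch by multi-start
  iterative closest point registration with exact injective assignment
  (Hungarian method) and Kabsch refits — reflections excluded, RMSD
  reported; the core statistic comparing a hydration motif with ice;
* estimates **CD melting midpoints** from temperature–ellipticity traces
  via the two-state normalization f(T) = (θ_T − θ_low)/(θ_high − θ_low)
  with ±0.4 °C smoothing, a 1 °C grid and first-crossing Tm;
* computes **hydrogen-bond forward lifetimes** (mean length of a bonded run
  from formation to first break, end-truncated runs excluded) pooled by
  surface region (IBS / non-IBS / whole) from trajectory event tables;
* ships seeded **synthetic generators** for every input — zigzags, rings,
  transformed lattice patches, melting traces, telegraph hydrogen-bond
  occupancies and writable toy crystals with planted waters — so the whole
  pipeline is testable offline with known ground truth.

The methods vignette (source at `vignettes/ibs-hydration.Rmd`) covers the
models, parameter choices and numerical details.

## Worked example

```r
library(icebound)

# a zigzag bound-water chain at crystallographic noise (sigma = 0.05 A)
z <- gen_zigzag(12, spacing = 2.86, angle = 116, noise_sigma = 0.05, seed = 7)
net <- build_network(z$waters, cutoff = 3.7)
network_stats(net)
#> <network_stats> 11 edges: 2.66-2.94 Angstrom (mean 2.85); 10 angles: 114-119 deg (mean 117)

# dock the chain onto a basal-plane patch of ideal ice Ih
ice   <- build_ice_lattice(4.52, 7.36, extent = 4)
patch <- extract_plane_patch(ice, "basal", thickness = 1.0, min_count = 12)
dock_waters_to_plane(z$waters, patch, n_starts = 24, seed = 1)
#> <superposition> 12 pairs, RMSD 1.2943 Angstrom

# CD melting midpoint from a noisy two-state trace planted at 47.5 degrees C
tr <- gen_cd_trace(t_m = 47.5, width = 2, noise_sigma = 0.32, seed = 7)
estimate_tm(fraction_unfolded(tr))
#> [1] 47.54279

# hydrogen-bond residence times by surface region (planted 80 vs 68 ps)
tab <- gen_telegraph_hbonds(c(80, 68), dt = 1, n_frames = 20000, n_bonds = 20,
                            residue_positions = c(20L, 60L), seed = 7)
region_residence(tab)
#> <residence_result> mean forward lifetime (ps):
#>   IBS           81.65  (2296 runs)
#>   non-IBS       68.07  (2730 runs)
#>   whole         74.27  (5026 runs)
```

Reading the numbers: the recovered network statistics (mean 2.85 Å, 117°)
sit on the planted zigzag geometry; the 12-water chain docks onto the basal
bilayer at 1.29 Å RMSD (an idealized planar zigzag is not an exact bilayer
fragment, so an RMSD around an O–O bond length's half is the expected
order); the melting midpoint lands within 0.05 °C of the
planted 47.5 °C under 2%-of-amplitude noise; and the two planted residence
regimes separate cleanly, with the whole-surface value between them.

For a full structure analysis, `run_analysis(analysis_config("file.pdb"))`
chains symmetry expansion, water selection, motifs and per-plane docking
into one JSON-serializable report, and `compare_structures()` adds Cα RMSD
and shared-water fractions across related crystals. A thin CLI wrapper with
subcommands (`analyze`, `compare`, `dock`, `melt`, `residence`, `simulate`)
is installed at `inst/scripts/icebound`.

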