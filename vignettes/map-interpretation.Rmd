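---
title: "Interpreting cryo-EM maps of flexible transporters: unmodeled ligand density, rigid fitting and conformational geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting cryo-EM maps of flexible transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-particle cryo-EM of an intrinsically flexible ABC transporter such as
P-glycoprotein yields intermediate-resolution (4-6 Å) maps of several
coexisting inward-facing conformations. When a hydrophobic drug is added at a
sub-stoichiometric ratio, drug-bound and drug-free particles coexist in the
same specimen and separate into different 3-D classes. The analytical
questions this package answers are then:

1. **Display**: at what density level should each map be shown so that all
   classes are compared at the same *enclosed physical volume* (e.g. the
   molecular volume of the protein-detergent complex)?
2. **Detection**: does a map contain a connected feature of density *not
   accounted for* by the refined atomic model that behaves like the drug —
   visible at the protein display level, roughly rod-shaped, of drug-sized
   volume, and fittable without serious clashes?
3. **Fitting**: where and in which orientation does the drug sit, judged by
   real-space correlation between the experimental density and a
   resolution-matched simulated ligand map — including the 180°
   end-over-end ambiguity of an elongated molecule?
4. **Geometry**: how do the conformations differ — center-of-mass separation
   of the two nucleotide-binding domains (NBDs), voxel-rule nucleotide-pocket
   volumes, and matched-Cα RMSD with iterative outlier pruning?

Every stage is exercised end-to-end on synthetic, ground-truthed scenes, so
the package needs no external data to test itself.

## Map model and conventions

A `density_map` is a scalar field on a regular orthogonal grid. Voxel
`(i, j, k)` (0-based) sits at `origin + (i, j, k) * voxel_size` — a
voxel-corner convention shared by all modules, so no half-voxel offsets can
creep in between simulation, masking and blob analysis. MRC2014 files are
read in modes 0/1/2 with arbitrary `mapc/mapr/maps` storage order normalized
to X-fastest; the origin is taken from the MRC2014 origin words when any is
nonzero, else from `nstart * voxel_size` (the two dialects in circulation).
Only orthogonal cells are supported, which is universally true of
single-particle reconstructions. Maps are written in mode 2 (float32) with
recomputed header statistics.

## Thresholding by enclosed volume

`threshold_for_volume(map, V)` returns the `m`-th largest voxel value with
`m = round(V / voxel_volume)`. Thresholding is *closed* (`value >= level`),
which makes the order-statistic construction exact: recomputing the enclosed
volume at the returned level reproduces the count, up to ties at the level
(all tied voxels are included, a deterministic and documented bias of at most
one voxel volume per tied voxel; ties have measure zero for continuous
data). The level is monotone non-increasing in the target volume.
`sd_threshold(map, k)` gives the complementary convention `mean + k * sd`
(population SD), used with `k = 7` for simulated ligand envelopes.

## Simulated density

`simulate_map()` places a mass-normalized isotropic Gaussian on each atom.
The nominal resolution is interpreted as the **FWHM** of that Gaussian
(`sigma = resolution / 2.355`); the convention is recorded in the JSON
sidecar, because simulation tools differ here and no universal standard
exists. Weights are atomic numbers by default (electron count; closer to
scattering physics) or uniform for toy fixtures. Kernels are truncated at 4
sigma (mass loss < 0.01%). The default box padding is 3x the resolution —
the convention of the widely used simulate-map tools. Padding matters more
than it looks: the `mean + 7 sd` envelope rule is evaluated on the simulated
map's own statistics, and a tighter box raises the SD and shrinks the
envelope; fixing the convention makes the reference ligand volume
reproducible.

## Detection: masking, blobs, and the four criteria

`mask_modeled_density()` sets every voxel within `mask_radius` (default
3.0 Å) of a model heavy atom to the map minimum. The study this package
reproduces judged "accounted for by the model" visually; an explicit radius
makes the judgement reproducible. After masking, `find_blobs()` labels
connected components of `{value >= level}` under 26-connectivity (default;
6 and 18 available) and drops components under 10 voxels (noise specks).
Blob shape is summarized by density-weighted PCA of the voxel-center
coordinates: principal extents `2 * sqrt(lambda)` and elongation =
first/second extent — deterministic and orientation-free.

A candidate blob is screened by four criteria:

1. visible at the protein display level (structural: the blob was found at
   that level);
2. roughly rod-shaped: elongation >= 2.0 (a single threshold rather than a
   fitted cylinder — the simplest faithful operationalization of "roughly
   rod-shaped"; the threshold is config);
3. continuous volume within [0.5, 2.0]x the expected ligand envelope volume,
   where the reference is the ligand simulated at the working resolution and
   thresholded at its own `mean + 7 sd`; the raw ratio is always reported
   alongside the flag, since the band is a config default and no numeric
   band is canonical;
4. after fitting, no ligand-protein heavy-atom pair closer than 2.0 Å. This
   is evaluated *pre-minimization*: in the original workflow, residual
   clashes were remedied by rotamer adjustment in an external minimizer,
   which is out of scope here, so criterion 4 is the stricter variant.

Note that residual protein density just outside the mask radius routinely
survives as large, poorly shaped blobs at loose display levels — by design
these fail criteria 2-3 rather than being silently suppressed.

## Rigid fitting and flip disambiguation

`rigid_fit()` scores poses by the Pearson correlation (about the mean, the
default; the raw-overlap variant is a config option) between the
experimental map and the simulated posed-ligand density, over the scoring
region where the simulated density reaches its own `mean + k sd` level
(default `k = 7`). The search is deterministic: a super-Fibonacci
quasi-uniform rotation grid (default 576 rotations) with the ligand centroid
pinned to the blob centroid, followed by coordinate-wise golden-section
refinement of the translation (±2 Å per axis) and of rotations about the
*posed ligand's own principal axes*, re-centered each sweep. The spin about
an elongated ligand's long axis is its weakly determined degree of freedom,
so that axis gets a wide (±90°) coarse-scan-then-refine treatment while the
two transverse axes get ±15°. Refinement never lowers the correlation (best
pose is kept).

`flip_compare()` composes a pose with a 180° rotation about the ligand's
second principal axis through its center — the end-over-end swap of an
elongated molecule — and reports both correlations; the decision rule is
simply to prefer the larger, with both values always reported. For a ligand
with (near-)symmetric ends the two correlations coincide and the comparison
is uninformative, which the reports make visible rather than hiding.

Correlation is invariant under affine rescaling of the experimental map, so
absolute map scale never matters.

## Geometry

* `center_of_mass()` / `domain_separation()`: mass-weighted (standard atomic
  masses) or geometric centers over user-supplied chain/residue-range
  selections. Residue ranges are always configuration — no NBD boundaries
  are hard-coded; a murine P-gp example ships in
  `inst/extdata/pgp_nbd_selections.yaml` for demonstration only.
* `pocket_volume()`: counts voxels strictly below the whole-map mean within
  5.0 Å (default) of reference (e.g. positioned-nucleotide) atoms. The
  whole-box mean is the documented rule; the cell-list implementation is
  tested for exact equality with an exhaustive double loop.
* `matched_rmsd()`: atoms are matched by (chain, residue number, insertion
  code, atom name), Cα by default — per-residue pairing matches how modeled
  residue counts are reported for large transporters. The procedure
  iterates least-squares (Kabsch) superposition over the retained pairs and
  pruning of pairs deviating by more than 2.0 Å until stable, then reports
  both the retained-pair RMSD and the all-pair RMSD in the final frame:
  "X over n pairs within 2 Å, Y overall m pairs". `max_iter = 1` gives the
  single-pass variant. If pruning would leave fewer than 3 pairs, the
  all-pair result is reported with a `pruning_failed` flag.

## The synthetic scene generator

`make_toy_transporter()` builds a Cα-trace pseudo-structure: two
three-helix-bundle "NBDs" (chains A/B) whose mass centers are placed
*exactly* at the requested separation on the x axis (the bundles are
recentered after jitter), and two double-stranded "TM" arms (chains C/D)
rising to a crossing apex, leaving a central aqueous cavity. The cavity site
(`ligand_site` attribute, at z = 16 in the model frame) is where the arm
clearance is about 18 Å, so a posed ligand's density envelope stays
disconnected from the residual protein halo outside the mask radius — the
geometric regime in which a drug in the central cavity of a real transporter
sits. It is a geometry phantom, not a fold: all quantities measured from it
(centers of mass, density, separations) depend only on where its atoms are.

`make_toy_ligand()` is the "rocket": a 1.5 Å-spaced linear shaft (10 atoms by
default) with two fin atoms branching at one end. With fins the molecule is
end-to-end asymmetric, so the flip comparison has a right answer; without
fins it is end-symmetric and the flip comparison correctly ties. The fins
also give the ligand an *exact* two-fold symmetry about its shaft, so pose
recovery is assessed modulo that symmetry.

`build_scene()` sums the simulated protein map, an occupancy-weighted posed
ligand (default occupancy 1, the spec of the bound class), an optional
low-amplitude Gaussian-tube torus emulating a detergent micelle annulus
(off by default), and white Gaussian voxel noise with SD equal to
`noise_sd` x signal peak (default 5%). White noise is appropriate because
the pipeline operates on reconstructed maps; CTF and radiation-damage
modelling belong to reconstruction, not interpretation. Each scene records a
truth object (seed, separation, pose, occupancy, noise, resolution, voxel
size, micelle flag) from which it is exactly reproducible, plus the scene's
display volume — the volume enclosed by the *noiseless protein-only* map at
its own `mean + 5 sd` level. That display rule is the generator's fixed
convention and mirrors the tight, molecular-volume-like display used for
experimental maps (a 153,000 Å^3 envelope for a ~150 kDa protein-detergent
complex); at much looser levels the Gaussian skirt of *any* structure
merges into a single envelope and per-feature criteria stop being
meaningful.

All randomness flows from one master seed through a documented splitting
scheme (`(seed * 1009 + stream * 101) mod (2^31 - 1)`), so Monte-Carlo
acceptance checks are exactly reproducible.

`make_ensemble()` produces the default five-class study: separations
60/56/60/55/53 Å with the ligand only in the first (widest) class —
the configuration in which detection should flag exactly one class.

### What the generator does *not* emulate

Real maps have colored noise, resolution anisotropy, micelle density far
stronger and more structured than the toy torus, model-coordinate error, and
partial-occupancy mixtures within a class. Passing the synthetic suite
therefore demonstrates that the *procedures* are correct and deterministic
— not that the default thresholds are optimal for any particular
experimental dataset. The four criteria thresholds, mask radius and display
volume are all configuration for exactly that reason.

## Numerical choices and degenerate inputs

* Population (divisor *n*) SD everywhere a SD-multiple rule is applied.
* Ties at a threshold level are all included (closed thresholding).
* Gaussian truncation at 4 sigma; truncation radius recorded.
* Blob PCA floors the minor extents at one voxel edge before forming the
  elongation ratio, so a 1-voxel-thick plane does not divide by zero.
* Empty FSC shells are omitted and listed in an attribute; FSC of two
  identical maps is 1 in every populated shell by construction.
* The FSC resolution read-out interpolates linearly across the first
  downward crossing; a curve that never crosses reports the Nyquist
  resolution with a `nyquist_limited` flag.
* `matched_rmsd` refuses to prune below 3 pairs (rigid motion would be
  underdetermined) and flags the condition.
* Scoring regions smaller than 2 voxels raise an error rather than
  returning a meaningless correlation.

## Problem sizes used in the bundled analyses

The scripts under `analysis/` and the acceptance script run the five-class
ensemble (maps of roughly 90 x 35 x 80 voxels at 1.043 Å), 576-rotation
fits for qualifying blobs, 10 master seeds for the detection Monte Carlo,
and 64^3/32^3 random maps for the thresholding, FSC and pocket checks —
sizes chosen so the whole workflow reruns from scratch in a few minutes on
one CPU while leaving every algorithmic path exercised at realistic voxel
pitch.

## Known limitations

* The MRC reader supports the single-particle dialects (orthogonal cells,
  modes 0/1/2); crystallographic symmetry records are ignored.
* Rotamer adjustment / energy minimization after fitting is out of scope, so
  clash counts are pre-minimization and stricter than a minimized workflow.
* Criterion 3's reference volume depends on the simulation padding and the
  `k` multiplier; both are fixed conventions (3x resolution, `k = 7`) and
  echoed into every report, but comparisons across tools must match them.
* Cross-species comparisons that require sequence alignment for residue
  matching are not implemented; matching is by identical residue numbering.
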