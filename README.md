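# cryomap

Interpretation of intermediate-resolution (4–6 Å) single-particle cryo-EM
density maps of flexible membrane transporters: equal-volume map display,
detection of unmodeled ligand density by explicit criteria, rigid-body ligand
fitting scored by real-space correlation, and conformational geometry
(domain separations, pocket volumes, pruned RMSD). A synthetic scene
generator makes the entire pipeline testable without downloading any data.

## Who this is for

Structural biologists comparing 3-D classes of a transporter imaged with a
sub-stoichiometric ligand, where drug-bound and drug-free particles coexist
and the question is *which class carries the drug, where does it sit, in
which orientation, and how does the conformation differ*.

## The methods at the core

* **Equal-volume thresholding.** Maps are compared at the density level λ
  enclosing a stated physical volume V: λ is the m-th largest voxel value,
  m = round(V / v), v the voxel volume. Thresholding is closed (≥ λ).
* **Four-criterion ligand-density screen.** After masking all density within
  r = 3 Å of model heavy atoms, connected components (26-connectivity) of
  the remaining density at the protein display level are screened: (i)
  visible at that level; (ii) rod-shaped, elongation e = 2√λ₁ / 2√λ₂ ≥ 2
  from density-weighted PCA; (iii) volume within [0.5, 2] × the expected
  ligand envelope — the ligand simulated at the working resolution (FWHM
  Gaussians, electron-count weights) thresholded at its own mean + 7σ; (iv)
  no fitted-pose heavy-atom pair under 2 Å.
* **Rigid fitting.** Exhaustive search over a deterministic super-Fibonacci
  rotation grid (576 rotations) with the ligand centroid at the blob
  centroid, then local refinement; the score is the Pearson correlation
  CC between simulated and experimental density over the simulated mean + 7σ
  envelope. The 180° end-over-end flip is scored explicitly and both CC
  values reported.
* **Geometry.** Domain separation |c₁ − c₂| between mass-weighted centers of
  user-selected residue ranges; pocket volume as the count of voxels below
  the map mean within 5 Å of reference atoms; matched-Cα RMSD with iterative
  Kabsch superposition and 2 Å pruning, reported as
  "X Å over n pairs within 2 Å, Y Å overall m pairs".
* **FSC.** Unmasked Fourier shell correlation between half maps, shells one
  reciprocal voxel wide, resolution read at the 0.143 crossing.

## Worked example

```r
library(cryomap)

# ground-truthed five-class ensemble: NBD separations 60/56/60/55/53 A,
# rocket-shaped ligand present only in the widest class, 5% voxel noise
ens <- make_ensemble(seed = 17)
lig <- ens$scenes[[1]]$ligand

s <- ens$scenes[[1]]                      # class a, the ligand-bearing class
cfg <- pipeline_config(display_target_volume = s$truth$display_volume,
                       seed = 17)
rep <- run_detection(s$map, s$model, lig, cfg)
print(rep)
```

```
detection_report 'scene': level 0.04505 (6428 A^3), 5 blob(s), ligand-bearing
  best fit cc 0.964 vs flipped 0.787, 0 serious clash(es)
```

The map is displayed at the level enclosing the scene's protein display
volume (6428 Å³ here); five unmodeled-density blobs survive masking; exactly
one passes all four criteria, and the fitted ligand's correlation (0.964)
clearly beats its 180°-flipped orientation (0.787), i.e. the fin end is
identified. Running the same call on the apo classes reports
`no qualifying feature`. Geometry over all five models:

```r
geo <- run_geometry(lapply(ens$scenes, `[[`, "model"))
geo$separations$separation_A
#> [1] 60 56 60 55 53
```

The numbered drivers under `analysis/` run the same workflow end to end and
write tables under `results/`: `01_make_fixtures.R` (scene triplets +
manifest), `02_detect_ligand.R` (per-class detection reports),
`03_geometry.R` (separations, pairwise pruned RMSDs, pocket volumes),
`04_fsc.R` (half-map FSC and the 0.143 resolution read-out). Each accepts
`--seed <int>`.

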