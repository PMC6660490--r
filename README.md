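# dixonac

Synthetic end-to-end analysis of how artifacts in four-class MR-derived
attenuation-correction (AC) maps bias myocardial PET quantification —
and how far the standard retrospective corrections recover it.

On integrated PET/MR systems the attenuation map is a Dixon-type MR
segmentation into background, lung, fat and soft tissue, each assigned
a fixed 511 keV coefficient (lung 0.0224 cm⁻¹). These maps suffer a
recurring artifact taxonomy — susceptibility voids around sternal wires
(STN) and implants (SMA), lung/soft (LSTI) and fat/soft (FSTI) tissue
inversions, photopenic bands above the diaphragm (PMA), truncation of
the arms, and rigid respiratory misalignment against the emission data.
`dixonac` builds digital thorax phantoms, injects every artifact class,
simulates attenuated parallel-beam emission data, reconstructs with
OSEM (3 iterations, 21 subsets, 5 mm Gaussian post-filter) using the
artifactual and the corrected maps, and quantifies the effect with the
field's standard chain:

* relative-difference maps, RD = (PET_corrected / PET_original) × 100 %,
* 42 %-threshold myocardial segmentation with SUVmean / SUVmax,
* lung volume = lung-class voxel count × voxel volume, with the > 10 %
  test–retest incoherence rule,
* simplified AHA 17-segment polar maps with defect extent, scar and
  hibernating percentages.

The three correction operators are the ones used in practice:
six-neighbour majority-vote filling of susceptibility gaps (wavefront
order, tie-break soft > fat > lung > background), rigid re-alignment of
the AC map by maximizing Dice overlap with the non-AC emission support,
and truncation completion from the emission body support.

## Worked example

Inject a metallic-implant cavity next to the LV wall, reconstruct with
the artifactual and the repaired map, and measure the myocardial bias:

```r
library(dixonac)

ph   <- generate_phantom(phantom_config(grid_shape = c(128, 128, 32)), seed = 5)
zmy  <- range(which(apply(ph$masks$myocardium, 3, any)))
act  <- crop_z(ph$activity, c(zmy[1] - 3, zmy[1] + 12))
lab  <- crop_z(ph$labels,   c(zmy[1] - 3, zmy[1] + 12))
mu   <- labels_to_mu(lab)
myo  <- ph$masks$myocardium[, , (zmy[1] - 3):(zmy[1] + 12)]

sino <- forward_project(act, mu, recon_protocol())
rec_true <- reconstruct_osem(sino, mu, recon_protocol())

lv  <- ph$lv
cav <- inject_artifact(lab, artifact_spec("SMA",
         region_sphere(c(lv$center_mm, (lv$z_apex_mm + lv$z_base_mm) / 2), 12)))
rec_art <- reconstruct_osem(sino, labels_to_mu(cav$labels), recon_protocol())

fix     <- fill_susceptibility(cav$labels, cav$mask)
rec_fix <- reconstruct_osem(sino, labels_to_mu(fix$labels), recon_protocol())
rd      <- relative_difference(rec_fix, rec_art)

mean(rec_art$data[myo]); mean(rec_true$data[myo])
#> [1] 6.414772
#> [1] 6.501145
mean(rd$rd[myo & rd$mask])
#> [1] 101.9719
```

The cavity makes the AC map under-attenuating, so myocardial uptake is
underestimated (6.41 vs 6.50); filling the gap raises the wall by ~2 %
(RD mean 102 %), with the same direction and magnitude as sternal-wire
artifacts show clinically. The numbered drivers under `analysis/` run
the full workflow — phantom construction, per-artifact footprints, the
adjacency contrast and misalignment recovery, and the cohort study —
writing their tables under `results/`:

```sh
Rscript analysis/01_phantom.R
Rscript analysis/02_artifacts.R
Rscript analysis/03_corrections.R
Rscript analysis/04_study.R 3 1    # n subjects, seed
```

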