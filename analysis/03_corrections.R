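#!/usr/bin/env Rscript
# Quantifies how attenuation-map artifacts bias myocardial PET and how
# the correction operators recover it, on a 16-slice slab around the LV:
#   (a) an air cavity next to the LV wall vs an equal cavity at the
#       sternum (adjacency contrast),
#   (b) an injected axial misalignment, re-aligned by the Dice search.

suppressPackageStartupMessages(library(dixonac))
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ph <- generate_phantom(phantom_config(grid_shape = c(128L, 128L, 32L)),
                       seed = 5)
zmy <- which(apply(ph$masks$myocardium, 3, any))
z0 <- max(1, min(zmy) - 3L); z1 <- z0 + 15L
act <- crop_z(ph$activity, c(z0, z1))
lab <- crop_z(ph$labels, c(z0, z1))
mu <- labels_to_mu(lab)
myo <- ph$masks$myocardium[, , z0:z1]
proto <- recon_protocol()

sino <- forward_project(act, mu, proto)
rec_true <- reconstruct_osem(sino, mu, proto)
lv <- ph$lv
zmid <- (lv$z_apex_mm + lv$z_base_mm) / 2

cavities <- list(
  lv_adjacent = region_sphere(c(lv$center_mm, zmid), 12),
  sternum_remote = region_sphere(c(ph$organs$sternum[1:2], zmid), 12))

rows <- lapply(names(cavities), function(nm) {
  kind <- if (nm == "lv_adjacent") "SMA" else "STN"
  art <- inject_artifact(lab, artifact_spec(kind, cavities[[nm]]))
  rec_art <- reconstruct_osem(sino, labels_to_mu(art$labels), proto)
  fix <- fill_susceptibility(art$labels, art$mask)
  rec_fix <- reconstruct_osem(sino, labels_to_mu(fix$labels), proto)
  rd <- relative_difference(rec_fix, rec_art)
  rdv <- rd$rd[myo & rd$mask]
  data.frame(cavity = nm, voxels = art$n_changed,
             suv_mean_artifact = round(mean(rec_art$data[myo]), 3),
             suv_mean_true = round(mean(rec_true$data[myo]), 3),
             rd_mean_pct = round(mean(rdv), 2),
             rd_max_pct = round(max(rdv), 2))
})
cav_tab <- do.call(rbind, rows)
cat("Susceptibility-cavity experiment (42%-chain on ground-truth wall):\n")
print(cav_tab, row.names = FALSE)
write.csv(cav_tab, file.path(out_dir, "cavity_bias.csv"),
          row.names = FALSE)

# misalignment: shift the full-volume mu-map, recover it from the nonAC
mu32 <- labels_to_mu(ph$labels)
sino32 <- forward_project(ph$activity, mu32, proto)
nonac <- reconstruct_osem(sino32, NULL, proto)
mis_rows <- lapply(c(-18, -10, 5, 12), function(s_mm) {
  mus <- shift_map(mu32, c(0, 0, s_mm))
  est <- estimate_shift(nonac, mus)
  data.frame(applied_mm = s_mm, recovered_mm = est$shift_mm[3],
             dice = round(est$dice, 4))
})
mis_tab <- do.call(rbind, mis_rows)
cat("\nAxial misalignment recovery:\n")
print(mis_tab, row.names = FALSE)
write.csv(mis_tab, file.path(out_dir, "misalignment_recovery.csv"),
          row.names = FALSE)
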