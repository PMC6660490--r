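#' Cohort configuration for the synthetic test-retest study
#'
#' Each synthetic subject receives one anatomy and two acquisitions
#' ("test": perfusion-like tracer, "retest": metabolism-like tracer), each
#' with its own attenuation map. Artifacts are drawn independently per
#' scan with the configured prevalences; respiratory misalignment is drawn
#' per scan from a truncated normal. Default prevalences mirror the
#' frequencies reported for clinical four-class attenuation maps
#' (truncation in every scan, susceptibility in roughly half the cohort,
#' tissue inversions rare); they are simulation parameters, not
#' reproduction targets.
#'
#' @param n_subjects number of synthetic subjects (>= 1).
#' @param grid_shape grid for the phantoms, default c(128, 128, 32) (a
#'   thorax slab; axial anatomy scales with the grid).
#' @param voxel_size_mm voxel size, default 2.6 mm isotropic.
#' @param prevalence named per-scan artifact probabilities.
#' @param misalign_prob per-scan probability of respiratory misalignment,
#'   named `test` and `retest`.
#' @param misalign_mean_mm,misalign_sd_mm,misalign_range_mm axial offset
#'   distribution: normal(mean, sd) clamped to the range.
#' @param defect_prob probability that a subject carries a perfusion
#'   defect in one LV sector; with probability `hibernating_prob` the
#'   defect spares metabolism (hibernating), otherwise it is matched
#'   (scar).
#' @param hibernating_prob see `defect_prob`.
#' @param noise_count_scale Poisson count scale, or NULL for noiseless
#'   emission data (the default; artifact bias is deterministic).
#' @param protocol a [recon_protocol()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 3L,
                          grid_shape = c(128L, 128L, 32L),
                          voxel_size_mm = c(2.6, 2.6, 2.6),
                          prevalence = c(STN = 0.25, SMA = 0.30,
                                         TRUNCATION = 1.0, LSTI = 0.05,
                                         FSTI = 0.10, PMA = 0.35),
                          misalign_prob = c(test = 0.55, retest = 0.70),
                          misalign_mean_mm = 7, misalign_sd_mm = 4,
                          misalign_range_mm = c(-18, 12),
                          defect_prob = 0.3, hibernating_prob = 0.5,
                          noise_count_scale = NULL,
                          protocol = recon_protocol()) {
  stopifnot(n_subjects >= 1, all(prevalence >= 0 & prevalence <= 1),
            all(misalign_prob >= 0 & misalign_prob <= 1))
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 prevalence = prevalence, misalign_prob = misalign_prob,
                 misalign_mean_mm = misalign_mean_mm,
                 misalign_sd_mm = misalign_sd_mm,
                 misalign_range_mm = misalign_range_mm,
                 defect_prob = defect_prob,
                 hibernating_prob = hibernating_prob,
                 noise_count_scale = noise_count_scale,
                 protocol = protocol), class = "cohort_config")
}

# draw the artifact specs for one scan; returns list(specs, ledger rows)
draw_scan_artifacts <- function(config, phantom) {
  g <- phantom$labels$grid
  organs <- phantom$organs
  lv <- phantom$lv
  fz <- (g$shape[3] * g$voxel_size_mm[3]) / (64 * 2.6)
  specs <- list()
  for (kind in names(config$prevalence)) {
    if (stats::runif(1) >= config$prevalence[[kind]]) next
    spec <- switch(kind,
      STN = artifact_spec("STN", region_sphere(organs$sternum,
                                               stats::runif(1, 9, 14))),
      SMA = {
        a <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 7, 11)
        ctr <- c(lv$center_mm + (lv$r_outer_mm + 0.5 * r) * c(cos(a), sin(a)),
                 (lv$z_apex_mm + lv$z_base_mm) / 2)
        artifact_spec("SMA", region_sphere(ctr, r))
      },
      LSTI = artifact_spec("LSTI",
                           region_sphere(organs$lung_right +
                                           c(0, 0, stats::runif(1, -5, 5)),
                                         stats::runif(1, 25, 35))),
      FSTI = artifact_spec("FSTI",
                           region_box(c(-60, 30, lv$z_apex_mm - 20 * fz),
                                      c(60, 95, lv$z_base_mm + 20 * fz))),
      PMA = {
        zd <- phantom$config$diaphragm_z_mm
        artifact_spec("PMA", region_band(zd, zd + stats::runif(1, 2, 4) *
                                           g$voxel_size_mm[3]))
      },
      TRUNCATION = artifact_spec("TRUNCATION",
                                 region_halfplane(1, organs$arm_edge_x, 1)))
    specs[[kind]] <- spec
  }
  specs
}

# apply artifact specs to a label map; returns labels, susceptibility mask
# and per-artifact changed-voxel counts. TRUNCATION cuts both sides.
apply_scan_artifacts <- function(labels, specs) {
  susc_mask <- array(FALSE, labels$grid$shape)
  counts <- integer(0)
  for (kind in names(specs)) {
    spec <- specs[[kind]]
    res <- inject_artifact(labels, spec)
    labels <- res$labels
    n <- res$n_changed
    if (kind == "TRUNCATION") {
      hp <- spec$region
      res2 <- inject_artifact(labels,
                              artifact_spec("TRUNCATION",
                                            region_halfplane(1, -hp$position,
                                                             -1)))
      labels <- res2$labels
      n <- n + res2$n_changed
    }
    if (kind %in% c("STN", "SMA")) susc_mask <- susc_mask | res$mask
    counts[kind] <- n
  }
  list(labels = labels, susc_mask = susc_mask, counts = counts)
}

#' Run the full pipeline for one synthetic subject
#'
#' Deterministic in (config, subject_seed): phantom generation, per-scan
#' artifact draws and injection, emission simulation with the true
#' attenuation, reconstruction with the original (artifactual) map,
#' corrections (six-neighbour filling of susceptibility gaps when present,
#' rigid re-alignment, truncation completion when truncation was
#' injected), reconstruction with the corrected map, and quantitation
#' (relative-difference statistics in the 42% myocardium, lung volumes,
#' polar maps).
#'
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier used in the report.
#' @return list of class `subject_report`; see the elements `scans`,
#'   `lung_report`, `viability` and `artifact_ledger`.
#' @export
run_subject <- function(config, subject_seed, subject_id = subject_seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(subject_seed))

  pcfg <- phantom_config(grid_shape = config$grid_shape,
                         voxel_size_mm = config$voxel_size_mm)
  phantom <- generate_phantom(pcfg, seed = subject_seed)
  g <- phantom$labels$grid
  protocol <- config$protocol
  mu_true <- labels_to_mu(phantom$labels)

  # optional perfusion defect (one 60-degree sector), possibly hibernating
  has_defect <- stats::runif(1) < config$defect_prob
  hibernating <- has_defect && stats::runif(1) < config$hibernating_prob
  defect_angle <- stats::runif(1, 0, 2 * pi)
  sector_mask <- if (has_defect)
    lv_sector_mask(g, phantom$lv, defect_angle, pi / 3) &
      phantom$masks$myocardium
  else array(FALSE, g$shape)
  perf <- phantom$activity$data
  perf[sector_mask] <- 0.3 * perf[sector_mask]
  metab <- phantom$activity$data
  if (has_defect && !hibernating) metab[sector_mask] <- 0.3 * metab[sector_mask]
  activities <- list(test = activity_map(perf, g),
                     retest = activity_map(metab, g))

  myo_box <- dilate_bbox(phantom$masks$myocardium, 2L)

  scans <- list()
  ledger <- list()
  for (scan in c("test", "retest")) {
    specs <- draw_scan_artifacts(config, phantom)
    misaligned <- stats::runif(1) < config$misalign_prob[[scan]]
    offset_mm <- 0
    if (misaligned) {
      offset_mm <- stats::rnorm(1, config$misalign_mean_mm,
                                config$misalign_sd_mm)
      offset_mm <- min(max(offset_mm, config$misalign_range_mm[1]),
                       config$misalign_range_mm[2])
    }
    applied <- apply_scan_artifacts(phantom$labels, specs)
    mu_ac <- labels_to_mu(applied$labels)
    if (misaligned) mu_ac <- shift_map(mu_ac, c(0, 0, offset_mm))

    sino <- forward_project(activities[[scan]], mu_true, protocol)
    if (!is.null(config$noise_count_scale))
      sino <- add_poisson_noise(sino, config$noise_count_scale,
                                seed = subject_seed * 7L +
                                  (scan == "retest"))
    nonac <- reconstruct_osem(sino, NULL, protocol)
    recon_orig <- reconstruct_osem(sino, mu_ac, protocol)

    # corrections target the recorded artifacts (ground-truth masks)
    labels_corr <- applied$labels
    if (any(applied$susc_mask))
      labels_corr <- fill_susceptibility(labels_corr, applied$susc_mask)$labels
    mu_corr <- labels_to_mu(labels_corr)
    if (misaligned) mu_corr <- shift_map(mu_corr, c(0, 0, offset_mm))
    est <- estimate_shift(nonac, mu_corr)
    mu_corr <- shift_map(mu_corr, est$shift_mm)
    if ("TRUNCATION" %in% names(specs))
      mu_corr <- complete_truncation(mu_corr, nonac)$mu
    # when no correction changed the map, the corrected reconstruction is
    # the original one
    recon_corr <- if (identical(mu_corr$data, mu_ac$data)) recon_orig
    else reconstruct_osem(sino, mu_corr, protocol)

    myo_mask <- segment_myocardium(recon_corr, myo_box)
    rd <- relative_difference(recon_corr, recon_orig)
    rdv <- rd$rd[myo_mask & rd$mask]
    pm_orig <- polar_map_17(recon_orig, phantom$lv)
    pm_corr <- polar_map_17(recon_corr, phantom$lv)

    scans[[scan]] <- list(
      artifacts = names(specs),
      artifact_voxels = applied$counts,
      misaligned = misaligned,
      offset_mm = offset_mm,
      recovered_mm = est$shift_mm[3],
      rd_mean = mean(rdv), rd_max = max(rdv),
      myo_stats_orig = myo_stats(recon_orig, myo_mask),
      myo_stats_corr = myo_stats(recon_corr, myo_mask),
      lung_volume_L = lung_volume(mu_ac),
      polar_orig = pm_orig, polar_corr = pm_corr)
    for (kind in names(specs))
      ledger[[length(ledger) + 1L]] <-
        data.frame(subject = subject_id, scan = scan, artifact = kind,
                   n_voxels = applied$counts[[kind]])
    if (misaligned)
      ledger[[length(ledger) + 1L]] <-
        data.frame(subject = subject_id, scan = scan,
                   artifact = "MISALIGNMENT", n_voxels = NA_integer_)
  }

  lung_rep <- test_retest(scans$test$lung_volume_L,
                          scans$retest$lung_volume_L)
  viability <- list(
    original = viability_scores(scans$test$polar_orig,
                                scans$retest$polar_orig),
    corrected = viability_scores(scans$test$polar_corr,
                                 scans$retest$polar_corr))

  structure(list(subject = subject_id, seed = subject_seed,
                 has_defect = has_defect, hibernating = hibernating,
                 scans = scans, lung_report = lung_rep,
                 viability = viability,
                 artifact_ledger = do.call(rbind, ledger)),
            class = "subject_report")
}

# mask of an angular LV sector (for defect placement)
lv_sector_mask <- function(grid, lv, angle0, width) {
  co <- voxel_coords(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  X <- matrix(co[[1]], nx, ny)
  Y <- matrix(co[[2]], nx, ny, byrow = TRUE)
  ang <- (atan2(Y - lv$center_mm[2], X - lv$center_mm[1]) - angle0) %%
    (2 * pi)
  outer3d(ang < width, rep(TRUE, grid$shape[3]))
}

# bounding box of a mask, dilated by `by` voxels, as a logical array
dilate_bbox <- function(mask, by = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  n <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - by, 1L)
  hi <- pmin(apply(idx, 2, max) + by, n)
  out <- array(FALSE, n)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  out
}

#' Run the synthetic cohort study
#'
#' Pure function of (config, master seed): loops subjects with derived
#' seeds and collects their reports.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return list of class `study_report` with `subjects` (list of
#'   [run_subject()] reports), `config` and `seed`.
#' @export
run_study <- function(config, seed = 1L) {
  seed <- as.integer(seed)
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    run_subject(config, subject_seed = seed * 1000L + i, subject_id = i))
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "study_report")
}

#' Summary tables of a cohort study
#'
#' Produces the descriptive tables of the synthetic study: per-artifact
#' frequencies (test, retest, combined; combined counts a subject once if
#' either scan was affected), relative-difference summaries in the
#' myocardium per artifact type, the misalignment offset summary (true
#' versus recovered), the lung-volume test-retest table and the polar-map
#' viability scores before and after correction.
#'
#' @param study a `study_report` from [run_study()].
#' @return list of data frames: `frequency`, `rd`, `misalignment`,
#'   `lung`, `polar`.
#' @export
summarize_study <- function(study) {
  subs <- study$subjects
  n <- length(subs)
  kinds <- c("STN", "SMA", "TRUNCATION", "LSTI", "FSTI", "PMA",
             "MISALIGNMENT")
  present <- function(s, scan, kind) {
    if (kind == "MISALIGNMENT") s$scans[[scan]]$misaligned
    else kind %in% s$scans[[scan]]$artifacts
  }
  freq <- do.call(rbind, lapply(kinds, function(k) {
    t_ <- sum(vapply(subs, present, logical(1), scan = "test", kind = k))
    r_ <- sum(vapply(subs, present, logical(1), scan = "retest", kind = k))
    c_ <- sum(vapply(subs, function(s)
      present(s, "test", k) || present(s, "retest", k), logical(1)))
    data.frame(artifact = k, test = t_, retest = r_, combined = c_,
               n_subjects = n)
  }))

  scan_rows <- do.call(rbind, lapply(subs, function(s)
    do.call(rbind, lapply(names(s$scans), function(sc) {
      x <- s$scans[[sc]]
      data.frame(subject = s$subject, scan = sc,
                 artifacts = paste(sort(c(x$artifacts,
                                          if (x$misaligned) "MISALIGNMENT")),
                                   collapse = "+"),
                 rd_mean = x$rd_mean, rd_max = x$rd_max,
                 offset_mm = x$offset_mm, recovered_mm = x$recovered_mm,
                 lung_volume_L = x$lung_volume_L)
    }))))
  rd <- do.call(rbind, lapply(kinds, function(k) {
    sel <- vapply(seq_len(nrow(scan_rows)), function(i) {
      s <- subs[[scan_rows$subject[i]]]
      present(s, scan_rows$scan[i], k)
    }, logical(1))
    if (!any(sel)) return(NULL)
    data.frame(artifact = k, n_scans = sum(sel),
               rd_mean = mean(scan_rows$rd_mean[sel]),
               rd_sd = stats::sd(scan_rows$rd_mean[sel]),
               rd_max = max(scan_rows$rd_max[sel]))
  }))

  mis <- scan_rows[scan_rows$offset_mm != 0, , drop = FALSE]
  misalignment <- data.frame(
    n_scans_affected = nrow(mis),
    offset_mean_mm = if (nrow(mis)) mean(mis$offset_mm) else NA_real_,
    offset_sd_mm = if (nrow(mis) > 1) stats::sd(mis$offset_mm) else NA_real_,
    recovery_error_mean_mm = if (nrow(mis))
      mean(abs(mis$recovered_mm + mis$offset_mm)) else NA_real_)

  lung <- do.call(rbind, lapply(subs, function(s)
    data.frame(subject = s$subject,
               vol_test_L = s$lung_report$volumes_L[1],
               vol_retest_L = s$lung_report$volumes_L[2],
               ratio = s$lung_report$ratio,
               incoherent = s$lung_report$incoherent)))

  polar <- do.call(rbind, lapply(subs, function(s)
    do.call(rbind, lapply(c("original", "corrected"), function(w)
      data.frame(subject = s$subject, maps = w,
                 extent_pct = s$viability[[w]]$extent_pct,
                 scar_pct = s$viability[[w]]$scar_pct,
                 hibernating_pct = s$viability[[w]]$hibernating_pct)))))

  list(frequency = freq, rd = rd, misalignment = misalignment,
       lung = lung, polar = polar, scans = scan_rows)
}

#' Write study summary tables to CSV
#'
#' @param tables output of [summarize_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
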