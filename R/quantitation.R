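#' Relative-difference map between two reconstructions
#'
#' RD = (corrected / original) x 100%, evaluated only where the original
#' image is above a validity floor (a fraction of its maximum); the ratio
#' is undefined at zero-activity voxels.
#'
#' @param corrected,original [activity_map()]s on the same grid.
#' @param floor validity floor as a fraction of `max(original)`,
#'   default 0.01.
#' @return list of class `rd_map`: `rd` (array in percent, NA outside the
#'   validity mask), `mask` (logical validity mask), `floor`.
#' @export
relative_difference <- function(corrected, original, floor = 0.01) {
  stopifnot(inherits(corrected, "activity_map"),
            inherits(original, "activity_map"), floor > 0)
  if (!same_grid(corrected, original)) stop("maps must share one grid")
  mx <- max(original$data)
  if (mx <= 0) stop("original image is all zero; RD is undefined")
  mask <- original$data >= floor * mx
  rd <- array(NA_real_, original$grid$shape)
  # ratio first: RD(x, x) is then exactly 100 in floating point
  rd[mask] <- 100 * (corrected$data[mask] / original$data[mask])
  structure(list(rd = rd, mask = mask, floor = floor,
                 grid = original$grid), class = "rd_map")
}

#' Threshold segmentation of the myocardium
#'
#' Voxels within a search region whose value is at least 42% of the
#' regional maximum (threshold configurable).
#'
#' @param pet an [activity_map()].
#' @param search_region logical array; in pipeline mode a box around the
#'   LV from phantom ground truth.
#' @param threshold fraction of the regional maximum, default 0.42.
#' @return logical mask array.
#' @export
segment_myocardium <- function(pet, search_region, threshold = 0.42) {
  stopifnot(inherits(pet, "activity_map"))
  region <- array(as.logical(search_region), pet$grid$shape)
  if (!any(region)) stop("search region is empty")
  v <- pet$data[region]
  if (max(v) - min(v) <= 0)
    stop("image is flat in the search region; threshold segmentation is undefined")
  mask <- region & pet$data >= threshold * max(v)
  mask
}

#' Mean and maximum uptake over a mask
#'
#' @param pet an [activity_map()].
#' @param mask logical array, nonempty.
#' @return list of class `myo_stats`: `suv_mean`, `suv_max`, `n_voxels`.
#'   Uptake is reconstructed activity in arbitrary units; only ratios are
#'   interpreted downstream.
#' @export
myo_stats <- function(pet, mask) {
  stopifnot(inherits(pet, "activity_map"))
  mask <- array(as.logical(mask), pet$grid$shape)
  if (!any(mask)) stop("mask is empty")
  v <- pet$data[mask]
  structure(list(suv_mean = mean(v), suv_max = max(v),
                 n_voxels = sum(mask)), class = "myo_stats")
}

#' Lung volume of an attenuation or label map
#'
#' Counts the voxels carrying the lung attenuation coefficient (or the
#' lung label) and multiplies by the voxel volume; reported in litres.
#'
#' @param x a [mu_map()] or [label_map()].
#' @param lung_mu lung coefficient to match when `x` is a mu-map (1/cm).
#' @return volume in litres.
#' @export
lung_volume <- function(x, lung_mu = 0.0224) {
  n <- if (inherits(x, "label_map")) sum(x$data == 1L)
  else if (inherits(x, "mu_map")) sum(abs(x$data - lung_mu) < 1e-9)
  else stop("x must be a label_map or mu_map")
  n * voxel_volume_mm3(x$grid) / 1e6
}

#' Test-retest comparison of two lung volumes
#'
#' @param vol1_L,vol2_L lung volumes of the two acquisitions in litres;
#'   `vol2_L` must be positive.
#' @return list of class `lung_volume_report`: `volumes_L`, `ratio`
#'   (vol1/vol2) and `incoherent`, TRUE iff the intra-scan variation
#'   exceeds 10% (strict inequality).
#' @export
test_retest <- function(vol1_L, vol2_L) {
  if (vol2_L <= 0) stop("second volume must be positive")
  ratio <- vol1_L / vol2_L
  structure(list(volumes_L = c(vol1_L, vol2_L), ratio = ratio,
                 incoherent = abs(ratio - 1) > 0.10),
            class = "lung_volume_report")
}

#' Simplified 17-segment polar map of left-ventricular uptake
#'
#' Samples the LV wall along its long axis (z) into basal, mid and apical
#' thirds plus the apical cap, with the standard sector counts (6 basal,
#' 6 mid, 4 apical, 1 apex). Sector boundaries start at the anterior
#' direction (+y) and advance counterclockwise when viewed from the apex.
#' Segment values are mean uptake per sector, normalized so the maximum
#' segment equals 100. The defect extent is the percentage of segments
#' below the defect threshold.
#'
#' @param pet an [activity_map()].
#' @param lv_geometry list with `center_mm` (x, y), `r_inner_mm`,
#'   `r_outer_mm`, `z_apex_mm`, `z_base_mm`, `cap_mm` (as produced by
#'   [generate_phantom()]).
#' @param defect_threshold segments below this value (on the normalized
#'   0-100 scale) count as defect, default 50.
#' @return list of class `polar_map17`: `segments` (17 values, max = 100),
#'   `defect_extent_pct`, `defect_segments` (logical 17-vector),
#'   `threshold`.
#' @export
polar_map_17 <- function(pet, lv_geometry, defect_threshold = 50) {
  stopifnot(inherits(pet, "activity_map"))
  g <- pet$grid
  co <- voxel_coords(g)
  lv <- lv_geometry
  if (lv$z_apex_mm < min(co[[3]]) - g$voxel_size_mm[3] ||
      lv$z_base_mm > max(co[[3]]) + g$voxel_size_mm[3])
    stop("LV geometry lies outside the volume")
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  X <- matrix(co[[1]], nx, ny)
  Y <- matrix(co[[2]], nx, ny, byrow = TRUE)
  r2 <- (X - lv$center_mm[1])^2 + (Y - lv$center_mm[2])^2
  theta <- atan2(Y - lv$center_mm[2], X - lv$center_mm[1])
  # angle measured from anterior (+y), counterclockwise, in [0, 2*pi)
  ang <- (theta - pi / 2) %% (2 * pi)

  z_cap <- lv$z_apex_mm + lv$cap_mm
  wall_len <- lv$z_base_mm - z_cap
  zc <- co[[3]]
  third <- function(lo, hi) zc >= lo & zc < hi
  z_bounds <- z_cap + wall_len * c(0, 1, 2, 3) / 3
  in_apical <- third(z_bounds[1], z_bounds[2])
  in_mid <- third(z_bounds[2], z_bounds[3])
  in_basal <- zc >= z_bounds[3] & zc <= lv$z_base_mm
  in_capz <- zc >= lv$z_apex_mm & zc < z_cap

  ring2d <- r2 >= lv$r_inner_mm^2 & r2 <= lv$r_outer_mm^2
  disc2d <- r2 <= lv$r_outer_mm^2

  sector <- function(n_sec) floor(ang / (2 * pi / n_sec)) + 1

  seg_vals <- numeric(17)
  seg_n <- integer(17)
  sec6 <- sector(6); sec4 <- sector(4)
  acc <- function(mask3d, sec2d, n_sec, offset) {
    for (s in seq_len(n_sec)) {
      m <- mask3d & outer3d(sec2d == s, rep(TRUE, nz))
      seg_vals[offset + s] <<- if (any(m)) mean(pet$data[m]) else NA_real_
      seg_n[offset + s] <<- sum(m)
    }
  }
  acc(outer3d(ring2d, in_basal), sec6, 6, 0)    # segments 1-6
  acc(outer3d(ring2d, in_mid), sec6, 6, 6)      # segments 7-12
  acc(outer3d(ring2d, in_apical), sec4, 4, 12)  # segments 13-16
  capm <- outer3d(disc2d, in_capz)
  seg_vals[17] <- if (any(capm)) mean(pet$data[capm]) else NA_real_
  seg_n[17] <- sum(capm)
  if (any(is.na(seg_vals)))
    stop("LV geometry produced empty polar-map segments on this grid")
  mx <- max(seg_vals)
  if (mx <= 0) stop("no uptake inside the LV geometry")
  segments <- 100 * seg_vals / mx
  defect <- segments < defect_threshold
  structure(list(segments = segments,
                 defect_extent_pct = 100 * sum(defect) / 17,
                 defect_segments = defect,
                 n_voxels = seg_n,
                 threshold = defect_threshold), class = "polar_map17")
}

#' Scar and hibernating scores from perfusion and metabolism polar maps
#'
#' A segment reduced below the defect threshold in both studies counts as
#' scar; reduced in perfusion but preserved in metabolism counts as
#' hibernating (the perfusion-metabolism mismatch). Percentages are of the
#' 17 left-ventricular segments.
#'
#' @param perfusion,metabolism `polar_map17` objects from the two tracer
#'   studies.
#' @return list of class `viability_scores`: `extent_pct` (perfusion
#'   defect extent), `scar_pct`, `hibernating_pct`.
#' @export
viability_scores <- function(perfusion, metabolism) {
  stopifnot(inherits(perfusion, "polar_map17"),
            inherits(metabolism, "polar_map17"))
  scar <- perfusion$defect_segments & metabolism$defect_segments
  hib <- perfusion$defect_segments & !metabolism$defect_segments
  structure(list(extent_pct = perfusion$defect_extent_pct,
                 scar_pct = 100 * sum(scar) / 17,
                 hibernating_pct = 100 * sum(hib) / 17),
            class = "viability_scores")
}
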