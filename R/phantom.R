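#' Configuration for the stylized thorax phantom
#'
#' The phantom is a stack of nested ellipsoids on an elliptical body
#' cylinder: a subcutaneous fat shell, two lungs clipped at a diaphragm
#' plane, a liver below the diaphragm, arms, and a left-ventricular (LV)
#' wall modelled as an annular cylinder with an apical cap. Everything the
#' downstream analysis measures (tissue-class volumes, ring uptake,
#' artifact adjacency) is preserved at this level of stylization; see the
#' methods vignette.
#'
#' Axial geometry scales with the grid's z extent so that thin-slab grids
#' carry a proportionally reduced lung target volume, mimicking a reduced
#' axial field of view.
#'
#' @param grid_shape integer triple, default c(128, 128, 64).
#' @param voxel_size_mm voxel size, default 2.6 mm isotropic.
#' @param body_half_axes_mm in-plane half axes of the elliptical body.
#' @param body_center_y_mm anterior-posterior offset of the body centre.
#' @param shoulder_start_frac fraction of the axial FOV (from caudal)
#'   above which the body outline tapers toward the shoulders.
#' @param shoulder_scale in-plane scale of the body outline at the
#'   cranial end of the FOV; the taper is linear from 1 at
#'   `shoulder_start_frac`.
#' @param waist_scale in-plane scale of the body outline at the caudal
#'   end of the FOV; the outline widens linearly up to the diaphragm.
#'   Together with the shoulder taper this gives the torso the
#'   non-monotone axial outline (waist, chest, shoulders) that makes
#'   rigid re-alignment against emission data identifiable in both axial
#'   directions.
#' @param fat_shell_mm thickness of the subcutaneous fat shell (0 = none).
#' @param arms logical; include arm cylinders at the lateral FOV edge.
#' @param lung_target_L total lung volume the generator calibrates to, in
#'   litres (cohort scale ~2.6 L at full axial coverage).
#' @param lv list with LV ring geometry: `center_mm` (x, y),
#'   `r_inner_mm`, `r_outer_mm`, `z_apex_mm`, `z_base_mm`, `cap_mm`.
#' @param diaphragm_z_mm axial position of the diaphragm plane.
#' @param activity_ratios named vector of relative tracer uptake for
#'   myocardium, blood pool, liver, lung and background soft tissue; the
#'   myocardium must be strictly largest.
#' @param jitter_sd_mm standard deviation of the seed-driven jitter applied
#'   to organ centres (truncated at 2 sd).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(128L, 128L, 64L),
                           voxel_size_mm = c(2.6, 2.6, 2.6),
                           body_half_axes_mm = c(130, 95),
                           body_center_y_mm = -10,
                           shoulder_start_frac = 0.78,
                           shoulder_scale = 0.55,
                           waist_scale = 0.85,
                           fat_shell_mm = 8,
                           arms = TRUE,
                           lung_target_L = NULL,
                           lv = NULL,
                           diaphragm_z_mm = NULL,
                           activity_ratios = c(myocardium = 8, blood = 2,
                                               liver = 4, lung = 0.5,
                                               background = 1),
                           jitter_sd_mm = 1.5) {
  grid <- grid_spec(grid_shape, voxel_size_mm)
  # scale axial geometry relative to the reference 64-slice 2.6 mm FOV
  fz <- (grid$shape[3] * grid$voxel_size_mm[3]) / (64 * 2.6)
  if (is.null(lung_target_L)) lung_target_L <- 2.6 * fz
  if (is.null(diaphragm_z_mm)) diaphragm_z_mm <- -40 * fz
  if (is.null(lv))
    lv <- list(center_mm = c(-20, -5), r_inner_mm = 22, r_outer_mm = 32,
               z_apex_mm = -20 * fz, z_base_mm = 30 * fz,
               cap_mm = max(voxel_size_mm[3], 10 * fz))
  cfg <- structure(list(
    grid = grid,
    body_half_axes_mm = body_half_axes_mm,
    body_center_y_mm = body_center_y_mm,
    shoulder_start_frac = shoulder_start_frac,
    shoulder_scale = shoulder_scale,
    waist_scale = waist_scale,
    fat_shell_mm = fat_shell_mm,
    arms = arms,
    arm_offset_mm = 12, arm_half_axes_mm = c(18, 24),
    lung_target_L = lung_target_L,
    lung_half_axes_mm = c(42, 62, 70 * fz),
    lung_center_x_mm = 62, lung_center_y_mm = 5, lung_center_z_mm = 15 * fz,
    liver_center_mm = c(55, -20, diaphragm_z_mm - 18 * fz),
    liver_half_axes_mm = c(58, 50, 26 * fz),
    sternum_mm = c(0, body_center_y_mm + body_half_axes_mm[2] -
                     fat_shell_mm - 12, 10 * fz),
    diaphragm_z_mm = diaphragm_z_mm,
    lv = lv,
    activity_ratios = activity_ratios,
    jitter_sd_mm = jitter_sd_mm
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  lv <- cfg$lv
  if (!(lv$r_outer_mm > lv$r_inner_mm && lv$r_inner_mm > 0))
    stop("LV radii must satisfy outer > inner > 0")
  if (!(cfg$lung_target_L > 0.5 * cfg$grid$shape[3] * cfg$grid$voxel_size_mm[3] / (64 * 2.6) &&
        cfg$lung_target_L < 6.0))
    stop("lung target volume out of the supported range")
  r <- cfg$activity_ratios
  if (any(r < 0)) stop("activity ratios must be nonnegative")
  if (!(r[["myocardium"]] > max(r[setdiff(names(r), "myocardium")])))
    stop("myocardium activity ratio must be strictly largest")
  if (lv$z_base_mm <= lv$z_apex_mm) stop("LV base must lie above the apex")
  invisible(cfg)
}

# truncated-normal jitter, deterministic under the caller's seed
jitter_mm <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

#' Generate a digital thorax phantom
#'
#' Builds the four-class tissue label map and the ground-truth activity
#' map. The lungs are calibrated by bisection of a global scale factor so
#' the rasterized lung volume matches the configured target. Organ centres
#' receive a small seed-driven jitter; the function is a pure function of
#' (config, seed).
#'
#' @param config a [phantom_config()].
#' @param seed integer seed driving the anatomical jitter.
#' @return A list of class `phantom` with elements `labels`
#'   ([label_map()]), `activity` ([activity_map()]), `lv` (LV geometry for
#'   polar-map sampling), `masks` (logical arrays: myocardium, blood,
#'   liver, lungs), `config`, `seed`.
#' @export
generate_phantom <- function(config, seed = 1L) {
  g <- config$grid
  co <- voxel_coords(g)
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  jl <- jitter_mm(2, config$jitter_sd_mm)   # lung centre (x magnitude, y)
  jh <- jitter_mm(2, config$jitter_sd_mm)   # LV centre
  jv <- jitter_mm(2, config$jitter_sd_mm)   # liver centre (x, y)

  X <- matrix(co[[1]], nx, ny)
  Y <- matrix(co[[2]], nx, ny, byrow = TRUE)
  zc <- co[[3]]

  bx <- config$body_half_axes_mm[1]; by <- config$body_half_axes_mm[2]
  cy <- config$body_center_y_mm
  ft <- config$fat_shell_mm

  # axial body outline: waist below the diaphragm, chest, shoulder taper
  zmin <- min(zc); zmax <- max(zc)
  z_sh <- zmin + config$shoulder_start_frac * (zmax - zmin)
  z_d <- config$diaphragm_z_mm
  kz <- ifelse(zc <= z_d,
               config$waist_scale + (1 - config$waist_scale) *
                 (zc - zmin) / max(z_d - zmin, 1),
               ifelse(zc <= z_sh, 1,
                      1 - (1 - config$shoulder_scale) * (zc - z_sh) /
                        (zmax - z_sh)))

  labels <- array(0L, g$shape)
  inner3d <- array(FALSE, g$shape)
  ar <- config$arm_half_axes_mm
  for (iz in seq_len(nz)) {
    k <- kz[iz]
    body2d <- (X / (bx * k))^2 + ((Y - cy) / (by * k))^2 <= 1
    inner2d <- (X / max(bx * k - ft, 1))^2 +
      ((Y - cy) / max(by * k - ft, 1))^2 <= 1
    lab2d <- matrix(0L, nx, ny)
    lab2d[body2d] <- 2L          # fat shell ...
    lab2d[inner2d] <- 3L         # ... soft interior
    if (ft <= 0) lab2d[body2d] <- 3L
    if (config$arms) {
      ax <- bx * k + config$arm_offset_mm
      arm2d <- ((abs(X) - ax) / ar[1])^2 + ((Y - cy) / ar[2])^2 <= 1
      lab2d[arm2d] <- 3L
    }
    labels[, , iz] <- lab2d
    inner3d[, , iz] <- inner2d
  }

  # LV annulus + apical cap + blood pool (soft tissue, overwrites lung)
  lvc <- config$lv$center_mm + jh
  r2 <- (X - lvc[1])^2 + (Y - lvc[2])^2
  ri2 <- config$lv$r_inner_mm^2; ro2 <- config$lv$r_outer_mm^2
  z_apex <- config$lv$z_apex_mm; z_base <- config$lv$z_base_mm
  z_cap <- z_apex + config$lv$cap_mm
  in_wall_z <- zc >= z_cap & zc <= z_base
  in_cap_z <- zc >= z_apex & zc < z_cap
  ring2d <- r2 >= ri2 & r2 <= ro2
  disc2d <- r2 <= ro2
  pool2d <- r2 < ri2
  myo <- outer3d(ring2d, in_wall_z) | outer3d(disc2d, in_cap_z)
  blood <- outer3d(pool2d, in_wall_z)
  if (any((myo | blood) & !inner3d))
    stop("LV ring exits the body outline; adjust the configuration")

  # lungs: scale calibrated so the labelled volume hits the target
  lx <- config$lung_center_x_mm + abs(jl[1]); ly <- config$lung_center_y_mm + jl[2]
  lz <- config$lung_center_z_mm
  ha <- config$lung_half_axes_mm
  qz <- ((zc - lz) / ha[3])^2
  qL <- array(rep((X + lx)^2 / ha[1]^2 + (Y - ly)^2 / ha[2]^2, nz), g$shape) +
    rep(qz, each = nx * ny)
  qR <- array(rep((X - lx)^2 / ha[1]^2 + (Y - ly)^2 / ha[2]^2, nz), g$shape) +
    rep(qz, each = nx * ny)
  above_d <- rep(zc > config$diaphragm_z_mm, each = nx * ny)
  eligible <- inner3d & above_d & !(myo | blood)
  qmin <- pmin(qL, qR)
  target_vox <- config$lung_target_L * 1e6 / voxel_volume_mm3(g)
  lo <- 0.25; hi <- 2.5
  count_at <- function(s) sum(eligible & qmin < s^2)
  if (count_at(hi) < 0.85 * target_vox)
    stop("lung target volume unreachable inside this body/grid")
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target_vox) lo <- mid else hi <- mid
  }
  s <- hi
  lungs <- eligible & qmin < s^2
  labels[lungs] <- 1L
  labels[myo | blood] <- 3L

  # liver below the diaphragm (soft tissue; separate activity)
  lc <- config$liver_center_mm + c(jv, 0)
  qliv <- array(rep((X - lc[1])^2 / config$liver_half_axes_mm[1]^2 +
                      (Y - lc[2])^2 / config$liver_half_axes_mm[2]^2, nz),
                g$shape) +
    rep(((zc - lc[3]) / config$liver_half_axes_mm[3])^2, each = nx * ny)
  liver <- qliv < 1 & inner3d & !above_d & !(myo | blood)

  r <- config$activity_ratios
  act <- array(0, g$shape)
  act[labels == 2L | labels == 3L] <- r[["background"]]
  act[labels == 1L] <- r[["lung"]]
  act[liver] <- r[["liver"]]
  act[blood] <- r[["blood"]]
  act[myo] <- r[["myocardium"]]

  structure(list(
    labels = label_map(labels, g),
    activity = activity_map(act, g),
    lv = list(center_mm = lvc, r_inner_mm = config$lv$r_inner_mm,
              r_outer_mm = config$lv$r_outer_mm, z_apex_mm = z_apex,
              z_base_mm = z_base, cap_mm = config$lv$cap_mm),
    masks = list(myocardium = myo, blood = blood, liver = liver,
                 lungs = labels == 1L),
    organs = list(lung_left = c(-lx, ly, lz), lung_right = c(lx, ly, lz),
                  liver = lc, sternum = config$sternum_mm,
                  arm_edge_x = config$body_half_axes_mm[1] + 4),
    lung_scale = s,
    config = config, seed = as.integer(seed)
  ), class = "phantom")
}

# logical 3-D array from an in-plane mask and a per-slice predicate
outer3d <- function(mask2d, keep_z) {
  out <- array(rep(mask2d, length(keep_z)), c(dim(mask2d), length(keep_z)))
  out & rep(keep_z, each = length(mask2d))
}
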