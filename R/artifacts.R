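#' Geometric regions for artifact placement
#'
#' Regions are specified in world mm and rasterized centre-inclusive: a
#' voxel belongs to a region iff its centre does.
#'
#' @param center_mm,radius_mm sphere centre and radius.
#' @name regions
NULL

#' @rdname regions
#' @export
region_sphere <- function(center_mm, radius_mm) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(kind = "sphere", center = as.numeric(center_mm),
                 radius = radius_mm), class = "region")
}

#' @rdname regions
#' @param lo_mm,hi_mm box corners (x, y, z) in mm.
#' @export
region_box <- function(lo_mm, hi_mm) {
  stopifnot(all(hi_mm >= lo_mm))
  structure(list(kind = "box", lo = as.numeric(lo_mm),
                 hi = as.numeric(hi_mm)), class = "region")
}

#' @rdname regions
#' @param z_lo_mm,z_hi_mm axial extent of a transaxial band.
#' @export
region_band <- function(z_lo_mm, z_hi_mm) {
  stopifnot(z_hi_mm >= z_lo_mm)
  structure(list(kind = "band", lo = z_lo_mm, hi = z_hi_mm),
            class = "region")
}

#' @rdname regions
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param position_mm plane position along `axis`.
#' @param side +1 keeps coordinates greater than `position_mm` in the
#'   region, -1 keeps smaller ones.
#' @export
region_halfplane <- function(axis, position_mm, side = 1) {
  stopifnot(axis %in% 1:3, side %in% c(-1, 1))
  structure(list(kind = "halfplane", axis = axis, position = position_mm,
                 side = side), class = "region")
}

# rasterize a region to a logical array on a grid (centre-inclusive)
region_mask <- function(region, grid) {
  co <- voxel_coords(grid)
  n <- grid$shape
  switch(region$kind,
    sphere = {
      dx2 <- (co[[1]] - region$center[1])^2
      dy2 <- (co[[2]] - region$center[2])^2
      dz2 <- (co[[3]] - region$center[3])^2
      q <- outer(outer(dx2, dy2, "+"), dz2, "+")
      array(q <= region$radius^2, n)
    },
    box = {
      inx <- co[[1]] >= region$lo[1] & co[[1]] <= region$hi[1]
      iny <- co[[2]] >= region$lo[2] & co[[2]] <= region$hi[2]
      inz <- co[[3]] >= region$lo[3] & co[[3]] <= region$hi[3]
      outer(outer(inx, iny, "&"), inz, "&")
    },
    band = {
      inz <- co[[3]] >= region$lo & co[[3]] <= region$hi
      array(rep(inz, each = n[1] * n[2]), n)
    },
    halfplane = {
      keep <- region$side * (co[[region$axis]] - region$position) > 0
      a <- array(FALSE, n)
      idx <- which(keep)
      if (region$axis == 1) a[idx, , ] <- TRUE
      else if (region$axis == 2) a[, idx, ] <- TRUE
      else a[, , idx] <- TRUE
      a
    },
    stop("unknown region kind"))
}

#' Declarative artifact specification
#'
#' Artifact taxonomy of four-class MR-derived attenuation maps:
#' \describe{
#'   \item{STN}{susceptibility void from sternal wires: fat/soft voxels in
#'     the region misclassified as air.}
#'   \item{SMA}{susceptibility void from stents/valves, same effect as STN
#'     but placed near the heart.}
#'   \item{LSTI}{lung and soft tissue swapped inside the region.}
#'   \item{FSTI}{fat and soft tissue swapped inside the region.}
#'   \item{PMA}{photopenic respiratory artifact: a transaxial band of lung
#'     voxels above the diaphragm set to soft tissue.}
#'   \item{TRUNCATION}{tissue beyond a lateral half-plane removed (limited
#'     MR field of view cutting the arms).}
#'   \item{MISALIGNMENT}{rigid offset of the attenuation map relative to
#'     the emission data; applied with [shift_map()], not with
#'     [inject_artifact()].}
#' }
#'
#' @param kind one of the artifact codes above.
#' @param region a region object (see [region_sphere()] and friends); for
#'   MISALIGNMENT may be NULL.
#' @param magnitude kind-specific: shift vector in mm for MISALIGNMENT,
#'   unused otherwise.
#' @param seed integer bookkeeping seed.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind, region = NULL, magnitude = NULL, seed = 0L) {
  kind <- match.arg(kind, c("STN", "SMA", "LSTI", "FSTI", "PMA",
                            "TRUNCATION", "MISALIGNMENT"))
  if (kind == "MISALIGNMENT") {
    stopifnot(!is.null(magnitude), length(magnitude) == 3)
    if (sqrt(sum(magnitude^2)) > 30)
      stop("misalignment shift magnitude must be <= 30 mm")
  } else if (is.null(region)) {
    stop("artifact kind ", kind, " requires a region")
  }
  structure(list(kind = kind, region = region, magnitude = magnitude,
                 seed = as.integer(seed)), class = "artifact_spec")
}

#' Inject an artifact into a tissue label map
#'
#' Applies the label-space artifact classes (everything except
#' MISALIGNMENT, which acts on the attenuation map via [shift_map()]).
#' Voxels outside the spec's region are untouched. STN/SMA set fat and
#' soft voxels in the region to background; LSTI swaps lung and soft;
#' FSTI swaps fat and soft; PMA sets lung voxels in a transaxial band to
#' soft tissue; TRUNCATION clears every voxel beyond a lateral half-plane.
#'
#' @param labels a [label_map()].
#' @param spec an [artifact_spec()].
#' @return list with `labels` (new [label_map()]), `mask` (logical array
#'   of voxels whose label changed) and `n_changed`.
#' @export
inject_artifact <- function(labels, spec) {
  stopifnot(inherits(labels, "label_map"), inherits(spec, "artifact_spec"))
  if (spec$kind == "MISALIGNMENT")
    stop("MISALIGNMENT acts on the mu-map; use shift_map()")
  g <- labels$grid
  rm_ <- region_mask(spec$region, g)
  if (!any(rm_))
    stop("region of artifact ", spec$kind, " does not intersect the grid")
  l <- labels$data
  new <- l
  target <- switch(spec$kind,
    STN = , SMA = rm_ & (l == 2L | l == 3L),
    LSTI = rm_ & (l == 1L | l == 3L),
    FSTI = rm_ & (l == 2L | l == 3L),
    PMA = {
      if (spec$region$kind != "band")
        stop("PMA requires a transaxial band region")
      rm_ & l == 1L
    },
    TRUNCATION = {
      if (spec$region$kind != "halfplane")
        stop("TRUNCATION requires a half-plane region")
      rm_ & l != 0L
    })
  if (!any(target))
    stop("artifact ", spec$kind,
         ": region contains no applicable tissue voxels")
  switch(spec$kind,
    STN = , SMA = { new[target] <- 0L },
    LSTI = {
      new[target & l == 1L] <- 3L
      new[target & l == 3L] <- 1L
    },
    FSTI = {
      new[target & l == 2L] <- 3L
      new[target & l == 3L] <- 2L
    },
    PMA = { new[target] <- 3L },
    TRUNCATION = { new[target] <- 0L })
  changed <- new != l
  list(labels = label_map(new, g), mask = changed,
       n_changed = sum(changed))
}

#' Rigid integer-voxel translation of a volume
#'
#' Shifts are quantized to whole voxels (round-half-away-from-zero) so
#' that the four-class structure of attenuation maps survives without
#' interpolation. Voxels shifted in from outside the grid are filled with
#' zero (background).
#'
#' @param volume a `mu_map`, `activity_map` or `label_map`.
#' @param shift_mm real triple, |shift| <= 30 mm.
#' @return A volume of the same class, translated by
#'   `round(shift_mm / voxel_size)` voxels.
#' @export
shift_map <- function(volume, shift_mm) {
  stopifnot(length(shift_mm) == 3)
  if (any(!is.finite(shift_mm))) stop("shift must be finite")
  if (sqrt(sum(shift_mm^2)) > 30 + 1e-9)
    stop("shift magnitude must be <= 30 mm")
  g <- volume$grid
  sv <- round_half_away(shift_mm / g$voxel_size_mm)
  a <- volume$data
  out <- array(if (is.integer(a)) 0L else 0, g$shape)
  n <- g$shape
  src <- lapply(1:3, function(ax) {
    i <- seq_len(n[ax]) - sv[ax]
    i[i >= 1 & i <= n[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    i <- seq_len(n[ax])
    i[i - sv[ax] >= 1 & i - sv[ax] <= n[ax]]
  })
  if (all(lengths(src) > 0))
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  switch(class(volume)[1],
         mu_map = mu_map(out, g),
         activity_map = activity_map(out, g),
         label_map = label_map(out, g))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
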