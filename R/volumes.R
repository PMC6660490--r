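#' Volumetric grid specification
#'
#' Defines the sampling grid shared by all volumes in the pipeline. Axes
#' follow the scanner convention x = left to right, y = posterior to
#' anterior, z = caudal to cranial; world coordinates are in mm with the
#' origin at the centre of the field of view.
#'
#' @param shape integer triple (nx, ny, nz); each dimension must be >= 16.
#' @param voxel_size_mm positive real triple, default 2.6 mm isotropic
#'   (the voxel size of the four-class MR-derived attenuation maps this
#'   package emulates).
#' @param origin_mm world coordinate of the volume centre; nonzero after
#'   cropping so that geometry stated in world mm stays valid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, voxel_size_mm = c(2.6, 2.6, 2.6),
                      origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(voxel_size_mm) == 3,
            length(origin_mm) == 3)
  if (any(shape < 16L))
    stop("all grid dimensions must be >= 16")
  if (any(voxel_size_mm <= 0))
    stop("voxel sizes must be positive")
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d x %d voxels at (%.3g, %.3g, %.3g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `grid_spec`
#' @return scalar voxel volume in mm^3
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

# Voxel-centre world coordinates (mm) per axis.
voxel_coords <- function(grid) {
  n <- grid$shape; d <- grid$voxel_size_mm; o <- grid$origin_mm
  lapply(1:3, function(a) (seq_len(n[a]) - (n[a] + 1) / 2) * d[a] + o[a])
}

same_grid <- function(a, b) {
  identical(a$grid$shape, b$grid$shape) &&
    isTRUE(all.equal(a$grid$voxel_size_mm, b$grid$voxel_size_mm)) &&
    isTRUE(all.equal(a$grid$origin_mm, b$grid$origin_mm))
}

#' Tissue label map
#'
#' Four-class segmentation volume: 0 = background/air, 1 = lung, 2 = fat,
#' 3 = soft tissue. This is the stand-in for a segmented MR-derived
#' attenuation-correction map before coefficients are assigned.
#'
#' @param labels integer array matching `grid$shape`, values in 0:3.
#' @param grid a `grid_spec`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, grid) {
  labels <- as.integer(labels)
  dim(labels) <- grid$shape
  if (!all(labels %in% 0:3))
    stop("label map may only contain codes 0 (background), 1 (lung), 2 (fat), 3 (soft)")
  structure(list(grid = grid, data = labels), class = "label_map")
}

#' Activity map
#'
#' Nonnegative tracer activity on a grid (arbitrary units). Both the
#' ground-truth phantom activity and reconstructed PET images use this
#' container.
#'
#' @param values numeric array matching `grid$shape`, all finite and >= 0.
#' @param grid a `grid_spec`.
#' @return An object of class `activity_map`.
#' @export
activity_map <- function(values, grid) {
  values <- as.numeric(values)
  dim(values) <- grid$shape
  if (any(!is.finite(values)) || any(values < 0))
    stop("activity values must be finite and nonnegative")
  structure(list(grid = grid, data = values), class = "activity_map")
}

#' Attenuation coefficient map
#'
#' Linear attenuation coefficients at 511 keV in 1/cm on a grid.
#'
#' @param mu numeric array matching `grid$shape`, finite, >= 0.
#' @param grid a `grid_spec`.
#' @return An object of class `mu_map`.
#' @export
mu_map <- function(mu, grid) {
  mu <- as.numeric(mu)
  dim(mu) <- grid$shape
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("attenuation coefficients must be finite and nonnegative")
  structure(list(grid = grid, data = mu), class = "mu_map")
}

#' Crop a volume to a range of axial slices
#'
#' Keeps in-plane sampling unchanged; useful for running the slice-based
#' reconstruction on a thin slab around the heart.
#'
#' @param vol a `label_map`, `activity_map` or `mu_map`.
#' @param z_range integer pair (first, last) of 1-based slice indices.
#' @return A volume of the same class on the cropped grid.
#' @export
crop_z <- function(vol, z_range) {
  z <- seq.int(z_range[1], z_range[2])
  stopifnot(min(z) >= 1, max(z) <= vol$grid$shape[3])
  zc <- voxel_coords(vol$grid)[[3]]
  g <- grid_spec(c(vol$grid$shape[1:2], length(z)), vol$grid$voxel_size_mm,
                 origin_mm = c(vol$grid$origin_mm[1:2], mean(zc[z])))
  data <- vol$data[, , z, drop = FALSE]
  switch(class(vol)[1],
         label_map = label_map(data, g),
         activity_map = activity_map(data, g),
         mu_map = mu_map(data, g),
         stop("unsupported volume class"))
}

#' Write a volume to NIfTI-1
#'
#' @param vol a `label_map`, `activity_map` or `mu_map`.
#' @param path output file, conventionally `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(array(as.numeric(vol$data), dim = vol$grid$shape))
  RNifti::pixdim(img) <- vol$grid$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @param type one of "activity", "label", "mu".
#' @return the corresponding volume object.
#' @export
read_volume <- function(path, type = c("activity", "label", "mu")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  g <- grid_spec(dim(img)[1:3], RNifti::pixdim(img)[1:3])
  a <- array(as.numeric(img), dim = g$shape)
  switch(type,
         activity = activity_map(a, g),
         label = label_map(round(a), g),
         mu = mu_map(a, g))
}
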