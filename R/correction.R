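#' Fill susceptibility gaps by six-neighbour majority vote
#'
#' Iterative wavefront fill of an artifact region in a four-class label
#' map. In each pass, every still-unassigned artifact voxel with at least
#' one assigned face-neighbour (6-connectivity) receives the most frequent
#' class among its non-artifact or already-assigned face-neighbours; ties
#' are broken by the fixed priority soft (3) > fat (2) > lung (1) >
#' background (0). Passes repeat until the region is filled, peeling the
#' artifact inward like an onion. Voxels outside the mask are untouched.
#'
#' @param labels a [label_map()] containing the artifact.
#' @param artifact_mask logical array marking the artifact voxels.
#' @return list with `labels` (filled [label_map()]) and `report`
#'   (artifact voxel count, per-class assigned counts, number of passes,
#'   unresolved count).
#' @export
fill_susceptibility <- function(labels, artifact_mask) {
  stopifnot(inherits(labels, "label_map"))
  g <- labels$grid
  mask <- array(as.logical(artifact_mask), g$shape)
  if (!any(mask)) stop("artifact mask is empty")
  if (all(mask))
    stop("artifact mask covers the entire volume; no seed neighbours exist")
  l <- labels$data
  assigned <- !mask
  n_art <- sum(mask)
  passes <- 0L
  while (any(!assigned)) {
    counts <- lapply(0:3, function(cl) {
      v <- array(0L, g$shape)
      src <- (l == cl) & assigned
      v + shift_int(src, 1, 1) + shift_int(src, 1, -1) +
        shift_int(src, 2, 1) + shift_int(src, 2, -1) +
        shift_int(src, 3, 1) + shift_int(src, 3, -1)
    })
    total <- counts[[1]] + counts[[2]] + counts[[3]] + counts[[4]]
    front <- !assigned & total > 0L
    if (!any(front)) break
    # argmax with priority soft > fat > lung > background
    best_cl <- array(3L, g$shape)
    best_ct <- counts[[4]]
    for (cl in c(2L, 1L, 0L)) {
      better <- counts[[cl + 1L]] > best_ct
      best_cl[better] <- cl
      best_ct[better] <- counts[[cl + 1L]][better]
    }
    l[front] <- best_cl[front]
    assigned <- assigned | front
    passes <- passes + 1L
  }
  unresolved <- sum(!assigned)
  out <- label_map(l, g)
  assigned_counts <- vapply(0:3, function(cl) sum(mask & out$data == cl),
                            integer(1))
  names(assigned_counts) <- c("background", "lung", "fat", "soft")
  list(labels = out,
       report = list(artifact_voxels = n_art,
                     assigned = assigned_counts,
                     passes = passes,
                     unresolved = unresolved))
}

# integer shift of a logical array along one axis (zero fill), as counts
shift_int <- function(x, axis, by) {
  n <- dim(x)
  out <- array(0L, n)
  i <- seq_len(n[axis])
  src <- i - by
  ok <- src >= 1 & src <= n[axis]
  idx_dst <- i[ok]; idx_src <- src[ok]
  if (axis == 1) out[idx_dst, , ] <- x[idx_src, , ]
  else if (axis == 2) out[, idx_dst, ] <- x[, idx_src, ]
  else out[, , idx_dst] <- x[, , idx_src]
  out
}

# body-support mask: voxels above a fraction of the image maximum,
# reduced to the largest 6-connected component, with internal holes
# filled (low-uptake lung regions belong to the body support)
body_support_mask <- function(values, threshold = 0.05, largest = TRUE) {
  m <- values >= threshold * max(values)
  if (!any(m)) stop("support mask is empty")
  if (largest) {
    lab <- cpp_label_components(array(as.integer(m), dim(m)), dim(m))
    tab <- tabulate(lab[lab > 0])
    m <- array(lab == which.max(tab), dim(m))
    m <- fill_holes3d(m)
  }
  m
}

# fill cavities: complement components not touching a lateral grid face.
# The axial faces are excluded because the torso is cut by the axial FOV;
# regions open only toward an axial face are still internal.
fill_holes3d <- function(mask) {
  n <- dim(mask)
  lab <- cpp_label_components(array(as.integer(!mask), n), n)
  edge <- unique(c(lab[1, , ], lab[n[1], , ], lab[, 1, ], lab[, n[2], ]))
  edge <- edge[edge > 0]
  array(!(lab %in% edge) | mask, n)
}

#' Estimate the rigid offset between an attenuation map and emission data
#'
#' Surrogate for the visual alignment check of attenuation maps against
#' the non-attenuation-corrected (nonAC) PET: an exhaustive integer-voxel
#' translation search maximizing the Dice overlap between the body-support
#' mask of the nonAC PET (threshold at 5% of its maximum) and the body
#' mask of the attenuation map (mu > 0). The default range emphasizes the
#' axial direction, where respiratory offsets occur.
#'
#' @param nonac_pet nonAC reconstruction ([activity_map()]).
#' @param mu the (possibly misaligned) [mu_map()] on the same grid.
#' @param search_mm list with per-axis half-ranges in mm, default
#'   `list(x = 10, y = 10, z = 20)`.
#' @param support_threshold fraction of the nonAC maximum defining its
#'   body-support mask.
#' @return list of class `shift_estimate`: `shift_mm` (translation to
#'   apply to the mu-map), `shift_vox`, `dice` (overlap score in \[0, 1\]),
#'   `search_mm`.
#' @export
estimate_shift <- function(nonac_pet, mu,
                           search_mm = list(x = 10, y = 10, z = 20),
                           support_threshold = 0.05) {
  stopifnot(inherits(nonac_pet, "activity_map"), inherits(mu, "mu_map"))
  if (!same_grid(nonac_pet, mu)) stop("volumes must share one grid")
  g <- nonac_pet$grid
  if (max(nonac_pet$data) <= 0 || stats::sd(nonac_pet$data) == 0)
    stop("nonAC PET is constant; no support mask can be derived")
  A <- body_support_mask(nonac_pet$data, support_threshold, largest = TRUE)
  B <- mu$data > 0
  if (!any(B)) stop("mu-map has empty body mask")
  rng <- lapply(1:3, function(ax) {
    r <- floor(c(search_mm$x, search_mm$y, search_mm$z)[ax] /
                 g$voxel_size_mm[ax])
    seq.int(-r, r)
  })
  shifts <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  # smallest shifts first so ties resolve toward the identity
  shifts <- shifts[order(rowSums(shifts^2)), , drop = FALSE]
  dice <- cpp_shift_dice(array(as.integer(A), g$shape),
                         array(as.integer(B), g$shape),
                         g$shape, shifts)
  best <- which.max(dice)
  sv <- as.integer(shifts[best, ])
  structure(list(shift_mm = sv * g$voxel_size_mm,
                 shift_vox = sv,
                 dice = dice[best],
                 search_mm = search_mm),
            class = "shift_estimate")
}

#' Complete a truncated attenuation map from the emission support
#'
#' Surrogate for vendor-style truncation completion: voxels that lie
#' inside the body-support mask of the nonAC PET (5% of maximum, largest
#' connected component) but are background in the attenuation map receive
#' the soft-tissue coefficient. No other voxel is modified.
#'
#' @param mu a [mu_map()] aligned with the emission data.
#' @param nonac_pet nonAC reconstruction defining the body support.
#' @param soft_mu coefficient assigned to restored voxels (1/cm).
#' @param support_threshold fraction of the nonAC maximum.
#' @return list with `mu` (completed [mu_map()]), `restored_mask` and
#'   `n_restored`.
#' @export
complete_truncation <- function(mu, nonac_pet, soft_mu = 0.1000,
                                support_threshold = 0.05) {
  stopifnot(inherits(mu, "mu_map"), inherits(nonac_pet, "activity_map"))
  if (!same_grid(mu, nonac_pet)) stop("volumes must share one grid")
  support <- body_support_mask(nonac_pet$data, support_threshold,
                               largest = TRUE)
  restore <- support & mu$data == 0
  out <- mu$data
  out[restore] <- soft_mu
  list(mu = mu_map(out, mu$grid), restored_mask = restore,
       n_restored = sum(restore))
}
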