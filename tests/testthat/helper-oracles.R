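# Independent oracles, coded without reference to the package internals.

# Brute-force wavefront majority fill: plain triple loops, simultaneous
# update per pass, tie-break priority soft(3) > fat(2) > lung(1) > bg(0).
oracle_wavefront_fill <- function(labels, mask) {
  n <- dim(labels)
  l <- labels
  assigned <- !mask
  passes <- 0L
  repeat {
    if (all(assigned)) break
    newl <- l
    newa <- assigned
    changed <- FALSE
    for (x in seq_len(n[1])) for (y in seq_len(n[2])) for (z in seq_len(n[3])) {
      if (assigned[x, y, z]) next
      counts <- c(0L, 0L, 0L, 0L) # classes 0..3
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
        if (xx < 1 || xx > n[1] || yy < 1 || yy > n[2] ||
            zz < 1 || zz > n[3]) next
        if (assigned[xx, yy, zz])
          counts[l[xx, yy, zz] + 1L] <- counts[l[xx, yy, zz] + 1L] + 1L
      }
      if (sum(counts) == 0L) next
      best <- 3L
      for (cl in c(2L, 1L, 0L))
        if (counts[cl + 1L] > counts[best + 1L]) best <- cl
      newl[x, y, z] <- best
      newa[x, y, z] <- TRUE
      changed <- TRUE
    }
    l <- newl; assigned <- newa
    passes <- passes + 1L
    if (!changed) break
  }
  l
}

# Fine-step nearest-neighbour ray march through a piecewise-constant
# slice image (voxel size d, centred coordinates), for projector checks.
oracle_ray_march <- function(img, d, p0, u, step = 0.02) {
  n <- dim(img)
  half <- c(n[1], n[2]) * d / 2
  tmax <- sqrt(sum((2 * half)^2))
  t <- seq(-tmax, tmax, by = step)
  xs <- p0[1] + t * u[1]
  ys <- p0[2] + t * u[2]
  i <- floor((xs + half[1]) / d) + 1
  j <- floor((ys + half[2]) / d) + 1
  ok <- i >= 1 & i <= n[1] & j >= 1 & j <= n[2]
  sum(img[cbind(i[ok], j[ok])]) * step
}
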