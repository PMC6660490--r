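make_disc <- function(n = 32L, d = 2.6, r_mm = 30, hot_r_mm = 10,
                      nz = 16L) {
  g <- grid_spec(c(n, n, nz), c(d, d, d))
  co <- dixonac:::voxel_coords(g)
  r2 <- outer(co[[1]]^2, co[[2]]^2, "+")
  act <- array(rep((r2 <= r_mm^2) * 1 + (r2 <= hot_r_mm^2) * 3, nz),
               g$shape)
  mu <- array(rep((r2 <= r_mm^2) * 0.1, nz), g$shape)
  list(activity = activity_map(act, g), mu = mu_map(mu, g), grid = g)
}

test_that("mu lookup assigns the standard lung coefficient and one value per class", {
  tab <- mu_table()
  expect_equal(unname(tab["lung"]), 0.0224)
  g <- grid_spec(c(16, 16, 16))
  l <- array(0L, g$shape)
  l[8, 8, 8] <- 1L; l[9, 8, 8] <- 2L; l[10, 8, 8] <- 3L
  mu <- labels_to_mu(label_map(l, g), tab)
  expect_equal(mu$data[8, 8, 8], 0.0224)
  expect_equal(sort(unique(as.vector(mu$data))),
               sort(unname(unclass(tab))))
  expect_error(mu_table(lung = 0.2), "lung < fat < soft")
})

test_that("projector matches the closed-form attenuated line integral to 6 significant figures", {
  g <- grid_spec(c(32, 32, 16), c(2, 2, 2))
  a <- array(0, g$shape); a[, 16, 8] <- 3    # row of activity along x
  mu <- array(0, g$shape); mu[10, , ] <- 0.1 # 2 mm slab, perpendicular
  p <- forward_project(activity_map(a, g), mu_map(mu, g),
                       recon_protocol(n_angles = 210))
  # LOR along x at the row's y: a*L through vacuum times exp(-mu * t_cm)
  expect_equal(p$data[1, 16, 8], 3 * 64 * exp(-0.1 * 0.2),
               tolerance = 1e-7)
  # vacuum case
  p0 <- forward_project(activity_map(a, g), NULL,
                        recon_protocol(n_angles = 210))
  expect_equal(p0$data[1, 16, 8], 3 * 64, tolerance = 1e-12)
})

test_that("projector agrees with a fine ray-march oracle on random LORs", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  worst <- 0
  for (i in 1:200) {
    th <- runif(1, 0, pi); s <- runif(1, -28, 28)
    u <- c(cos(th), sin(th)); p0 <- s * c(-sin(th), cos(th))
    v1 <- dixonac:::cpp_ray_integral(img, 2, p0[1], p0[2], u[1], u[2])
    v2 <- oracle_ray_march(img, 2, p0, u)
    if (v1 > 1) worst <- max(worst, abs(v1 - v2) / v1)
  }
  expect_lt(worst, 0.005)
})

test_that("zero activity projects to a zero sinogram and grids must match", {
  g <- grid_spec(c(16, 16, 16))
  z <- activity_map(array(0, g$shape), g)
  expect_true(all(forward_project(z, NULL, recon_protocol())$data == 0))
  g2 <- grid_spec(c(16, 16, 16), c(2, 2, 2))
  mu2 <- mu_map(array(0, g2$shape), g2)
  expect_error(forward_project(z, mu2, recon_protocol()), "grid")
})

test_that("Poisson noise preserves expectation, is seed-reproducible and vanishes at high counts", {
  d <- make_disc()
  sino <- forward_project(d$activity, d$mu, recon_protocol())
  n1 <- add_poisson_noise(sino, 1e6, seed = 3)
  n2 <- add_poisson_noise(sino, 1e6, seed = 3)
  expect_identical(n1$data, n2$data)
  big <- sino$data > 1
  rel_rms <- sqrt(mean(((n1$data[big] - sino$data[big]) /
                          sino$data[big])^2))
  expect_lt(rel_rms, 0.01)
  zero <- add_poisson_noise(new_zero <- forward_project(
    activity_map(array(0, d$grid$shape), d$grid), NULL, recon_protocol()),
    10, seed = 1)
  expect_true(all(zero$data == 0))
})

test_that("reconstruction with a zero mu-map is bit-identical to the nonAC reconstruction", {
  d <- make_disc()
  proto <- recon_protocol(iterations = 1)
  sino <- forward_project(d$activity, NULL, proto)
  mu0 <- mu_map(array(0, d$grid$shape), d$grid)
  r_null <- reconstruct_osem(sino, NULL, proto)
  r_zero <- reconstruct_osem(sino, mu0, proto)
  expect_identical(r_null$data, r_zero$data)
})

test_that("an all-zero sinogram reconstructs to an all-zero image", {
  d <- make_disc()
  proto <- recon_protocol(iterations = 1)
  sino <- forward_project(activity_map(array(0, d$grid$shape), d$grid),
                          NULL, proto)
  expect_true(all(reconstruct_osem(sino, NULL, proto)$data == 0))
})

test_that("omitting attenuation correction depresses the centre of a disc", {
  d <- make_disc()
  proto <- recon_protocol()
  sino <- forward_project(d$activity, d$mu, proto)
  ac <- reconstruct_osem(sino, d$mu, proto)
  nonac <- reconstruct_osem(sino, NULL, proto)
  ctr <- c(16, 16, 8)
  expect_lt(nonac$data[ctr[1], ctr[2], ctr[3]],
            ac$data[ctr[1], ctr[2], ctr[3]])
})

test_that("protocol validation enforces subset divisibility", {
  expect_error(recon_protocol(subsets = 20, n_angles = 210), "divisible")
  d <- make_disc()
  sino <- forward_project(d$activity, NULL, recon_protocol(n_angles = 210))
  sino$angles <- sino$angles[1:100]
  expect_error(reconstruct_osem(sino, NULL, recon_protocol()), "angle count")
})

test_that("the Gaussian post-filter preserves a flat region's level", {
  x <- array(5, c(20, 20, 20))
  y <- dixonac:::gaussian_filter3d(x, 5, c(2.6, 2.6, 2.6))
  expect_equal(y, x, tolerance = 1e-12)
})
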