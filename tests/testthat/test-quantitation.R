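rand_act <- function(g, seed = 1) {
  set.seed(seed)
  activity_map(array(runif(prod(g$shape), 0.5, 2), g$shape), g)
}

test_that("relative difference is exact for identical and doubled images", {
  g <- grid_spec(c(16, 16, 16))
  x <- rand_act(g)
  rd <- relative_difference(x, x)
  expect_true(all(rd$rd[rd$mask] == 100))
  x2 <- activity_map(2 * x$data, g)
  rd2 <- relative_difference(x2, x)
  expect_true(all(rd2$rd[rd2$mask] == 200))
})

test_that("relative difference matches the scalar definition elementwise and masks the floor", {
  g <- grid_spec(c(16, 16, 16))
  set.seed(4)
  o <- array(runif(prod(g$shape)), g$shape)
  co <- array(runif(prod(g$shape)), g$shape)
  rd <- relative_difference(activity_map(co, g), activity_map(o, g),
                            floor = 0.2)
  mask <- o >= 0.2 * max(o)
  expect_equal(rd$mask, mask)
  expect_equal(rd$rd[mask], 100 * (co[mask] / o[mask]))
  expect_true(all(is.na(rd$rd[!mask])))
  zero <- activity_map(array(0, g$shape), g)
  expect_error(relative_difference(zero, zero), "all zero")
})

test_that("42% threshold segmentation keeps exactly the voxels above threshold", {
  g <- grid_spec(c(16, 16, 16))
  v <- array(0, g$shape)
  v[1:3, 1, 1] <- c(100, 50, 41.9)
  region <- array(FALSE, g$shape); region[1:3, 1, 1] <- TRUE
  m <- segment_myocardium(activity_map(v, g), region)
  expect_equal(which(m), which(region)[1:2])
  flat <- activity_map(array(1, g$shape), g)
  expect_error(segment_myocardium(flat, region), "flat")
  expect_error(segment_myocardium(flat, array(FALSE, g$shape)), "empty")
})

test_that("myocardial statistics equal a brute-force scan", {
  g <- grid_spec(c(16, 16, 16))
  x <- rand_act(g, seed = 9)
  mask <- array(runif(prod(g$shape)) < 0.1, g$shape)
  s <- myo_stats(x, mask)
  expect_equal(s$suv_mean, mean(x$data[mask]))
  expect_equal(s$suv_max, max(x$data[mask]))
  expect_equal(s$n_voxels, sum(mask))
  one <- array(FALSE, g$shape); one[3, 4, 5] <- TRUE
  s1 <- myo_stats(x, one)
  expect_equal(s1$suv_mean, s1$suv_max)
  expect_equal(s1$suv_mean, x$data[3, 4, 5])
  expect_error(myo_stats(x, array(FALSE, g$shape)), "empty")
})

test_that("lung volume is the lung voxel count times the voxel volume, in litres", {
  g <- grid_spec(c(16, 16, 16))
  l <- array(0L, g$shape)
  expect_equal(lung_volume(label_map(l, g)), 0)
  l[1, 1, 1] <- 1L
  expect_equal(lung_volume(label_map(l, g)), 1.7576e-5)
  # linearity in the count
  l2 <- l; l2[2:10, 1, 1] <- 1L
  expect_equal(lung_volume(label_map(l2, g)), 10 * 1.7576e-5)
  # mu-map route via the lung coefficient
  mu <- labels_to_mu(label_map(l, g))
  expect_equal(lung_volume(mu), 1.7576e-5)
})

test_that("test-retest flags fire strictly above 10% deviation", {
  r <- test_retest(2.6, 2.6)
  expect_equal(r$ratio, 1)
  expect_false(r$incoherent)
  r2 <- test_retest(2.86, 2.6) # exactly 1.10: boundary, not flagged
  expect_equal(r2$ratio, 1.10)
  expect_false(r2$incoherent)
  r3 <- test_retest(3.64, 2.6)
  expect_equal(r3$ratio, 1.4)
  expect_true(r3$incoherent)
  expect_error(test_retest(2.6, 0), "positive")
})

test_that("polar maps score a uniform ring as 100 everywhere and count single-segment defects", {
  ph <- fx_phantom32()
  pm <- polar_map_17(ph$activity, ph$lv)
  expect_equal(pm$segments, rep(100, 17))
  expect_equal(pm$defect_extent_pct, 0)

  # zero one angular sector of the mid third: exactly 1/17 segments drop
  g <- ph$activity$grid
  sec <- dixonac:::lv_sector_mask(g, ph$lv, pi / 2, pi / 3)
  zc <- dixonac:::voxel_coords(g)[[3]]
  zcap <- ph$lv$z_apex_mm + ph$lv$cap_mm
  wall <- ph$lv$z_base_mm - zcap
  midz <- zc >= zcap + wall / 3 & zc < zcap + 2 * wall / 3
  m <- sec & ph$masks$myocardium &
    dixonac:::outer3d(matrix(TRUE, g$shape[1], g$shape[2]), midz)
  act <- ph$activity$data; act[m] <- 0
  pm2 <- polar_map_17(activity_map(act, g), ph$lv)
  expect_equal(sum(pm2$defect_segments), 1)
  expect_equal(pm2$defect_extent_pct, 100 / 17)

  # normalization property: global rescaling leaves segments unchanged
  pm3 <- polar_map_17(activity_map(act * 3.7, g), ph$lv)
  expect_equal(pm3$segments, pm2$segments)

  # perfusion defect with preserved metabolism counts as hibernating
  v <- viability_scores(pm2, pm)
  expect_equal(v$hibernating_pct, 100 / 17)
  expect_equal(v$scar_pct, 0)
  # matched defect counts as scar
  v2 <- viability_scores(pm2, pm2)
  expect_equal(v2$scar_pct, 100 / 17)
  expect_equal(v2$hibernating_pct, 0)
})
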