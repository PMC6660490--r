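test_that("susceptibility voids clear exactly the fat/soft voxels inside the region", {
  ph <- fx_phantom32()
  st <- ph$organs$sternum
  reg <- region_sphere(st, 12)
  rm_ <- dixonac:::region_mask(reg, ph$labels$grid)
  expected <- sum(rm_ & ph$labels$data %in% c(2L, 3L))
  res <- inject_artifact(ph$labels, artifact_spec("STN", reg))
  expect_equal(res$n_changed, expected)
  expect_true(all(res$labels$data[res$mask] == 0L))
  # locality: untouched outside the region
  expect_identical(res$labels$data[!rm_], ph$labels$data[!rm_])
  expect_true(all(res$labels$data %in% 0:3))
})

test_that("tissue inversions are involutions on their region", {
  ph <- fx_phantom32()
  whole <- region_box(c(-200, -200, -200), c(200, 200, 200))
  once <- inject_artifact(ph$labels, artifact_spec("FSTI", whole))
  twice <- inject_artifact(once$labels, artifact_spec("FSTI", whole))
  expect_identical(twice$labels$data, ph$labels$data)

  lung_reg <- region_sphere(ph$organs$lung_right, 30)
  o1 <- inject_artifact(ph$labels, artifact_spec("LSTI", lung_reg))
  o2 <- inject_artifact(o1$labels, artifact_spec("LSTI", lung_reg))
  expect_identical(o2$labels$data, ph$labels$data)
})

test_that("a photopenic band removes exactly its lung voxels from the lung volume", {
  ph <- fx_phantom32()
  zd <- ph$config$diaphragm_z_mm
  band <- region_band(zd, zd + 3 * 2.6)
  rm_ <- dixonac:::region_mask(band, ph$labels$grid)
  n_lung_in_band <- sum(rm_ & ph$labels$data == 1L)
  res <- inject_artifact(ph$labels, artifact_spec("PMA", band))
  expect_equal(res$n_changed, n_lung_in_band)
  dv <- lung_volume(ph$labels) - lung_volume(res$labels)
  expect_equal(dv, n_lung_in_band * voxel_volume_mm3(ph$labels$grid) / 1e6)
  # converted voxels become soft tissue
  expect_true(all(res$labels$data[res$mask] == 3L))
})

test_that("truncation clears every tissue voxel beyond the lateral half-plane", {
  ph <- fx_phantom32()
  hp <- region_halfplane(1, ph$organs$arm_edge_x, 1)
  res <- inject_artifact(ph$labels, artifact_spec("TRUNCATION", hp))
  rm_ <- dixonac:::region_mask(hp, ph$labels$grid)
  expect_true(all(res$labels$data[rm_] == 0L))
  expect_identical(res$labels$data[!rm_], ph$labels$data[!rm_])
  expect_gt(res$n_changed, 0)
})

test_that("artifacts with no applicable tissue in their region are rejected by name", {
  ph <- fx_phantom32()
  far <- region_sphere(c(160, 120, 0), 5) # air corner
  expect_error(inject_artifact(ph$labels, artifact_spec("STN", far)),
               "STN")
  expect_error(inject_artifact(ph$labels,
                               artifact_spec("MISALIGNMENT",
                                             magnitude = c(0, 0, 10))),
               "shift_map")
})

test_that("shift_map quantizes to voxels, is invertible in the interior and validates input", {
  ph <- fx_phantom32()
  mu <- labels_to_mu(ph$labels)
  expect_identical(shift_map(mu, c(0, 0, 0))$data, mu$data)
  # 18 mm on a 2.6 mm grid is 7 voxels
  s <- shift_map(mu, c(0, 0, 18))
  expect_identical(s$data[, , 8:32], mu$data[, , 1:25])
  expect_true(all(s$data[, , 1:7] == 0))
  # round-half-away-from-zero
  expect_equal(dixonac:::round_half_away(c(1.3, -1.3, 0.5, -0.5) / 1),
               c(1, -1, 1, -1))
  back <- shift_map(s, c(0, 0, -18))
  expect_identical(back$data[, , 8:25], mu$data[, , 8:25])
  expect_error(shift_map(mu, c(0, 0, NA)), "finite")
  expect_error(shift_map(mu, c(31, 0, 0)), "30 mm")
})
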