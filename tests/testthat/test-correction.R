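test_that("majority fill follows the six-neighbour vote and the declared tie-break", {
  g <- grid_spec(c(16, 16, 16))
  l <- array(3L, g$shape)
  # neighbours of (8,8,8): soft, soft, fat, lung, soft, fat -> soft wins
  l[7, 8, 8] <- 3L; l[9, 8, 8] <- 3L; l[8, 7, 8] <- 2L
  l[8, 9, 8] <- 1L; l[8, 8, 7] <- 3L; l[8, 8, 9] <- 2L
  mask <- array(FALSE, g$shape); mask[8, 8, 8] <- TRUE
  res <- fill_susceptibility(label_map(l, g), mask)
  expect_equal(res$labels$data[8, 8, 8], 3L)

  # 3 soft vs 3 fat: declared priority gives soft
  l2 <- array(0L, g$shape)
  l2[7, 8, 8] <- 3L; l2[9, 8, 8] <- 3L; l2[8, 7, 8] <- 3L
  l2[8, 9, 8] <- 2L; l2[8, 8, 7] <- 2L; l2[8, 8, 9] <- 2L
  res2 <- fill_susceptibility(label_map(l2, g), mask)
  expect_equal(res2$labels$data[8, 8, 8], 3L)
})

test_that("fill matches the brute-force wavefront oracle on random label maps", {
  set.seed(21)
  for (trial in 1:10) {
    g <- grid_spec(rep(16L, 3))
    n <- c(12L, 12L, 12L)
    l <- array(sample(0:3, prod(n), TRUE), n)
    mask <- array(runif(prod(n)) < 0.25, n)
    if (!any(mask) || all(mask)) next
    # embed the 12^3 problem in a 16^3 grid (padding stays non-artifact)
    L <- array(0L, g$shape); L[1:12, 1:12, 1:12] <- l
    M <- array(FALSE, g$shape); M[1:12, 1:12, 1:12] <- mask
    got <- fill_susceptibility(label_map(L, g), M)$labels$data
    want <- oracle_wavefront_fill(L, M)
    expect_identical(got, want)
  }
})

test_that("fill restores an artifact embedded in one tissue class and is idempotent", {
  lm <- fx_block()
  g <- lm$grid
  mask <- dixonac:::region_mask(region_sphere(c(0, 0, 0), 10), g)
  broken <- lm$data; broken[mask] <- 0L
  res <- fill_susceptibility(label_map(broken, g), mask)
  expect_identical(res$labels$data, lm$data)
  expect_equal(res$report$unresolved, 0L)
  expect_equal(sum(res$report$assigned), res$report$artifact_voxels)
  again <- fill_susceptibility(res$labels, mask)
  expect_identical(again$labels$data, res$labels$data)
})

test_that("fill rejects empty and all-covering masks", {
  lm <- fx_block()
  expect_error(fill_susceptibility(lm, array(FALSE, lm$grid$shape)),
               "empty")
  expect_error(fill_susceptibility(lm, array(TRUE, lm$grid$shape)),
               "entire")
})

test_that("shift estimation recovers injected offsets against a clean reference", {
  ph <- fx_phantom32()
  mu <- labels_to_mu(ph$labels)
  ref <- ph$activity # ground-truth emission as the support reference
  est0 <- estimate_shift(ref, mu)
  expect_equal(est0$shift_mm, c(0, 0, 0))
  expect_gt(est0$dice, 0.9)
  for (s_mm in c(-18, -8, 5, 12)) {
    mus <- shift_map(mu, c(0, 0, s_mm))
    est <- estimate_shift(ref, mus)
    applied <- dixonac:::round_half_away(s_mm / 2.6) * 2.6
    expect_lte(abs(est$shift_mm[3] + applied), 2.6)
    expect_equal(est$shift_mm[1:2], c(0, 0))
  }
})

test_that("shift estimation rejects degenerate input", {
  ph <- fx_phantom32()
  mu <- labels_to_mu(ph$labels)
  flat <- activity_map(array(1, mu$grid$shape), mu$grid)
  expect_error(estimate_shift(flat, mu), "constant")
})

test_that("truncation completion restores exactly the support-covered background", {
  ph <- fx_phantom32()
  mu <- labels_to_mu(ph$labels)
  ref <- ph$activity
  # untruncated map: unchanged
  un <- complete_truncation(mu, ref)
  expect_identical(un$mu$data, mu$data)
  expect_equal(un$n_restored, 0)
  # truncate the arms, then complete from the emission support
  tr <- inject_artifact(ph$labels,
                        artifact_spec("TRUNCATION",
                                      region_halfplane(1, ph$organs$arm_edge_x,
                                                       1)))
  mut <- labels_to_mu(tr$labels)
  support <- dixonac:::body_support_mask(ref$data, 0.05)
  det <- complete_truncation(mut, ref)
  expect_equal(det$n_restored, sum(support & mut$data == 0))
  expect_true(all(det$mu$data[det$restored_mask] == 0.1))
  # nonbackground voxels never modified
  nb <- mut$data > 0
  expect_identical(det$mu$data[nb], mut$data[nb])
  # truncated voxels inside the support are all back
  expect_true(all(det$mu$data[support & tr$mask] > 0))
})
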