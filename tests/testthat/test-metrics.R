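test_that("DSC matches set arithmetic and complements dice loss", {
  g <- random_mixed_mask(c(3, 3, 3))
  expect_equal(dsc(g, g), 1)
  a <- array(0, c(1, 1, 4)); a[1, 1, 1:2] <- 1
  b <- array(0, c(1, 1, 4)); b[1, 1, 3:4] <- 1
  expect_equal(dsc(a, b), 0)
  # |P| = |G| = 4, |P ∩ G| = 2 -> 0.5
  p <- array(0, c(2, 2, 2)); p[1:4] <- 1
  q <- array(0, c(2, 2, 2)); q[3:6] <- 1
  expect_equal(dsc(p, q), 0.5)
  # DSC + dice loss = 1 (vanishing smoothing)
  set.seed(5)
  for (i in 1:20) {
    m1 <- random_mixed_mask(c(2, 3, 2)); m2 <- random_mixed_mask(c(2, 3, 2))
    if (sum(m1) + sum(m2) == 0) next
    expect_equal(dsc(m1, m2) + dice_loss(m1, m2, smooth = 1e-14), 1,
                 tolerance = 1e-9)
  }
  expect_warning(z <- dsc(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), "empty")
  expect_equal(z, 1)
})

test_that("surface extraction finds 6-connected boundary voxels", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  expect_identical(nrow(surface_points(m)), 1L)
  # solid 3x3x3 cube: all but the centre voxel are surface
  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surface_points(cube)), 26L)
  # a 1-voxel-thick plane is all surface
  plane <- array(0, c(4, 4, 1)); plane[, , 1] <- 1
  expect_identical(nrow(surface_points(plane)), 16L)
  # volume faces count as background: a full block is all surface too
  expect_identical(nrow(surface_points(array(1, c(2, 2, 2)))), 8L)
  expect_error(surface_points(array(0, c(2, 2, 2))), "no foreground")
})

test_that("ASD matches single-pair and all-pairs arithmetic", {
  A <- matrix(c(0, 0, 0), 1, 3)
  B <- matrix(c(0, 0, 3), 1, 3)
  expect_equal(asd(A, A), 0)
  expect_equal(asd(A, B), 3)
  A2 <- rbind(c(0, 0, 0), c(0, 0, 2))
  B2 <- matrix(c(0, 0, 1), 1, 3)
  expect_equal(asd(A2, B2), 1)  # (1 + 1 + 1) / 3
})

test_that("Hausdorff distance honours the quantile and reduces to the max at q = 1", {
  A <- matrix(c(0, 0, 0), 1, 3)
  B <- matrix(c(0, 0, 3), 1, 3)
  expect_equal(hd(A, A), 0)
  expect_equal(hd(A, B, quantile = 1), 3)
  # 20 matched points at distance 1 plus one one-sided outlier at 50:
  # the 95th percentile discards the outlier, the max does not
  C <- cbind(0, 0, seq(0, 19))
  D <- rbind(cbind(1, 0, seq(0, 19)), c(50, 0, 0))
  h100 <- hd(C, D, 1); h95 <- hd(C, D, 0.95)
  expect_equal(h100, 50)
  expect_lt(h95, 2)
  expect_error(hd(A, B, quantile = 0), "quantile")
})

test_that("surface metrics agree with brute-force oracles on random mask pairs", {
  set.seed(13)
  for (i in 1:40) {
    m1 <- random_mixed_mask(c(2, 2, 3))
    m2 <- random_mixed_mask(c(2, 2, 3))
    sp <- runif(3, 0.4, 1.2)
    A <- surface_points(m1, sp); B <- surface_points(m2, sp)
    expect_equal(asd(A, B), bf_asd(A, B), tolerance = 1e-12)
    expect_equal(hd(A, B, 1), bf_hd(A, B, 1), tolerance = 1e-12)
    expect_equal(hd(A, B, 0.95), bf_hd(A, B, 0.95), tolerance = 1e-12)
    # symmetry at q = 1 and the hd100 >= hd95 >= 0 ordering
    expect_equal(hd(A, B, 1), hd(B, A, 1), tolerance = 1e-12)
    expect_gte(hd(A, B, 1), hd(A, B, 0.95))
    expect_equal(asd(A, B), asd(B, A), tolerance = 1e-12)
  }
})

test_that("distances scale linearly with spacing; overlap metrics do not change", {
  set.seed(17)
  m1 <- random_mixed_mask(c(3, 4, 4))
  m2 <- random_mixed_mask(c(3, 4, 4))
  sp <- c(0.8, 0.5, 0.5)
  A1 <- surface_points(m1, sp); B1 <- surface_points(m2, sp)
  A2 <- surface_points(m1, 2 * sp); B2 <- surface_points(m2, 2 * sp)
  expect_equal(asd(A2, B2), 2 * asd(A1, B1), tolerance = 1e-12)
  expect_equal(hd(A2, B2, 0.95), 2 * hd(A1, B1, 0.95), tolerance = 1e-12)
})

test_that("accuracy is the covered fraction of the target", {
  g <- array(0, c(2, 2, 2)); g[1:4] <- 1
  expect_equal(seg_accuracy(g, g), 1)
  expect_equal(seg_accuracy(array(0, c(2, 2, 2)), g), 0)
  p <- array(0, c(2, 2, 2)); p[2:4] <- 1
  expect_equal(seg_accuracy(p, g), 0.75)
  expect_error(seg_accuracy(g, array(0, c(2, 2, 2))), "empty")
})

test_that("loss-curve RSS is zero for a line, 2/3 for the tent example, and grows with noise", {
  expect_equal(rss_of_loss_curve(seq(2, 1, length.out = 10)), 0,
               tolerance = 1e-12)
  expect_equal(rss_of_loss_curve(c(0, 1, 0)), 2 / 3, tolerance = 1e-12)
  expect_error(rss_of_loss_curve(c(1, 2)), "at least 3")
  # Monte-Carlo: expected RSS scales with the noise variance
  set.seed(23)
  base <- seq(3, 1, length.out = 60)
  rss_at <- function(sig) mean(replicate(40, {
    rss_of_loss_curve(base + rnorm(60, 0, sig))
  }))
  r1 <- rss_at(0.05); r2 <- rss_at(0.1); r4 <- rss_at(0.2)
  expect_lt(r1, r2)
  expect_lt(r2, r4)
  # quadrupling sigma multiplies expected RSS by ~16 (58/ (n-2) dof scaling)
  expect_equal(r4 / r1, 16, tolerance = 0.35)
})

test_that("evaluate_segmentation binarizes and reports the full metric suite", {
  cs <- generate_case(phantom_config(volume_shape = c(24, 32, 32),
                                     n_vessels = 2, n_aneurysms = 1,
                                     aneurysm_diameter_mm = c(3, 4), seed = 2))
  g <- cs$label
  m <- evaluate_segmentation(g, g)   # perfect prediction
  expect_equal(m$dsc, 1)
  expect_equal(m$asd, 0)
  expect_equal(m$hd95, 0)
  expect_equal(m$accuracy, 1)
  # threshold 0 predicts everything: accuracy is 1 by definition
  p_any <- volume(array(0.4, dim(g$data)), g$spacing)
  m0 <- evaluate_segmentation(p_any, g, threshold = 0)
  expect_equal(m0$accuracy, 1)
  # shifting a mask by one voxel gives surface distances of about one voxel
  shifted <- array(0, dim(g$data))
  shifted[, , 2:dim(g$data)[3]] <- g$data[, , 1:(dim(g$data)[3] - 1)]
  ms <- evaluate_segmentation(label_mask(shifted, g$spacing), g)
  A <- surface_points(shifted, g$spacing); B <- surface_points(g)
  expect_equal(ms$asd, bf_asd(A, B), tolerance = 1e-12)
  expect_equal(ms$hd95, bf_hd(A, B, 0.95), tolerance = 1e-12)
})
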