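as3d <- function(v) array(v, c(1, 1, length(v)))

test_that("dice loss reproduces hand-computed values", {
  g <- array(rbinom(24, 1, 0.5), c(2, 3, 4))
  expect_equal(dice_loss(g, g, smooth = 1e-5), 0, tolerance = 1e-6)
  # p=[1,1,0,0] vs g=[1,0,1,0]: 1 - 2/(2+2) = 0.5 as w -> 0
  expect_equal(dice_loss(as3d(c(1, 1, 0, 0)), as3d(c(1, 0, 1, 0)),
                         smooth = 1e-12), 0.5)
  # smoothing rescues the all-empty 0/0 case
  expect_equal(dice_loss(as3d(rep(0, 4)), as3d(rep(0, 4)), smooth = 1e-5), 0)
  expect_error(dice_loss(as3d(c(1, 0)), as3d(c(1, 0, 0))), "shapes differ")
})

test_that("dice loss stays in [0,1) and vanishes only at agreement", {
  set.seed(1)
  for (i in 1:50) {
    d <- sample(2:4, 3, replace = TRUE)
    p <- array(runif(prod(d)), d)
    g <- array(rbinom(prod(d), 1, 0.4), d)
    l <- dice_loss(p, g)
    expect_gte(l, 0)
    expect_lt(l, 1)
  }
})

test_that("cross-entropy matches direct arithmetic and stays finite when saturated", {
  eps <- 1e-7
  expect_lt(ce_loss(as3d(c(1 - eps, eps)), as3d(c(1, 0))), 1e-5)
  expect_equal(ce_loss(as3d(0.5), as3d(1)), -log(0.5), tolerance = 1e-12)
  expect_equal(ce_loss(as3d(c(0.5, 0.5)), as3d(c(1, 0))), -log(0.5),
               tolerance = 1e-12)
  # exact 0/1 predictions are clipped, not infinite
  expect_true(is.finite(ce_loss(as3d(c(0, 1)), as3d(c(1, 0)))))
  # literal foreground-only form drops the background term
  expect_equal(ce_loss(as3d(c(0.5, 0.1)), as3d(c(1, 0)), foreground_only = TRUE),
               -log(0.5) / 2, tolerance = 1e-12)
})

test_that("signed distance maps match hand examples and the sign convention", {
  phi <- signed_distance(as3d(c(0, 1, 0)))
  expect_equal(as.vector(phi), c(1, -1, 1))
  phi2 <- signed_distance(as3d(c(0, 0, 1, 1)))
  expect_equal(as.vector(phi2), c(2, 1, -1, -2))
  g <- random_mixed_mask(c(3, 4, 2))
  phi3 <- signed_distance(g)
  expect_identical(sign(as.vector(phi3)), as.vector(1 - 2 * g))
  # degenerate single-class masks have no boundary: phi is identically zero
  expect_true(all(signed_distance(array(0, c(2, 2, 2))) == 0))
  expect_true(all(signed_distance(array(1, c(2, 2, 2))) == 0))
})

test_that("signed distance agrees exactly with the all-pairs oracle on every 2x2x3 mask", {
  d <- c(2, 2, 3)
  n <- prod(d)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[1:n])
    g <- array(bits, d)
    expect_equal(unclass(signed_distance(g)), bf_signed_distance(g),
                 tolerance = 1e-12)
  }
})

test_that("signed distance respects anisotropic spacing", {
  set.seed(3)
  sp <- c(0.8, 0.5, 0.5)
  for (i in 1:10) {
    g <- random_mixed_mask(c(3, 3, 4))
    expect_equal(unclass(signed_distance(g, spacing = sp)),
                 bf_signed_distance(g, spacing = sp), tolerance = 1e-12)
  }
})

test_that("boundary loss is the phi-weighted mean of the prediction", {
  g <- as3d(c(0, 1, 0))
  phi <- signed_distance(g)
  expect_equal(boundary_loss(g, phi), -1 / 3)
  expect_equal(boundary_loss(as3d(c(1, 1, 1)), phi), 1 / 3)
  expect_equal(boundary_loss(as3d(c(0, 0, 0)), phi), 0)
})

test_that("with fixed foreground budget the boundary loss is minimized on the most negative phi", {
  # exhaustive over all binary predictions of a 2x2x2 block
  set.seed(9)
  g <- random_mixed_mask(c(2, 2, 2))
  phi <- signed_distance(g)
  n <- 8
  for (budget in 1:7) {
    best <- Inf
    for (code in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(code)[1:n])
      if (sum(bits) != budget) next
      best <- min(best, boundary_loss(array(bits, c(2, 2, 2)), phi))
    }
    expect_equal(best, sum(sort(as.vector(phi))[1:budget]) / n,
                 tolerance = 1e-12)
  }
})

test_that("ensemble composes dice with the configured auxiliary term", {
  set.seed(4)
  p <- array(runif(24), c(2, 3, 4))
  g <- random_mixed_mask(c(2, 3, 4))
  # lambda = 0 degenerates every mode to plain dice
  for (mode in c("dice", "dice+ce", "dice+boundary")) {
    cfg0 <- loss_config(mode, aux_weight = 0)
    expect_equal(ensemble_loss(p, g, cfg0), dice_loss(p, g), tolerance = 1e-12)
  }
  expect_equal(ensemble_loss(p, g, loss_config("dice+ce", aux_weight = 0.7)),
               dice_loss(p, g) + 0.7 * ce_loss(p, g), tolerance = 1e-12)
  # worked dice+boundary example: p == g on [0,1,0], w -> 0
  pg <- as3d(c(0, 1, 0))
  expect_equal(ensemble_loss(pg, pg, loss_config("dice+boundary",
                                                 smooth = 1e-12)),
               -1 / 3, tolerance = 1e-9)
  # near-perfect prediction makes dice+ce nearly zero
  eps <- 1e-7
  pg2 <- as3d(c(1 - eps, eps))
  expect_lt(abs(ensemble_loss(pg2, as3d(c(1, 0)), loss_config("dice+ce"))),
            1e-4)
})

test_that("all losses are finite on boundary-of-domain inputs", {
  g <- random_mixed_mask(c(2, 2, 2))
  for (p in list(array(0, c(2, 2, 2)), array(1, c(2, 2, 2)), g)) {
    expect_true(is.finite(dice_loss(p, g)))
    expect_true(is.finite(ce_loss(p, g)))
    expect_true(is.finite(boundary_loss(p, signed_distance(g))))
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(11)
  d <- c(2, 3, 2)
  p <- array(runif(prod(d), 0.05, 0.95), d)
  g <- random_mixed_mask(d)
  phi <- signed_distance(g)
  cases <- list(
    list(f = function(p) dice_loss(p, g),
         gr = otoseg:::dice_loss_grad(p, g, 1e-5)),
    list(f = function(p) ce_loss(p, g),
         gr = otoseg:::ce_loss_grad(p, g)),
    list(f = function(p) boundary_loss(p, phi),
         gr = otoseg:::boundary_loss_grad(p, phi)),
    list(f = function(p) ensemble_loss(p, g, loss_config("dice+boundary"),
                                       phi = phi),
         gr = otoseg:::ensemble_loss_grad(p, g, loss_config("dice+boundary"),
                                          phi = phi)))
  eps <- 1e-6
  for (cs in cases) {
    for (k in sample(length(p), 4)) {
      p2 <- p; p2[k] <- p2[k] + eps
      fd <- (cs$f(p2) - cs$f(p)) / eps
      expect_equal(fd, cs$gr[k], tolerance = 1e-4)
    }
  }
})
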