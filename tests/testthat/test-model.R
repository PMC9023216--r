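test_that("forward pass preserves spatial shape and outputs probabilities", {
  net <- tiny_net(base = 2, seed = 7)
  for (d in list(c(16, 16, 16), c(8, 12, 16), c(32, 64, 64))) {
    p <- predict(net, array(rnorm(prod(d)), d))
    expect_identical(dim(p), as.integer(d))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("indivisible input dimensions are rejected before any computation", {
  net <- tiny_net()
  expect_error(predict(net, array(0, c(10, 16, 16))), "divisible by 4")
  expect_error(shape_trace(net, c(64, 130, 128)), "divisible by 4")
})

test_that("the stage schedule halves resolution and doubles channels", {
  net <- oto_net(oto_model_config(base_channels = 16))
  tr <- shape_trace(net, c(64, 128, 128))
  expect_identical(tr$stage[5], "T-Stage3")
  expect_identical(tr$height,
                   c(128L, 64L, 128L, 64L, 32L, 64L, 128L, 64L, 128L))
  expect_identical(tr$depth[1], 64L)
  expect_identical(tr$channels,
                   c(16L, 32L, 16L, 32L, 64L, 32L, 16L, 32L, 16L))
  # deepest stage of the middle structure is 64 channels at quarter size
  expect_identical(tr$channels[tr$stage == "T-Stage3"], 64L)
  expect_identical(tr$height[tr$stage == "T-Stage3"], 32L)

  tr2 <- shape_trace(net, c(32, 32, 32))
  expect_identical(min(tr2$height), 8L)
})

test_that("channel counts change 16->32 at the first descent and 32->16 at the first ascent", {
  net <- oto_net(oto_model_config(base_channels = 16))
  # first downsampling convolution maps 16 to 32 channels
  expect_identical(dim(net$params$o1s2_down$W)[4:5], c(16L, 32L))
  # first transposed convolution maps 32 back to 16 (adjoint layout stores
  # the conv direction 16 -> 32)
  l <- net$layers$ts1_up
  expect_identical(c(l$cin, l$cout), c(32L, 16L))
  expect_identical(dim(net$params$ts1_up$W)[4:5], c(16L, 32L))
  # every kernel is 3x3x3
  expect_true(all(vapply(net$params,
                         function(p) all(dim(p$W)[1:3] == 3L), logical(1))))
})

test_that("parameter count is deterministic and closed-form for one conv", {
  # one 3x3x3 conv, 16 -> 16 channels, with bias
  n16 <- oto_net(oto_model_config(base_channels = 16))
  expect_identical(length(n16$params$o1s1_c2$W) + length(n16$params$o1s1_c2$b),
                   3L * 3L * 3L * 16L * 16L + 16L)
  expect_identical(count_parameters(oto_net(oto_model_config(seed = 5))),
                   count_parameters(oto_net(oto_model_config(seed = 5))))
  # doubling base_channels quadruples a square conv's weight count
  n32 <- oto_net(oto_model_config(base_channels = 32))
  expect_identical(length(n32$params$o1s1_c2$W), 4L * length(n16$params$o1s1_c2$W))
})

test_that("two builds from the same config have identical weights", {
  a <- oto_net(oto_model_config(base_channels = 2, seed = 9))
  b <- oto_net(oto_model_config(base_channels = 2, seed = 9))
  expect_identical(a$params, b$params)
})

test_that("network gradients match finite differences through the full graph", {
  net <- tiny_net(base = 2, seed = 3)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  set.seed(21)
  g <- array(rbinom(512, 1, 0.2), c(8, 8, 8))
  lcfg <- loss_config("dice+boundary")
  phi <- signed_distance(g)
  lossfun <- function(nn) {
    p <- otoseg:::net_forward(nn, x, training = FALSE)
    ensemble_loss(array(p, dim(p)[1:3]), g, lcfg, phi = phi)
  }
  cache <- new.env()
  p <- otoseg:::net_forward(net, x, training = FALSE, cache = cache)
  dLdp <- otoseg:::ensemble_loss_grad(array(p, dim(p)[1:3]), g, lcfg,
                                      phi = phi)
  dim(dLdp) <- dim(p)
  grads <- otoseg:::net_backward(net, cache, dLdp)
  L0 <- lossfun(net)
  for (nm in c("o1s1_c1", "ts1_up", "ts3_c2", "ts4_up", "o2s2_c1", "head")) {
    k <- sample(length(grads[[nm]]$W), 2)
    for (kk in k) {
      eps <- 1e-5
      n2 <- net
      n2$params[[nm]]$W[kk] <- n2$params[[nm]]$W[kk] + eps
      fd <- (lossfun(n2) - L0) / eps
      expect_equal(fd, grads[[nm]]$W[kk], tolerance = 1e-3)
    }
  }
})

test_that("model config validates channel, kernel, and dropout settings", {
  expect_error(oto_model_config(base_channels = 0), ">= 1")
  expect_error(oto_model_config(kernel = c(3, 4, 3)), "odd")
  expect_error(oto_model_config(dropout = 1), "dropout")
})
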