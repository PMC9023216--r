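test_that("non-overlapping partition of a 512x512x128 scan gives 4x4 in-plane and 2 in depth", {
  v <- volume(array(0, c(128, 512, 512)))          # (Z, Y, X)
  bs <- partition(v, block_spec(c(64, 128, 128)))
  expect_identical(length(bs$blocks), 32L)         # 2 * 4 * 4
  expect_identical(length(unique(bs$origins[, "z"])), 2L)
  expect_identical(length(unique(bs$origins[, "y"])), 4L)
  expect_identical(length(unique(bs$origins[, "x"])), 4L)
})

test_that("a block-sized volume partitions into exactly itself", {
  a <- array(rnorm(64 * 128 * 128), c(64, 128, 128))
  bs <- partition(volume(a), block_spec(c(64, 128, 128)))
  expect_identical(length(bs$blocks), 1L)
  expect_identical(unname(bs$origins[1, ]), c(0L, 0L, 0L))
  expect_equal(bs$blocks[[1]], a)
})

test_that("half-stride overlapping partition enumerates the full origin grid", {
  v <- volume(array(0, c(128, 256, 256)))
  bs <- partition(v, block_spec(c(64, 128, 128), stride = c(32, 64, 64)))
  expect_identical(length(bs$blocks), 27L)  # {0,32,64} x {0,64,128}^2
  expect_setequal(unique(bs$origins[, "z"]), c(0L, 32L, 64L))
  expect_setequal(unique(bs$origins[, "y"]), c(0L, 64L, 128L))
})

test_that("clamped final origins cover non-divisible dimensions without padding", {
  v <- volume(array(rnorm(10 * 11 * 12), c(10, 11, 12)))
  bs <- partition(v, block_spec(c(4, 4, 4)))
  expect_false(anyDuplicated(bs$origins) > 0)
  expect_true(all(bs$origins + 3L <= rep(dim(v$data) - 1L, each = nrow(bs$origins))))
  # reassembly of the unmodified blocks reproduces the source exactly
  expect_equal(reassemble(bs)$data, v$data)
})

test_that("partition rejects blocks larger than the volume", {
  expect_error(partition(volume(array(0, c(8, 8, 8))), block_spec(c(16, 8, 8))),
               "exceeds")
})

test_that("culling retains exactly the pairs whose label block has foreground", {
  img <- volume(array(rnorm(4 * 4 * 16), c(4, 4, 16)))
  lab <- array(0, c(4, 4, 16))
  # four 4x4x4 blocks with foreground counts 0, 5, 0, 2
  lab[, , 5:8][sample(64, 5)] <- 1
  lab[, , 13:16][sample(64, 2)] <- 1
  bi <- partition(img, block_spec(c(4, 4, 4)))
  bl <- partition(label_mask(lab), block_spec(c(4, 4, 4)))
  kept <- cull_empty(bi, bl)
  expect_identical(length(kept$images$blocks), 2L)
  expect_identical(kept$images$origins, kept$labels$origins)
  expect_identical(unname(kept$labels$origins[, "x"]), c(4L, 12L))

  # all-empty labels give an empty (but valid) result
  bl0 <- partition(label_mask(array(0, c(4, 4, 16))), block_spec(c(4, 4, 4)))
  kept0 <- cull_empty(bi, bl0)
  expect_identical(length(kept0$images$blocks), 0L)

  # all-foreground labels are the identity
  bl1 <- partition(label_mask(array(1, c(4, 4, 16))), block_spec(c(4, 4, 4)))
  kept1 <- cull_empty(bi, bl1)
  expect_identical(length(kept1$images$blocks), 4L)

  mism <- partition(label_mask(array(0, c(4, 4, 16))), block_spec(c(4, 4, 8)))
  expect_error(cull_empty(bi, mism), "paired")
})

test_that("culling matches a brute-force filter on random cases", {
  set.seed(42)
  for (i in 1:20) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1)) * 2L
    blk <- d %/% 2L
    lab <- array(rbinom(prod(d), 1, 0.02), d)
    bi <- partition(volume(array(rnorm(prod(d)), d)), block_spec(blk))
    bl <- partition(label_mask(lab), block_spec(blk))
    kept <- cull_empty(bi, bl)
    keep_ref <- vapply(bl$blocks, function(b) any(b > 0), logical(1))
    expect_identical(length(kept$labels$blocks), sum(keep_ref))
    expect_true(all(vapply(kept$labels$blocks, function(b) max(b) > 0,
                           logical(1))))
  }
})

test_that("reassembly averages overlapping block predictions", {
  v <- volume(array(0, c(4, 4, 8)))
  bs <- partition(v, block_spec(c(4, 4, 4), stride = c(4, 4, 4)))
  # make the two blocks overlap by using explicit origins 0 and 2 along x
  bs2 <- partition(v, block_spec(c(4, 4, 6), stride = c(4, 4, 2)))
  expect_identical(length(bs2$blocks), 2L)
  bs2$blocks[[1]][] <- 0.2
  bs2$blocks[[2]][] <- 0.6
  out <- reassemble(bs2)$data
  expect_equal(unique(as.vector(out[, , 3:6])), 0.4)  # overlap region
  expect_equal(unique(as.vector(out[, , 1:2])), 0.2)
  expect_equal(unique(as.vector(out[, , 7:8])), 0.6)
})

test_that("partition then reassemble is the identity for random specs", {
  set.seed(7)
  for (i in 1:10) {
    d <- sample(6:14, 3, replace = TRUE)
    blk <- pmin(d, sample(3:6, 3, replace = TRUE))
    st <- pmax(1L, blk - sample(0:2, 3, replace = TRUE))
    a <- array(rnorm(prod(d)), d)
    bs <- partition(volume(a), block_spec(blk, stride = st))
    expect_equal(reassemble(bs)$data, a)
  }
})

test_that("overlapping mode yields at least the non-overlapping block count", {
  v <- volume(array(0, c(16, 32, 32)))
  n_no <- length(partition(v, block_spec(c(8, 16, 16)))$blocks)
  n_ov <- length(partition(v, block_spec(c(8, 16, 16), overlap = TRUE))$blocks)
  expect_gte(n_ov, n_no)
})
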