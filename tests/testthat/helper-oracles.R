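# Brute-force oracles and small fixture builders shared across tests.
# The oracles deliberately use naive all-pairs / exhaustive formulations so
# they stay independent of the implementation paths they check.

# All-pairs signed Euclidean distance map: for every voxel, distance to the
# nearest voxel of the opposite class (negative inside the mask).
bf_signed_distance <- function(g, spacing = c(1, 1, 1)) {
  d <- dim(g)
  coords <- as.matrix(expand.grid(z = seq_len(d[1]) - 1,
                                  y = seq_len(d[2]) - 1,
                                  x = seq_len(d[3]) - 1))
  # expand.grid varies the first factor fastest, matching column-major order
  coords <- sweep(coords, 2, spacing, "*")
  fg <- as.vector(g) > 0
  phi <- numeric(length(fg))
  if (all(fg) || !any(fg)) return(array(0, d))
  for (i in seq_along(fg)) {
    opp <- coords[fg != fg[i], , drop = FALSE]
    dmin <- sqrt(min(rowSums(sweep(opp, 2, coords[i, ], "-")^2)))
    phi[i] <- if (fg[i]) -dmin else dmin
  }
  array(phi, d)
}

bf_nn_dists <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min(rowSums(sweep(B, 2, A[i, ], "-")^2)))
  }, numeric(1))
}

bf_asd <- function(A, B) {
  (sum(bf_nn_dists(A, B)) + sum(bf_nn_dists(B, A))) / (nrow(A) + nrow(B))
}

bf_hd <- function(A, B, q = 1) {
  max(quantile(bf_nn_dists(A, B), q, names = FALSE),
      quantile(bf_nn_dists(B, A), q, names = FALSE))
}

# Random binary mask with at least one voxel of each class.
random_mixed_mask <- function(d) {
  repeat {
    m <- array(rbinom(prod(d), 1, runif(1, 0.2, 0.8)), d)
    if (any(m > 0) && any(m == 0)) return(m)
  }
}

# Small phantom configuration used for pipeline-level tests.  Lesions are
# kept at the bottom of the clinical size range so even tiny test volumes
# honour the < 1% foreground guarantee.
toy_phantom_config <- function(seed, shape = c(64, 128, 128)) {
  phantom_config(volume_shape = shape, n_vessels = 4, n_aneurysms = 2,
                 aneurysm_diameter_mm = c(3, 4.5), seed = seed)
}

tiny_net <- function(base = 2, seed = 1, dropout = 0) {
  oto_net(oto_model_config(base_channels = base, dropout = dropout,
                           seed = seed))
}
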