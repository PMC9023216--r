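#' Block specification
#'
#' Describes how a volume is partitioned into fixed-size 3D blocks.  The
#' default block shape is 64x128x128 (Z, Y, X), the input size of the
#' network.  In non-overlapping mode the stride equals the block shape and
#' (for evenly divisible dimensions) every voxel is covered exactly once; in
#' overlapping mode the default stride is half the block shape per axis, so
#' interior structure always appears away from a block border in at least one
#' block.
#'
#' @param block_shape Integer length-3 (Z, Y, X) block size.
#' @param stride Integer length-3 step between block origins; defaults to
#'   `block_shape` (non-overlapping) or `block_shape / 2` (`overlap = TRUE`).
#' @param overlap Logical; use the half-shape stride default.
#' @return An object of class `oto_block_spec`.
#' @export
block_spec <- function(block_shape = c(64, 128, 128), stride = NULL,
                       overlap = FALSE) {
  block_shape <- as.integer(block_shape)
  if (length(block_shape) != 3L || any(block_shape < 1L))
    stop("`block_shape` must be 3 positive integers", call. = FALSE)
  if (is.null(stride))
    stride <- if (overlap) pmax(1L, block_shape %/% 2L) else block_shape
  stride <- as.integer(stride)
  if (length(stride) != 3L || any(stride < 1L) || any(stride > block_shape))
    stop("`stride` must satisfy 1 <= stride <= block_shape per axis",
         call. = FALSE)
  structure(list(block_shape = block_shape, stride = stride),
            class = "oto_block_spec")
}

# Origin grid along one axis: 0, s, 2s, ... with a final origin clamped to
# dim - block whenever the grid does not land exactly on the volume end.
axis_origins <- function(dim, block, stride) {
  last <- dim - block
  g <- seq.int(0L, last, by = stride)
  if (g[length(g)] != last) g <- c(g, last)
  unique(g)
}

#' Partition a volume into blocks
#'
#' Cuts a volume into fixed-size sub-volumes on a regular origin grid.  For
#' dimensions that the stride does not divide exactly, the final origin per
#' axis is clamped to `dim - block` (blocks never pad), so every voxel is
#' covered by at least one block.
#'
#' @param v An [volume()], [label_mask()], or bare 3D array.
#' @param spec An [block_spec()].
#' @return An `oto_blockset`: blocks plus per-block (z, y, x) integer voxel
#'   origins (0-based) and the source shape needed for [reassemble()].
#' @examples
#' v <- volume(array(0, c(128, 512, 512)))
#' bs <- partition(v, block_spec(c(64, 128, 128)))
#' length(bs$blocks)  # 2 x 4 x 4 = 32
#' @export
partition <- function(v, spec = block_spec()) {
  dat <- as_vol_array(v)
  d <- dim(dat)
  bs <- spec$block_shape
  if (any(bs > d))
    stop(sprintf("block shape (%s) exceeds volume shape (%s)",
                 paste(bs, collapse = "x"), paste(d, collapse = "x")),
         call. = FALSE)
  oz <- axis_origins(d[1], bs[1], spec$stride[1])
  oy <- axis_origins(d[2], bs[2], spec$stride[2])
  ox <- axis_origins(d[3], bs[3], spec$stride[3])
  origins <- as.matrix(expand.grid(z = oz, y = oy, x = ox,
                                   KEEP.OUT.ATTRS = FALSE))
  blocks <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    blocks[[i]] <- dat[(o[1] + 1):(o[1] + bs[1]),
                       (o[2] + 1):(o[2] + bs[2]),
                       (o[3] + 1):(o[3] + bs[3]), drop = FALSE]
  }
  structure(list(blocks = blocks, origins = origins, source_shape = d,
                 spec = spec, spacing = vol_spacing(v),
                 source_id = if (inherits(v, "oto_volume")) v$source_id else NA),
            class = "oto_blockset")
}

#' @export
print.oto_blockset <- function(x, ...) {
  cat(sprintf("<blockset> %d blocks of %s from a %s volume\n",
              length(x$blocks), paste(x$spec$block_shape, collapse = "x"),
              paste(x$source_shape, collapse = "x")))
  invisible(x)
}

#' Disequilibrium culling of lesion-free block pairs
#'
#' The lesion occupies a minuscule fraction of the brain, so most blocks of a
#' partitioned training volume contain no foreground at all.  Training on
#' those blocks aggravates the class imbalance, so any image/label block pair
#' whose label block contains no voxel greater than zero is discarded.
#' Ordering is preserved and the image and label sets stay paired.
#'
#' @param images,labels Paired `oto_blockset`s (same spec, same origins).
#' @return A list with elements `images` and `labels`, the retained pairs.
#' @export
cull_empty <- function(images, labels) {
  stopifnot(inherits(images, "oto_blockset"), inherits(labels, "oto_blockset"))
  if (!identical(unname(images$origins), unname(labels$origins)) ||
      !identical(images$spec$block_shape, labels$spec$block_shape))
    stop("image and label block sets are not paired (origins/spec differ)",
         call. = FALSE)
  keep <- vapply(labels$blocks, function(b) max(b) > 0, logical(1))
  subset_blockset <- function(bs) {
    bs$blocks <- bs$blocks[keep]
    bs$origins <- bs$origins[keep, , drop = FALSE]
    bs
  }
  list(images = subset_blockset(images), labels = subset_blockset(labels))
}

#' Reassemble block-wise predictions into a full volume
#'
#' Each voxel receives the arithmetic mean of all block predictions covering
#' it.  On a non-overlapping exact tiling this is pure placement; partition
#' followed by reassembly of the unmodified blocks reproduces the source
#' volume exactly for any valid spec.
#'
#' @param preds An `oto_blockset` of (predicted) blocks.
#' @return An [volume()] with the block set's source shape.
#' @export
reassemble <- function(preds) {
  stopifnot(inherits(preds, "oto_blockset"))
  d <- preds$source_shape
  bs <- preds$spec$block_shape
  acc <- array(0, d)
  cnt <- array(0L, d)
  for (i in seq_along(preds$blocks)) {
    o <- preds$origins[i, ]
    iz <- (o[1] + 1):(o[1] + bs[1])
    iy <- (o[2] + 1):(o[2] + bs[2])
    ix <- (o[3] + 1):(o[3] + bs[3])
    acc[iz, iy, ix] <- acc[iz, iy, ix] + preds$blocks[[i]]
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1L
  }
  if (any(cnt == 0L))
    stop("block origins do not cover the full source volume", call. = FALSE)
  volume(acc / cnt, spacing = preds$spacing,
         source_id = paste0(preds$source_id, ":reassembled"))
}
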