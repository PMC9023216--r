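#' Dice similarity coefficient
#'
#' `2|P∩G| / (|P| + |G|)` for binary masks, the standard overlap agreement
#' between a predicted and a true segmentation.  Equals `1 - dice_loss()` in
#' the limit of vanishing smoothing.  Two empty masks are in perfect
#' agreement; that case returns 1 with a warning since the quotient is
#' formally 0/0.
#'
#' @param p Binary predicted mask (array or [label_mask()]).
#' @param g Binary ground-truth mask, same shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(p, g) {
  z <- check_pg(p, g)
  if (!all(z$p %in% c(0, 1)) || !all(z$g %in% c(0, 1)))
    stop("dsc() expects binary masks; threshold probabilities first",
         call. = FALSE)
  den <- sum(z$p) + sum(z$g)
  if (den == 0) {
    warning("both masks are empty; DSC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(z$p * z$g) / den
}

#' Surface points of a binary mask
#'
#' The surface of a mask is the set of foreground voxels having at least one
#' background 6-neighbour, with out-of-volume treated as background (so
#' foreground touching the volume faces is surface).  Returned as voxel
#' centre coordinates scaled by spacing, the point sets between which the
#' surface-distance metrics are computed.
#'
#' @param m Binary mask (array or [label_mask()]); must contain foreground.
#' @param spacing Voxel spacing (Z, Y, X) in mm; defaults to the mask's own
#'   spacing, or unit spacing for a bare array.
#' @return A numeric matrix with one row per surface voxel, columns (z, y, x)
#'   in mm.
#' @export
surface_points <- function(m, spacing = NULL) {
  md <- as_vol_array(m) > 0
  if (!any(md)) stop("mask has no foreground; surface is undefined",
                     call. = FALSE)
  if (is.null(spacing)) spacing <- vol_spacing(m)
  d <- dim(md)
  # a face-padded copy: out-of-volume counts as background
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- md
  sub <- function(i, j, k) {
    s <- pad[i, j, k, drop = FALSE]
    dim(s) <- d
    s
  }
  iz <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); ix <- 2:(d[3] + 1)
  nb_all <- sub(iz - 1L, iy, ix) & sub(iz + 1L, iy, ix) &
            sub(iz, iy - 1L, ix) & sub(iz, iy + 1L, ix) &
            sub(iz, iy, ix - 1L) & sub(iz, iy, ix + 1L)
  surf <- md & !nb_all
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, "*")
  colnames(pts) <- c("z", "y", "x")
  pts
}

#' Average surface distance
#'
#' Symmetric mean of nearest-neighbour distances between two surface point
#' sets: every point of each surface contributes its distance to the nearest
#' point of the other surface, and the grand mean over both directions is
#' taken (pooled over `|S_A| + |S_B|` points).
#'
#' @param A,B Surface point sets from [surface_points()] (n x 3 matrices,
#'   mm), both non-empty.
#' @return ASD in mm (>= 0; 0 iff the point sets coincide).
#' @export
asd <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B) || nrow(A) == 0 || nrow(B) == 0)
    stop("asd() needs two non-empty point matrices", call. = FALSE)
  dAB <- cpp_nn_dists(A, B)
  dBA <- cpp_nn_dists(B, A)
  (sum(dAB) + sum(dBA)) / (nrow(A) + nrow(B))
}

#' Hausdorff distance with quantile robustification
#'
#' The maximum of the two directed distances, where each directed distance is
#' the `quantile`-th percentile (linear interpolation) of the per-point
#' nearest-neighbour distances from one set to the other.  `quantile = 1`
#' reproduces the classical Hausdorff maximum; the 95% default discards
#' outlier surface points for stability.
#'
#' @inheritParams asd
#' @param quantile Percentile in `(0, 1]` applied to each directed distance
#'   vector.
#' @return HD (or HD95) in mm.
#' @export
hd <- function(A, B, quantile = 0.95) {
  if (!is.matrix(A) || !is.matrix(B) || nrow(A) == 0 || nrow(B) == 0)
    stop("hd() needs two non-empty point matrices", call. = FALSE)
  if (quantile <= 0 || quantile > 1)
    stop("`quantile` must be in (0, 1]", call. = FALSE)
  hAB <- stats::quantile(cpp_nn_dists(A, B), quantile, names = FALSE, type = 7)
  hBA <- stats::quantile(cpp_nn_dists(B, A), quantile, names = FALSE, type = 7)
  max(hAB, hBA)
}

#' Segmentation accuracy (foreground recall)
#'
#' The ratio of the correctly predicted area to the target area,
#' `|P∩G| / |G|`.  Note this is a recall-type quantity: a prediction
#' covering everything scores 1 regardless of false positives, which is why
#' it is always reported alongside DSC and the surface distances.
#'
#' @inheritParams dsc
#' @return Accuracy in `[0, 1]`.
#' @export
seg_accuracy <- function(p, g) {
  z <- check_pg(p, g)
  ng <- sum(z$g)
  if (ng == 0) stop("ground truth is empty; accuracy undefined", call. = FALSE)
  sum(z$p * z$g) / ng
}

#' Residual sum of squares of a training-loss curve
#'
#' Fits an ordinary-least-squares line to the loss values against their
#' index and returns the sum of squared residuals.  Used as a volatility
#' statistic for loss curves: the smaller the RSS, the less the curve
#' fluctuates about its linear trend, i.e. the more stable the optimization.
#'
#' @param losses Ordered numeric vector of loss values (>= 3 points).
#' @return The residual sum of squares.
#' @export
rss_of_loss_curve <- function(losses) {
  losses <- as.numeric(losses)
  if (length(losses) < 3)
    stop("need at least 3 loss values to measure curve volatility",
         call. = FALSE)
  i <- seq_along(losses)
  fit <- stats::lm(losses ~ i)
  sum(stats::residuals(fit)^2)
}

#' Evaluate a probability map against ground truth
#'
#' Binarizes the predicted probabilities at `threshold` and computes the full
#' metric suite: DSC, symmetric average surface distance, 95th-percentile
#' Hausdorff distance (both in mm, via the mask spacing), and foreground
#' recall accuracy.  If either binarized mask is empty the surface metrics
#' are undefined and reported as `NA`.
#'
#' @param pred_prob Predicted probabilities ([volume()] or array).
#' @param g Ground-truth [label_mask()] (or binary array).
#' @param threshold Binarization threshold, default 0.5.
#' @return A list of class `oto_metrics` with elements `dsc`, `asd`, `hd95`,
#'   `accuracy`.
#' @export
evaluate_segmentation <- function(pred_prob, g, threshold = 0.5) {
  pd <- as_vol_array(pred_prob)
  gd <- as_vol_array(g)
  if (!identical(dim(pd), dim(gd)))
    stop("prediction and label shapes differ", call. = FALSE)
  spacing <- vol_spacing(g)
  pbin <- (pd >= threshold) * 1
  dim(pbin) <- dim(pd)
  res <- list(dsc = dsc(pbin, gd),
              asd = NA_real_, hd95 = NA_real_,
              accuracy = seg_accuracy(pbin, gd))
  if (any(pbin > 0) && any(gd > 0)) {
    A <- surface_points(pbin, spacing)
    B <- surface_points(gd, spacing)
    res$asd <- asd(A, B)
    res$hd95 <- hd(A, B, 0.95)
  }
  structure(res, class = "oto_metrics")
}

#' @export
print.oto_metrics <- function(x, ...) {
  cat(sprintf("DSC %.4f | ASD %s mm | HD95 %s mm | accuracy %.4f\n",
              x$dsc, format(x$asd, digits = 4), format(x$hd95, digits = 4),
              x$accuracy))
  invisible(x)
}
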