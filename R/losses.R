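#' Loss configuration
#'
#' Declares the loss-ensemble composition used as the training objective.
#' `"dice"` is the smoothed soft-Dice loss alone; `"dice+ce"` adds binary
#' cross-entropy; `"dice+boundary"` adds the boundary loss, the mean of the
#' prediction weighted by the ground truth's signed distance map.  The
#' auxiliary term enters with weight `aux_weight` (lambda); all losses are
#' voxel means so lambda is scale-free across block sizes.
#'
#' @param mode One of `"dice"`, `"dice+ce"`, `"dice+boundary"`.
#' @param smooth Smoothing coefficient w of the Dice loss, a minimal positive
#'   number guarding the 0/0 case; default `1e-5`.
#' @param aux_weight Nonnegative weight lambda of the auxiliary term.
#' @param ramp_epochs If positive, training scales lambda linearly from 0 in
#'   the first epoch up to `aux_weight` after `ramp_epochs` epochs, so the
#'   Dice term alone drives the early search for the lesion.  Recommended
#'   for the boundary loss, whose raw magnitude (distances grow with block
#'   size) otherwise dominates before the network has found any foreground.
#'   0 disables the ramp; direct calls of [ensemble_loss()] always use the
#'   full weight.
#' @param phi_physical Logical; compute the signed distance map in
#'   spacing-scaled mm rather than voxel units.
#' @param foreground_only Logical; use the literal single-term (foreground
#'   only) cross-entropy instead of the two-class expansion.  The two-class
#'   form is the default because a one-term loss is degenerate for a sigmoid
#'   output: it is minimized by predicting 1 everywhere.
#' @return An object of class `oto_loss_config`.
#' @export
loss_config <- function(mode = c("dice", "dice+ce", "dice+boundary"),
                        smooth = 1e-5, aux_weight = 1, ramp_epochs = 0,
                        phi_physical = FALSE, foreground_only = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(smooth) || smooth <= 0)
    stop("`smooth` (w) must be > 0", call. = FALSE)
  if (!is.numeric(aux_weight) || aux_weight < 0)
    stop("`aux_weight` (lambda) must be >= 0", call. = FALSE)
  if (!is.numeric(ramp_epochs) || ramp_epochs < 0)
    stop("`ramp_epochs` must be >= 0", call. = FALSE)
  structure(list(mode = mode, smooth = smooth, aux_weight = aux_weight,
                 ramp_epochs = ramp_epochs, phi_physical = phi_physical,
                 foreground_only = foreground_only),
            class = "oto_loss_config")
}

check_pg <- function(p, g) {
  p <- as_vol_array(p); g <- as_vol_array(g)
  if (!identical(dim(p), dim(g)))
    stop("prediction and label shapes differ", call. = FALSE)
  list(p = p, g = g)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * g) + w) / (sum(p^2) + sum(g^2) + w)`, the smoothed
#' complement of the Dice similarity coefficient, differentiable in the
#' predicted probabilities.  Values lie in `[0, 1)`; identical binary inputs
#' give 0 (the smoothing term also makes the all-empty case 0 rather than
#' 0/0).
#'
#' @param p Predicted foreground probabilities in `[0, 1]` (array or
#'   [volume()]).
#' @param g Binary ground-truth labels, same shape.
#' @param smooth Smoothing coefficient w > 0.
#' @return A single numeric loss value.
#' @export
dice_loss <- function(p, g, smooth = 1e-5) {
  z <- check_pg(p, g)
  num <- 2 * sum(z$p * z$g) + smooth
  den <- sum(z$p^2) + sum(z$g^2) + smooth
  1 - num / den
}

# dL/dp of the soft Dice loss.
dice_loss_grad <- function(p, g, smooth = 1e-5) {
  num <- 2 * sum(p * g) + smooth
  den <- sum(p^2) + sum(g^2) + smooth
  -(2 * g * den - num * 2 * p) / den^2
}

CE_EPS <- 1e-7

#' Cross-entropy loss
#'
#' Mean over voxels of the per-voxel cross-entropy between the one-hot label
#' distribution and the predicted Bernoulli distribution,
#' `-[g log p + (1 - g) log(1 - p)]`.  Probabilities are clipped to
#' `[eps, 1 - eps]` before the logarithm so the loss is finite even for
#' saturated predictions.  With `foreground_only = TRUE` only the `-g log p`
#' term is kept (the literal one-term form).
#'
#' @inheritParams dice_loss
#' @param foreground_only Logical; see [loss_config()].
#' @return A single numeric loss value.
#' @export
ce_loss <- function(p, g, foreground_only = FALSE) {
  z <- check_pg(p, g)
  pc <- pmin(pmax(z$p, CE_EPS), 1 - CE_EPS)
  if (foreground_only) mean(-z$g * log(pc))
  else mean(-(z$g * log(pc) + (1 - z$g) * log(1 - pc)))
}

ce_loss_grad <- function(p, g, foreground_only = FALSE) {
  pc <- pmin(pmax(p, CE_EPS), 1 - CE_EPS)
  inner <- pc > CE_EPS & pc < 1 - CE_EPS  # zero gradient in the clipped range
  gr <- if (foreground_only) -g / pc else -g / pc + (1 - g) / (1 - pc)
  gr * inner / length(p)
}

#' Signed Euclidean distance map of a label mask
#'
#' For every voxel, the Euclidean distance (voxel centre to voxel centre) to
#' the nearest voxel of the opposite class: positive on background voxels
#' (distance to the foreground), negative on foreground voxels (distance to
#' the background).  This is the level-set map phi_G that weights the
#' boundary loss.  Degenerate masks containing a single class have no
#' boundary; the map is identically zero there so the boundary loss
#' contributes nothing.
#'
#' @param g Binary mask (array or [label_mask()]).
#' @param spacing Voxel spacing (Z, Y, X).  The default unit spacing gives
#'   voxel-unit distances; pass the mask's physical spacing for mm.
#' @return A numeric array of class `oto_sdm`, same shape as `g`.
#' @export
signed_distance <- function(g, spacing = c(1, 1, 1)) {
  gd <- as_vol_array(g)
  spacing <- as.numeric(spacing)
  nf <- sum(gd > 0)
  if (nf == 0 || nf == length(gd)) {
    phi <- array(0, dim(gd))
  } else {
    d_to_fg <- cpp_edt(as.numeric(gd > 0), dim(gd), spacing)
    d_to_bg <- cpp_edt(as.numeric(gd <= 0), dim(gd), spacing)
    phi <- ifelse(gd > 0, -d_to_bg, d_to_fg)
    dim(phi) <- dim(gd)
  }
  structure(phi, class = c("oto_sdm", class(phi)))
}

#' Boundary loss
#'
#' Mean over voxels of `phi_G(q) * p(q)`: predicted mass far outside the true
#' boundary is penalized in proportion to its distance, while mass inside the
#' truth (negative phi) is rewarded, so the loss may be negative.  Linear,
#' hence trivially differentiable, in the prediction.
#'
#' @param p Predicted foreground probabilities.
#' @param phi A signed distance map from [signed_distance()], same shape.
#' @return A single numeric loss value.
#' @export
boundary_loss <- function(p, phi) {
  pd <- as_vol_array(p)
  phid <- unclass(phi)
  if (!identical(dim(pd), dim(phid)))
    stop("prediction and distance-map shapes differ", call. = FALSE)
  mean(phid * pd)
}

boundary_loss_grad <- function(p, phi) {
  unclass(phi) / length(p)
}

#' Loss-ensemble objective
#'
#' Evaluates the configured training objective: plain Dice, Dice plus
#' lambda-weighted cross-entropy, or Dice plus lambda-weighted boundary loss.
#' For the boundary mode the signed distance map of the label block is
#' computed on the fly unless a precomputed `phi` is supplied (training
#' caches it per block, since labels are fixed).
#'
#' @inheritParams dice_loss
#' @param cfg An [loss_config()].
#' @param phi Optional precomputed [signed_distance()] map of `g`.
#' @param components Logical; return the pieces as well as the total.
#' @return The total loss, or (with `components = TRUE`) a list with
#'   `total`, `dice`, and `aux`.
#' @export
ensemble_loss <- function(p, g, cfg = loss_config(), phi = NULL,
                          components = FALSE) {
  stopifnot(inherits(cfg, "oto_loss_config"))
  z <- check_pg(p, g)
  ld <- dice_loss(z$p, z$g, cfg$smooth)
  aux <- if (cfg$aux_weight == 0) 0 else switch(cfg$mode,
    "dice" = 0,
    "dice+ce" = ce_loss(z$p, z$g, cfg$foreground_only),
    "dice+boundary" = {
      if (is.null(phi)) phi <- loss_phi(z$g, cfg)
      boundary_loss(z$p, phi)
    })
  total <- ld + cfg$aux_weight * aux
  if (components) list(total = total, dice = ld, aux = aux) else total
}

loss_phi <- function(g, cfg, spacing = c(1, 1, 1)) {
  signed_distance(g, spacing = if (cfg$phi_physical) spacing else c(1, 1, 1))
}

# dL/dp of the configured ensemble.
ensemble_loss_grad <- function(p, g, cfg, phi = NULL) {
  gr <- dice_loss_grad(p, g, cfg$smooth)
  if (cfg$aux_weight > 0) {
    ga <- switch(cfg$mode,
      "dice" = 0,
      "dice+ce" = ce_loss_grad(p, g, cfg$foreground_only),
      "dice+boundary" = {
        if (is.null(phi)) phi <- loss_phi(g, cfg)
        boundary_loss_grad(p, phi)
      })
    gr <- gr + cfg$aux_weight * ga
  }
  gr
}
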