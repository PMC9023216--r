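#' Training control parameters
#'
#' Optimization settings for [oto_train()].  Defaults follow the reference
#' configuration for the full-size network: Adam at learning rate 0.001,
#' dropout 0.5 (set in the model config), batch size 2, and training on
#' overlapping blocks after disequilibrium culling.  Epochs default low
#' because the package's own examples run at CPU scale; raise for real use.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the culled training blocks (>= 1).
#' @param batch_size Blocks per gradient step (>= 1).
#' @param loss An [loss_config()].
#' @param block_shape Training block shape (Z, Y, X).
#' @param overlap Logical; extract training blocks with half-shape stride so
#'   structures appear away from block borders in at least one block.
#' @param normalize Logical; min-max scale each volume to `[0, 1]` before
#'   blocking (applied at training/prediction time, never at I/O time).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param loss_csv Optional path; per-step loss components are written there
#'   as CSV (step, epoch, total, dice, aux).
#' @return An object of class `oto_train_control`.
#' @export
oto_train_control <- function(learning_rate = 0.001, epochs = 10,
                              batch_size = 2,
                              loss = loss_config("dice+boundary"),
                              block_shape = c(64, 128, 128), overlap = TRUE,
                              normalize = TRUE, seed = 1L, loss_csv = NULL) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  stopifnot(inherits(loss, "oto_loss_config"))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 block_shape = as.integer(block_shape), overlap = overlap,
                 normalize = normalize, seed = as.integer(seed),
                 loss_csv = loss_csv),
            class = "oto_train_control")
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

# Materialize training cases: accepts an oto_manifest (paths are read) or a
# list of list(image = oto_volume, label = oto_mask).
resolve_cases <- function(cases, split = "train") {
  if (inherits(cases, "oto_manifest")) {
    rows <- which(cases$split == split)
    lapply(rows, function(i) {
      list(image = read_volume(manifest_path(cases, cases$image[i])),
           label = read_volume(manifest_path(cases, cases$label[i]),
                               mask = TRUE))
    })
  } else if (is.list(cases)) {
    lapply(cases, function(cs) {
      stopifnot(inherits(cs$image, "oto_volume"), inherits(cs$label, "oto_mask"))
      cs
    })
  } else stop("`cases` must be an oto_manifest or a list of image/label pairs",
              call. = FALSE)
}

#' Fit the one-two-one segmentation network
#'
#' The main fitting function of the package.  Each training volume is
#' (optionally min-max normalized and) partitioned into blocks; lesion-free
#' block pairs are culled; the network is then trained with Adam on the
#' surviving blocks under the configured loss ensemble.  For the boundary
#' loss, the signed distance map of each label block is computed once and
#' cached, since labels do not change across epochs.
#'
#' @param cases Training data: an `oto_manifest` (its train split is used)
#'   or a list of `list(image = , label = )` pairs of [volume()] /
#'   [label_mask()] objects.
#' @param model An [oto_model_config()] or a pre-built [oto_net()] (e.g. to
#'   continue training).
#' @param control An [oto_train_control()].
#' @return An object of class `oto_fit` with components `net` (the trained
#'   network), `history` (per-epoch mean loss), `steps` (per-step loss
#'   components), `control`, and `n_blocks` (blocks surviving culling).
#' @seealso [predict.oto_fit()], [evaluate_segmentation()]
#' @export
oto_train <- function(cases, model = oto_model_config(),
                      control = oto_train_control()) {
  stopifnot(inherits(control, "oto_train_control"))
  net <- if (inherits(model, "oto_net")) model else oto_net(model)
  cases <- resolve_cases(cases, "train")
  if (length(cases) < 1) stop("no training cases", call. = FALSE)

  spec <- block_spec(control$block_shape, overlap = control$overlap)
  check_input_dims(control$block_shape)
  imgs <- list(); labs <- list()
  for (cs in cases) {
    im <- cs$image
    if (control$normalize) im$data <- minmax_scale(im$data)
    bi <- partition(im, spec)
    bl <- partition(cs$label, spec)
    kept <- cull_empty(bi, bl)
    imgs <- c(imgs, kept$images$blocks)
    labs <- c(labs, kept$labels$blocks)
  }
  n <- length(imgs)
  if (n == 0)
    stop(paste0("no blocks survived disequilibrium culling; the labels may ",
                "be empty or the blocks too large -- add foreground or ",
                "reduce `block_shape`"), call. = FALSE)

  lcfg <- control$loss
  phis <- NULL
  if (lcfg$mode == "dice+boundary" && lcfg$aux_weight > 0)
    phis <- lapply(labs, loss_phi, cfg = lcfg)

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(control$seed)

  opt <- adam_state(net$params, control$learning_rate)
  steps <- list()
  history <- data.frame(epoch = integer(), loss = numeric())
  step_i <- 0L
  for (ep in seq_len(control$epochs)) {
    lcfg_ep <- lcfg
    if (lcfg$ramp_epochs > 0)
      lcfg_ep$aux_weight <- lcfg$aux_weight *
        min(1, (ep - 1) / lcfg$ramp_epochs)
    ord <- sample.int(n)
    ep_losses <- c()
    for (start in seq(1, n, by = control$batch_size)) {
      batch <- ord[start:min(start + control$batch_size - 1L, n)]
      gsum <- NULL
      comp <- c(total = 0, dice = 0, aux = 0)
      for (j in batch) {
        x <- imgs[[j]]
        dim(x) <- c(dim(x), 1L)
        cache <- new.env(parent = emptyenv())
        p <- net_forward(net, x, training = TRUE, cache = cache)
        pp <- array(p, dim(p)[1:3])
        phi_j <- if (is.null(phis)) NULL else phis[[j]]
        lc <- ensemble_loss(pp, labs[[j]], lcfg_ep, phi = phi_j,
                            components = TRUE)
        dLdp <- ensemble_loss_grad(pp, labs[[j]], lcfg_ep, phi = phi_j)
        dim(dLdp) <- dim(p)
        g <- net_backward(net, cache, dLdp)
        gsum <- if (is.null(gsum)) g else add_grads(gsum, g)
        comp <- comp + c(lc$total, lc$dice, lc$aux)
      }
      nb <- length(batch)
      comp <- comp / nb
      step_i <- step_i + 1L
      steps[[step_i]] <- data.frame(step = step_i, epoch = ep,
                                    total = comp[1], dice = comp[2],
                                    aux = comp[3])
      ep_losses <- c(ep_losses, comp[1])
      net$params <- adam_step(net$params, scale_grads(gsum, 1 / nb), opt)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(ep_losses)))
  }
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  if (!is.null(control$loss_csv))
    utils::write.csv(steps, control$loss_csv, row.names = FALSE)

  structure(list(net = net, history = history, steps = steps,
                 control = control, n_blocks = n),
            class = "oto_fit")
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else a[[nm]] <- list(W = a[[nm]]$W + b[[nm]]$W, b = a[[nm]]$b + b[[nm]]$b)
  }
  a
}

scale_grads <- function(g, s) {
  lapply(g, function(p) list(W = p$W * s, b = p$b * s))
}

adam_state <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      st$m[[nm]][[fld]] <- b1 * st$m[[nm]][[fld]] + (1 - b1) * g
      st$v[[nm]][[fld]] <- b2 * st$v[[nm]][[fld]] + (1 - b2) * g^2
      mhat <- st$m[[nm]][[fld]] / corr1
      vhat <- st$v[[nm]][[fld]] / corr2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        st$lr * mhat / (sqrt(vhat) + st$eps)
    }
  }
  params
}

#' Predict a probability volume from a fitted model
#'
#' Partitions the input volume non-overlapping (no culling -- inference must
#' cover every voxel), forward-passes each block, and reassembles the
#' block-wise probabilities by averaging, exactly mirroring the training
#' preprocessing but on the whole volume.
#'
#' @param object An `oto_fit` from [oto_train()].
#' @param newdata An [volume()] (or 3D array) with every dimension at least
#'   the block shape.
#' @param block_shape Block shape for inference; defaults to the training
#'   block shape.
#' @param overlap Logical; use overlapping blocks (half stride) and average
#'   where they overlap.  Default non-overlapping.
#' @param ... Unused.
#' @return An [volume()] of per-voxel foreground probabilities in (0, 1).
#' @export
predict.oto_fit <- function(object, newdata, block_shape = NULL,
                            overlap = FALSE, ...) {
  v <- if (inherits(newdata, "oto_volume")) newdata
       else volume(newdata)
  if (is.null(block_shape)) block_shape <- object$control$block_shape
  if (any(dim(v$data) < block_shape))
    stop(sprintf("volume (%s) smaller than block shape (%s)",
                 paste(dim(v$data), collapse = "x"),
                 paste(block_shape, collapse = "x")), call. = FALSE)
  if (object$control$normalize) v$data <- minmax_scale(v$data)
  bs <- partition(v, block_spec(block_shape, overlap = overlap))
  bs$blocks <- lapply(bs$blocks, function(b) predict(object$net, b))
  out <- reassemble(bs)
  out$source_id <- paste0(v$source_id, ":prob")
  out
}

#' @export
print.oto_fit <- function(x, ...) {
  cat("One-two-one FCN segmentation fit\n")
  print(x$net)
  cat(sprintf("  loss: %s (lambda = %g), %d epochs over %d blocks, final loss %.4f\n",
              x$control$loss$mode, x$control$loss$aux_weight,
              nrow(x$history), x$n_blocks,
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.oto_fit <- function(object, ...) {
  h <- object$history
  cat("One-two-one FCN segmentation fit\n\n")
  print(object$net)
  ctl <- object$control
  cat(sprintf("loss mode      : %s (w = %g, lambda = %g)\n", ctl$loss$mode,
              ctl$loss$smooth, ctl$loss$aux_weight))
  cat(sprintf("optimizer      : Adam, lr %g, batch size %d\n",
              ctl$learning_rate, ctl$batch_size))
  cat(sprintf("training blocks: %d of shape %s (%s)\n", object$n_blocks,
              paste(ctl$block_shape, collapse = "x"),
              if (ctl$overlap) "overlapping" else "non-overlapping"))
  cat(sprintf("epoch loss     : %.4f -> %.4f over %d epochs\n",
              h$loss[1], h$loss[nrow(h)], nrow(h)))
  cat(sprintf("loss-curve RSS : %.4g\n",
              if (nrow(object$steps) >= 3)
                rss_of_loss_curve(object$steps$total) else NA))
  invisible(object)
}

#' Plot the training loss curve
#'
#' @param x An `oto_fit`.
#' @param which `"epoch"` for per-epoch mean loss, `"step"` for per-step.
#' @param ... Passed to [plot()].
#' @export
plot.oto_fit <- function(x, which = c("epoch", "step"), ...) {
  which <- match.arg(which)
  if (which == "epoch")
    plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
         ylab = "mean training loss", ...)
  else
    plot(x$steps$step, x$steps$total, type = "l", xlab = "step",
         ylab = "training loss", ...)
  invisible(x)
}

#' Residuals of a fitted segmentation model
#'
#' For segmentation the natural residual is the signed difference between
#' the predicted probability map and the binary truth on a given case.
#'
#' @param object An `oto_fit`.
#' @param image,label The case to evaluate ([volume()] and [label_mask()]).
#' @param ... Passed to [predict.oto_fit()].
#' @return An [volume()] of residuals `p - g`.
#' @export
residuals.oto_fit <- function(object, image, label, ...) {
  p <- predict(object, image, ...)
  r <- p$data - as_vol_array(label)
  volume(r, spacing = p$spacing, source_id = paste0(p$source_id, ":resid"))
}

#' Montage of a 3D block as a tiled 2D image
#'
#' Converts a block of `D` depth slices into a single 2D image by tiling the
#' slices row-major into a square grid (64 slices -> 8x8 tiles, giving a
#' 1024x1024 image for 128x128 slices).  The slice count must be a perfect
#' square.
#'
#' @param block 3D array (Z, Y, X), an [volume()], or the probability output
#'   of [predict.oto_fit()].
#' @return A 2D matrix of size `(sqrt(D) * Y, sqrt(D) * X)`.
#' @export
montage <- function(block) {
  b <- as_vol_array(block)
  d <- dim(b)
  g <- sqrt(d[1])
  if (g != floor(g))
    stop(sprintf(paste0("slice count %d is not a perfect square; valid ",
                        "depths near it: %d, %d"), d[1],
                 floor(g)^2, ceiling(g)^2), call. = FALSE)
  g <- as.integer(g)
  out <- matrix(0, nrow = g * d[2], ncol = g * d[3])
  for (k in seq_len(d[1])) {
    r <- (k - 1L) %/% g
    cc <- (k - 1L) %% g
    out[r * d[2] + seq_len(d[2]), cc * d[3] + seq_len(d[3])] <- b[k, , ]
  }
  out
}
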