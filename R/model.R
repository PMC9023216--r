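#' Model configuration for the one-two-one network
#'
#' The architecture is a cascade of three complete encoder-decoder
#' structures of depths one, two, one ("one-two-one").  All convolutions use
#' 3x3x3 kernels in SAME mode with ReLU activations; downsampling is a
#' stride-2 convolution doubling the channel count, upsampling a stride-2
#' transposed convolution halving it; skip connections stack (concatenate)
#' the same-resolution encoder features onto the decoder; within every stage
#' the stage input is added element-wise to the output of its convolution
#' run (residual addition).  The output head is a single-channel convolution
#' with a sigmoid, so predictions are per-voxel foreground probabilities.
#'
#' With the default `base_channels = 16` the channel schedule is 16 at full
#' resolution, 32 at half, 64 at quarter (the deepest stage of the middle
#' structure).  `base_channels = 4` gives a reduced network usable for
#' CPU-scale experiments.
#'
#' @param in_channels Input channels (1 for a TOF-MRA intensity volume).
#' @param base_channels Channels at full resolution; doubled at each
#'   downsampling.
#' @param kernel 3 odd integers; only 3x3x3 is supported by the engine.
#' @param dropout Dropout rate in `[0, 1)`, applied after the deepest stage
#'   of each encoder-decoder structure, training only.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `oto_model_config`.
#' @export
oto_model_config <- function(in_channels = 1, base_channels = 16,
                             kernel = c(3, 3, 3), dropout = 0.5, seed = 1L) {
  if (base_channels < 1) stop("`base_channels` must be >= 1", call. = FALSE)
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel %% 2L == 0L) || any(kernel < 1L))
    stop("`kernel` entries must be odd positive integers", call. = FALSE)
  if (!all(kernel == 3L))
    stop("the convolution engine supports 3x3x3 kernels only", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 kernel = kernel, dropout = dropout, seed = as.integer(seed)),
            class = "oto_model_config")
}

# Layer table of the architecture.  Each convolution is named; tconv weights
# are stored in the adjoint-convolution layout (3,3,3,Cout,Cin) so the
# transposed convolution is computed as the exact adjoint of a stride-2
# convolution.
oto_layer_table <- function(cfg) {
  ci <- cfg$in_channels
  c1 <- cfg$base_channels; c2 <- 2L * c1; c3 <- 4L * c1
  L <- list()
  add <- function(name, cin, cout, type = "conv", stride = 1L) {
    L[[name]] <<- list(cin = cin, cout = cout, type = type, stride = stride)
  }
  # structure one (depth 1)
  add("o1s1_c1", ci, c1); add("o1s1_c2", c1, c1)
  add("o1s2_down", c1, c2, stride = 2L)
  add("o1s2_c1", c2, c2); add("o1s2_c2", c2, c2); add("o1s2_c3", c2, c2)
  add("ts1_up", c2, c1, type = "tconv")
  add("ts1_c1", 2L * c1, c1); add("ts1_c2", c1, c1); add("ts1_c3", c1, c1)
  # structure two (depth 2)
  add("ts2_down", c1, c2, stride = 2L)
  add("ts2_c1", c2, c2); add("ts2_c2", c2, c2); add("ts2_c3", c2, c2)
  add("ts3_down", c2, c3, stride = 2L)
  add("ts3_c1", c3, c3); add("ts3_c2", c3, c3); add("ts3_c3", c3, c3)
  add("ts4_up", c3, c2, type = "tconv")
  add("ts4_c1", 2L * c2, c2); add("ts4_c2", c2, c2); add("ts4_c3", c2, c2)
  add("ts5_up", c2, c1, type = "tconv")
  add("ts5_c1", 2L * c1, c1); add("ts5_c2", c1, c1); add("ts5_c3", c1, c1)
  # structure three (depth 1)
  add("o2s1_down", c1, c2, stride = 2L)
  add("o2s1_c1", c2, c2); add("o2s1_c2", c2, c2); add("o2s1_c3", c2, c2)
  add("o2s2_up", c2, c1, type = "tconv")
  add("o2s2_c1", 2L * c1, c1); add("o2s2_c2", c1, c1); add("o2s2_c3", c1, c1)
  # output head
  add("head", c1, 1L)
  L
}

#' Build the one-two-one segmentation network
#'
#' Constructs the full layer graph described in [oto_model_config()] and
#' initializes its weights with a fan-in (He) scheme, deterministically from
#' the config seed.  The network is fully convolutional: it runs on any
#' input whose spatial dimensions are divisible by 4 (two downsamplings),
#' not only the nominal 64x128x128 block.
#'
#' @param cfg An [oto_model_config()].
#' @return An object of class `oto_net` holding the parameters and config.
#' @examples
#' net <- oto_net(oto_model_config(base_channels = 2))
#' count_parameters(net)
#' @export
oto_net <- function(cfg = oto_model_config()) {
  stopifnot(inherits(cfg, "oto_model_config"))
  layers <- oto_layer_table(cfg)
  params <- vector("list", length(layers))
  names(params) <- names(layers)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$type == "tconv") {
      # adjoint layout: weight of the stride-2 conv mapping cout -> cin
      wdim <- c(3L, 3L, 3L, l$cout, l$cin)
      fan_in <- 27 * l$cin / 8  # each output voxel sees ~27/8 taps per ci
      nb <- l$cout
    } else {
      wdim <- c(3L, 3L, 3L, l$cin, l$cout)
      fan_in <- 27 * l$cin
      nb <- l$cout
    }
    sdw <- sqrt(2 / fan_in)
    if (nm == "head") sdw <- sqrt(1 / fan_in)  # sigmoid head: milder init
    # The network carries no normalization layers, so the closing convolution
    # of every residual branch starts near zero (SkipInit-style): each stage
    # is close to the identity around its down/up-sampling path at
    # initialization, which keeps the 29-convolution cascade trainable from
    # scratch.  A small positive bias keeps the following ReLU gate open so
    # these convolutions still receive gradient.
    bias0 <- numeric(nb)
    if (grepl("_c3$", nm) || nm == "o1s1_c2") {
      sdw <- 0
      bias0 <- rep(0.01, nb)
    }
    # The head bias starts at the logit of a low foreground prior (~0.1)
    # rather than 0: with p = 0.5 everywhere the Dice denominator is
    # dominated by the background mass and the first optimizer steps
    # suppress the prediction globally, saturating the sigmoid before any
    # foreground discrimination can form.
    if (nm == "head") bias0 <- rep(-2.2, nb)
    params[[nm]] <- list(W = array(stats::rnorm(prod(wdim), 0, sdw), wdim),
                         b = bias0)
  }
  structure(list(params = params, layers = layers, config = cfg),
            class = "oto_net")
}

#' Count trainable parameters
#'
#' @param net An [oto_net()] or a fitted model.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "oto_fit")) net <- net$net
  stopifnot(inherits(net, "oto_net"))
  sum(vapply(net$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.oto_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<one-two-one FCN> base %d channels (schedule %d/%d/%d), %s parameters\n",
    cfg$base_channels, cfg$base_channels, 2 * cfg$base_channels,
    4 * cfg$base_channels, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

check_input_dims <- function(d) {
  if (any(d[1:3] %% 4L != 0L))
    stop(sprintf(paste0("input spatial dims (%s) must be divisible by 4 ",
                        "(two stride-2 downsamplings)"),
                 paste(d[1:3], collapse = "x")), call. = FALSE)
}

#' Stage-by-stage shape trace
#'
#' Walks the nine named stages of the network for a given input shape and
#' reports each stage's spatial size and channel count: full resolution at
#' the base width, halving spatially and doubling channels at each descent.
#' Useful for conformance-checking the channel schedule.
#'
#' @param net An [oto_net()].
#' @param input_shape Integer length-3 spatial input shape (Z, Y, X), all
#'   divisible by 4.
#' @return A data frame with columns `stage`, `depth`, `height`, `width`,
#'   `channels`.
#' @export
shape_trace <- function(net, input_shape = c(64, 128, 128)) {
  stopifnot(inherits(net, "oto_net"))
  input_shape <- as.integer(input_shape)
  check_input_dims(input_shape)
  stages <- c("OI-Stage1", "OI-Stage2", "T-Stage1", "T-Stage2", "T-Stage3",
              "T-Stage4", "T-Stage5", "OII-Stage1", "OII-Stage2")
  level <- c(1L, 2L, 1L, 2L, 3L, 2L, 1L, 2L, 1L)
  f <- as.integer(2^(level - 1L))
  data.frame(stage = stages,
             depth = input_shape[1] %/% f,
             height = input_shape[2] %/% f,
             width = input_shape[3] %/% f,
             channels = net$config$base_channels * f,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Forward and backward passes.  Feature tensors have dim (Z, Y, X, C).  The
# cache environment stores, per layer, the input tensor (for weight
# gradients) and the ReLU mask (for activation gradients).

relu <- function(x) { x[x < 0] <- 0; x }

add_bias <- function(x, b) {
  d <- dim(x)
  for (c in seq_along(b)) if (b[c] != 0)
    x[, , , c] <- x[, , , c] + b[c]
  x
}

net_forward <- function(net, x, training = FALSE, cache = NULL) {
  params <- net$params
  keep <- !is.null(cache)
  drop_rate <- if (training) net$config$dropout else 0

  conv_f <- function(name, x, relu_act = TRUE) {
    l <- net$layers[[name]]
    p <- params[[name]]
    pre <- cpp_conv3d_fwd(x, dim(x), p$W, p$b, l$stride)
    if (keep) cache[[paste0(name, ".x")]] <- x
    if (relu_act) {
      if (keep) cache[[paste0(name, ".m")]] <- pre > 0
      relu(pre)
    } else pre
  }
  tconv_f <- function(name, x) {
    l <- net$layers[[name]]
    p <- params[[name]]
    d <- dim(x)
    out_dim <- c(d[1:3] * 2L, l$cout)
    pre <- cpp_conv3d_bwd_dx(x, d, p$W, out_dim, 2L)
    pre <- add_bias(pre, p$b)
    if (keep) {
      cache[[paste0(name, ".x")]] <- x
      cache[[paste0(name, ".m")]] <- pre > 0
    }
    relu(pre)
  }
  drop_f <- function(name, x) {
    if (drop_rate <= 0) return(x)
    m <- (stats::runif(length(x)) >= drop_rate) / (1 - drop_rate)
    dim(m) <- dim(x)
    if (keep) cache[[paste0(name, ".m")]] <- m
    x * m
  }
  concat_c <- function(a, b) {
    da <- dim(a); db <- dim(b)
    out <- array(0, c(da[1:3], da[4] + db[4]))
    out[, , , seq_len(da[4])] <- a
    out[, , , da[4] + seq_len(db[4])] <- b
    out
  }
  enc_stage <- function(prefix, x) {
    d <- conv_f(paste0(prefix, "_down"), x)
    h <- conv_f(paste0(prefix, "_c1"), d)
    h <- conv_f(paste0(prefix, "_c2"), h)
    h <- conv_f(paste0(prefix, "_c3"), h)
    d + h
  }
  dec_stage <- function(prefix, x, skip) {
    u <- tconv_f(paste0(prefix, "_up"), x)
    h <- conv_f(paste0(prefix, "_c1"), concat_c(u, skip))
    h <- conv_f(paste0(prefix, "_c2"), h)
    h <- conv_f(paste0(prefix, "_c3"), h)
    u + h
  }

  h1 <- conv_f("o1s1_c1", x)
  h2 <- conv_f("o1s1_c2", h1)
  A1 <- h1 + h2
  A2 <- drop_f("do1", enc_stage("o1s2", A1))
  A3 <- dec_stage("ts1", A2, A1)
  A4 <- enc_stage("ts2", A3)
  A5 <- drop_f("do2", enc_stage("ts3", A4))
  A6 <- dec_stage("ts4", A5, A4)
  A7 <- dec_stage("ts5", A6, A3)
  A8 <- drop_f("do3", enc_stage("o2s1", A7))
  A9 <- dec_stage("o2s2", A8, A7)
  z <- conv_f("head", A9, relu_act = FALSE)
  p <- 1 / (1 + exp(-z))
  if (keep) cache[["p"]] <- p
  p
}

# Backward pass; dLdp is the gradient of the scalar loss w.r.t. the sigmoid
# output.  Returns a named list of gradients matching net$params.
net_backward <- function(net, cache, dLdp) {
  grads <- new.env(parent = emptyenv())

  conv_b <- function(name, g, relu_act = TRUE) {
    l <- net$layers[[name]]
    p <- net$params[[name]]
    if (relu_act) g <- g * cache[[paste0(name, ".m")]]
    x <- cache[[paste0(name, ".x")]]
    dwb <- cpp_conv3d_bwd_dw(x, dim(x), g, dim(g), l$stride)
    acc_grad(grads, name, dwb$dw, dwb$db)
    cpp_conv3d_bwd_dx(g, dim(g), p$W, dim(x), l$stride)
  }
  tconv_b <- function(name, g) {
    p <- net$params[[name]]
    g <- g * cache[[paste0(name, ".m")]]
    x <- cache[[paste0(name, ".x")]]
    db <- apply(g, 4, sum)
    # adjoint pair: dw accumulates with (conv-input = g, conv-gout = x)
    dwb <- cpp_conv3d_bwd_dw(g, dim(g), x, dim(x), 2L)
    acc_grad(grads, name, dwb$dw, db)
    cpp_conv3d_fwd(g, dim(g), p$W, numeric(dim(p$W)[5]), 2L)
  }
  drop_b <- function(name, g) {
    m <- cache[[paste0(name, ".m")]]
    if (is.null(m)) g else g * m
  }
  split_c <- function(g, ca) {
    d <- dim(g)
    list(a = g[, , , seq_len(ca), drop = FALSE],
         b = g[, , , (ca + 1):d[4], drop = FALSE])
  }
  enc_b <- function(prefix, g) {
    gh <- conv_b(paste0(prefix, "_c3"), g)
    gh <- conv_b(paste0(prefix, "_c2"), gh)
    gh <- conv_b(paste0(prefix, "_c1"), gh)
    conv_b(paste0(prefix, "_down"), g + gh)
  }
  dec_b <- function(prefix, g) {
    gh <- conv_b(paste0(prefix, "_c3"), g)
    gh <- conv_b(paste0(prefix, "_c2"), gh)
    gcc <- conv_b(paste0(prefix, "_c1"), gh)
    cu <- net$layers[[paste0(prefix, "_up")]]$cout
    sp <- split_c(gcc, cu)
    gx <- tconv_b(paste0(prefix, "_up"), g + sp$a)
    list(gx = gx, gskip = sp$b)
  }

  p <- cache[["p"]]
  gz <- dLdp * p * (1 - p)
  gA9 <- conv_b("head", gz, relu_act = FALSE)
  o2 <- dec_b("o2s2", gA9)
  gA7 <- o2$gskip + enc_b("o2s1", drop_b("do3", o2$gx))
  t5 <- dec_b("ts5", gA7)
  t4 <- dec_b("ts4", t5$gx)
  gA4 <- t4$gskip + enc_b("ts3", drop_b("do2", t4$gx))
  gA3 <- t5$gskip + enc_b("ts2", gA4)
  t1 <- dec_b("ts1", gA3)
  gA1 <- t1$gskip + enc_b("o1s2", drop_b("do1", t1$gx))
  gh1 <- gA1 + conv_b("o1s1_c2", gA1)
  conv_b("o1s1_c1", gh1)
  as.list(grads)
}

acc_grad <- function(grads, name, dw, db) {
  cur <- get0(name, grads, ifnotfound = NULL)
  if (is.null(cur)) assign(name, list(W = dw, b = db), grads)
  else assign(name, list(W = cur$W + dw, b = cur$b + db), grads)
}

#' Forward pass of the network on a single block
#'
#' Runs the network in inference mode (dropout off) on one 3D block and
#' returns the per-voxel foreground probabilities; output spatial shape
#' equals input spatial shape, values strictly in (0, 1).
#'
#' @param object An [oto_net()].
#' @param newdata 3D array (Z, Y, X) or 4D array (Z, Y, X, channels) with
#'   spatial dims divisible by 4, or an [volume()].
#' @param ... Unused.
#' @return 3D array of probabilities (channel axis dropped for 1 output).
#' @export
predict.oto_net <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "oto_volume")) newdata$data else newdata
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L || dim(x)[4] != object$config$in_channels)
    stop("input must be (Z, Y, X[, channels]) matching the config",
         call. = FALSE)
  check_input_dims(dim(x))
  p <- net_forward(object, x, training = FALSE)
  array(p, dim(p)[1:3])
}
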