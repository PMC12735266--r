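#' Predictor configuration
#'
#' The location-map predictor can be any encoder-decoder that outputs a
#' non-negative map at the same resolution as its input.  The built-in
#' model is a small two-level U-style network: two 3x3 conv+ReLU blocks,
#' 2x average pooling, two more conv blocks at half resolution, nearest
#' upsampling, a skip concatenation, one fusing conv block and a final
#' 1x1 conv with ReLU output (the ReLU is what guarantees
#' non-negativity of the predicted location map).
#'
#' @param base_channels Channels of the first level (the second level
#'   uses twice as many).  Default 8 keeps the model at a few thousand
#'   parameters, enough for quasi-circular blob detection and cheap to
#'   train on one CPU core.
#' @param in_channels Image channels (1 for grayscale).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(base_channels = 8L, in_channels = 1L) {
  stopifnot(base_channels >= 1, in_channels >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 n_levels = 2L),
            class = "predictor_config")
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Initialize predictor weights
#'
#' He-normal weight initialization, zero biases.  Deterministic given
#' `seed`.
#'
#' @param cfg A [predictor_config()].
#' @param seed Integer seed for the weight draws.
#' @return A list of class `pu_localizer` with `config` and `weights`.
#' @export
init_model <- function(cfg = predictor_config(), seed = 1L) {
  C <- cfg$base_channels; ci <- cfg$in_channels
  weights <- withr_seed(seed, list(
    w1 = he_init(3, 3, ci, C),      b1 = numeric(C),
    w2 = he_init(3, 3, C, C),       b2 = numeric(C),
    w3 = he_init(3, 3, C, 2 * C),   b3 = numeric(2 * C),
    w4 = he_init(3, 3, 2 * C, 2 * C), b4 = numeric(2 * C),
    w5 = he_init(3, 3, 3 * C, C),   b5 = numeric(C),
    # non-negative head: the pre-ReLU output starts >= 0 wherever the
    # penultimate features are active, so the output ReLU can never be
    # dead at initialization (a sign-symmetric draw can land negative
    # across a whole near-constant background image, freezing training).
    # The small scale keeps initial box-summed counts inside tanh's
    # active range instead of saturating it.
    w6 = abs(he_init(1, 1, C, 1)) / 50, b6 = 0.01))
  structure(list(config = cfg, weights = weights), class = "pu_localizer")
}

relu <- function(x) pmax(x, 0)

# Interior activations are leaky (slope 0.01 below zero): in a network
# this small a hard ReLU can leave whole channels dead, which the
# background-suppression pressure of PU training then cannot revive.
lrelu <- function(x) pmax(x, 0.01 * x)

lrelu_grad <- function(z) 0.01 + 0.99 * (z > 0)

# 2x average pooling / nearest upsampling as (cached) matrix products.
pool_mats <- function(n) {
  g <- (seq_len(n) + 1L) %/% 2L
  np <- max(g)
  M <- matrix(0, np, n)
  M[cbind(g, seq_len(n))] <- 1
  list(avg = M / rowSums(M), rep = M, groups = g)
}

# Apply row operator A and column operator B to every channel of a
# cube: out[,,c] = A %*% x[,,c] %*% t(B), as two whole-cube GEMMs
# (rows in one multiply, columns via a transpose shuffle).
cube_rowcol_op <- function(x, A, B) {
  d <- dim(x)
  y <- A %*% matrix(x, d[1L], d[2L] * d[3L])        # rows of all slices
  y <- array(y, c(nrow(A), d[2L], d[3L]))
  y <- aperm(y, c(2L, 1L, 3L))
  y <- B %*% matrix(y, d[2L], nrow(A) * d[3L])      # columns
  aperm(array(y, c(nrow(B), nrow(A), d[3L])), c(2L, 1L, 3L))
}

avg_pool2 <- function(x, pr, pc) cube_rowcol_op(x, pr$avg, pc$avg)

avg_pool2_bwd <- function(g, pr, pc)
  cube_rowcol_op(g, t(pr$avg), t(pc$avg))

upsample2 <- function(x, pr, pc) cube_rowcol_op(x, t(pr$rep), t(pc$rep))

upsample2_bwd <- function(g, pr, pc) cube_rowcol_op(g, pr$rep, pc$rep)

as_input_cube <- function(image, cfg) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L || dim(image)[3L] != cfg$in_channels)
    stop("image channel count does not match the predictor config",
         call. = FALSE)
  image
}

# Full forward pass; optionally keeps every intermediate (activations
# and im2col matrices) needed for backprop.
model_forward <- function(model, image, keep = FALSE) {
  cfg <- model$config; w <- model$weights
  a0 <- as_input_cube(image, cfg)
  H <- dim(a0)[1L]; W <- dim(a0)[2L]
  pr <- pool_mats(H); pc <- pool_mats(W)
  conv <- if (keep) cpp_conv2d_fwd_cache else
    function(x, wt, b) list(y = cpp_conv2d_fwd(x, wt, b))
  c1 <- conv(a0, w$w1, w$b1); z1 <- c1$y; a1 <- lrelu(z1)
  c2 <- conv(a1, w$w2, w$b2); z2 <- c2$y; a2 <- lrelu(z2)
  p  <- avg_pool2(a2, pr, pc)
  c3 <- conv(p, w$w3, w$b3);  z3 <- c3$y; a3 <- lrelu(z3)
  c4 <- conv(a3, w$w4, w$b4); z4 <- c4$y; a4 <- lrelu(z4)
  u  <- upsample2(a4, pr, pc)
  ct <- array(c(u, a2), dim = c(H, W, dim(u)[3L] + dim(a2)[3L]))
  c5 <- conv(ct, w$w5, w$b5); z5 <- c5$y; a5 <- lrelu(z5)
  c6 <- conv(a5, w$w6, w$b6); z6 <- c6$y; out <- relu(z6)
  res <- list(out = out[, , 1L])
  if (keep)
    res$cache <- list(z1 = z1, z2 = z2, p = p, z3 = z3, z4 = z4, u = u,
                      z5 = z5, z6 = z6, pr = pr, pc = pc,
                      col1 = c1$col, col2 = c2$col, col3 = c3$col,
                      col4 = c4$col, col5 = c5$col, col6 = c6$col)
  res
}

# Backward pass: gout is dLoss/d(location map), an H x W matrix.
# Returns gradients with the same structure as model$weights.
# `out_leak`: subgradient used on the clamped side of the output ReLU.
# The default 0 is the exact subgradient.  The trainer passes a small
# leak instead: the background-suppression term can push the whole
# head below zero early in training, and with a hard zero subgradient
# that state is absorbing (no signal can revive a fully clamped
# output), while a leak lets the positive-sample loss pull it back.
# Predictions are exactly non-negative either way.
model_backward <- function(model, cache, gout, out_leak = 0) {
  w <- model$weights
  C2 <- dim(cache$u)[3L]
  g6 <- array(gout, dim = dim(cache$z6)) *
    (out_leak + (1 - out_leak) * (cache$z6 > 0))
  b6 <- cpp_conv2d_bwd_cached(cache$col6, w$w6, g6)
  g5 <- b6$gx * lrelu_grad(cache$z5)
  b5 <- cpp_conv2d_bwd_cached(cache$col5, w$w5, g5)
  gu <- b5$gx[, , seq_len(C2), drop = FALSE]
  gskip <- b5$gx[, , -seq_len(C2), drop = FALSE]
  ga4 <- upsample2_bwd(gu, cache$pr, cache$pc)
  g4 <- ga4 * lrelu_grad(cache$z4)
  b4 <- cpp_conv2d_bwd_cached(cache$col4, w$w4, g4)
  g3 <- b4$gx * lrelu_grad(cache$z3)
  b3 <- cpp_conv2d_bwd_cached(cache$col3, w$w3, g3)
  ga2 <- avg_pool2_bwd(b3$gx, cache$pr, cache$pc) + gskip
  g2 <- ga2 * lrelu_grad(cache$z2)
  b2 <- cpp_conv2d_bwd_cached(cache$col2, w$w2, g2)
  g1 <- b2$gx * lrelu_grad(cache$z1)
  b1 <- cpp_conv2d_bwd_cached(cache$col1, w$w1, g1)
  list(w1 = b1$gw, b1 = c(b1$gb), w2 = b2$gw, b2 = c(b2$gb),
       w3 = b3$gw, b3 = c(b3$gb), w4 = b4$gw, b4 = c(b4$gb),
       w5 = b5$gw, b5 = c(b5$gb), w6 = b6$gw, b6 = c(b6$gb))
}

#' Predict a location map for an image
#'
#' Runs the encoder-decoder in inference mode.  The output is a
#' non-negative matrix with the same height and width as the input;
#' object centers appear as prominent local maxima (see
#' [find_peaks()]).
#'
#' @param model An [init_model()] result or a trained checkpoint's
#'   `model` element.
#' @param image Numeric matrix in \[0, 1\] (or an H x W x C array
#'   matching the configured channels).
#' @return Non-negative numeric matrix, same spatial shape as `image`.
#' @export
predict_location_map <- function(model, image) {
  model_forward(model, image, keep = FALSE)$out
}

#' Save or load a training checkpoint
#'
#' Checkpoints bundle the predictor config, weights, the training-stage
#' tag and the validation score of the stored weights.
#'
#' @param ckpt A checkpoint list (as returned by the training
#'   functions).
#' @param path File path (RDS).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
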