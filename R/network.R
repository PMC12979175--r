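# 2D densely connected U-Net: parameter initialization, forward pass and
# exact backpropagation, built on the C++ conv/pool/upconv/batch-norm kernels.
#
# Topology (base filter count b, growth per level g_l = b * 2^l):
#   3x3 conv + BN + ReLU (in -> b)
#   encoder: [dense block -> 2x2 maxpool] x 2
#   bottleneck: dense block
#   decoder: [2x2 transposed conv + BN + ReLU -> concat encoder skip ->
#             dense block] x 2
#   1x1 conv -> sigmoid probability map
# A dense block has 4 sequential 3x3 conv+BN+ReLU sub-blocks; sub-block k
# receives the concatenation of the block input and all previous sub-block
# outputs, and the block output concatenates the 4 sub-block outputs (4*g
# channels). Batch normalization follows every convolution except the output
# 1x1; it keeps activations in range, which stabilizes Tversky-loss training
# under extreme class imbalance. All conv weights are He-normal initialized.
#
# Arrays are (H, W, C, N). Spatial dims are zero-padded internally to a
# multiple of 4 (two pooling levels) and the output is cropped back.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Network configuration
#'
#' @param base_filters Channel count of the initial convolution (default 16).
#'   Dense-block growth doubles per encoder level: `base_filters` at full
#'   resolution, `2*base_filters` after one pooling, `4*base_filters` in the
#'   bottleneck.
#' @param in_channels Input image channels (default 1).
#' @param input_shape Optional 2D slice shape, recorded for bookkeeping; the
#'   network itself is fully convolutional.
#' @return A `wml_net_config` list. `dense_sub_blocks` (4), `kernel_size`
#'   (3x3) and `encoder_levels` (2) are architectural constants.
#' @export
network_config <- function(base_filters = 16, in_channels = 1,
                           input_shape = NULL) {
  stopifnot(base_filters >= 1)
  structure(list(base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 input_shape = input_shape,
                 dense_sub_blocks = 4L,
                 encoder_levels = 2L,
                 kernel_size = c(3L, 3L)),
            class = "wml_net_config")
}

he_normal <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

# conv followed by batch norm: no conv bias (the BN shift beta serves);
# rm/rv are the running mean/variance used at inference time
conv_bn_param <- function(kh, kw, cin, cout) {
  list(W = he_normal(kh, kw, cin, cout), gamma = rep(1, cout),
       beta = numeric(cout), rm = numeric(cout), rv = rep(1, cout))
}

dense_block_param <- function(cin, growth) {
  list(sub = lapply(1:4, function(k)
         conv_bn_param(3, 3, cin + (k - 1) * growth, growth)),
       cin = cin, growth = growth)
}

#' Build an untrained network
#'
#' Allocates and He-normal-initializes all parameters of the dense U-Net for
#' the given configuration. Deterministic per seed.
#'
#' @param cfg A [network_config()].
#' @param seed Integer RNG seed for the initialization.
#' @return A `wml_net_params` nested list of weight arrays.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  b <- cfg$base_filters
  with_seed(seed, {
    structure(list(
      conv_in = conv_bn_param(3, 3, cfg$in_channels, b),
      enc1 = dense_block_param(b, b),            # out 4b
      enc2 = dense_block_param(4 * b, 2 * b),    # out 8b
      bott = dense_block_param(8 * b, 4 * b),    # out 16b
      up2 = conv_bn_param(2, 2, 16 * b, 8 * b),
      dec2 = dense_block_param(16 * b, 2 * b),   # in: up(8b) + skip e2(8b)
      up1 = conv_bn_param(2, 2, 8 * b, 4 * b),
      dec1 = dense_block_param(8 * b, b),        # in: up(4b) + skip e1(4b)
      out = list(W = he_normal(1, 1, 4 * b, 1), b = numeric(1)),
      base_filters = b
    ), class = "wml_net_params")
  })
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_c <- function(lst) cpp_concat_c(lst)

split_c <- function(x, sizes) cpp_split_c(x, as.integer(sizes))

# conv (3x3 "same" or 2x2-stride-2 transposed) + batch norm + ReLU
cbr_forward <- function(p, x, training, up = FALSE) {
  nb <- length(p$gamma)
  z <- if (up) cpp_upconv2_forward(x, p$W, numeric(nb))
       else cpp_conv2d_forward(x, p$W, numeric(nb))
  if (training) {
    st <- cpp_bn_stats(z)
    invstd <- 1 / sqrt(st$var + BN_EPS)
    ap <- cpp_bn_apply(z, st$mean, invstd, p$gamma, p$beta)
    a <- relu(ap$y)
    list(a = a, cache = list(xhat = ap$xhat, invstd = invstd, a = a,
                             mean = st$mean, var = st$var))
  } else {
    y <- cpp_bn_infer(z, p$rm, 1 / sqrt(p$rv + BN_EPS), p$gamma, p$beta)
    list(a = relu(y), cache = NULL)
  }
}

cbr_backward <- function(p, x, cache, da, up = FALSE) {
  dy <- da * (cache$a > 0)
  bn <- cpp_bn_backward(cache$xhat, cache$invstd, p$gamma, dy)
  cw <- if (up) cpp_upconv2_backward(x, p$W, bn$dx)
        else cpp_conv2d_backward(x, p$W, bn$dx)
  list(dx = cw$dx,
       grad = list(W = cw$dw, gamma = bn$dgamma, beta = bn$dbeta))
}

dense_forward <- function(p, x, training) {
  feats <- list(x)
  outs <- caches <- vector("list", 4L)
  for (k in 1:4) {
    inp <- if (k == 1) x else concat_c(feats)
    fw <- cbr_forward(p$sub[[k]], inp, training)
    outs[[k]] <- fw$a
    caches[[k]] <- fw$cache
    feats[[k + 1L]] <- outs[[k]]
  }
  list(out = concat_c(outs), x = x, outs = outs, caches = caches)
}

dense_backward <- function(p, cache, dout) {
  g <- p$growth
  grads_a <- split_c(dout, rep(g, 4))
  grads <- vector("list", 4L)
  dx <- array(0, dim(cache$x))
  for (k in 4:1) {
    inp <- if (k == 1) cache$x else
      concat_c(c(list(cache$x), cache$outs[seq_len(k - 1)]))
    bw <- cbr_backward(p$sub[[k]], inp, cache$caches[[k]], grads_a[[k]])
    grads[[k]] <- bw$grad
    parts <- split_c(bw$dx, c(p$cin, rep(g, k - 1)))
    dx <- dx + parts[[1]]
    if (k > 1) for (j in seq_len(k - 1))
      grads_a[[j]] <- grads_a[[j]] + parts[[j + 1L]]
  }
  list(dx = dx, sub = grads)
}

pad4 <- function(x) {
  d <- dim(x)
  H2 <- 4L * ((d[1] + 3L) %/% 4L)
  W2 <- 4L * ((d[2] + 3L) %/% 4L)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, orig = d[1:2]))
  out <- array(0, c(H2, W2, d[3], d[4]))
  out[1:d[1], 1:d[2], , ] <- x
  list(x = out, orig = d[1:2])
}

unpad4 <- function(x, orig) {
  d <- dim(x)
  if (d[1] == orig[1] && d[2] == orig[2]) return(x)
  x[1:orig[1], 1:orig[2], , , drop = FALSE]
}

# Forward pass; x is (H, W, C, N). Returns sigmoid probabilities (H, W, 1, N)
# and, in training mode, all intermediates needed for backprop. Inference
# mode (training = FALSE) uses the running batch-norm statistics.
net_forward <- function(params, x, training = FALSE) {
  pd <- pad4(x)
  x <- pd$x
  c_in <- cbr_forward(params$conv_in, x, training)
  e1 <- dense_forward(params$enc1, c_in$a, training)
  p1 <- cpp_maxpool2_forward(e1$out)
  e2 <- dense_forward(params$enc2, p1$out, training)
  p2 <- cpp_maxpool2_forward(e2$out)
  bt <- dense_forward(params$bott, p2$out, training)
  u2 <- cbr_forward(params$up2, bt$out, training, up = TRUE)
  d2 <- dense_forward(params$dec2, concat_c(list(u2$a, e2$out)), training)
  u1 <- cbr_forward(params$up1, d2$out, training, up = TRUE)
  d1 <- dense_forward(params$dec1, concat_c(list(u1$a, e1$out)), training)
  logits <- cpp_conv2d_forward(d1$out, params$out$W, params$out$b)
  prob <- unpad4(sigmoid(logits), pd$orig)
  if (!training) return(list(prob = prob))
  list(prob = prob,
       cache = list(x = x, c_in = c_in, e1 = e1, p1 = p1, e2 = e2, p2 = p2,
                    bt = bt, u2 = u2, d2 = d2, u1 = u1, d1 = d1,
                    orig = pd$orig))
}

# Backprop from d(loss)/d(logits) (already multiplied by sigmoid'); returns
# gradients in the same nested structure as the parameters.
net_backward <- function(params, cache, dlogits) {
  b <- params$base_filters
  dl <- dlogits
  d <- dim(cache$x)
  if (d[1] != dim(dl)[1] || d[2] != dim(dl)[2]) {  # re-pad to internal grid
    full <- array(0, c(d[1], d[2], 1L, d[4]))
    full[seq_len(dim(dl)[1]), seq_len(dim(dl)[2]), , ] <- dl
    dl <- full
  }
  bw_out <- cpp_conv2d_backward(cache$d1$out, params$out$W, dl)
  d1_bw <- dense_backward(params$dec1, cache$d1, bw_out$dx)
  parts <- split_c(d1_bw$dx, c(4L * b, 4L * b))
  de1_skip <- parts[[2]]
  u1_bw <- cbr_backward(params$up1, cache$d2$out, cache$u1$cache,
                        parts[[1]], up = TRUE)
  d2_bw <- dense_backward(params$dec2, cache$d2, u1_bw$dx)
  parts <- split_c(d2_bw$dx, c(8L * b, 8L * b))
  de2_skip <- parts[[2]]
  u2_bw <- cbr_backward(params$up2, cache$bt$out, cache$u2$cache,
                        parts[[1]], up = TRUE)
  bt_bw <- dense_backward(params$bott, cache$bt, u2_bw$dx)
  de2 <- cpp_maxpool2_backward(cache$p2$idx, bt_bw$dx, dim(cache$e2$out)) +
    de2_skip
  e2_bw <- dense_backward(params$enc2, cache$e2, de2)
  de1 <- cpp_maxpool2_backward(cache$p1$idx, e2_bw$dx, dim(cache$e1$out)) +
    de1_skip
  e1_bw <- dense_backward(params$enc1, cache$e1, de1)
  in_bw <- cbr_backward(params$conv_in, cache$x, cache$c_in$cache, e1_bw$dx)
  list(conv_in = in_bw$grad,
       enc1 = list(sub = e1_bw$sub),
       enc2 = list(sub = e2_bw$sub),
       bott = list(sub = bt_bw$sub),
       up2 = u2_bw$grad,
       dec2 = list(sub = d2_bw$sub),
       up1 = u1_bw$grad,
       dec1 = list(sub = d1_bw$sub),
       out = list(W = bw_out$dw, b = bw_out$db))
}

# Fold the batch statistics recorded in a training-mode forward cache into
# the running means/variances: r <- momentum r + (1 - momentum) batch.
update_running_stats <- function(params, cache) {
  upd <- function(p, cc) {
    p$rm <- BN_MOMENTUM * p$rm + (1 - BN_MOMENTUM) * cc$mean
    p$rv <- BN_MOMENTUM * p$rv + (1 - BN_MOMENTUM) * cc$var
    p
  }
  params$conv_in <- upd(params$conv_in, cache$c_in$cache)
  blocks <- c(enc1 = "e1", enc2 = "e2", bott = "bt", dec2 = "d2",
              dec1 = "d1")
  for (blk in names(blocks)) {
    for (k in 1:4)
      params[[blk]]$sub[[k]] <- upd(params[[blk]]$sub[[k]],
                                    cache[[blocks[[blk]]]]$caches[[k]])
  }
  params$up2 <- upd(params$up2, cache$u2$cache)
  params$up1 <- upd(params$up1, cache$u1$cache)
  params
}

#' Tversky loss parameters
#'
#' @param alpha False-positive penalty weight (default 0.3).
#' @param beta False-negative penalty weight (default 0.7). `beta > alpha`
#'   puts a higher penalty on missed lesion voxels, countering the extreme
#'   class imbalance of lesion segmentation.
#' @param epsilon Numerical smoothing term (default 1e-6).
#' @return A `wml_tversky` list.
#' @export
tversky_params <- function(alpha = 0.3, beta = 0.7, epsilon = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "wml_tversky")
}

#' Tversky loss
#'
#' `L = 1 - (sum(p*g) + eps) / (sum(p*g) + alpha*sum(p*(1-g)) +
#' beta*sum((1-p)*g) + eps)` where `p` is the predicted lesion probability and
#' `g` the reference label. At `alpha = beta = 0.5` this equals one minus the
#' soft Dice coefficient. The loss is bounded in `[0, 1]`.
#'
#' @param y_true Reference labels in `[0, 1]` (binary allowed).
#' @param y_pred Predicted probabilities in `[0, 1]`, same shape.
#' @param params A [tversky_params()].
#' @return Scalar loss.
#' @export
tversky_loss <- function(y_true, y_pred, params = tversky_params()) {
  if (!identical(dim(y_true) %||% length(y_true),
                 dim(y_pred) %||% length(y_pred)))
    stop_wml("tversky_loss: shape mismatch")
  if (any(y_true < 0 | y_true > 1) || any(y_pred < 0 | y_pred > 1))
    stop_wml("tversky_loss: values must lie in [0, 1]")
  g <- as.numeric(y_true)
  p <- as.numeric(y_pred)
  tp <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  1 - (tp + params$epsilon) /
    (tp + params$alpha * fp + params$beta * fn + params$epsilon)
}

#' Gradient of the Tversky loss
#'
#' Analytic `dL/dp` for [tversky_loss()], same shape as `y_pred`.
#'
#' @inheritParams tversky_loss
#' @return Array of partial derivatives.
#' @export
tversky_grad <- function(y_true, y_pred, params = tversky_params()) {
  g <- as.numeric(y_true)
  p <- as.numeric(y_pred)
  tp <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  num <- tp + params$epsilon
  den <- tp + params$alpha * fp + params$beta * fn + params$epsilon
  dden <- g + params$alpha * (1 - g) - params$beta * g
  out <- (num * dden - den * g) / den^2
  if (!is.null(dim(y_pred))) dim(out) <- dim(y_pred)
  out
}
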