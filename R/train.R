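# Training loop (RMSprop + early stopping), slice prediction and the
# cross-validation harness.

#' Training configuration
#'
#' @param learning_rate Initial learning rate (default 1e-3).
#' @param momentum Heavy-ball momentum of the RMSprop update (default 0.95).
#' @param rho Decay of the squared-gradient running average (default 0.9).
#' @param patience Epochs without validation-loss improvement before training
#'   stops (default 10).
#' @param max_epochs Hard epoch cap (default 100).
#' @param batch_size Slices per gradient step (default 8).
#' @param tversky [tversky_params()] used as training and early-stopping loss;
#'   the Dice coefficient is logged alongside.
#' @param seed RNG seed covering weight initialization and batch shuffling.
#' @return A `wml_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, momentum = 0.95, rho = 0.9,
                         patience = 10, max_epochs = 100, batch_size = 8,
                         tversky = tversky_params(), seed = 1) {
  stopifnot(learning_rate > 0, patience >= 1, max_epochs >= 1,
            batch_size >= 1)
  structure(list(optimizer = "rmsprop", learning_rate = learning_rate,
                 momentum = momentum, rho = rho, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), tversky = tversky,
                 seed = as.integer(seed)),
            class = "wml_train_config")
}

zeros_like <- function(p) {
  if (is.numeric(p)) {
    z <- p
    z[] <- 0
    return(z)
  }
  if (is.list(p)) return(lapply(p, zeros_like))
  p
}

# One RMSprop step over the nested parameter/gradient structure:
#   v <- rho v + (1 - rho) grad^2
#   m <- momentum m + grad / sqrt(v + 1e-8)
#   w <- w - lr clamp(m)
# The per-parameter update is clamped (|lr m| <= 10 lr) so that momentum
# cannot compound the normalized gradient into a step that saturates the
# sigmoid output and kills training.
rmsprop_step <- function(params, grads, state, cfg) {
  clip <- 10
  rec <- function(p, g, v, m) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, v = v, m = m))
      v <- cfg$rho * v + (1 - cfg$rho) * g * g
      m <- cfg$momentum * m + g / sqrt(v + 1e-8)
      return(list(p = p - cfg$learning_rate * pmin(pmax(m, -clip), clip),
                  v = v, m = m))
    }
    if (is.list(p)) {
      for (nm in seq_along(p)) {
        key <- if (!is.null(names(p))) names(p)[nm] else nm
        gk <- if (is.list(g)) g[[key]] else NULL
        if (is.null(gk) && !is.numeric(p[[nm]])) gk <- list()
        res <- rec(p[[nm]], gk, v[[nm]], m[[nm]])
        p[[nm]] <- res$p
        v[[nm]] <- res$v
        m[[nm]] <- res$m
      }
      return(list(p = p, v = v, m = m))
    }
    list(p = p, v = v, m = m)
  }
  res <- rec(params, grads, state$v, state$m)
  list(params = res$p, state = list(v = res$v, m = res$m))
}

slice_tversky <- function(prob, truth, tv) {
  # per-slice Tversky terms; prob/truth are (H, W, 1, N) and (H, W, 1, N)
  n <- dim(prob)[4]
  pm <- matrix(prob, ncol = n)
  gm <- matrix(truth, ncol = n)
  tp <- colSums(pm * gm)
  fp <- colSums(pm * (1 - gm))
  fn <- colSums((1 - pm) * gm)
  1 - (tp + tv$epsilon) / (tp + tv$alpha * fp + tv$beta * fn + tv$epsilon)
}

slice_tversky_grad <- function(prob, truth, tv) {
  d <- dim(prob)
  n <- d[4]
  pm <- matrix(prob, ncol = n)
  gm <- matrix(truth, ncol = n)
  tp <- colSums(pm * gm)
  fp <- colSums(pm * (1 - gm))
  fn <- colSums((1 - pm) * gm)
  num <- tp + tv$epsilon
  den <- tp + tv$alpha * fp + tv$beta * fn + tv$epsilon
  # dL/dp per slice, broadcast the per-slice scalars over voxels
  dden <- gm + tv$alpha * (1 - gm) - tv$beta * gm
  out <- sweep(dden, 2, num / den^2, `*`) - sweep(gm, 2, 1 / den, `*`)
  dim(out) <- d
  out
}

as_batch <- function(images, ids) {
  d <- dim(images)
  array(images[, , ids], dim = c(d[1], d[2], 1L, length(ids)))
}

#' Train one orientation model
#'
#' Trains the dense U-Net on paired 2D slices with the Tversky loss, RMSprop
#' and early stopping: training halts when the validation Tversky loss has not
#' improved for `patience` consecutive epochs (or at `max_epochs`), and the
#' parameters of the best validation epoch are returned. The log records
#' per-epoch training loss, validation loss and validation Dice.
#'
#' @param train,val Lists with `images` and `masks`, each an `(H, W, N)`
#'   array; masks are binary. Both sets must be nonempty.
#' @param net_cfg A [network_config()].
#' @param cfg A [train_config()].
#' @return A `wml_model` with `params`, `log` (data.frame), `best_epoch`,
#'   `net_cfg` and `train_cfg`.
#' @export
train_orientation_model <- function(train, val, net_cfg = network_config(),
                                    cfg = train_config()) {
  nt <- dim(train$images)[3] %||% 0
  nv <- dim(val$images)[3] %||% 0
  if (is.na(nt) || nt < 1 || is.na(nv) || nv < 1)
    stop_wml("empty training or validation slice set")
  tv <- cfg$tversky
  with_seed(cfg$seed, {
    params <- build_network(net_cfg, seed = sample.int(.Machine$integer.max, 1))
    state <- list(v = zeros_like(params), m = zeros_like(params))
    best_loss <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    log <- NULL
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nt)
      tr_losses <- numeric(0)
      for (start in seq(1, nt, by = cfg$batch_size)) {
        ids <- ord[start:min(start + cfg$batch_size - 1, nt)]
        x <- as_batch(train$images, ids)
        y <- as_batch(train$masks, ids)
        fw <- net_forward(params, x, training = TRUE)
        losses <- slice_tversky(fw$prob, y, tv)
        if (any(!is.finite(losses)))
          stop_wml("training diverged (non-finite loss) at epoch %d", epoch)
        tr_losses <- c(tr_losses, losses)
        dldp <- slice_tversky_grad(fw$prob, y, tv) / length(ids)
        dlogits <- dldp * fw$prob * (1 - fw$prob)
        grads <- net_backward(params, fw$cache, dlogits)
        upd <- rmsprop_step(params, grads, state, cfg)
        params <- update_running_stats(upd$params, fw$cache)
        state <- upd$state
      }
      ev <- evaluate_slices(params, val, tv, cfg$batch_size)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(tr_losses),
                                   val_loss = ev$loss, val_dice = ev$dice))
      if (ev$loss < best_loss - 1e-9) {
        best_loss <- ev$loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(list(params = best_params, log = log, best_epoch = best_epoch,
                   net_cfg = net_cfg, train_cfg = cfg),
              class = "wml_model")
  })
}

evaluate_slices <- function(params, val, tv, batch_size) {
  n <- dim(val$images)[3]
  losses <- numeric(0)
  tp2 <- s <- 0
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    x <- as_batch(val$images, ids)
    y <- as_batch(val$masks, ids)
    prob <- net_forward(params, x)$prob
    losses <- c(losses, slice_tversky(prob, y, tv))
    pb <- prob >= 0.5
    tp2 <- tp2 + 2 * sum(pb & (y > 0))
    s <- s + sum(pb) + sum(y > 0)
  }
  list(loss = mean(losses), dice = if (s == 0) 1 else tp2 / s)
}

#' @export
print.wml_model <- function(x, ...) {
  cat(sprintf(
    "<wml_model> base_filters=%d, %d epochs trained, best epoch %d (val loss %.4f, val Dice %.4f)\n",
    x$net_cfg$base_filters, nrow(x$log), x$best_epoch,
    x$log$val_loss[x$best_epoch], x$log$val_dice[x$best_epoch]))
  invisible(x)
}

#' Predict probability maps for a stack of slices
#'
#' @param model A trained `wml_model`.
#' @param images `(H, W, N)` array of slices.
#' @param batch_size Slices per forward pass.
#' @return `(H, W, N)` array of per-pixel lesion probabilities.
#' @export
predict_slices <- function(model, images, batch_size = 8) {
  d <- dim(images)
  out <- array(0, d)
  for (start in seq(1, d[3], by = batch_size)) {
    ids <- start:min(start + batch_size - 1, d[3])
    prob <- net_forward(model$params, as_batch(images, ids))$prob
    out[, , ids] <- prob[, , 1, ]
  }
  out
}

#' Cross-validation splits
#'
#' Repeated random splits: each of `n_repeats` splits independently holds out
#' `val_fraction` of the subjects for validation. Deterministic per seed.
#'
#' @param subject_ids Character or integer subject identifiers (at least 5).
#' @param n_repeats Number of splits (default 10).
#' @param val_fraction Held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @return List of `wml_fold` lists with `repeat_index`, `train_ids`,
#'   `val_ids`.
#' @export
make_cv_splits <- function(subject_ids, n_repeats = 10, val_fraction = 0.2,
                           seed = 1) {
  n <- length(subject_ids)
  if (n < 5) stop_wml("need at least 5 subjects, got %d", n)
  n_val <- round(val_fraction * n)
  if (n_val < 1) stop_wml("val_fraction %.2f leaves an empty validation set",
                          val_fraction)
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      val <- sort(sample.int(n, n_val))
      structure(list(repeat_index = r,
                     train_ids = subject_ids[-val],
                     val_ids = subject_ids[val]),
                class = "wml_fold")
    })
  })
}

array_to_json <- function(a) list(dim = dim(a) %||% length(a),
                                  data = as.numeric(a))

json_to_array <- function(x) {
  a <- as.numeric(unlist(x$data))
  dims <- as.integer(unlist(x$dim))
  if (length(dims) > 1) dim(a) <- dims
  a
}

#' Save / load a trained model
#'
#' Parameters and configuration are serialized as JSON (text checkpoint).
#'
#' @param model A `wml_model`.
#' @param path Output `.json` path.
#' @return `read_model` returns the restored `wml_model`.
#' @export
write_model <- function(model, path) {
  enc <- function(p) {
    if (is.numeric(p)) return(array_to_json(p))
    if (is.list(p)) return(lapply(p, enc))
    p
  }
  unclass_deep <- function(x) {
    x <- unclass(x)
    if (is.list(x)) x <- lapply(x, unclass_deep)
    x
  }
  obj <- list(params = enc(model$params), log = model$log,
              best_epoch = model$best_epoch,
              net_cfg = unclass_deep(model$net_cfg),
              train_cfg = unclass_deep(model$train_cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.list(obj$log))
    obj$log <- do.call(rbind.data.frame, obj$log)
  dec <- function(p) {
    if (is.list(p) && !is.null(p$data) && !is.null(p$dim))
      return(json_to_array(p))
    if (is.list(p)) return(lapply(p, dec))
    p
  }
  params <- dec(obj$params)
  params$base_filters <- as.integer(obj$net_cfg$base_filters)
  class(params) <- "wml_net_params"
  structure(list(params = params, log = obj$log,
                 best_epoch = obj$best_epoch,
                 net_cfg = structure(obj$net_cfg, class = "wml_net_config"),
                 train_cfg = structure(obj$train_cfg,
                                       class = "wml_train_config")),
            class = "wml_model")
}
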