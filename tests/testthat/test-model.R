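# Dense U-Net, Tversky loss, training loop, CV splits.

test_that("tversky loss matches its closed-form corner cases", {
  tv <- tversky_params()
  g <- array(0, c(6, 6)); g[2:4, 2:4] <- 1
  expect_lt(tversky_loss(g, g, tv), 1e-6)          # perfect prediction
  inv <- 1 - g
  fp <- sum(inv * (1 - g)); fn <- sum((1 - inv) * g)
  expect_equal(tversky_loss(g, inv, tv),
               1 - tv$epsilon / (tv$alpha * fp + tv$beta * fn + tv$epsilon),
               tolerance = 1e-12)                  # zero intersection
  expect_error(tversky_loss(g, array(0, c(3, 3))), "shape")
  expect_error(tversky_loss(g, g * 2), "\\[0, 1\\]")
})

test_that("tversky at alpha = beta = 0.5 equals soft Dice", {
  set.seed(21)
  tv <- tversky_params(alpha = 0.5, beta = 0.5)
  for (i in 1:100) {
    g <- matrix(runif(64), 8)
    p <- matrix(runif(64), 8)
    expect_lt(abs(tversky_loss(g, p, tv) - oracle_soft_dice(g, p)), 1e-6)
  }
})

test_that("tversky loss is bounded and monotone in beta when FN > 0", {
  set.seed(22)
  for (i in 1:20) {
    g <- matrix(rbinom(64, 1, 0.3), 8)
    p <- matrix(runif(64), 8)
    l <- tversky_loss(g, p)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  g <- matrix(rbinom(64, 1, 0.4), 8)
  p <- matrix(runif(64, 0, 0.9), 8)  # FN > 0 guaranteed
  betas <- c(0.1, 0.4, 0.7, 1.0)
  losses <- vapply(betas, function(b)
    tversky_loss(g, p, tversky_params(alpha = 0.3, beta = b)), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("analytic tversky gradient matches finite differences", {
  set.seed(23)
  g <- matrix(rbinom(16, 1, 0.4), 4)
  p <- matrix(runif(16, 0.05, 0.95), 4)
  gr <- tversky_grad(g, p)
  eps <- 1e-6
  for (i in seq_len(16)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (tversky_loss(g, p1) - tversky_loss(g, p2)) / (2 * eps)
    expect_lt(abs(gr[i] - num) / max(abs(num), 1e-8), 1e-4)
  }
})

test_that("dense blocks follow the concatenation channel arithmetic", {
  for (b in c(2L, 8L)) {
    params <- build_network(network_config(base_filters = b), seed = 1)
    plan <- list(enc1 = c(b, b), enc2 = c(4 * b, 2 * b),
                 bott = c(8 * b, 4 * b), dec2 = c(16 * b, 2 * b),
                 dec1 = c(8 * b, b))
    for (blk in names(plan)) {
      cin <- plan[[blk]][1]; g <- plan[[blk]][2]
      for (k in 1:4) {
        wd <- dim(params[[blk]]$sub[[k]]$W)
        expect_equal(wd, c(3L, 3L, cin + (k - 1L) * g, g))
      }
    }
    # block output = concatenation of the four sub-block outputs (4g channels)
    x <- array(rnorm(8 * 8 * b), c(8, 8, b, 1))
    blk_out <- wmlseg:::dense_forward(params$enc1, x, training = TRUE)$out
    expect_equal(dim(blk_out)[3], 4L * b)
  }
})

test_that("network build is deterministic and forward obeys the contract", {
  p1 <- build_network(network_config(base_filters = 4), seed = 9)
  p2 <- build_network(network_config(base_filters = 4), seed = 9)
  expect_identical(p1, p2)
  x <- array(0, c(16, 16, 1, 2))
  prob <- wmlseg:::net_forward(p1, x)$prob
  expect_equal(dim(prob), c(16L, 16L, 1L, 2L))
  expect_true(all(prob > 0 & prob < 1))
  # odd shapes are padded internally and cropped back
  x2 <- array(rnorm(10 * 14 * 1 * 1), c(10, 14, 1, 1))
  expect_equal(dim(wmlseg:::net_forward(p1, x2)$prob), c(10L, 14L, 1L, 1L))
})

test_that("network backprop matches finite differences through all blocks", {
  set.seed(2)
  tv <- tversky_params()
  params <- build_network(network_config(base_filters = 2), seed = 3)
  xs <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  ys <- array(rbinom(8 * 8 * 2, 1, 0.2), c(8, 8, 1, 2))
  fw <- wmlseg:::net_forward(params, xs, training = TRUE)
  dlog <- wmlseg:::slice_tversky_grad(fw$prob, ys, tv) / 2 *
    fw$prob * (1 - fw$prob)
  gr <- wmlseg:::net_backward(params, fw$cache, dlog)
  lossfun <- function(pp) {
    f <- wmlseg:::net_forward(pp, xs, training = TRUE)
    mean(wmlseg:::slice_tversky(f$prob, ys, tv))
  }
  eps <- 1e-6
  paths <- list(list("conv_in", "W"), list("conv_in", "gamma"),
                list("enc1", "sub", 2, "W"), list("enc2", "sub", 4, "beta"),
                list("bott", "sub", 1, "W"), list("up2", "W"),
                list("dec2", "sub", 3, "W"), list("up1", "gamma"),
                list("dec1", "sub", 1, "W"), list("out", "W"),
                list("out", "b"))
  getp <- function(l, path) { for (k in path) l <- l[[k]]; l }
  setp <- function(l, path, i, v) {
    if (length(path) == 1) { l[[path[[1]]]][i] <- v; return(l) }
    l[[path[[1]]]] <- setp(l[[path[[1]]]], path[-1], i, v)
    l
  }
  for (path in paths) {
    ga <- getp(gr, path)
    pv <- getp(params, path)
    i <- which.max(abs(ga))
    num <- (lossfun(setp(params, path, i, pv[i] + eps)) -
            lossfun(setp(params, path, i, pv[i] - eps))) / (2 * eps)
    expect_lt(abs(ga[i] - num) / max(abs(num), 1e-10), 1e-4)
  }
})

test_that("training learns, stops early, and is reproducible", {
  ds <- generate_blob_dataset_2d(seed = 31, n_images = 40, image_size = 32)
  tr <- list(images = ds$images[, , 1:30], masks = ds$masks[, , 1:30])
  va <- list(images = ds$images[, , 31:40], masks = ds$masks[, , 31:40])
  cfg <- train_config(max_epochs = 4, patience = 1, seed = 5)
  m1 <- train_orientation_model(tr, va, network_config(base_filters = 2), cfg)
  m2 <- train_orientation_model(tr, va, network_config(base_filters = 2), cfg)
  expect_identical(m1$log, m2$log)                 # seed determinism
  expect_lt(m1$log$train_loss[nrow(m1$log)], m1$log$train_loss[1])
  # early-stopping contract: with patience 1, training ends exactly one
  # epoch after the best validation epoch (unless max_epochs hit first)
  if (nrow(m1$log) < cfg$max_epochs)
    expect_equal(nrow(m1$log), m1$best_epoch + 1)
  expect_equal(which.min(m1$log$val_loss), m1$best_epoch)
  expect_error(train_orientation_model(list(images = array(0, c(8, 8, 0)),
                                            masks = array(0, c(8, 8, 0))),
                                       va, network_config(2)), "empty")
})

test_that("saved models restore to identical predictions", {
  dir <- withr::local_tempdir()
  ds <- generate_blob_dataset_2d(seed = 32, n_images = 12, image_size = 32)
  tr <- list(images = ds$images[, , 1:8], masks = ds$masks[, , 1:8])
  va <- list(images = ds$images[, , 9:12], masks = ds$masks[, , 9:12])
  m <- train_orientation_model(tr, va, network_config(base_filters = 2),
                               train_config(max_epochs = 1, seed = 5))
  f <- file.path(dir, "model.json")
  write_model(m, f)
  m2 <- read_model(f)
  p1 <- predict_slices(m, va$images)
  p2 <- predict_slices(m2, va$images)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("cross-validation splits hold out 20% reproducibly", {
  ids <- sprintf("subj%02d", 1:10)
  s1 <- make_cv_splits(ids, n_repeats = 10, seed = 42)
  s2 <- make_cv_splits(ids, n_repeats = 10, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  for (sp in s1) {
    expect_length(sp$val_ids, 2)
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids), ids)
  }
  expect_error(make_cv_splits(letters[1:4]), "at least 5")
  expect_error(make_cv_splits(letters[1:6], val_fraction = 0.01), "empty")
})
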