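# Voxel- and object-level metrics against hand counts and brute-force oracles.

test_that("dice matches hand-counted examples and conventions", {
  d <- c(6, 6, 6)
  a <- array(0L, d); a[1:2, 1, 1] <- 1L
  expect_equal(dice(a, a), 1)
  b <- array(0L, d); b[1, 2:3, 2] <- 1L
  expect_equal(dice(a, b), 0)
  # ref 2 voxels, pred those 2 plus 2 extra -> 2*2/(2+4)
  p <- a; p[4:5, 4, 4] <- 1L
  expect_equal(dice(a, p), 2 * 2 / (2 + 4))
  empty <- array(0L, d)
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, array(0L, c(5, 5, 5))), "grid")
})

test_that("ppv matches hand counts with documented sentinels", {
  d <- c(6, 6, 6)
  ref <- array(0L, d); ref[1:3, 1, 1] <- 1L
  sub <- array(0L, d); sub[1:2, 1, 1] <- 1L
  expect_equal(ppv(ref, sub), 1)                   # pred subset of ref
  dis <- array(0L, d); dis[5, 5, 5] <- 1L
  expect_equal(ppv(ref, dis), 0)
  p <- array(0L, d); p[1:3, 1, 1] <- 1L; p[6, 6, 6] <- 1L  # TP=3, FP=1
  expect_equal(ppv(ref, p), 0.75)
  empty <- array(0L, d)
  expect_equal(ppv(empty, empty), 1)
  expect_true(is.nan(ppv(ref, empty)))
})

test_that("object dice matches the two-sum enumeration", {
  d <- c(10, 10, 10)
  m <- array(0L, d); m[2:3, 2:3, 2] <- 1L; m[7:8, 7:8, 7] <- 1L
  expect_equal(object_dice(m, m), 1)
  # one of two equal-size objects perfectly found, none spurious:
  # 0.5*(0.5*1 + 0.5*0) + 0.5*(1*1) = 0.75
  half <- array(0L, d); half[2:3, 2:3, 2] <- 1L
  expect_equal(object_dice(m, half), 0.75)
  expect_equal(object_dice(m, array(0L, d)), 0)
  expect_equal(object_dice(array(0L, d), array(0L, d)), 1)
})

test_that("object rates count detected and spurious components", {
  d <- c(12, 12, 12)
  ref <- array(0L, d)
  ref[2, 2, 2] <- 1L; ref[6, 6, 6] <- 1L; ref[10, 10, 10] <- 1L
  same <- object_rates(ref, ref)
  expect_equal(same$otpr, 1); expect_equal(same$ofpr, 0)
  # miss all three, add two spurious
  sp <- array(0L, d); sp[4, 8, 2] <- 1L; sp[8, 4, 10] <- 1L
  r <- object_rates(ref, sp)
  expect_equal(r$otpr, 0); expect_equal(r$ofpr, 1)
  # 2 ref objects, 1 detected; 4 pred objects, 3 spurious -> (0.5, 0.75)
  ref2 <- array(0L, d); ref2[2, 2, 2] <- 1L; ref2[10, 10, 10] <- 1L
  pred <- array(0L, d)
  pred[2, 2, 2] <- 1L; pred[5, 5, 5] <- 1L; pred[8, 2, 8] <- 1L
  pred[2, 10, 4] <- 1L
  r2 <- object_rates(ref2, pred)
  expect_equal(r2$otpr, 0.5); expect_equal(r2$ofpr, 0.75)
  er <- object_rates(array(0L, d), pred)
  expect_true(is.nan(er$otpr))
})

test_that("assd matches analytic distances and is symmetric", {
  d <- c(9, 9, 9)
  a <- array(0L, d); a[2, 5, 5] <- 1L
  expect_equal(assd(a, a), 0)
  b <- array(0L, d); b[5, 5, 5] <- 1L  # 3 voxels along one axis
  expect_equal(assd(a, b), 3)
  set.seed(61)
  x <- rand_mask(d, 0.2); y <- rand_mask(d, 0.2)
  expect_equal(assd(x, y), assd(y, x))
  # anisotropic spacing scales distances
  expect_equal(assd(a, b, spacing = c(2, 1, 1)), 6)
  expect_error(assd(a, array(0L, d)), "empty")
})

test_that("all metrics agree with the brute-force oracle on random masks", {
  set.seed(62)
  for (i in 1:50) {
    r <- rand_mask(c(8, 8, 8), runif(1, 0.05, 0.4))
    p <- rand_mask(c(8, 8, 8), runif(1, 0.05, 0.4))
    expect_equal(dice(r, p), oracle_dice(r, p))
    expect_equal(ppv(r, p), oracle_ppv(r, p))
    expect_equal(object_dice(r, p), oracle_object_dice(r, p))
    rt <- object_rates(r, p); ot <- oracle_object_rates(r, p)
    expect_equal(rt$otpr, ot$otpr)
    expect_equal(rt$ofpr, ot$ofpr)
    if (sum(r) > 0 && sum(p) > 0)
      expect_equal(assd(r, p), oracle_assd(r, p), tolerance = 1e-12)
  }
})

test_that("evaluate bundles all metrics with degenerate-case sentinels", {
  ph <- generate_phantom(phantom_spec(seed = 13))
  truth <- ph$lesion_truth$data
  rep0 <- evaluate(truth, truth)
  expect_equal(rep0$dice, 1); expect_equal(rep0$dice_obj, 1)
  expect_equal(rep0$ppv, 1); expect_equal(rep0$otpr, 1)
  expect_equal(rep0$ofpr, 0); expect_equal(rep0$assd_mm, 0)
  expect_equal(rep0$n_ref_objects, rep0$n_pred_objects)
  # corrupted prediction: all fields consistent with the single metrics
  set.seed(63)
  pred <- truth
  near <- wmlseg:::dilate_mask(truth, wmlseg:::sphere_offsets(1.5))
  flip <- sample(which(near == 1), 40)
  pred[flip] <- 1L - pred[flip]
  rep1 <- evaluate(truth, pred)
  expect_equal(rep1$dice, dice(truth, pred))
  expect_equal(rep1$dice_obj, object_dice(truth, pred))
  expect_equal(rep1$assd_mm, assd(truth, pred))
  expect_equal(rep1$dice_obj_by_size[["small"]] >= 0, TRUE)
  # empty vs empty
  e <- array(0L, c(6, 6, 6))
  rep2 <- evaluate(e, e)
  expect_equal(rep2$dice, 1)
  expect_true(is.nan(rep2$assd_mm))
  expect_equal(rep2$n_ref_objects, 0)
})

test_that("removing a true-positive voxel never increases dice", {
  set.seed(64)
  r <- rand_mask(c(8, 8, 8), 0.3)
  p <- r
  tp <- which(r == 1 & p == 1)
  for (v in sample(tp, 5)) {
    p2 <- p; p2[v] <- 0L
    expect_lte(dice(r, p2), dice(r, p))
  }
})
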