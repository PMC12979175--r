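# Anatomical bands, lesion classification, confluent counting, size bins.

test_that("PV bands are the dilated shell around the binarized map", {
  d <- c(15, 15, 15)
  empty <- array(0, d)
  expect_equal(sum(periventricular_band(empty)), 0)
  # single CSF voxel: band is the 7-wide sphere minus its center
  single <- array(0, d); single[8, 8, 8] <- 1
  band <- periventricular_band(single)
  offs <- expand.grid(-3:3, -3:3, -3:3)
  n_sphere <- sum(rowSums(offs^2) <= 9)  # enumerate the spherical element
  expect_equal(sum(band), n_sphere - 1)
  expect_equal(band[8, 8, 8], 0L)
  # band never overlaps the binarized source
  set.seed(51)
  pv <- array(runif(prod(d)), d)
  b2 <- periventricular_band(pv)
  expect_equal(sum(b2 == 1 & pv > 0.5), 0)
  # juxtacortical band uses the identical construction
  expect_equal(juxtacortical_band(single), band)
})

test_that("lesions are classified by overlap with priority resolution", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  ctx <- anatomy_context(ph$csf_pv, ph$gm_pv, ph$infratentorial_mask)
  out <- classify_lesions(ph$lesion_truth, ctx, ph$flair)
  expect_equal(nrow(out), nrow(ph$lesion_table))
  merged <- merge(out, ph$lesion_table[, c("component_id", "class")],
                  by = "component_id")
  expect_equal(merged$location, merged$class)
  expect_true(all(out$n_sublesions >= 1))
  expect_equal(out$volume_ml, out$voxel_count / 1000)
  # empty lesion mask -> empty table
  none <- classify_lesions(new_volume(array(0, dim(ph$flair$data))), ctx,
                           ph$flair)
  expect_equal(nrow(none), 0)
})

test_that("infratentorial wins over periventricular when both overlap", {
  d <- c(20, 20, 20)
  csf <- array(0, d); csf[9:11, 9:11, 9:11] <- 1
  infra <- array(0L, d); infra[14:16, 9:11, 9:11] <- 1L
  gm <- array(0, d)
  lesion <- array(0L, d); lesion[12:14, 9:11, 9:11] <- 1L  # touches both
  ctx <- anatomy_context(csf, gm, infra)
  flair <- new_volume(array(1, d))
  out <- classify_lesions(lesion, ctx, flair)
  expect_equal(out$location, "infratentorial")
})

test_that("local maxima counting separates confluent lesions", {
  d <- c(24, 24, 24)
  coords <- lapply(1:3, function(a) seq_len(d[a]))
  gauss3 <- function(ctr, sd) {
    gx <- exp(-(coords[[1]] - ctr[1])^2 / (2 * sd^2))
    gy <- exp(-(coords[[2]] - ctr[2])^2 / (2 * sd^2))
    gz <- exp(-(coords[[3]] - ctr[3])^2 / (2 * sd^2))
    outer(outer(gx, gy), gz)
  }
  sphere <- function(ctr, r) {
    g <- expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]])
    arr <- array(0L, d)
    arr[as.matrix(g[(g$x - ctr[1])^2 + (g$y - ctr[2])^2 +
                      (g$z - ctr[3])^2 <= r^2, ])] <- 1L
    arr
  }
  # unimodal: a single bright sphere counts once
  m1 <- sphere(c(12, 12, 12), 4)
  f1 <- new_volume(50 * gauss3(c(12, 12, 12), 4))
  expect_equal(count_local_maxima(m1, f1), 1)
  # dumbbell: two bumps 10 voxels apart joined into one component count twice
  c1 <- c(7, 12, 12); c2 <- c(17, 12, 12)
  m2 <- pmax(sphere(c1, 4), sphere(c2, 4))
  m2[7:17, 11:13, 11:13] <- 1L  # bridge
  f2 <- new_volume(50 * (gauss3(c1, 3) + gauss3(c2, 3)))
  expect_equal(connected_components_26(m2)$n_components, 1)
  expect_equal(count_local_maxima(m2, f2), 2)
  # flat plateau: no strict maximum, floor at 1
  f3 <- new_volume(array(5, d))
  expect_equal(count_local_maxima(m1, f3), 1)
  expect_error(count_local_maxima(array(0L, d), f1), "empty")
})

test_that("size stratification uses the 5/15 ml bins", {
  obj <- data.frame(component_id = 1:4, voxel_count = c(4900, 5000, 15000,
                                                        15100),
                    volume_ml = c(4.9, 5.0, 15.0, 15.1),
                    location = "deep-WM", n_sublesions = 1)
  out <- size_stratify(obj)
  expect_equal(unname(out$counts), c(1L, 2L, 1L))
  expect_equal(out$objects$small$volume_ml, 4.9)
  expect_equal(out$objects$medium$volume_ml, c(5.0, 15.0))
  expect_equal(out$objects$large$volume_ml, 15.1)
  expect_equal(sum(out$counts), nrow(obj))
  empty <- size_stratify(obj[0, ])
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
})
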