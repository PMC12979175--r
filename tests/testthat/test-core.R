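# Volume container, NIfTI I/O, grid conformance, connected components.

test_that("NIfTI write/read round-trips data, spacing and affine", {
  dir <- withr::local_tempdir()
  set.seed(10)
  # binary mask: bit-exact round trip
  m <- array(as.numeric(rand_mask(c(8, 8, 8))), c(8, 8, 8))
  v <- new_volume(m)
  f <- file.path(dir, "mask.nii.gz")
  write_nifti(v, f, datatype = "uint8")
  back <- read_nifti(f)
  expect_identical(back$data, m)
  # probability map: float tolerance
  p <- array(runif(4 * 4 * 4), c(4, 4, 4))
  f2 <- file.path(dir, "prob.nii.gz")
  write_nifti(new_volume(p), f2)
  expect_lt(max(abs(read_nifti(f2)$data - p)), 1e-6)
  # header passthrough: spacing and a non-identity affine
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-5, 3, 7)
  v3 <- new_volume(p, spacing = c(2, 2, 2), affine = aff)
  f3 <- file.path(dir, "aff.nii.gz")
  write_nifti(v3, f3)
  b3 <- read_nifti(f3)
  expect_equal(b3$spacing, c(2, 2, 2))
  expect_equal(b3$affine[1:3, 4], c(-5, 3, 7), tolerance = 1e-6)
})

test_that("reading reorients flipped axes to canonical RAS", {
  dir <- withr::local_tempdir()
  a <- array(seq_len(2 * 3 * 4), c(2, 3, 4))
  img <- RNifti::asNifti(a)
  aff <- diag(c(-1, 1, 1, 1)); aff[1, 4] <- 1  # left-right flipped (LAS)
  RNifti::qform(img) <- structure(aff, code = 2L)
  f <- file.path(dir, "flip.nii")
  RNifti::writeNifti(img, f)
  v <- read_nifti(f)
  expect_equal(v$data, a[2:1, , ])  # manually flipped oracle
})

test_that("read_nifti raises distinct errors for bad inputs", {
  expect_error(read_nifti("/nonexistent/file.nii"), "does not exist")
  dir <- withr::local_tempdir()
  f4 <- file.path(dir, "4d.nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), f4)
  expect_error(read_nifti(f4), "3D")
})

test_that("conform resamples to 1 mm, crops/pads to shape, and is idempotent", {
  # already conformed input returned unchanged
  a <- array(rnorm(16 * 24 * 20), c(16, 24, 20))
  v <- new_volume(a)
  out <- conform(v, shape = c(16, 24, 20))
  expect_identical(out$data, a)
  # idempotence on a resampled input
  v2 <- new_volume(array(rnorm(10 * 12 * 8), c(10, 12, 8)),
                   spacing = c(2, 2, 2))
  c1 <- conform(v2, shape = c(20, 24, 16))
  c2 <- conform(c1, shape = c(20, 24, 16))
  expect_identical(c1$data, c2$data)
  expect_equal(c1$spacing, c(1, 1, 1))
  # 2 mm piecewise-constant volume: region values preserved after upsampling
  pc <- array(1, c(10, 10, 10)); pc[1:5, , ] <- 4
  cc <- conform(new_volume(pc, spacing = c(2, 2, 2)), shape = c(20, 20, 20))
  expect_equal(dim(cc$data), c(20, 20, 20))
  expect_equal(cc$data[3, 10, 10], 4)   # deep inside each constant region
  expect_equal(cc$data[18, 10, 10], 1)
  # center crop: marker at the input center stays at the output center
  big <- array(0, c(25, 31, 29))
  ctr_in <- floor(dim(big) / 2) + 1
  big[ctr_in[1], ctr_in[2], ctr_in[3]] <- 9
  cr <- conform(new_volume(big), shape = c(15, 17, 13))
  ctr_out <- floor(c(15, 17, 13) / 2) + 1
  expect_equal(cr$data[ctr_out[1], ctr_out[2], ctr_out[3]], 9)
  expect_equal(sum(cr$data), 9)
  # zero padding on small inputs
  sm <- conform(new_volume(array(1, c(4, 4, 4))), shape = c(8, 8, 8))
  expect_equal(sum(sm$data), 64)
  expect_equal(sm$data[1, 1, 1], 0)
  expect_error(conform(new_volume(array(0, c(0, 4, 4)))), "degenerate|length 0")
})

test_that("masks are conformed with nearest neighbor and stay binary", {
  m <- rand_mask(c(9, 9, 9), 0.3)
  out <- conform(new_volume(m, spacing = c(2, 2, 2)), shape = c(18, 18, 18))
  expect_true(all(out$data %in% c(0, 1)))
})

test_that("26-connectivity merges corner contacts and splits gaps", {
  empty <- array(0L, c(4, 4, 4))
  expect_equal(connected_components_26(empty)$n_components, 0)
  # two voxels touching only at a corner: one component
  corner <- array(0L, c(4, 4, 4))
  corner[1, 1, 1] <- 1L; corner[2, 2, 2] <- 1L
  expect_equal(connected_components_26(corner)$n_components, 1)
  # one-voxel gap along an axis: two components
  gap <- array(0L, c(5, 1, 1))
  gap[1, 1, 1] <- 1L; gap[3, 1, 1] <- 1L
  cc <- connected_components_26(gap)
  expect_equal(cc$n_components, 2)
  expect_equal(cc$labels[1, 1, 1], 1L)  # scan-order labeling
  expect_equal(cc$labels[3, 1, 1], 2L)
  expect_error(connected_components_26(array(2, c(2, 2, 2))), "binary")
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(77)
  for (rep in 1:100) {
    m <- rand_mask(c(6, 6, 6), runif(1, 0.1, 0.5))
    got <- connected_components_26(m)
    want <- oracle_label_26(m)
    expect_equal(got$n_components, max(want))
    # identical partitions up to relabeling: label pairs must be bijective
    fg <- m > 0
    expect_equal(as.numeric(tapply(want[fg], got$labels[fg],
                                   function(v) length(unique(v)))),
                 rep(1, got$n_components))
    expect_equal(as.numeric(tapply(got$labels[fg], want[fg],
                                   function(v) length(unique(v)))),
                 rep(1, max(want)))
  }
})
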