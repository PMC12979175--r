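# Tri-planar slicing, reconstruction, majority voting, CSF post-processing.

test_that("extract/reconstruct is the identity for all orientations", {
  set.seed(41)
  v <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  for (o in c("axial", "coronal", "sagittal")) {
    st <- extract_slices(v, o)
    expect_identical(reconstruct(st), v)
  }
  expect_error(extract_slices(v, "oblique"), "orientation")
})

test_that("slice geometry matches the canonical shapes", {
  v <- array(0, c(160, 256, 176))
  ax <- extract_slices(v, "axial")
  expect_equal(dim(ax$slices), c(160L, 256L, 176L))
  co <- extract_slices(v, "coronal")
  expect_equal(dim(co$slices), c(160L, 176L, 256L))
  sa <- extract_slices(v, "sagittal")
  expect_equal(dim(sa$slices), c(256L, 176L, 160L))
})

test_that("a marked voxel lands on exactly one slice at the right index", {
  v <- array(0, c(8, 10, 12))
  v[3, 5, 9] <- 1
  idx <- c(axial = 9, coronal = 5, sagittal = 3)
  for (o in names(idx)) {
    st <- extract_slices(v, o)
    hits <- which(apply(st$slices, 3, sum) > 0)
    expect_equal(hits, unname(idx[o]))
  }
})

test_that("reconstruct validates shape and preserves constants", {
  st <- extract_slices(array(0.5, c(6, 6, 6)), "coronal")
  expect_equal(reconstruct(st), array(0.5, c(6, 6, 6)))
  st$slices <- st$slices[, , 1:3]
  expect_error(reconstruct(st), "shape")
})

test_that("majority vote implements the 2-of-3 rule", {
  d <- c(4, 4, 4)
  one <- array(1, d); zero <- array(0, d)
  expect_equal(sum(majority_vote(list(one, one, zero))), prod(d))
  expect_equal(sum(majority_vote(list(one, zero, zero))), 0)
  # unanimity equals the thresholded map
  set.seed(42)
  p <- array(runif(prod(d)), d)
  expect_equal(majority_vote(list(p, p, p)), array(as.integer(p >= 0.5), d))
  # random maps vs an explicit per-voxel vote oracle; order invariance
  maps <- lapply(1:3, function(i) array(runif(prod(d)), d))
  got <- majority_vote(maps)
  votes <- (maps[[1]] >= 0.5) + (maps[[2]] >= 0.5) + (maps[[3]] >= 0.5)
  expect_equal(got, array(as.integer(votes >= 2), d))
  expect_equal(majority_vote(maps[c(3, 1, 2)]), got)
  expect_error(majority_vote(maps[1:2]), "3 maps")
})

test_that("csf postprocessing removes CSF-interior voxels and nothing else", {
  d <- c(6, 6, 6)
  set.seed(43)
  les <- rand_mask(d, 0.3)
  zero_csf <- array(0, d)
  expect_equal(csf_postprocess(les, zero_csf), les)
  full_csf <- array(1, d)
  expect_equal(sum(csf_postprocess(les, full_csf)), 0)
  csf <- array(runif(prod(d)), d)
  out <- csf_postprocess(les, csf)
  expect_true(all(out <= les))                    # never adds voxels
  expect_equal(out, array(as.integer(les > 0 & csf <= 0.5), d))
})

test_that("segment_volume composes prediction, voting and postprocessing", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  truth <- ph$lesion_truth$data
  truth_model <- function(slices) slices  # probabilities = slice content
  models <- list(axial = truth_model, coronal = truth_model,
                 sagittal = truth_model)
  # feeding the truth through three identity models returns the truth
  seg <- segment_volume(new_volume(truth), models)
  expect_equal(seg$data, truth)
  # 2-of-3: one all-zero model does not change the outcome
  models$coronal <- function(slices) array(0, dim(slices))
  seg2 <- segment_volume(new_volume(truth), models)
  expect_equal(seg2$data, truth)
  # a prediction polluted with the CSF distractor is cleaned by csf_pv
  polluted <- pmax(truth, ph$bright_distractor_mask$data)
  modelsP <- list(axial = function(s) s, coronal = function(s) s,
                  sagittal = function(s) s)
  seg3 <- segment_volume(new_volume(polluted), modelsP, csf_pv = ph$csf_pv)
  expect_equal(sum(seg3$data * ph$bright_distractor_mask$data), 0)
  expect_true(all(seg3$data[truth > 0] == 1))
  expect_error(segment_volume(new_volume(truth), models[1:2]), "axial")
})
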