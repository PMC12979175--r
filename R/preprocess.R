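# Histogram-landmark intensity standardization (Nyul-style) and brain-mask
# application.
#
# MR intensities have no absolute scale: the same tissue maps to different
# gray values across subjects and scanners. The landmark method learns, from
# training volumes, the mean position of a set of histogram percentiles on a
# fixed standard scale, and maps each new volume piecewise-linearly so its own
# percentiles land on those standard landmarks. The mapping is invariant to
# positive affine changes of the input intensities.

DEFAULT_LANDMARKS <- c(1, seq(10, 90, by = 10), 99)

#' Fit an intensity standardization model
#'
#' For each training volume, landmark percentiles of the within-brain
#' intensity histogram are computed and mapped affinely so that p1 lands on
#' `scale_range[1]` and p99 on `scale_range[2]`; the standard-scale landmarks
#' are the across-volume means of these mapped landmarks.
#'
#' @param volumes List of `wml_volume`s (or arrays).
#' @param brain_masks List of binary masks, one per volume; each nonempty.
#' @param percentiles Landmark percentiles, strictly increasing in (0, 100).
#'   Default: p1, deciles, p99.
#' @param scale_range Output scale, default `c(0, 100)`.
#' @return A `wml_standardizer` with the learned standard-scale landmarks.
#' @export
fit_standardizer <- function(volumes, brain_masks,
                             percentiles = DEFAULT_LANDMARKS,
                             scale_range = c(0, 100)) {
  if (length(volumes) < 1) stop_wml("need at least one volume")
  if (length(volumes) != length(brain_masks))
    stop_wml("volumes and brain_masks differ in length")
  percentiles <- as.numeric(percentiles)
  if (is.unsorted(percentiles, strictly = TRUE))
    stop_wml("percentiles must be strictly increasing")
  mapped <- matrix(NA_real_, length(volumes), length(percentiles))
  for (i in seq_along(volumes)) {
    mapped[i, ] <- mapped_landmarks(volumes[[i]], brain_masks[[i]],
                                    percentiles, scale_range)
  }
  structure(list(percentiles = percentiles,
                 standard_landmarks = colMeans(mapped),
                 scale_range = scale_range,
                 trained = TRUE),
            class = "wml_standardizer")
}

volume_landmarks <- function(vol, mask, percentiles) {
  a <- vol_data(vol)
  m <- vol_data(mask) > 0
  if (!any(m)) stop_wml("brain mask is empty")
  lm <- unname(quantile(a[m], probs = percentiles / 100, type = 7))
  if (lm[1] == lm[length(lm)])
    stop_wml("degenerate intensity histogram: p%g == p%g",
             percentiles[1], percentiles[length(percentiles)])
  lm
}

mapped_landmarks <- function(vol, mask, percentiles, scale_range) {
  lm <- volume_landmarks(vol, mask, percentiles)
  k <- length(lm)
  scale_range[1] + (lm - lm[1]) / (lm[k] - lm[1]) * diff(scale_range)
}

#' Apply an intensity standardization model
#'
#' Maps the volume's own landmark percentiles onto the model's standard-scale
#' landmarks with a monotone piecewise-linear transform; intensities beyond
#' the outermost landmarks are extrapolated linearly with the end-segment
#' slopes. Voxels outside the brain mask are set to 0.
#'
#' @param model A trained `wml_standardizer`.
#' @param vol Volume to standardize.
#' @param brain_mask Binary brain mask on the same grid.
#' @return Standardized `wml_volume`.
#' @export
apply_standardizer <- function(model, vol, brain_mask) {
  if (!inherits(model, "wml_standardizer") || !isTRUE(model$trained))
    stop_wml("model is not a trained standardizer")
  vol <- as_volume(vol)
  assert_same_grid(vol, brain_mask, "volume and brain mask")
  src <- volume_landmarks(vol, brain_mask, model$percentiles)
  if (is.unsorted(src, strictly = TRUE))
    stop_wml("volume landmarks are not strictly increasing; histogram too discrete")
  dst <- model$standard_landmarks
  a <- vol_data(vol)
  m <- vol_data(brain_mask) > 0
  x <- a[m]
  k <- length(src)
  y <- approx(src, dst, xout = pmin(pmax(x, src[1]), src[k]))$y
  # linear extrapolation with the end-segment slopes
  lo <- x < src[1]
  if (any(lo)) {
    slope <- (dst[2] - dst[1]) / (src[2] - src[1])
    y[lo] <- dst[1] + (x[lo] - src[1]) * slope
  }
  hi <- x > src[k]
  if (any(hi)) {
    slope <- (dst[k] - dst[k - 1]) / (src[k] - src[k - 1])
    y[hi] <- dst[k] + (x[hi] - src[k]) * slope
  }
  out <- array(0, dim(a))
  out[m] <- y
  with_data(vol, out)
}

#' Serialize / restore a standardizer
#'
#' The model is stored as plain JSON (percentiles, standard landmarks, scale).
#' @param model A `wml_standardizer`.
#' @param path JSON file path.
#' @return `read_standardizer` returns the restored model.
#' @export
write_standardizer <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(percentiles = as.numeric(m$percentiles),
                 standard_landmarks = as.numeric(m$standard_landmarks),
                 scale_range = as.numeric(m$scale_range),
                 trained = isTRUE(m$trained)),
            class = "wml_standardizer")
}

#' Apply a brain mask
#'
#' Zeroes every voxel outside the mask and leaves in-mask voxels untouched.
#'
#' @param vol Volume.
#' @param mask Binary mask on the same grid.
#' @return Masked `wml_volume`.
#' @export
apply_brain_mask <- function(vol, mask) {
  vol <- as_volume(vol)
  assert_same_grid(vol, mask, "volume and mask")
  assert_binary(mask, "brain mask")
  with_data(vol, vol_data(vol) * (vol_data(mask) > 0))
}
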