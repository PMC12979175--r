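# Canonical volume data model and NIfTI I/O.
#
# A wml_volume holds a 3D scalar grid in canonical anatomical order
# (axis 1 = left-right, axis 2 = posterior-anterior, axis 3 = inferior-superior,
# i.e. RAS), a per-axis spacing in mm and a 4x4 voxel-to-world affine.

CANONICAL_SHAPE <- c(160L, 256L, 176L)

#' Construct a volume
#'
#' A `wml_volume` is the package's canonical container for one 3D scalar grid:
#' the image data, the voxel spacing in millimetres, and the 4x4 voxel-to-world
#' affine. Axes are assumed to follow the canonical RAS anatomical order
#' (left-right, posterior-anterior, inferior-superior).
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, mm per axis; strictly positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine built
#'   from `spacing`.
#' @return An object of class `wml_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop_wml("volume data must be a 3D array, got %d dims",
             length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_wml("spacing must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop_wml("affine must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "wml_volume")
}

#' @export
print.wml_volume <- function(x, ...) {
  cat(sprintf("<wml_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Coerce to a volume
#'
#' Arrays are wrapped with unit spacing; volumes pass through.
#' @param x Array or `wml_volume`.
#' @param spacing Spacing used when `x` is a bare array.
#' @return A `wml_volume`.
#' @export
as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "wml_volume")) return(x)
  new_volume(x, spacing = spacing)
}

vol_data <- function(v) if (inherits(v, "wml_volume")) v$data else v
vol_spacing <- function(v) if (inherits(v, "wml_volume")) v$spacing else c(1, 1, 1)

with_data <- function(v, data) {
  v$data <- data
  v
}

is_binary_data <- function(a) {
  all(a == 0 | a == 1)
}

assert_binary <- function(v, what = "mask") {
  if (!is_binary_data(vol_data(v)))
    stop_wml("%s must be binary (0/1)", what)
  invisible(TRUE)
}

assert_probability <- function(v, what = "probability map") {
  a <- vol_data(v)
  if (any(a < 0 | a > 1))
    stop_wml("%s must lie in [0, 1]", what)
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a single 3D NIfTI-1/NIfTI-2 image, reorients the data to the canonical
#' RAS axis order and extracts spacing and affine from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `wml_volume`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    stop_wml("NIfTI file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(img[, , , 1], reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop_wml("expected a single 3D volume, got a %dD image: %s",
             length(d), path)
  aff <- RNifti::xform(img)
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop_wml("non-invertible affine in %s", path)
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  sp <- RNifti::pixdim(img)[1:3]
  new_volume(array(as.numeric(img), dim = dim(img)), spacing = sp,
             affine = rbind(aff, c(0, 0, 0, 1))[1:4, ])
}

#' Write a volume to NIfTI
#'
#' Round-trips through [read_nifti()]: data are preserved bit-exactly for
#' integer-valued masks and to float precision otherwise.
#'
#' @param vol A `wml_volume`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype NIfTI storage type; binary masks fit `"uint8"`, scalars
#'   default to `"double"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "double") {
  vol <- as_volume(vol)
  if (!dir.exists(dirname(path)))
    stop_wml("directory does not exist: %s", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Conform a volume to the canonical grid
#'
#' Resamples to 1 mm isotropic spacing (trilinear for scalar images, nearest
#' neighbor for binary masks) and center-crops/zero-pads to the canonical
#' shape. Inputs already on the target grid are returned unchanged, so the
#' operation is idempotent. Inputs are assumed co-registered and axis-aligned;
#' no registration is performed.
#'
#' @param vol A `wml_volume` (or array).
#' @param shape Target grid shape; defaults to the canonical (160, 256, 176).
#' @param interpolation `"auto"` (nearest for 0/1 data, trilinear otherwise),
#'   `"trilinear"` or `"nearest"`.
#' @return A conformed `wml_volume` with unit spacing and shape `shape`.
#' @export
conform <- function(vol, shape = CANONICAL_SHAPE,
                    interpolation = c("auto", "trilinear", "nearest")) {
  vol <- as_volume(vol)
  interpolation <- match.arg(interpolation)
  d <- dim(vol$data)
  if (any(d == 0)) stop_wml("degenerate volume: axis of length 0")
  a <- vol$data
  sp <- vol$spacing

  if (any(abs(sp - 1) > 1e-6)) {
    out_dims <- pmax(1L, as.integer(round(d * sp)))
    mode <- switch(interpolation,
                   auto = if (is_binary_data(a)) 1L else 0L,
                   trilinear = 0L,
                   nearest = 1L)
    a <- cpp_resample(as.numeric(a), d, out_dims, mode)
    d <- out_dims
  }

  shape <- as.integer(shape)
  out <- array(0, shape)
  # center crop/pad bookkeeping per axis: source and destination index ranges
  src <- dst <- vector("list", 3L)
  offset <- numeric(3)
  for (ax in 1:3) {
    n <- d[ax]; N <- shape[ax]
    if (n >= N) {
      start <- (n - N) %/% 2L         # crop
      src[[ax]] <- (start + 1L):(start + N)
      dst[[ax]] <- 1:N
      offset[ax] <- start
    } else {
      before <- (N - n) %/% 2L        # pad
      src[[ax]] <- 1:n
      dst[[ax]] <- (before + 1L):(before + n)
      offset[ax] <- -before
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]

  # the affine keeps the canonical axis directions at 1 mm and shifts the
  # origin by the crop/pad offset (in world mm, axis-aligned by assumption)
  affine <- diag(4)
  affine[1:3, 4] <- vol$affine[1:3, 4] + offset
  new_volume(out, spacing = c(1, 1, 1), affine = affine)
}

#' Label 26-connected components
#'
#' Lesions are defined as groups of 26-connected voxels: any two foreground
#' voxels sharing a face, edge or corner belong to the same component. Labels
#' `1..n` are assigned deterministically in order of each component's first
#' voxel in the column-major scan.
#'
#' @param mask Binary `wml_volume` or 0/1 array.
#' @return A `wml_components` list with `labels` (integer array), `n_components`
#'   and `connectivity = 26`.
#' @export
connected_components_26 <- function(mask) {
  a <- vol_data(mask)
  if (!is_binary_data(a)) stop_wml("connected_components_26: input must be binary")
  res <- cpp_label_components_26(as.integer(a > 0), dim(a))
  structure(list(labels = res$labels, n_components = res$n,
                 connectivity = 26L),
            class = "wml_components")
}
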