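# Tri-planar inference: slice a volume along each anatomical axis, predict
# per-slice probability maps, reassemble three 3D probability volumes,
# binarize and fuse by per-voxel 2-of-3 majority vote, then optionally remove
# detections inside ventricular CSF (choroid-plexus-like false positives).

ORIENTATIONS <- c("axial", "coronal", "sagittal")

# slicing axis per orientation in canonical (LR, PA, IS) axis order
slice_axis <- function(orientation) {
  switch(orientation, axial = 3L, coronal = 2L, sagittal = 1L,
         stop_wml("unknown orientation '%s'", orientation))
}

# permutation that puts the slicing axis last
slice_perm <- function(orientation) {
  switch(orientation, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L),
         sagittal = c(2L, 3L, 1L),
         stop_wml("unknown orientation '%s'", orientation))
}

#' Extract 2D slices along one orientation
#'
#' Axial slices are (LR, PA) planes ordered along the inferior-superior axis;
#' coronal slices are (LR, IS) planes along posterior-anterior; sagittal
#' slices are (PA, IS) planes along left-right. On the canonical grid the
#' slice shapes are (160, 256), (160, 176) and (256, 176).
#'
#' @param vol A `wml_volume` or 3D array.
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @return A `wml_stack`: `orientation`, `slices` (3D array, slice index
#'   last), `source_shape`.
#' @export
extract_slices <- function(vol, orientation) {
  a <- vol_data(vol)
  perm <- slice_perm(orientation)
  structure(list(orientation = orientation,
                 slices = aperm(a, perm),
                 source_shape = dim(a)),
            class = "wml_stack")
}

#' Reassemble a 3D volume from a slice stack
#'
#' Inverse of [extract_slices()]: the round trip is the identity.
#'
#' @param stack A `wml_stack`.
#' @return 3D array on the source grid.
#' @export
reconstruct <- function(stack) {
  perm <- slice_perm(stack$orientation)
  d <- dim(stack$slices)
  if (!identical(d, stack$source_shape[perm]))
    stop_wml("stack shape %s does not match source shape %s",
             paste(d, collapse = "x"),
             paste(stack$source_shape, collapse = "x"))
  aperm(stack$slices, order(perm))
}

#' Majority vote over three probability maps
#'
#' Each map is binarized at `threshold` (votes are `p >= threshold`) and a
#' voxel is foreground iff at least 2 of the 3 votes agree. The result is
#' invariant to the order of the maps.
#'
#' @param maps List of exactly three probability volumes on the same grid.
#' @param threshold Binarization threshold (default 0.5).
#' @return Binary 0/1 array.
#' @export
majority_vote <- function(maps, threshold = 0.5) {
  if (length(maps) != 3) stop_wml("majority_vote needs exactly 3 maps, got %d",
                                  length(maps))
  d <- dim(vol_data(maps[[1]]))
  votes <- array(0L, d)
  for (m in maps) {
    a <- vol_data(m)
    if (!identical(dim(a), d)) stop_wml("majority_vote: grid mismatch")
    votes <- votes + (a >= threshold)
  }
  out <- (votes >= 2L) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Remove lesion voxels inside ventricular CSF
#'
#' FLAIR-hyperintense structures inside the CSF (choroid plexus, pineal
#' gland) are common false positives; voxels where the CSF partial volume
#' exceeds 0.5 are removed from the lesion mask. Never adds voxels.
#'
#' @param lesions Binary lesion mask.
#' @param csf_pv CSF partial-volume map on the same grid.
#' @return Binary 0/1 array.
#' @export
csf_postprocess <- function(lesions, csf_pv) {
  assert_same_grid(lesions, csf_pv, "lesions and csf_pv")
  assert_binary(lesions, "lesion mask")
  out <- (vol_data(lesions) > 0 & !(vol_data(csf_pv) > 0.5)) * 1L
  storage.mode(out) <- "integer"
  out
}

predict_stack <- function(model, slices) {
  if (is.function(model)) return(model(slices))
  predict_slices(model, slices)
}

#' Segment a FLAIR volume with three orientation models
#'
#' Runs extract -> per-slice prediction -> 3D reconstruction for each of the
#' three orientations, fuses the probability volumes by majority vote and,
#' when a CSF partial-volume map is supplied, removes CSF-interior voxels.
#'
#' @param flair Conformed, standardized FLAIR `wml_volume`.
#' @param models Named list (`axial`, `coronal`, `sagittal`) of trained
#'   `wml_model`s, or functions mapping an `(a, b, n)` slice array to
#'   probabilities (useful for testing).
#' @param csf_pv Optional CSF partial-volume map for post-processing.
#' @param threshold Voting threshold.
#' @return Binary lesion mask as a `wml_volume` on the input grid.
#' @export
segment_volume <- function(flair, models, csf_pv = NULL, threshold = 0.5) {
  if (!all(ORIENTATIONS %in% names(models)))
    stop_wml("models must be named axial, coronal, sagittal")
  probs <- lapply(ORIENTATIONS, function(o) {
    st <- extract_slices(flair, o)
    st$slices <- predict_stack(models[[o]], st$slices)
    reconstruct(st)
  })
  seg <- majority_vote(probs, threshold)
  if (!is.null(csf_pv)) seg <- csf_postprocess(seg, csf_pv)
  vol <- as_volume(flair)
  new_volume(seg, spacing = vol$spacing, affine = vol$affine)
}
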