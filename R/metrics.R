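# Voxel- and object-level segmentation metrics.
#
# Conventions for degenerate inputs (documented and tested):
#   * dice(empty, empty) = 1, ppv(empty, empty) = 1
#   * ppv = NaN when the prediction is empty but the reference is not
#   * object rates use NaN when their denominator (object count) is zero
#   * assd() errors on an empty mask; evaluate() reports NaN instead
# Objects are 26-connected components throughout.

mask_overlap_table <- function(rl, pl) {
  # count co-occurring (ref label, pred label) pairs over foreground voxels
  sel <- rl > 0L & pl > 0L
  if (!any(sel)) return(matrix(0, 0, 3,
                               dimnames = list(NULL, c("ref", "pred", "n"))))
  key <- paste(rl[sel], pl[sel])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  cbind(ref = as.integer(parts[, 1]), pred = as.integer(parts[, 2]),
        n = as.integer(tab))
}

#' Dice similarity coefficient
#'
#' Voxel-wise overlap `2*TP / (2*TP + FP + FN)` between a reference and a
#' predicted binary mask. Two empty masks score 1.
#'
#' @param ref,pred Binary masks (`wml_volume` or 0/1 arrays) on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(ref, pred) {
  assert_same_grid(ref, pred, "masks")
  r <- vol_data(ref) > 0; p <- vol_data(pred) > 0
  assert_binary(ref); assert_binary(pred)
  denom <- sum(r) + sum(p)
  if (denom == 0) return(1)
  2 * sum(r & p) / denom
}

#' Positive predictive value (precision)
#'
#' `TP / (TP + FP)` over voxels. Returns 1 when both masks are empty and NaN
#' when the prediction is empty but the reference is not (undefined precision).
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`, or NaN.
#' @export
ppv <- function(ref, pred) {
  assert_same_grid(ref, pred, "masks")
  r <- vol_data(ref) > 0; p <- vol_data(pred) > 0
  if (!any(p)) return(if (!any(r)) 1 else NaN)
  sum(r & p) / sum(p)
}

#' Object-level Dice
#'
#' Symmetric size-weighted average of per-object Dice scores: every reference
#' object is paired with the predicted object of maximal voxel overlap (Dice 0
#' if none overlaps) and vice versa; each directed sum weights objects by their
#' voxel-count fraction, and the two sums are averaged. Ties in overlap break
#' toward the smaller label.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
object_dice <- function(ref, pred) {
  assert_same_grid(ref, pred, "masks")
  assert_binary(ref); assert_binary(pred)
  R <- connected_components_26(ref); P <- connected_components_26(pred)
  if (R$n_components == 0 && P$n_components == 0) return(1)
  if (R$n_components == 0 || P$n_components == 0) return(0)
  ov <- mask_overlap_table(R$labels, P$labels)
  rsize <- tabulate(R$labels[R$labels > 0], R$n_components)
  psize <- tabulate(P$labels[P$labels > 0], P$n_components)

  directed <- function(sizes_a, sizes_b, ia, ib) {
    # for each object of side a, Dice against its maximal-overlap partner in b
    s <- 0
    for (i in seq_along(sizes_a)) {
      rows <- which(ov[, ia] == i)
      d_i <- 0
      if (length(rows)) {
        best <- rows[order(-ov[rows, "n"], ov[rows, ib])][1]
        j <- ov[best, ib]
        d_i <- 2 * unname(ov[best, "n"]) / (sizes_a[i] + sizes_b[j])
      }
      s <- s + sizes_a[i] / sum(sizes_a) * d_i
    }
    s
  }
  0.5 * (directed(rsize, psize, "ref", "pred") +
         directed(psize, rsize, "pred", "ref"))
}

#' Object-level detection rates
#'
#' With lesions as 26-connected components: OTPR is the fraction of reference
#' objects touched by at least one predicted voxel; OFPR is the fraction of
#' predicted objects with no reference overlap (object-level true negatives
#' are undefined, so this is 1 minus object precision). Empty object sets give
#' NaN for the affected rate.
#'
#' @inheritParams dice
#' @return Named list with `otpr` and `ofpr`.
#' @export
object_rates <- function(ref, pred) {
  assert_same_grid(ref, pred, "masks")
  assert_binary(ref); assert_binary(pred)
  R <- connected_components_26(ref); P <- connected_components_26(pred)
  ov <- mask_overlap_table(R$labels, P$labels)
  otpr <- if (R$n_components == 0) NaN else
    length(unique(ov[, "ref"])) / R$n_components
  ofpr <- if (P$n_components == 0) NaN else
    (P$n_components - length(unique(ov[, "pred"]))) / P$n_components
  list(otpr = otpr, ofpr = ofpr)
}

surface_mask <- function(m) {
  # mask voxels with at least one face-adjacent background neighbor
  # (the grid border counts as background)
  m <- vol_data(m) > 0
  storage.mode(m) <- "integer"
  any_bg <- array(FALSE, dim(m))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    any_bg <- any_bg | (shift_array(m, off) == 0)
  }
  m == 1 & any_bg
}

#' Average symmetric surface distance
#'
#' Mean Euclidean distance (mm) between the two mask surfaces: every surface
#' voxel of each mask contributes its distance to the nearest surface voxel of
#' the other mask, and the total is divided by the combined surface voxel
#' count. Surfaces are mask voxels with a face-adjacent background neighbor;
#' distances are computed with an anisotropy-aware exact distance transform.
#'
#' @inheritParams dice
#' @param spacing Voxel spacing in mm (length 3); defaults to the reference
#'   volume's spacing.
#' @return Distance in mm (0 for identical masks).
#' @export
assd <- function(ref, pred, spacing = NULL) {
  assert_same_grid(ref, pred, "masks")
  assert_binary(ref); assert_binary(pred)
  spacing <- spacing %||% vol_spacing(ref)
  r <- vol_data(ref) > 0; p <- vol_data(pred) > 0
  if (!any(r) || !any(p))
    stop_wml("assd is undefined for an empty mask")
  sr <- surface_mask(ref); sp_ <- surface_mask(pred)
  d <- dim(r)
  dt_pred <- cpp_edt(as.integer(sp_), d, spacing)  # distance to pred surface
  dt_ref <- cpp_edt(as.integer(sr), d, spacing)
  (sum(dt_pred[sr]) + sum(dt_ref[sp_])) / (sum(sr) + sum(sp_))
}

#' Full evaluation report
#'
#' Computes every segmentation metric for one (reference, prediction) pair:
#' voxel Dice, object Dice, PPV, object-level true/false positive rates, ASSD
#' and object-Dice stratified by reference-lesion size (`<5`, `5-15`, `>15`
#' ml). Per-bin object Dice is the size-weighted mean of per-reference-object
#' Dice scores for reference objects in that bin (NaN for empty bins); ASSD is
#' NaN when either mask is empty.
#'
#' @inheritParams assd
#' @return A `wml_metrics` list: `dice`, `dice_obj`, `ppv`, `otpr`, `ofpr`,
#'   `assd_mm`, `dice_obj_by_size` (named length-3), `n_ref_objects`,
#'   `n_pred_objects`.
#' @export
evaluate <- function(ref, pred, spacing = NULL) {
  assert_same_grid(ref, pred, "masks")
  spacing <- spacing %||% vol_spacing(ref)
  rates <- object_rates(ref, pred)
  R <- connected_components_26(ref); P <- connected_components_26(pred)
  assd_val <- if (any(vol_data(ref) > 0) && any(vol_data(pred) > 0))
    assd(ref, pred, spacing) else NaN

  # size-stratified object Dice over reference objects
  by_size <- c(small = NaN, medium = NaN, large = NaN)
  if (R$n_components > 0) {
    rsize <- tabulate(R$labels[R$labels > 0], R$n_components)
    psize <- if (P$n_components > 0)
      tabulate(P$labels[P$labels > 0], P$n_components) else integer()
    ov <- mask_overlap_table(R$labels, P$labels)
    d_i <- numeric(R$n_components)
    for (i in seq_len(R$n_components)) {
      rows <- which(ov[, "ref"] == i)
      if (length(rows)) {
        best <- rows[order(-ov[rows, "n"], ov[rows, "pred"])][1]
        j <- ov[best, "pred"]
        d_i[i] <- 2 * unname(ov[best, "n"]) / (rsize[i] + psize[j])
      }
    }
    vol_ml <- rsize * prod(spacing) / 1000
    bin <- size_bin(vol_ml)
    for (b in names(by_size)) {
      sel <- bin == b
      if (any(sel)) by_size[b] <- sum(rsize[sel] * d_i[sel]) / sum(rsize[sel])
    }
  }

  structure(list(
    dice = dice(ref, pred),
    dice_obj = object_dice(ref, pred),
    ppv = ppv(ref, pred),
    otpr = rates$otpr,
    ofpr = rates$ofpr,
    assd_mm = assd_val,
    dice_obj_by_size = by_size,
    n_ref_objects = R$n_components,
    n_pred_objects = P$n_components
  ), class = "wml_metrics")
}

#' @export
print.wml_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Segmentation metrics (%d reference / %d predicted objects)\n",
    "  Dice      %.4f   Dice_obj %.4f   PPV  %.4f\n",
    "  OTPR      %.4f   OFPR     %.4f   ASSD %.4f mm\n",
    "  Dice_obj by size: <5 ml %.4f | 5-15 ml %.4f | >15 ml %.4f\n"),
    x$n_ref_objects, x$n_pred_objects, x$dice, x$dice_obj, x$ppv,
    x$otpr, x$ofpr, x$assd_mm,
    x$dice_obj_by_size["small"], x$dice_obj_by_size["medium"],
    x$dice_obj_by_size["large"]))
  invisible(x)
}
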