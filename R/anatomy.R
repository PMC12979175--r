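# Anatomical lesion classification and confluent-lesion counting.
#
# Locations follow the radiological (McDonald-style) classes: a lesion is
# infratentorial if it overlaps the brainstem/cerebellum mask, otherwise
# periventricular if it touches a band around the ventricular CSF, otherwise
# juxtacortical if it touches the corresponding cortical-GM band, otherwise
# deep white matter. The priority order resolves multi-label overlaps.

#' Anatomy context
#'
#' Bundles the tissue maps needed for lesion classification: CSF and cortical
#' gray-matter partial-volume maps and a binary infratentorial
#' (brainstem/cerebellum) mask, all co-registered to the lesion grid.
#'
#' @param csf_pv,gm_pv Probability maps (`wml_volume` or arrays in `[0,1]`).
#' @param infratentorial_mask Binary mask.
#' @param dilation_radius Radius in voxels of the spherical structuring
#'   element used for the periventricular/juxtacortical bands. The default 3
#'   gives the sphere inscribed in a 7x7x7 cube.
#' @return A `wml_anatomy_ctx` list.
#' @export
anatomy_context <- function(csf_pv, gm_pv, infratentorial_mask,
                            dilation_radius = 3) {
  assert_probability(csf_pv, "csf_pv")
  assert_probability(gm_pv, "gm_pv")
  assert_binary(infratentorial_mask, "infratentorial_mask")
  structure(list(csf_pv = csf_pv, gm_pv = gm_pv,
                 infratentorial_mask = infratentorial_mask,
                 dilation_radius = dilation_radius),
            class = "wml_anatomy_ctx")
}

pv_band <- function(pv, dilation_radius) {
  hard <- vol_data(pv) > 0.5
  storage.mode(hard) <- "integer"
  dil <- dilate_mask(hard, sphere_offsets(dilation_radius))
  band <- dil == 1 & hard == 0
  storage.mode(band) <- "integer"
  band
}

#' Periventricular band
#'
#' Binarizes the CSF partial-volume map at 0.5, dilates it with a spherical
#' structuring element (7 voxels wide by default) and subtracts the original
#' binary mask, leaving the shell of voxels adjacent to ventricular CSF.
#'
#' @param csf_pv CSF partial-volume map.
#' @param dilation_radius Structuring-element radius in voxels (default 3).
#' @return Binary 0/1 array of the band.
#' @export
periventricular_band <- function(csf_pv, dilation_radius = 3) {
  assert_probability(csf_pv, "csf_pv")
  pv_band(csf_pv, dilation_radius)
}

#' Juxtacortical band
#'
#' Same construction as [periventricular_band()] applied to the cortical
#' gray-matter partial-volume map.
#'
#' @param gm_pv Cortical GM partial-volume map.
#' @inheritParams periventricular_band
#' @return Binary 0/1 array of the band.
#' @export
juxtacortical_band <- function(gm_pv, dilation_radius = 3) {
  assert_probability(gm_pv, "gm_pv")
  pv_band(gm_pv, dilation_radius)
}

#' Count sub-lesions within a confluent component
#'
#' Confluent lesions merge into one connected component; the count of
#' underlying lesions is estimated from the image intensities: the FLAIR
#' signal restricted to the component is Gaussian-smoothed and the strict
#' local maxima over the 26-neighborhood (within the component) are counted,
#' keeping only maxima separated by at least `min_distance` voxels (greedy,
#' in decreasing intensity order). A component with no strict maximum (e.g. a
#' flat plateau) counts as one lesion.
#'
#' @param component_mask Binary mask of one component.
#' @param flair The FLAIR volume (same grid).
#' @param smoothing_sigma Gaussian sigma in mm (default 1).
#' @param min_distance Minimum separation between counted maxima, in voxels
#'   (default 3).
#' @return Integer count, at least 1.
#' @export
count_local_maxima <- function(component_mask, flair, smoothing_sigma = 1,
                               min_distance = 3) {
  assert_same_grid(component_mask, flair, "component mask and FLAIR")
  m <- vol_data(component_mask) > 0
  if (!any(m)) stop_wml("count_local_maxima: empty component")
  sp <- vol_spacing(flair)
  f <- vol_data(flair)
  f[!m] <- 0
  sm <- gaussian_blur3(f, smoothing_sigma / sp)
  sm[!m] <- -Inf

  is_max <- array(TRUE, dim(sm))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift_array_inf(sm, c(dx, dy, dz))
    is_max <- is_max & (sm > nb)
  }
  peaks <- which(is_max & m, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(1L)
  vals <- sm[is_max & m]
  ord <- order(-vals, peaks[, 1], peaks[, 2], peaks[, 3])
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums((kept - matrix(p, nrow(kept), 3,
                                        byrow = TRUE))^2)) >= min_distance)) {
      kept <- rbind(kept, p)
    }
  }
  max(1L, nrow(kept))
}

# shift with -Inf fill so out-of-grid neighbors never beat a real voxel
shift_array_inf <- function(a, off) {
  out <- shift_array(a, off)
  d <- dim(a)
  for (ax in 1:3) {
    o <- off[ax]
    idx <- if (o > 0) seq_len(min(o, d[ax])) else if (o < 0)
      seq(d[ax] + max(o, -d[ax]) + 1L, d[ax]) else integer()
    if (length(idx)) {
      sl <- rep(list(quote(expr = )), 3)
      sl[[ax]] <- idx
      out <- do.call(`[<-`, c(list(out), sl, list(value = -Inf)))
    }
  }
  out
}

#' Classify segmented lesions by anatomical location
#'
#' Labels every 26-connected lesion component as infratentorial,
#' periventricular, juxtacortical or deep white matter (in that priority
#' order, using single-voxel overlap with the infratentorial mask and the two
#' PV-derived bands), computes its volume in ml from the voxel spacing, and
#' counts sub-lesions via [count_local_maxima()].
#'
#' @param lesions Binary lesion mask.
#' @param ctx A [anatomy_context()].
#' @param flair FLAIR volume on the same grid (used for sub-lesion counting).
#' @param smoothing_sigma,min_distance Passed to [count_local_maxima()].
#' @return A data.frame with one row per lesion: `component_id`,
#'   `voxel_count`, `volume_ml`, `location`, `n_sublesions`.
#' @export
classify_lesions <- function(lesions, ctx, flair, smoothing_sigma = 1,
                             min_distance = 3) {
  assert_binary(lesions, "lesion mask")
  assert_same_grid(lesions, ctx$csf_pv, "lesions and csf_pv")
  assert_same_grid(lesions, ctx$gm_pv, "lesions and gm_pv")
  assert_same_grid(lesions, ctx$infratentorial_mask, "lesions and atlas mask")
  sp <- vol_spacing(flair)
  cc <- connected_components_26(lesions)
  if (cc$n_components == 0)
    return(data.frame(component_id = integer(), voxel_count = integer(),
                      volume_ml = numeric(), location = character(),
                      n_sublesions = integer()))
  pv_band_m <- periventricular_band(ctx$csf_pv, ctx$dilation_radius) > 0
  jc_band_m <- juxtacortical_band(ctx$gm_pv, ctx$dilation_radius) > 0
  infra <- vol_data(ctx$infratentorial_mask) > 0

  out <- vector("list", cc$n_components)
  for (i in seq_len(cc$n_components)) {
    comp <- cc$labels == i
    loc <- if (any(comp & infra)) "infratentorial"
           else if (any(comp & pv_band_m)) "periventricular"
           else if (any(comp & jc_band_m)) "juxtacortical"
           else "deep-WM"
    nvox <- sum(comp)
    comp_mask <- array(as.integer(comp), dim(comp))
    n_sub <- count_local_maxima(new_volume(comp_mask, spacing = sp), flair,
                                smoothing_sigma, min_distance)
    out[[i]] <- data.frame(component_id = i, voxel_count = nvox,
                           volume_ml = nvox * prod(sp) / 1000,
                           location = loc, n_sublesions = n_sub)
  }
  do.call(rbind, out)
}

size_bin <- function(volume_ml) {
  ifelse(volume_ml < 5, "small", ifelse(volume_ml <= 15, "medium", "large"))
}

#' Stratify lesions by size
#'
#' Bins lesions into the standard size groups: small (`<5` ml), medium
#' (`5-15` ml, boundaries inclusive) and large (`>15` ml).
#'
#' @param objects A data.frame with a `volume_ml` column (as returned by
#'   [classify_lesions()]).
#' @return A list with `counts` (named integer length 3) and `objects` (the
#'   input split by bin).
#' @export
size_stratify <- function(objects) {
  bins <- c("small", "medium", "large")
  if (nrow(objects) == 0) {
    return(list(counts = stats::setNames(integer(3), bins),
                objects = stats::setNames(
                  replicate(3, objects[0, , drop = FALSE],
                            simplify = FALSE), bins)))
  }
  b <- factor(size_bin(objects$volume_ml), levels = bins)
  list(counts = stats::setNames(as.integer(table(b)), bins),
       objects = split(objects, b))
}
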