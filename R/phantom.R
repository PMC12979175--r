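# Synthetic brain phantom with planted lesions.
#
# The phantom emulates the inputs the pipeline needs on real data: a FLAIR
# volume (CSF dark, GM slightly brighter than WM, lesions hyperintense over
# WM), CSF and cortical-GM partial-volume maps, an infratentorial
# (brainstem/cerebellum-like) mask, a brain mask, and a bright
# choroid-plexus-like distractor inside the ventricles. Geometry is built
# from concentric ellipsoids: brain envelope, a cortical GM shell, a central
# ventricular cavity and a posterior-inferior infratentorial region. Lesions
# are spheres placed so that each provably satisfies its anatomical class
# rule with margin (the placement constraints are expressed through distance
# transforms of the tissue masks).

#' Phantom specification
#'
#' @param seed RNG seed; identical specs give identical phantoms.
#' @param shape Grid dimensions; default 64^3 (the canonical grid is also
#'   supported). Spacing is 1 mm isotropic.
#' @param n_lesions Named counts per location class
#'   (`periventricular`, `juxtacortical`, `infratentorial`, `deep-WM`).
#' @param lesion_radius_range Sphere radius range in mm.
#' @param lesion_contrast Intensity offset of a lesion over white matter
#'   (arbitrary units; WM base level is 42).
#' @param noise_sigma Additive Gaussian noise SD.
#' @param pv_smoothing Gaussian sigma (mm) applied to hard tissue labels to
#'   create partial-volume maps.
#' @param distractor Whether to plant the bright CSF-interior distractor.
#' @return A `wml_phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1, shape = c(64, 64, 64),
                         n_lesions = c("periventricular" = 2,
                                       "juxtacortical" = 1,
                                       "infratentorial" = 1,
                                       "deep-WM" = 2),
                         lesion_radius_range = c(2, 4),
                         lesion_contrast = 30,
                         noise_sigma = 2,
                         pv_smoothing = 1,
                         distractor = TRUE) {
  classes <- c("periventricular", "juxtacortical", "infratentorial", "deep-WM")
  full <- stats::setNames(numeric(4), classes)
  full[names(n_lesions)] <- n_lesions
  if (any(full < 0)) stop_wml("lesion counts must be >= 0")
  if (any(lesion_radius_range <= 0) || diff(lesion_radius_range) < 0)
    stop_wml("lesion_radius_range must be positive and ordered")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 n_lesions = full,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 noise_sigma = noise_sigma, pv_smoothing = pv_smoothing,
                 distractor = isTRUE(distractor)),
            class = "wml_phantom_spec")
}

# normalized coordinates: array center -> 0, array edge -> about +/-1
norm_coords <- function(shape) {
  lapply(1:3, function(ax) (seq_len(shape[ax]) - (shape[ax] + 1) / 2) /
           (shape[ax] / 2))
}

ellipsoid_mask <- function(shape, center, semi, coords = norm_coords(shape)) {
  ux <- (coords[[1]] - center[1]) / semi[1]
  uy <- (coords[[2]] - center[2]) / semi[2]
  uz <- (coords[[3]] - center[3]) / semi[3]
  q <- outer(outer(ux^2, uy^2, `+`), uz^2, `+`)
  out <- (q <= 1) * 1L
  storage.mode(out) <- "integer"
  out
}

sphere_voxels <- function(shape, center, radius) {
  # binary sphere in voxel units around a (1-based) voxel center
  r <- ceiling(radius)
  rng <- lapply(1:3, function(ax)
    max(1, center[ax] - r):min(shape[ax], center[ax] + r))
  out <- array(0L, shape)
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 +
    (g$z - center[3])^2 <= radius^2
  out[as.matrix(g[keep, ])] <- 1L
  out
}

# brain geometry shared by all phantoms (normalized units)
PHANTOM_GEOM <- list(
  brain_semi = c(0.88, 0.92, 0.85),
  interior_scale = 0.80,
  ventricle_center = c(0, 0.05, 0.12),
  ventricle_semi = c(0.16, 0.34, 0.20),
  infra_center = c(0, -0.42, -0.50),
  infra_semi = c(0.38, 0.30, 0.28)
)

#' Generate a synthetic brain phantom
#'
#' Deterministic for a fixed spec. Lesion spheres are placed by rejection
#' sampling over voxels that satisfy the class rule with margin:
#' periventricular lesions abut the ventricular surface (within the
#' dilated-CSF band) without entering CSF; juxtacortical lesions abut the
#' cortical GM shell; infratentorial lesions lie inside the infratentorial
#' region; deep-WM lesions keep clear of all three. Lesions are mutually
#' separated so each is its own 26-connected component.
#'
#' @param spec A [phantom_spec()].
#' @return A `wml_phantom` list: `flair`, `lesion_truth`, `lesion_table`
#'   (per-lesion class/volume ground truth), `csf_pv`, `gm_pv`,
#'   `infratentorial_mask`, `brain_mask`, `bright_distractor_mask`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  if (any(shape < 48))
    stop_wml("phantom shape must be at least 48 voxels per axis")
  g <- PHANTOM_GEOM
  coords <- norm_coords(shape)
  brain <- ellipsoid_mask(shape, c(0, 0, 0), g$brain_semi, coords)
  interior <- ellipsoid_mask(shape, c(0, 0, 0),
                             g$interior_scale * g$brain_semi, coords)
  gm_hard <- (brain == 1 & interior == 0) * 1L
  csf_hard <- ellipsoid_mask(shape, g$ventricle_center, g$ventricle_semi,
                             coords)
  infra <- (ellipsoid_mask(shape, g$infra_center, g$infra_semi, coords) &
              brain == 1) * 1L
  storage.mode(infra) <- "integer"
  wm <- interior == 1 & csf_hard == 0

  sp1 <- c(1, 1, 1)
  d_csf <- cpp_edt(csf_hard, shape, sp1)
  d_gm <- cpp_edt(gm_hard, shape, sp1)
  d_infra <- cpp_edt(infra, shape, sp1)
  d_notinfra <- cpp_edt(as.integer(infra == 0), shape, sp1)
  d_out <- cpp_edt(as.integer(brain == 0), shape, sp1)

  eligibility <- function(class, r) {
    switch(class,
      "periventricular" =
        wm & d_csf >= r + 1 & d_csf <= r + 2 & d_gm > r + 5 &
          d_infra > r + 3 & d_out > r + 2,
      "juxtacortical" =
        wm & d_gm >= r + 1 & d_gm <= r + 2 & d_csf > r + 5 &
          d_infra > r + 3 & d_out > r + 2,
      "infratentorial" =
        infra == 1 & d_notinfra >= r + 1 & d_csf > r + 5 & d_gm > r + 1,
      "deep-WM" =
        wm & d_csf > r + 5 & d_gm > r + 5 & d_infra > r + 3 & d_out > r + 2)
  }

  with_seed(spec$seed, {
    lesion <- array(0L, shape)
    placed <- NULL  # centers + radii of accepted lesions
    rows <- list()
    for (class in names(spec$n_lesions)) {
      for (i in seq_len(spec$n_lesions[[class]])) {
        # rejection sampling over radius draws: an unlucky large radius can
        # leave no admissible center once earlier lesions claim space
        cand <- NULL
        for (attempt in 1:20) {
          r <- runif(1, spec$lesion_radius_range[1],
                     spec$lesion_radius_range[2])
          elig <- eligibility(class, r)
          cand <- which(elig, arr.ind = TRUE)
          if (!is.null(placed) && nrow(cand)) {
            ok <- rep(TRUE, nrow(cand))
            for (j in seq_len(nrow(placed))) {
              dd <- sqrt((cand[, 1] - placed[j, 1])^2 +
                         (cand[, 2] - placed[j, 2])^2 +
                         (cand[, 3] - placed[j, 3])^2)
              ok <- ok & dd >= r + placed[j, 4] + 4
            }
            cand <- cand[ok, , drop = FALSE]
          }
          if (nrow(cand) > 0) break
        }
        if (is.null(cand) || nrow(cand) == 0)
          stop_wml("cannot place a %s lesion of radius %.1f mm in this geometry",
                   class, r)
        ctr <- cand[sample.int(nrow(cand), 1), ]
        lesion <- pmax(lesion, sphere_voxels(shape, ctr, r))
        placed <- rbind(placed, c(ctr, r))
        rows[[length(rows) + 1]] <-
          data.frame(class = class, radius_mm = r,
                     cx = ctr[1], cy = ctr[2], cz = ctr[3])
      }
    }
    storage.mode(lesion) <- "integer"

    blur_sig <- spec$pv_smoothing  # spacing is 1 mm
    csf_pv <- pmin(pmax(gaussian_blur3(csf_hard, blur_sig), 0), 1)
    gm_pv <- pmin(pmax(gaussian_blur3(gm_hard, blur_sig), 0), 1)
    brain_pv <- pmin(pmax(gaussian_blur3(brain, blur_sig), 0), 1)
    wm_pv <- pmax(brain_pv - csf_pv - gm_pv, 0)

    flair <- 10 * csf_pv + 52 * gm_pv + 42 * wm_pv
    flair <- flair + spec$lesion_contrast * gaussian_blur3(lesion, 0.6)

    distractor <- array(0L, shape)
    if (spec$distractor) {
      vc <- round((shape + 1) / 2 + g$ventricle_center * shape / 2)
      distractor <- sphere_voxels(shape, vc, 2)
      distractor <- (distractor == 1 & csf_pv > 0.5) * 1L
      storage.mode(distractor) <- "integer"
      if (!any(distractor == 1))
        stop_wml("phantom geometry too small for the CSF distractor")
      # boost to lesion-like brightness over the CSF base level
      flair <- flair + (42 + spec$lesion_contrast - 10) *
        gaussian_blur3(distractor, 0.6)
    }

    flair <- flair + rnorm(length(flair), 0, spec$noise_sigma)
    dim(flair) <- shape

    # ground-truth classes per final component id
    cc <- connected_components_26(lesion)
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) {
      tab$component_id <- vapply(seq_len(nrow(tab)), function(k)
        cc$labels[tab$cx[k], tab$cy[k], tab$cz[k]], integer(1))
      tab$voxel_count <- vapply(tab$component_id, function(id)
        sum(cc$labels == id), integer(1))
      tab$volume_ml <- tab$voxel_count / 1000
      tab <- tab[order(tab$component_id),
                 c("component_id", "class", "radius_mm", "voxel_count",
                   "volume_ml", "cx", "cy", "cz")]
    } else {
      tab <- data.frame(component_id = integer(), class = character(),
                        radius_mm = numeric(), voxel_count = integer(),
                        volume_ml = numeric(), cx = integer(),
                        cy = integer(), cz = integer())
    }

    structure(list(
      flair = new_volume(flair),
      lesion_truth = new_volume(lesion),
      lesion_table = tab,
      csf_pv = new_volume(csf_pv),
      gm_pv = new_volume(gm_pv),
      infratentorial_mask = new_volume(infra),
      brain_mask = new_volume(brain),
      bright_distractor_mask = new_volume(distractor),
      spec = spec
    ), class = "wml_phantom")
  })
}

#' Build 2D training slices from phantoms
#'
#' Extracts paired (FLAIR, lesion) slices along one orientation from a list
#' of phantoms, keeping only slices that contain brain tissue.
#'
#' @param bundles List of `wml_phantom` objects.
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @return List with `images` and `masks`, `(H, W, N)` arrays.
#' @export
phantom_slices <- function(bundles, orientation) {
  imgs <- masks <- list()
  for (b in bundles) {
    st_img <- extract_slices(b$flair, orientation)$slices
    st_msk <- extract_slices(b$lesion_truth, orientation)$slices
    st_brain <- extract_slices(b$brain_mask, orientation)$slices
    keep <- which(apply(st_brain, 3, function(s) any(s > 0)))
    imgs[[length(imgs) + 1]] <- st_img[, , keep, drop = FALSE]
    masks[[length(masks) + 1]] <- st_msk[, , keep, drop = FALSE]
  }
  d <- dim(imgs[[1]])
  n <- sum(vapply(imgs, function(a) dim(a)[3], integer(1)))
  images <- array(0, c(d[1], d[2], n))
  lab <- array(0, c(d[1], d[2], n))
  off <- 0L
  for (i in seq_along(imgs)) {
    k <- dim(imgs[[i]])[3]
    images[, , (off + 1):(off + k)] <- imgs[[i]]
    lab[, , (off + 1):(off + k)] <- masks[[i]]
    off <- off + k
  }
  list(images = images, masks = lab)
}

#' Generate a 2D blob dataset
#'
#' CPU-scale training fixture: each image is Gaussian noise with 0-3 bright
#' disks; the masks are the exact disks. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param n_images Number of image/mask pairs (>= 1).
#' @param image_size Side length in pixels.
#' @param radius_range Disk radius range in pixels.
#' @param contrast Disk intensity over the zero background.
#' @param noise_sigma Additive noise SD.
#' @param n_blobs_range Length-2 inclusive range for the per-image blob count.
#' @return List with `images` and `masks`, `(H, W, N)` arrays.
#' @export
generate_blob_dataset_2d <- function(seed = 1, n_images = 10, image_size = 64,
                                     radius_range = c(4, 8), contrast = 1,
                                     noise_sigma = 0.2,
                                     n_blobs_range = c(0, 3)) {
  if (n_images < 1) stop_wml("n_images must be >= 1")
  if (image_size < 8) stop_wml("image_size too small")
  with_seed(seed, {
    images <- array(0, c(image_size, image_size, n_images))
    masks <- array(0, c(image_size, image_size, n_images))
    xs <- matrix(rep(seq_len(image_size), image_size), image_size)
    ys <- t(xs)
    for (i in seq_len(n_images)) {
      img <- matrix(rnorm(image_size^2, 0, noise_sigma), image_size)
      msk <- matrix(0, image_size, image_size)
      nb <- sample(n_blobs_range[1]:n_blobs_range[2], 1)
      for (b in seq_len(nb)) {
        r <- runif(1, radius_range[1], radius_range[2])
        cx <- runif(1, r + 1, image_size - r)
        cy <- runif(1, r + 1, image_size - r)
        disk <- (xs - cx)^2 + (ys - cy)^2 <= r^2
        img[disk] <- img[disk] + contrast
        msk[disk] <- 1
      }
      images[, , i] <- img
      masks[, , i] <- msk
    }
    list(images = images, masks = masks)
  })
}
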