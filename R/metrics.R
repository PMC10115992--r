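#' Classify a mu-map into air/tissue/bone
#'
#' Class bounds in cm^-1: air `mu < 0.05`, tissue `0.05 <= mu <= 0.1`
#' (closed interval, so both boundary values are tissue), bone `mu > 0.1`.
#' Classification is restricted to the head mask (and, when given, the CT
#' field of view); voxels outside are `NA`.
#'
#' @param mu mu-map `image_volume` (cm^-1).
#' @param head binary head mask.
#' @param fov optional binary field-of-view mask.
#' @return an `image_volume` of integer classes (0 air, 1 tissue, 2 bone,
#'   `NA` outside).
#' @export
classify_mu <- function(mu, head, fov = NULL) {
  stopifnot(is_image_volume(mu))
  h <- mask_array(head, ref = mu, what = "head mask")
  if (!is.null(fov)) h <- h & mask_array(fov, ref = mu, what = "fov mask")
  neg <- sum(mu$data[h] < 0)
  if (neg > 0)
    stop("mu-map contains ", neg, " negative value(s) within the head")
  cls <- array(NA_integer_, dim = dim(mu$data))
  v <- mu$data[h]
  cls[h] <- ifelse(v < 0.05, MU_CLASS_AIR,
                   ifelse(v <= 0.1, MU_CLASS_TISSUE, MU_CLASS_BONE))
  out <- mu
  out$data <- cls
  out
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks agree perfectly (returns 1).
#'
#' @param a,b binary masks on one grid.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- mask_array(a)
  mb <- mask_array(b, ref = a, what = "masks")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}

# Dice between two class maps for one class value, within an optional mask
class_dice <- function(cls_a, cls_b, class_value, within = NULL) {
  a <- cls_a$data == class_value & !is.na(cls_a$data)
  b <- cls_b$data == class_value & !is.na(cls_b$data)
  if (!is.null(within)) {
    w <- mask_array(within)
    a <- a & w; b <- b & w
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Sphere(s) around the BTV peak(s)
#'
#' The BTV-proximal evaluation region: the union over BTV components of
#' spheres of the given radius centered at each component's TBR-max
#' location.
#'
#' @param btv a `btv_result` with at least one component.
#' @param radius_mm sphere radius in mm (default 50 = 5 cm).
#' @return a binary `image_volume`.
#' @export
proximity_sphere <- function(btv, radius_mm = 50) {
  stopifnot(inherits(btv, "btv_result"))
  if (nrow(btv$components) == 0) stop("empty BTV has no peak")
  vol <- btv$mask
  sh <- dim(vol$data)
  cc <- lapply(1:3, function(ax)
    vol$origin[ax] + (seq_len(sh[ax]) - 1) * vol$spacing[ax])
  out <- array(FALSE, dim = sh)
  for (k in seq_len(nrow(btv$components))) {
    cen <- as.numeric(btv$components[k, c("peak_x", "peak_y", "peak_z")])
    out <- out | sphere_mask(cc, cen, radius_mm)
  }
  image_volume(out * 1, spacing = vol$spacing, origin = vol$origin)
}

# 3D SSIM with Gaussian window (sigma in voxels), standard constants;
# returns the SSIM map.
ssim_map <- function(a, b, data_range, sigma_vox = 1.5, K1 = 0.01,
                     K2 = 0.03) {
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  sv <- rep(sigma_vox, 3)
  mu1 <- smooth_sigma_vox(a, sv)
  mu2 <- smooth_sigma_vox(b, sv)
  s11 <- smooth_sigma_vox(a * a, sv) - mu1^2
  s22 <- smooth_sigma_vox(b * b, sv) - mu2^2
  s12 <- smooth_sigma_vox(a * b, sv) - mu1 * mu2
  ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
}

#' Attenuation-map similarity (MAE and SSIM)
#'
#' MAE is the mean absolute mu difference over the head (cm^-1).  SSIM uses
#' a 3D Gaussian window (sigma 1.5 voxels, K1 = 0.01, K2 = 0.03) with the
#' data range set to the maximum of `a` over the head, averaged over head
#' voxels.
#'
#' @param a,b mu-maps on one grid (`a` is the reference).
#' @param head binary head mask.
#' @return list with `mae` and `ssim`.
#' @export
mu_similarity <- function(a, b, head) {
  stopifnot(is_image_volume(a), is_image_volume(b))
  check_same_grid(a, b, "mu-maps")
  h <- mask_array(head, ref = a, what = "head mask")
  if (!any(h)) stop("head mask is empty")
  mae <- mean(abs(a$data[h] - b$data[h]))
  R <- max(a$data[h])
  sm <- ssim_map(a$data, b$data, data_range = R)
  list(mae = mae, ssim = mean(sm[h]))
}

# 0-based indices of surface voxels (mask voxels with a 6-neighbour outside)
surface_indices <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  arrayInd(which(m & !interior), d) - 1L
}

#' Contour agreement: Dice and Hausdorff distance
#'
#' Hausdorff distance is the maximum over both directions of surface-voxel
#' distances in mm; `percentile` selects the robust variant (e.g. 95), the
#' maximum of the two directed percentiles.
#'
#' @param ref,test binary masks on one grid; `ref` must be nonempty, and an
#'   empty `test` is an error (the distance is undefined).
#' @param percentile optional percentile in (0, 100] for the robust
#'   Hausdorff.
#' @return list with `dice` and `hausdorff_mm`.
#' @export
contour_agreement <- function(ref, test, percentile = NULL) {
  mr <- mask_array(ref)
  mt <- mask_array(test, ref = ref, what = "contours")
  if (!any(mr)) stop("reference mask is empty")
  if (!any(mt)) stop("test mask is empty; Hausdorff distance undefined")
  spacing <- if (is_image_volume(ref)) ref$spacing else c(1, 1, 1)
  sr <- surface_indices(mr)
  st <- surface_indices(mt)
  d_rt <- .min_distances_mm(sr, st, spacing)
  d_tr <- .min_distances_mm(st, sr, spacing)
  hd <- if (is.null(percentile)) max(max(d_rt), max(d_tr))
        else max(quantile(d_rt, percentile / 100, names = FALSE),
                 quantile(d_tr, percentile / 100, names = FALSE))
  list(dice = dice(ref, test), hausdorff_mm = hd)
}

#' Shape deviation between two tumor contours
#'
#' Smooths the binary symmetric difference of the two masks with a Gaussian
#' (default 4 mm FWHM) and measures the volume where the smoothed image
#' reaches 1 (within a numerical tolerance `eps`).  Thin one-voxel contour
#' displacements smooth well below 1 and contribute nothing; focal
#' structures with a core deeper than the kernel reach 1 and are counted.
#'
#' A smoothed binary image approaches 1 asymptotically, so "reaches 1" needs
#' a plateau tolerance.  The default `eps = 0.02` separates the two regimes
#' cleanly at the default 4 mm FWHM: the core of a focal blob a few kernel
#' widths across smooths to > 0.99, while a one-voxel contour shell peaks
#' near 0.27.
#'
#' @param ref_btv,test_btv binary masks on one grid.
#' @param fwhm_mm Gaussian FWHM in mm (default 4).
#' @param level nominal threshold (default 1).
#' @param eps plateau tolerance for "= level" (default 0.02).
#' @return deviation-region volume in ml.
#' @export
shape_deviation <- function(ref_btv, test_btv, fwhm_mm = 4, level = 1,
                            eps = 0.02) {
  mr <- mask_array(ref_btv)
  mt <- mask_array(test_btv, ref = ref_btv, what = "contours")
  spacing <- if (is_image_volume(ref_btv)) ref_btv$spacing else c(1, 1, 1)
  D <- (mr != mt) * 1
  sigma_vox <- fwhm_mm * FWHM_TO_SIGMA / spacing
  S <- smooth_sigma_vox(D, sigma_vox)
  sum(S >= level - eps) * prod(spacing) / 1000
}

#' Distance between TBR peak locations
#'
#' Euclidean distance in mm between the two peaks, with the biopsy-planning
#' criterion flag (strictly below `criterion_mm`).
#'
#' @param ref,test `btv_result` objects with nonempty masks.
#' @param criterion_mm acceptance distance (default 10 mm).
#' @return list with `distance_mm` and `within_criterion`.
#' @export
peak_distance <- function(ref, test, criterion_mm = 10) {
  stopifnot(inherits(ref, "btv_result"), inherits(test, "btv_result"))
  if (is.null(ref$peak_location) || is.null(test$peak_location))
    stop("empty BTV has no peak location")
  d <- sqrt(sum((ref$peak_location - test$peak_location)^2))
  list(distance_mm = d, within_criterion = d < criterion_mm)
}

#' PET similarity within the brain (MAE, SSIM, PSNR)
#'
#' MAE and SSIM as in [mu_similarity()] but over the brain mask; PSNR is
#' `10 log10(R^2 / MSE)` with `R` the maximum of the reference PET over the
#' brain.  Identical images give `Inf` PSNR.
#'
#' @param ref_pet,test_pet PET `image_volume`s on one grid.
#' @param brain binary brain mask.
#' @return list with `mae`, `ssim`, `psnr`.
#' @export
pet_similarity <- function(ref_pet, test_pet, brain) {
  stopifnot(is_image_volume(ref_pet), is_image_volume(test_pet))
  check_same_grid(ref_pet, test_pet, "PET images")
  b <- mask_array(brain, ref = ref_pet, what = "brain mask")
  if (!any(b)) stop("brain mask is empty")
  dv <- ref_pet$data[b] - test_pet$data[b]
  mae <- mean(abs(dv))
  mse <- mean(dv^2)
  R <- max(ref_pet$data[b])
  psnr <- if (mse == 0) Inf else 10 * log10(R^2 / mse)
  sm <- ssim_map(ref_pet$data, test_pet$data, data_range = R)
  list(mae = mae, ssim = mean(sm[b]), psnr = psnr)
}

#' Regional relative percent differences
#'
#' Per region label: `100 (mean(test) - mean(ref)) / mean(ref)`.  Label 0 is
#' treated as background and skipped; labels whose reference mean is zero
#' are skipped with a warning.
#'
#' @param ref_pet,test_pet PET `image_volume`s on one grid.
#' @param regions integer label `image_volume`.
#' @return named numeric vector of percent differences.
#' @export
regional_differences <- function(ref_pet, test_pet, regions) {
  stopifnot(is_image_volume(ref_pet), is_image_volume(test_pet))
  check_same_grid(ref_pet, test_pet, "PET images")
  check_same_grid(ref_pet, regions, "regions")
  lab <- regions$data
  labels <- sort(unique(lab[lab != 0 & !is.na(lab)]))
  if (!length(labels)) stop("region label map is empty")
  out <- numeric(0)
  for (l in labels) {
    sel <- lab == l
    mr <- mean(ref_pet$data[sel])
    if (mr == 0) {
      warning("region ", l, " has zero reference mean; skipped")
      next
    }
    out[as.character(l)] <- 100 * (mean(test_pet$data[sel]) - mr) / mr
  }
  out
}
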