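#' Superimpose a fallback mu-map outside a field-of-view mask
#'
#' Regions not covered by the reference CT field of view are filled from a
#' fallback attenuation map so that all methods share coverage.
#'
#' @param test_mu mu-map under evaluation.
#' @param fallback_mu mu-map supplying values outside the FOV.
#' @param fov binary field-of-view mask.
#' @return an `image_volume`: `test_mu` inside the FOV, `fallback_mu`
#'   outside.
#' @export
apply_fov_superimposition <- function(test_mu, fallback_mu, fov) {
  stopifnot(is_image_volume(test_mu), is_image_volume(fallback_mu))
  check_same_grid(test_mu, fallback_mu, "mu-maps")
  f <- mask_array(fov, ref = test_mu, what = "fov mask")
  out <- test_mu
  out$data <- ifelse(f, test_mu$data, fallback_mu$data)
  dim(out$data) <- dim(test_mu$data)
  out
}

#' Mean activity in a background ROI
#'
#' The per-method normalization constant: each AC method's PET image gets
#' its own background mean from the same ROI.
#'
#' @param pet PET `image_volume`.
#' @param roi binary background-ROI mask.
#' @return scalar mean activity over the ROI.
#' @export
compute_background_mean <- function(pet, roi) {
  stopifnot(is_image_volume(pet))
  r <- mask_array(roi, ref = pet, what = "background ROI")
  if (!any(r)) stop("background ROI is empty")
  mean(pet$data[r])
}

# lexicographic (z, y, x) tie-break among candidate linear indices
peak_index <- function(tbr, cand_idx) {
  vals <- tbr[cand_idx]
  best <- cand_idx[vals == max(vals)]
  if (length(best) > 1L) {
    d <- dim(tbr)
    ai <- arrayInd(best, d)
    best <- best[order(ai[, 3], ai[, 2], ai[, 1])][1L]
  }
  best
}

#' Delineate the biological tumor volume (BTV)
#'
#' Computes the TBR image (`pet / background_mean`), applies the brain mask
#' (excluding extracerebral uptake) and any exclusion masks (physiological
#' structures), keeps voxels with TBR strictly above the threshold, labels
#' 26-connected components, and records the TBR peak (ties broken by lowest
#' (z, y, x) position).
#'
#' @param pet PET `image_volume`.
#' @param background_mean positive normalization constant.
#' @param brain binary brain mask.
#' @param exclusions list of binary exclusion masks.
#' @param threshold TBR isocontour threshold (default 1.6, strict `>`).
#' @return a `btv_result`: binary mask, `volume_ml`, `threshold`,
#'   `background_mean`, per-component table (voxels, peak location/value),
#'   overall `peak_location` (mm), `peak_value`, `peak_index`.
#' @export
delineate_btv <- function(pet, background_mean, brain, exclusions = list(),
                          threshold = 1.6) {
  stopifnot(is_image_volume(pet))
  if (!is.numeric(background_mean) || background_mean <= 0)
    stop("background_mean must be positive")
  b <- mask_array(brain, ref = pet, what = "brain mask")
  if (!any(b)) stop("brain mask is empty")
  tbr <- pet$data / background_mean
  sel <- (tbr > threshold) & b
  for (ex in exclusions) sel <- sel & !mask_array(ex, ref = pet, "exclusion")
  lab <- .cc_label_26(as.logical(sel), as.integer(dim(sel)))
  ncomp <- max(lab)
  comp <- if (ncomp > 0) {
    rows <- lapply(seq_len(ncomp), function(k) {
      idx <- which(lab == k)
      pk <- peak_index(tbr, idx)
      loc <- voxel_to_mm(pet, arrayInd(pk, dim(tbr)))
      data.frame(component = k, voxels = length(idx),
                 peak_x = loc[1], peak_y = loc[2], peak_z = loc[3],
                 peak_tbr = tbr[pk])
    })
    do.call(rbind, rows)
  } else {
    data.frame(component = integer(), voxels = integer(), peak_x = numeric(),
               peak_y = numeric(), peak_z = numeric(), peak_tbr = numeric())
  }
  vox_ml <- voxel_volume_ml(pet)
  idx_all <- which(sel)
  pk_idx <- if (length(idx_all)) peak_index(tbr, idx_all) else NA_integer_
  structure(list(
    mask = image_volume((lab > 0) * 1, spacing = pet$spacing,
                        origin = pet$origin),
    labels = image_volume(lab * 1, spacing = pet$spacing, origin = pet$origin),
    volume_ml = sum(sel) * vox_ml,
    threshold = threshold,
    background_mean = background_mean,
    components = comp,
    peak_index = pk_idx,
    peak_location = if (length(idx_all))
      drop(voxel_to_mm(pet, arrayInd(pk_idx, dim(tbr)))) else NULL,
    peak_value = if (length(idx_all)) tbr[pk_idx] else NA_real_,
    tbr = image_volume(tbr, spacing = pet$spacing, origin = pet$origin)),
    class = "btv_result")
}

#' @export
print.btv_result <- function(x, ...) {
  cat("<btv_result> ", format(x$volume_ml, digits = 4), " ml in ",
      nrow(x$components), " component(s); TBR > ", x$threshold,
      "; TBRmax ", format(x$peak_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' BTV inclusion rule
#'
#' Only studies whose reference-method BTV is strictly above the minimum
#' volume enter the PET evaluation.
#'
#' @param btv a `btv_result` computed with the reference AC method.
#' @param min_ml inclusion threshold in ml (default 1, strict `>`).
#' @return logical.
#' @export
btv_inclusion <- function(btv, min_ml = 1) {
  stopifnot(inherits(btv, "btv_result"))
  btv$volume_ml > min_ml
}
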