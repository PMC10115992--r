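#' Construct a 3D/4D image volume
#'
#' The common container for mu-maps (cm^-1), PET activity (kBq/ml), binary
#' masks, and 4D dynamic series.  Physical coordinates follow
#' `origin + (index - 1) * spacing` with 1-based voxel indices, all in mm.
#'
#' @param data numeric 3D array, or 4D array for a dynamic series.
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm, all strictly positive.
#' @param origin physical position of voxel (1,1,1) in mm.
#' @param frame_info for 4D data, a list with one `c(start_s, duration_s)`
#'   per frame.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         frame_info = NULL) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("expected 3D/4D array, got ", paste(dim(data), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L)
    stop("spacing must have 3 components")
  bad <- which(!is.finite(spacing) | spacing <= 0)
  if (length(bad))
    stop("non-positive voxel spacing on axis ", paste(c("x", "y", "z")[bad],
         collapse = ", "))
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have 3 components")
  if (length(dim(data)) == 4L) {
    if (is.null(frame_info))
      stop("4D data requires frame_info (one (start_s, duration_s) per frame)")
    if (length(frame_info) != dim(data)[4L])
      stop("frame_info length (", length(frame_info),
           ") does not match number of frames (", dim(data)[4L], ")")
    durs <- vapply(frame_info, function(f) as.numeric(f[2L]), 0)
    if (any(durs <= 0)) stop("frame durations must be positive")
  } else if (!is.null(frame_info)) {
    stop("frame_info supplied for 3D data")
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame_info = frame_info),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_volume> ", paste(d, collapse = " x "),
      " | spacing ", paste(format(x$spacing), collapse = " x "), " mm",
      if (!is.null(x$frame_info)) paste0(" | ", length(x$frame_info), " frames"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Test whether a volume is binary-valued
#'
#' @param x an `image_volume` (or plain array).
#' @return `TRUE` if every voxel is 0 or 1.
#' @export
is_mask <- function(x) {
  v <- if (is_image_volume(x)) x$data else x
  all(v %in% c(0, 1))
}

# extract a logical 3D array from a mask given as image_volume or array
mask_array <- function(m, ref = NULL, what = "mask") {
  a <- if (is_image_volume(m)) m$data else m
  if (!is.null(ref)) check_same_grid(ref, m, what)
  if (!all(a %in% c(0, 1)))
    stop(what, " is not binary ({0,1}-valued)")
  array(a != 0, dim = dim(a))
}

check_same_grid <- function(a, b, what = "volumes") {
  da <- if (is_image_volume(a)) dim(a$data)[1:3] else dim(a)[1:3]
  db <- if (is_image_volume(b)) dim(b$data)[1:3] else dim(b)[1:3]
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid mismatch for ", what, ": ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (is_image_volume(a) && is_image_volume(b) &&
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("spacing mismatch for ", what)
  invisible(TRUE)
}

#' Voxel volume in milliliters
#'
#' @param vol an `image_volume`.
#' @return `dx * dy * dz / 1000` (mm^3 to ml).
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot(is_image_volume(vol))
  prod(vol$spacing) / 1000
}

#' Physical coordinates (mm) of voxel indices
#'
#' @param vol an `image_volume`.
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

frame_sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 image.  4D images require a JSON timing sidecar
#' (`<basename>.json` with field `frames` holding `[start_s, duration_s]`
#' pairs) to become a dynamic series.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!(nd %in% c(3L, 4L)))
    stop("expected 3D/4D image, got ", nd, "D: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  bad <- which(!is.finite(pd) | pd <= 0)
  if (length(bad))
    stop("non-positive voxel spacing on axis ",
         paste(c("x", "y", "z")[bad], collapse = ", "), " in ", path)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  frame_info <- NULL
  if (nd == 4L) {
    sc <- frame_sidecar_path(path)
    if (!file.exists(sc))
      stop("4D image requires a timing sidecar: ", sc)
    fr <- jsonlite::fromJSON(sc, simplifyMatrix = FALSE)$frames
    frame_info <- lapply(fr, as.numeric)
  }
  arr <- array(as.numeric(img), dim = dim(img))
  image_volume(arr, spacing = pd, origin = origin, frame_info = frame_info)
}

#' Write a NIfTI volume
#'
#' Writes float32 data with spacing and origin in the qform; 4D dynamic
#' series also get a JSON timing sidecar.
#'
#' @param vol an `image_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(vol$frame_info)) {
    jsonlite::write_json(list(frames = lapply(vol$frame_info, as.numeric)),
                         frame_sidecar_path(path), auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}

# reflective (mirror, edge duplicated) index vector of length n + 2r
reflect_idx <- function(n, r) {
  idx <- seq_len(n + 2L * r) - r
  # reflect repeatedly until within range (handles r >= n)
  repeat {
    lo <- idx < 1L
    hi <- idx > n
    if (!any(lo) && !any(hi)) break
    idx[lo] <- 1L - idx[lo]
    idx[hi] <- 2L * n + 1L - idx[hi]
  }
  idx
}

# 1D Gaussian convolution along axis `ax` of 3D array, sigma in voxels,
# reflective boundary.  Returns the filtered array.
conv_gauss_axis <- function(arr, sigma, ax) {
  if (sigma <= 0) return(arr)
  n <- dim(arr)[ax]
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  idx <- reflect_idx(n, r)
  # band matrix folding padded positions back to source rows
  B <- matrix(0, n, n + 2L * r)
  B[cbind(rep(seq_len(n), each = 2L * r + 1L),
          as.vector(t(outer(seq_len(n), seq(0L, 2L * r), `+`))))] <-
    rep(w, times = n)
  W <- matrix(0, n, n)
  for (j in seq_len(n + 2L * r)) W[, idx[j]] <- W[, idx[j]] + B[, j]
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  out <- W %*% matrix(a, nrow = d[1])
  dim(out) <- d
  aperm(out, order(perm))
}

smooth_sigma_vox <- function(arr, sigma_vox) {
  for (ax in 1:3) arr <- conv_gauss_axis(arr, sigma_vox[ax], ax)
  arr
}

#' Gaussian smoothing with FWHM in mm
#'
#' Separable Gaussian filter; per-axis sigma is `fwhm / (2 sqrt(2 ln 2))` in
#' mm, converted to voxel units by the spacing.  Boundaries are handled by
#' mirror reflection so constants are preserved exactly.
#'
#' @param vol an `image_volume` (3D).
#' @param fwhm full width at half maximum in mm (scalar, > 0).
#' @return the smoothed `image_volume` on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  stopifnot(is_image_volume(vol))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("fwhm must be a positive scalar (mm)")
  sigma_vox <- fwhm * FWHM_TO_SIGMA / vol$spacing
  out <- vol
  out$data <- smooth_sigma_vox(vol$data, sigma_vox)
  out
}

resample_common <- function(moving, reference) {
  # fractional 0-based moving-grid coordinates of reference voxel centers
  lapply(1:3, function(ax) {
    X <- reference$origin[ax] +
      (seq_len(dim(reference$data)[ax]) - 1) * reference$spacing[ax]
    (X - moving$origin[ax]) / moving$spacing[ax]
  })
}

overlap_warning <- function(fidx, dm) {
  inside <- mapply(function(f, n) any(f > -0.5 & f < n - 0.5), fidx, dm)
  if (!all(inside))
    warning("moving and reference grids do not overlap; zero-filling")
}

#' Nearest-neighbour resampling onto a reference grid
#'
#' Intended for masks and label maps.  Voxels outside the moving volume's
#' extent are zero-filled (with a warning when there is no overlap at all).
#'
#' @param moving `image_volume` to resample.
#' @param reference `image_volume` defining the target grid.
#' @return an `image_volume` on the reference grid.
#' @export
resample_nearest <- function(moving, reference) {
  stopifnot(is_image_volume(moving), is_image_volume(reference))
  f <- resample_common(moving, reference)
  dm <- dim(moving$data)[1:3]
  overlap_warning(f, dm)
  ii <- lapply(1:3, function(ax) as.integer(round(f[[ax]])) + 1L)
  dr <- vapply(1:3, function(ax) length(f[[ax]]), 0L)
  IX <- array(ii[[1]], dim = dr)
  IY <- array(rep(ii[[2]], each = dr[1]), dim = dr)
  IZ <- array(rep(ii[[3]], each = dr[1] * dr[2]), dim = dr)
  ok <- IX >= 1L & IX <= dm[1] & IY >= 1L & IY <= dm[2] & IZ >= 1L & IZ <= dm[3]
  out <- array(0, dim = dr)
  out[ok] <- moving$data[cbind(IX[ok], IY[ok], IZ[ok])]
  image_volume(out, spacing = reference$spacing, origin = reference$origin)
}

#' Trilinear resampling onto a reference grid
#'
#' The continuous-image counterpart of [resample_nearest()]; outside-extent
#' voxels are zero-filled.
#'
#' @inheritParams resample_nearest
#' @return an `image_volume` on the reference grid.
#' @export
resample_linear <- function(moving, reference) {
  stopifnot(is_image_volume(moving), is_image_volume(reference))
  f <- resample_common(moving, reference)
  dm <- dim(moving$data)[1:3]
  overlap_warning(f, dm)
  dr <- vapply(1:3, function(ax) length(f[[ax]]), 0L)
  FX <- array(f[[1]], dim = dr)
  FY <- array(rep(f[[2]], each = dr[1]), dim = dr)
  FZ <- array(rep(f[[3]], each = dr[1] * dr[2]), dim = dr)
  out <- array(0, dim = dr)
  X0 <- floor(FX); Y0 <- floor(FY); Z0 <- floor(FZ)
  WX <- FX - X0; WY <- FY - Y0; WZ <- FZ - Z0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    IX <- as.integer(X0) + dx + 1L
    IY <- as.integer(Y0) + dy + 1L
    IZ <- as.integer(Z0) + dz + 1L
    w <- (if (dx) WX else 1 - WX) * (if (dy) WY else 1 - WY) *
         (if (dz) WZ else 1 - WZ)
    ok <- IX >= 1L & IX <= dm[1] & IY >= 1L & IY <= dm[2] &
          IZ >= 1L & IZ <= dm[3] & w > 0
    if (any(ok))
      out[ok] <- out[ok] + w[ok] * moving$data[cbind(IX[ok], IY[ok], IZ[ok])]
  }
  image_volume(out, spacing = reference$spacing, origin = reference$origin)
}
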