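#' Declarative specification of a digital head phantom
#'
#' The phantom is a piecewise-constant head model on an axis-aligned grid:
#' an outer scalp layer (tissue), a skull shell (bone), and an interior brain
#' compartment, all nested ellipsoids centered at the physical origin.
#' Spherical lesions and physiological hot foci carry configurable
#' tumor-to-background ratios (TBR); spherical air cavities model
#' post-surgical pneumocephalus or sinuses.
#'
#' Default attenuation coefficients are standard 511 keV values: tissue
#' 0.096 cm^-1 and bone 0.151 cm^-1, inside the tissue (0.05-0.1 cm^-1) and
#' bone (> 0.1 cm^-1) classification bounds used for map evaluation.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing in mm.
#' @param head_semi_axes outer head ellipsoid semi-axes (mm).
#' @param scalp_mm scalp (extracranial tissue) thickness in mm.
#' @param skull_mm skull shell thickness in mm.
#' @param brain_margin_mm gap between inner skull surface and brain mask.
#' @param air_cavities list of `list(center = c(x,y,z) mm, radius = mm)`.
#' @param lesions list of `list(center, radius, tbr, edge_mm)`; must lie
#'   inside the brain.  `edge_mm` (default 0) adds a linear activity falloff
#'   from the lesion TBR at `radius` to background at `radius + edge_mm`,
#'   emulating infiltrative margins; with the default hard edge the true
#'   tumor volume is exactly the discretized sphere.
#' @param foci physiological hot foci, same form as `lesions`.
#' @param background_kbq background (healthy brain) activity in kBq/ml.
#' @param extracerebral_frac extracerebral tissue activity as a fraction of
#'   background.
#' @param noise_sd Gaussian noise s.d. as a fraction of background activity.
#' @param mu_tissue,mu_bone attenuation coefficients (cm^-1).
#' @param tbr_threshold isocontour threshold defining the true tumor volume.
#' @param seed integer seed fixing every stochastic draw.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         spacing = c(2, 2, 2),
                         head_semi_axes = c(70, 85, 75),
                         scalp_mm = 4,
                         skull_mm = 6,
                         brain_margin_mm = 2,
                         air_cavities = list(),
                         lesions = list(list(center = c(25, 20, 10),
                                             radius = 12, tbr = 2.5)),
                         foci = list(),
                         background_kbq = 2.5,
                         extracerebral_frac = 0.25,
                         noise_sd = 0.05,
                         mu_tissue = 0.096,
                         mu_bone = 0.151,
                         tbr_threshold = 1.6,
                         seed = 1L) {
  for (l in c(lesions, foci)) {
    if (l$radius <= 0) stop("lesion/focus radii must be positive")
    if (is.null(l$tbr) || l$tbr <= 0) stop("lesion/focus TBR must be positive")
  }
  if (!(mu_tissue >= 0.05 && mu_tissue <= 0.1))
    stop("mu_tissue must lie in the tissue class bounds [0.05, 0.1] cm^-1")
  if (mu_bone <= 0.1) stop("mu_bone must exceed the bone class bound 0.1 cm^-1")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 head_semi_axes = head_semi_axes, scalp_mm = scalp_mm,
                 skull_mm = skull_mm, brain_margin_mm = brain_margin_mm,
                 air_cavities = air_cavities, lesions = lesions, foci = foci,
                 background_kbq = background_kbq,
                 extracerebral_frac = extracerebral_frac,
                 noise_sd = noise_sd, mu_tissue = mu_tissue,
                 mu_bone = mu_bone, tbr_threshold = tbr_threshold,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinate grids centered so the head center is at (0,0,0)
phantom_coords <- function(shape, spacing) {
  lapply(1:3, function(ax)
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * spacing[ax])
}

# squared normalized ellipsoid radius field for semi-axes ax3
ellipsoid_field <- function(cc, semi) {
  outer(outer((cc[[1]] / semi[1])^2, (cc[[2]] / semi[2])^2, `+`),
        (cc[[3]] / semi[3])^2, `+`)
}

sphere_mask <- function(cc, center, radius) {
  outer(outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, `+`),
        (cc[[3]] - center[3])^2, `+`) <= radius^2
}

MU_CLASS_AIR <- 0L
MU_CLASS_TISSUE <- 1L
MU_CLASS_BONE <- 2L

#' Build a digital head phantom
#'
#' Deterministic given the spec (including its seed).  Produces the label
#' map, true mu-map, brain/head masks, a background ROI, per-octant region
#' labels, the true activity image (with optional Gaussian noise), and the
#' true tumor mask per lesion (noiseless TBR above the threshold).
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; sp <- spec$spacing
  origin <- -(sh - 1) / 2 * sp
  cc <- phantom_coords(sh, sp)
  a <- spec$head_semi_axes
  head <- ellipsoid_field(cc, a) <= 1
  skull_outer <- ellipsoid_field(cc, a - spec$scalp_mm) <= 1
  skull_inner <- ellipsoid_field(cc, a - spec$scalp_mm - spec$skull_mm) <= 1
  brain <- ellipsoid_field(
    cc, a - spec$scalp_mm - spec$skull_mm - spec$brain_margin_mm) <= 1

  label <- array(MU_CLASS_AIR, dim = sh)
  label[head] <- MU_CLASS_TISSUE
  label[skull_outer & !skull_inner] <- MU_CLASS_BONE
  for (cav in spec$air_cavities)
    label[sphere_mask(cc, cav$center, cav$radius)] <- MU_CLASS_AIR

  mu <- array(0, dim = sh)
  mu[label == MU_CLASS_TISSUE] <- spec$mu_tissue
  mu[label == MU_CLASS_BONE] <- spec$mu_bone

  brain <- brain & label == MU_CLASS_TISSUE

  # activity: background in brain, reduced extracerebral tissue, lesions/foci
  act <- array(0, dim = sh)
  B <- spec$background_kbq
  act[label == MU_CLASS_TISSUE] <- spec$extracerebral_frac * B
  act[brain] <- B
  blob_tbr <- function(l) {
    w <- if (is.null(l$edge_mm)) 0 else l$edge_mm
    outer_m <- sphere_mask(cc, l$center, l$radius + w)
    if (any(outer_m & !brain))
      stop("lesion/focus at (", paste(l$center, collapse = ", "),
           ") extends outside the brain compartment")
    if (w == 0) {
      act[outer_m] <<- l$tbr * B
    } else {
      idx <- which(outer_m)
      ai <- arrayInd(idx, sh)
      r <- sqrt((cc[[1]][ai[, 1]] - l$center[1])^2 +
                (cc[[2]][ai[, 2]] - l$center[2])^2 +
                (cc[[3]][ai[, 3]] - l$center[3])^2)
      f <- pmin(1, pmax(0, (l$radius + w - r) / w))
      act[idx] <<- pmax(act[idx], (1 + (l$tbr - 1) * f) * B)
    }
    invisible(NULL)
  }
  for (l in c(spec$lesions, spec$foci)) blob_tbr(l)
  focus_mask <- array(FALSE, dim = sh)
  for (l in spec$foci)
    focus_mask <- focus_mask | sphere_mask(cc, l$center, l$radius)
  act_true <- act
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    act <- act + rnorm(length(act), sd = spec$noise_sd * B)
    act[!head] <- 0
  }

  # true tumor masks from the noiseless TBR image (lesions only, not foci)
  btv_true <- lapply(spec$lesions, function(l) {
    w <- if (is.null(l$edge_mm)) 0 else l$edge_mm
    m <- sphere_mask(cc, l$center, l$radius + w)
    m & (act_true / B > spec$tbr_threshold) & brain
  })

  # per-lobe octant region labels within the brain
  sx <- array(rep(cc[[1]] > 0, times = prod(sh[2:3])), dim = sh)
  sy <- array(rep(rep(cc[[2]] > 0, each = sh[1]), times = sh[3]), dim = sh)
  sz <- array(rep(cc[[3]] > 0, each = prod(sh[1:2])), dim = sh)
  regions <- array(0L, dim = sh)
  regions[brain] <- 1L + sx[brain] + 2L * sy[brain] + 4L * sz[brain]

  vol <- function(x) image_volume(x * 1, spacing = sp, origin = origin)
  ph <- structure(list(
    spec = spec,
    label = vol(label),
    mu = vol(mu),
    head = vol(head),
    brain = vol(brain),
    focus_mask = vol(focus_mask),
    regions = vol(regions),
    activity = vol(act),
    activity_true = vol(act_true),
    btv_true = lapply(btv_true, vol),
    coords = cc), class = "phantom")
  ph$background_roi <- phantom_background_roi(ph)
  ph
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> grid", paste(x$spec$shape, collapse = "x"), "@",
      paste(x$spec$spacing, collapse = "x"), "mm;",
      length(x$spec$lesions), "lesion(s),",
      length(x$spec$foci), "focus/foci, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Background ROI in normal-appearing tissue
#'
#' Emulates the manual background-region workflow: a crescent-shaped band of
#' healthy brain in the hemisphere contralateral to the first lesion, in an
#' axial slab above the phantom's insula level, at a safe distance from every
#' lesion and focus, trimmed to a target volume.
#'
#' @param phantom a `phantom`.
#' @param volume_ml target ROI volume (ml).
#' @param slab_frac axial slab as fractions of the brain's z-extent.
#' @param min_dist_mm minimum distance from any lesion/focus center minus its
#'   radius.
#' @return a binary `image_volume`.
#' @export
phantom_background_roi <- function(phantom, volume_ml = 10,
                                   slab_frac = c(0.55, 0.8),
                                   min_dist_mm = 15) {
  spec <- phantom$spec
  cc <- phantom$coords
  sh <- spec$shape
  brain <- phantom$brain$data != 0
  zr <- range(cc[[3]][apply(brain, 3, any)])
  zlo <- zr[1] + slab_frac[1] * diff(zr)
  zhi <- zr[1] + slab_frac[2] * diff(zr)
  Z <- array(rep(cc[[3]], each = prod(sh[1:2])), dim = sh)
  X <- array(rep(cc[[1]], times = prod(sh[2:3])), dim = sh)
  lesx <- if (length(spec$lesions)) spec$lesions[[1]]$center[1] else 1
  contra <- if (lesx >= 0) X < 0 else X > 0
  elig <- brain & contra & Z >= zlo & Z <= zhi
  for (l in c(spec$lesions, spec$foci)) {
    keep <- !sphere_mask(cc, l$center, l$radius + min_dist_mm)
    elig <- elig & keep
  }
  idx <- which(elig)
  if (!length(idx)) stop("no eligible background-ROI voxels")
  # outermost radial band first gives a crescent along the brain surface
  r2 <- (X[idx])^2 + (array(rep(rep(cc[[2]], each = sh[1]),
                                times = sh[3]), dim = sh)[idx])^2
  k <- min(length(idx), max(1L, round(volume_ml / (prod(spec$spacing) / 1000))))
  sel <- idx[order(-r2, idx)][seq_len(k)]
  roi <- array(0, dim = sh)
  roi[sel] <- 1
  image_volume(roi, spacing = spec$spacing, origin = phantom$mu$origin)
}

#' Specify a mu-map artifact
#'
#' @param kind one of `"false_bone_patch"`, `"metal_void"`,
#'   `"air_filled_as_water"`, `"missing_skull_flap"`, `"registration_shift"`.
#' @param center artifact center (mm); unused for `registration_shift`.
#' @param radius artifact radius (mm); unused for `registration_shift`.
#' @param shift translation vector (mm) for `registration_shift`.
#' @return an `artifact_spec` list.
#' @export
artifact_spec <- function(kind, center = c(0, 0, 0), radius = 10,
                          shift = c(0, 0, 0)) {
  kinds <- c("false_bone_patch", "metal_void", "air_filled_as_water",
             "missing_skull_flap", "registration_shift")
  if (!(is.character(kind) && length(kind) == 1L && kind %in% kinds))
    stop("unknown artifact kind: ", paste(kind, collapse = ", "))
  if (kind != "registration_shift" && radius <= 0)
    stop("artifact radius must be positive")
  structure(list(kind = kind, center = as.numeric(center),
                 radius = as.numeric(radius), shift = as.numeric(shift)),
            class = "artifact_spec")
}

#' Inject attenuation-map artifacts
#'
#' Perturbs the phantom's true mu-map with the surgical/metal artifact
#' taxonomy: false bone along an implant, metal-induced signal void (mu = 0),
#' an air cavity filled with soft-tissue attenuation (the pneumocephalus
#' failure mode), a skull flap replaced by tissue, or a rigid translation of
#' the whole map.
#'
#' @param phantom a `phantom`.
#' @param artifacts list of [artifact_spec()] objects.
#' @return the perturbed mu-map as an `image_volume`.
#' @export
perturb_mu_map <- function(phantom, artifacts = list()) {
  stopifnot(inherits(phantom, "phantom"))
  mu <- phantom$mu
  spec <- phantom$spec
  cc <- phantom$coords
  label <- phantom$label$data
  head <- phantom$head$data != 0
  for (a in artifacts) {
    if (!inherits(a, "artifact_spec")) stop("artifacts must be artifact_spec")
    if (a$kind == "registration_shift") {
      sh_vox <- round(a$shift / spec$spacing)
      mu$data <- shift_array(mu$data, as.integer(sh_vox))
      next
    }
    region <- sphere_mask(cc, a$center, a$radius)
    sel <- switch(a$kind,
      false_bone_patch = region & head,
      metal_void = region & head,
      air_filled_as_water = region & head & label == MU_CLASS_AIR,
      missing_skull_flap = region & label == MU_CLASS_BONE)
    mu$data[sel] <- switch(a$kind,
      false_bone_patch = spec$mu_bone,
      metal_void = 0,
      air_filled_as_water = spec$mu_tissue,
      missing_skull_flap = spec$mu_tissue)
  }
  mu
}

# integer-voxel translation with zero fill
shift_array <- function(arr, sh_vox) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- list()
  for (ax in 1:3) {
    s <- sh_vox[ax]
    if (abs(s) >= d[ax]) return(out)
    src[[ax]] <- seq_len(d[ax] - abs(s)) + max(0L, -s)
    dst[[ax]] <- seq_len(d[ax] - abs(s)) + max(0L, s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' First-order attenuation-bias field
#'
#' For each voxel, the mean over `n_angles` evenly spaced in-plane line
#' directions of `exp` of the line integral of `mu_alt - mu_ref` along the
#' full-grid line through the voxel.  This is the first-order effect of
#' reconstructing with a wrong mu-map: corrected activity scales with the
#' ratio of attenuation factors along lines of response.
#'
#' @param mu_ref,mu_alt mu-maps (cm^-1) on one grid.
#' @param n_angles number of in-plane angles (>= 1).
#' @param step integral sampling step in mm; default half the smallest
#'   spacing.
#' @return the bias field as an `image_volume` (1 where the maps agree).
#' @export
ac_bias_field <- function(mu_ref, mu_alt, n_angles = 8L, step = NULL) {
  stopifnot(is_image_volume(mu_ref), is_image_volume(mu_alt))
  check_same_grid(mu_ref, mu_alt, "mu-maps")
  if (n_angles < 1) stop("n_angles must be >= 1")
  if (is.null(step)) step <- min(mu_ref$spacing) / 2
  dmu <- mu_alt$data - mu_ref$data
  out <- mu_ref
  if (max(abs(dmu)) == 0) {
    out$data <- array(1, dim = dim(dmu))
    return(out)
  }
  out$data <- .ray_bias_field(dmu, as.integer(dim(dmu)),
                              as.numeric(mu_ref$spacing),
                              as.integer(n_angles), as.numeric(step))
  out
}

#' Propagate a mu-map error into PET activity
#'
#' Multiplies the activity image by [ac_bias_field()]; stands in for a full
#' reconstruction with the alternative mu-map.
#'
#' @param activity PET activity `image_volume`.
#' @inheritParams ac_bias_field
#' @return the biased activity `image_volume`.
#' @export
apply_ac_bias <- function(activity, mu_ref, mu_alt, n_angles = 8L,
                          step = NULL) {
  stopifnot(is_image_volume(activity))
  check_same_grid(activity, mu_ref, "activity vs mu-map")
  bias <- ac_bias_field(mu_ref, mu_alt, n_angles = n_angles, step = step)
  out <- activity
  out$data <- activity$data * bias$data
  out
}

#' Dynamic frame scheme
#'
#' The 14-frame 40-min scheme: five 1-min, five 3-min, and four 5-min
#' frames.
#'
#' @return data.frame with `start_min`, `duration_min`, `mid_min`.
#' @export
frame_scheme <- function() {
  dur <- c(rep(1, 5), rep(3, 5), rep(5, 4))
  start <- cumsum(c(0, dur[-length(dur)]))
  data.frame(start_min = start, duration_min = dur, mid_min = start + dur / 2)
}

# lesion time course relative to its static TBR: uptake ramp to 1.0 at
# 10 min, then pattern-specific late behaviour
tac_shape_factor <- function(t_min, pattern, late_change = 0.2) {
  f <- ifelse(t_min < 10, 0.6 + 0.4 * t_min / 10, 1)
  late <- pmax(0, t_min - 10) / 30
  switch(pattern,
         increasing = f * (1 + late_change * late),
         plateau = f,
         decreasing = f * (1 - late_change * late),
         stop("unknown TAC pattern: ", pattern))
}

#' Synthesize a dynamic PET series for a phantom
#'
#' Background activity is constant over time; lesion (and focus) activity
#' follows an uptake ramp to 10 min and then the requested late pattern:
#' `increasing` ramps +20% from 10 to 40 min, `plateau` stays constant, and
#' `decreasing` ramps -20% from the 10-min peak (fractions configurable).
#'
#' @param phantom a `phantom`.
#' @param pattern `"increasing"`, `"plateau"`, or `"decreasing"`.
#' @param late_change late-phase fractional change (default 0.2).
#' @param noise_sd per-frame Gaussian noise s.d. as a fraction of
#'   background; default 0 (noise-free frames).
#' @return a 4D `image_volume` with `frame_info` in seconds.
#' @export
make_dynamic_frames <- function(phantom, pattern = c("plateau", "increasing",
                                                     "decreasing"),
                                late_change = 0.2, noise_sd = 0) {
  stopifnot(inherits(phantom, "phantom"))
  pattern <- match.arg(pattern)
  spec <- phantom$spec
  fs <- frame_scheme()
  sh <- spec$shape
  base <- phantom$activity_true$data
  lesion <- array(FALSE, dim = sh)
  for (m in phantom$btv_true) lesion <- lesion | (m$data != 0)
  lesion <- lesion | (phantom$focus_mask$data != 0)
  arr <- array(0, dim = c(sh, nrow(fs)))
  if (noise_sd > 0) set.seed(spec$seed + 1L)
  head <- phantom$head$data != 0
  for (i in seq_len(nrow(fs))) {
    f <- tac_shape_factor(fs$mid_min[i], pattern, late_change)
    fr <- base
    fr[lesion] <- base[lesion] * f
    if (noise_sd > 0) {
      fr <- fr + rnorm(length(fr), sd = noise_sd * spec$background_kbq)
      fr[!head] <- 0
    }
    arr[, , , i] <- fr
  }
  image_volume(arr, spacing = spec$spacing, origin = phantom$mu$origin,
               frame_info = lapply(seq_len(nrow(fs)), function(i)
                 c(fs$start_min[i] * 60, fs$duration_min[i] * 60)))
}
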