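#' Pipeline run configuration
#'
#' Bundles every protocol parameter with its default: TBR isocontour
#' threshold 1.6, BTV inclusion above 1 ml, the paired acceptance criteria,
#' 50 mm BTV-proximity sphere, 4 mm shape-deviation FWHM, 10 mm peak
#' criterion, and the phantom grid / bias-model settings used by
#' [run_phantom_study()].
#'
#' @param threshold TBR isocontour threshold.
#' @param min_btv_ml BTV inclusion bound (ml, strict).
#' @param criteria an [acceptance_criteria()] object.
#' @param proximity_radius_mm BTV-proximal sphere radius (mm).
#' @param shape_fwhm_mm shape-deviation Gaussian FWHM (mm).
#' @param peak_criterion_mm peak-location acceptance distance (mm).
#' @param n_angles in-plane angles for the attenuation-bias model.
#' @param grid_shape,grid_spacing phantom grid (voxels, mm).
#' @param noise_sd phantom activity noise (fraction of background).
#' @param followup_frac fraction of phantom subjects with a follow-up scan.
#' @param small_lesion_frac fraction of phantom subjects whose lesion stays
#'   below the inclusion bound.
#' @return a `run_config` list.
#' @export
run_config <- function(threshold = 1.6, min_btv_ml = 1,
                       criteria = acceptance_criteria(),
                       proximity_radius_mm = 50, shape_fwhm_mm = 4,
                       peak_criterion_mm = 10, n_angles = 8L,
                       grid_shape = c(96, 96, 96), grid_spacing = c(2, 2, 2),
                       noise_sd = 0.05, followup_frac = 0.3,
                       small_lesion_frac = 0.15) {
  stopifnot(threshold > 0, min_btv_ml > 0, proximity_radius_mm > 0,
            shape_fwhm_mm > 0, peak_criterion_mm > 0, n_angles >= 1,
            inherits(criteria, "acceptance_criteria"))
  structure(list(threshold = threshold, min_btv_ml = min_btv_ml,
                 criteria = criteria,
                 proximity_radius_mm = proximity_radius_mm,
                 shape_fwhm_mm = shape_fwhm_mm,
                 peak_criterion_mm = peak_criterion_mm,
                 n_angles = as.integer(n_angles),
                 grid_shape = as.integer(grid_shape),
                 grid_spacing = as.numeric(grid_spacing),
                 noise_sd = noise_sd, followup_frac = followup_frac,
                 small_lesion_frac = small_lesion_frac),
            class = "run_config")
}

# rbind data.frames with differing columns (missing filled with NA)
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

# ---- shared per-study evaluation core -------------------------------------

# Evaluate one study: reference mu/PET against named lists of test mu/PET.
# Returns one row per method with mu-map metrics always, PET metrics when
# the reference BTV passes the inclusion rule.
evaluate_study <- function(mu_ref, mu_tests, pet_ref, pet_tests, brain, head,
                           roi, exclusions = list(), regions = NULL,
                           config = run_config()) {
  cls_ref <- classify_mu(mu_ref, head)
  bg_ref <- compute_background_mean(pet_ref, roi)
  btv_ref <- delineate_btv(pet_ref, bg_ref, brain, exclusions,
                           threshold = config$threshold)
  included <- btv_inclusion(btv_ref, config$min_btv_ml)
  prox <- if (included && nrow(btv_ref$components) > 0)
    proximity_sphere(btv_ref, config$proximity_radius_mm) else NULL
  clin_ref <- clinical_metrics(pet_ref, btv_ref$tbr, btv_ref)

  rows <- list()
  details <- list()
  for (nm in names(mu_tests)) {
    cls_t <- classify_mu(mu_tests[[nm]], head)
    sim <- mu_similarity(mu_ref, mu_tests[[nm]], head)
    row <- data.frame(
      method = nm,
      dice_tissue = class_dice(cls_ref, cls_t, MU_CLASS_TISSUE),
      dice_bone = class_dice(cls_ref, cls_t, MU_CLASS_BONE),
      dice_tissue_prox = if (!is.null(prox))
        class_dice(cls_ref, cls_t, MU_CLASS_TISSUE, within = prox)
        else NA_real_,
      dice_bone_prox = if (!is.null(prox))
        class_dice(cls_ref, cls_t, MU_CLASS_BONE, within = prox)
        else NA_real_,
      mu_mae = sim$mae, mu_ssim = sim$ssim,
      ref_btv_ml = btv_ref$volume_ml, included = included)
    det <- list(btv_ref = btv_ref, clin_ref = clin_ref)
    if (included) {
      pet_t <- pet_tests[[nm]]
      bg_t <- compute_background_mean(pet_t, roi)
      btv_t <- delineate_btv(pet_t, bg_t, brain, exclusions,
                             threshold = config$threshold)
      clin_t <- clinical_metrics(pet_t, btv_t$tbr, btv_t)
      diffs <- metric_differences(clin_ref, clin_t)
      acc <- acceptance_check(diffs, config$criteria)
      psim <- pet_similarity(pet_ref, pet_t, brain)
      dd <- function(m, col) diffs[diffs$metric == m, col]
      row$tbr_mean_ref <- clin_ref$tbr_mean
      row$tbr_mean_test <- clin_t$tbr_mean
      row$tbr_max_ref <- clin_ref$tbr_max
      row$tbr_max_test <- clin_t$tbr_max
      row$btv_ml_test <- clin_t$btv_ml
      row$tbr_mean_abs <- dd("tbr_mean", "abs_diff")
      row$tbr_mean_rel <- dd("tbr_mean", "rel_diff_pct")
      row$tbr_max_abs <- dd("tbr_max", "abs_diff")
      row$tbr_max_rel <- dd("tbr_max", "rel_diff_pct")
      row$btv_abs <- dd("btv_ml", "abs_diff")
      row$btv_rel <- dd("btv_ml", "rel_diff_pct")
      row$exceeds <- acc$exceeds
      row$class_ref <- tissue_classification(clin_ref)
      row$class_test <- tissue_classification(clin_t)
      nonempty <- !clin_t$empty
      if (nonempty) {
        ca <- contour_agreement(btv_ref$mask, btv_t$mask)
        pk <- peak_distance(btv_ref, btv_t,
                            criterion_mm = config$peak_criterion_mm)
        row$contour_dice <- ca$dice
        row$hausdorff_mm <- ca$hausdorff_mm
        row$peak_dist_mm <- pk$distance_mm
        row$peak_within <- pk$within_criterion
      } else {
        row$contour_dice <- 0
        row$hausdorff_mm <- NA_real_
        row$peak_dist_mm <- NA_real_
        row$peak_within <- NA
      }
      row$shape_dev_ml <- shape_deviation(btv_ref$mask, btv_t$mask,
                                          fwhm_mm = config$shape_fwhm_mm)
      row$pet_mae <- psim$mae
      row$pet_ssim <- psim$ssim
      row$pet_psnr <- psim$psnr
      brain_pct <- regional_differences(
        pet_ref, pet_t,
        image_volume(mask_array(brain) * 1L, spacing = pet_ref$spacing,
                     origin = pet_ref$origin))
      row$brain_pct <- unname(brain_pct["1"])
      if (!is.null(regions)) {
        rp <- regional_differences(pet_ref, pet_t, regions)
        row$max_region_pct <- max(abs(rp))
      }
      det$btv_test <- btv_t
      det$clin_test <- clin_t
      det$diffs <- diffs
      det$acceptance <- acc
    }
    rows[[nm]] <- row
    details[[nm]] <- det
  }
  list(rows = do.call(rbind, rows), details = details,
       btv_ref = btv_ref, clin_ref = clin_ref, included = included)
}

# ---- phantom cohort generation --------------------------------------------

study_seed <- function(seed, i) as.integer((seed %% 100000L) * 10007L + i)

# draw one subject's lesion/cavity/focus layout; deterministic retries keep
# blobs inside the brain and apart from each other
draw_subject_spec <- function(i, seed, config, followup = FALSE,
                              base = NULL) {
  set.seed(study_seed(seed, i) + if (followup) 500000L else 0L)
  if (followup) {
    les <- base$lesions[[1]]
    les$radius <- les$radius * runif(1, 0.8, 1.25)
    les$tbr <- les$tbr * runif(1, 0.96, 1.06)
    out <- base
    out$lesions <- list(les)
    out$seed <- base$seed + 1L
    return(out)
  }
  small <- runif(1) < config$small_lesion_frac
  brain_semi <- c(70, 85, 75) - 12
  edge <- 4
  for (try in 1:50) {
    radius <- if (small) runif(1, 2.6, 3.2) else runif(1, 8, 14)
    tbr <- if (small) runif(1, 1.9, 2.4) else runif(1, 1.9, 3.4)
    center <- c(sample(c(-1, 1), 1) * runif(1, 14, 26),
                runif(1, -18, 18), runif(1, -12, 12))
    inside <- sum(((abs(center) + radius + edge + 4) / brain_semi)^2) <= 1
    has_cavity <- runif(1) < 0.25
    cavity <- if (has_cavity)
      list(center = c(0, 48, 5), radius = 7) else NULL
    has_focus <- runif(1) < 0.3
    focus <- if (has_focus)
      list(center = c(0, -44, -6), radius = 4, tbr = 2.2) else NULL
    clear <- TRUE
    for (b in c(list(cavity), list(focus))) {
      if (is.null(b)) next
      gap <- sqrt(sum((center - b$center)^2)) - radius - edge - b$radius
      if (gap < 4) clear <- FALSE
    }
    if (inside && clear) break
  }
  list(shape = config$grid_shape, spacing = config$grid_spacing,
       air_cavities = if (is.null(cavity)) list() else list(cavity),
       lesions = list(list(center = center, radius = radius, tbr = tbr,
                           edge_mm = edge)),
       foci = if (is.null(focus)) list() else list(focus),
       noise_sd = config$noise_sd,
       seed = study_seed(seed, i))
}

#' Default test-method artifact plans for the phantom study
#'
#' Two emulated MR-AC methods: `mrac_cnn` is high fidelity (occasionally a
#' small false-bone patch far from the lesion), `mrac_atlas` is
#' artifact-prone (registration shift, a skull-base false-bone patch, and
#' the water-filled-air failure when the subject has an air cavity).
#'
#' @return named list of functions `(spec_args, subject, seed) -> list of
#'   [artifact_spec()]`.
#' @export
default_method_plans <- function() {
  list(
    mrac_cnn = function(spec_args, subject, seed) {
      set.seed(study_seed(seed, subject) + 900000L)
      if (runif(1) < 0.1)
        list(artifact_spec("false_bone_patch", center = c(-45, -55, 0),
                           radius = 5))
      else list()
    },
    mrac_atlas = function(spec_args, subject, seed) {
      set.seed(study_seed(seed, subject) + 910000L)
      arts <- list(
        artifact_spec("registration_shift",
                      shift = c(runif(1, 1, 3), runif(1, -2, 2), 0)),
        artifact_spec("false_bone_patch", center = c(0, -50, -40),
                      radius = runif(1, 6, 10)))
      for (cav in spec_args$air_cavities)
        arts <- c(arts, list(artifact_spec("air_filled_as_water",
                                           center = cav$center,
                                           radius = cav$radius + 2)))
      arts
    })
}

#' Run the end-to-end phantom study
#'
#' Generates a cohort of digital head phantoms (a fraction with follow-up
#' scans and sub-inclusion lesions), perturbs each subject's mu-map per test
#' method, propagates the mu-map error into the PET image with the
#' first-order bias model, and runs delineation, map/PET metrics, acceptance
#' classification, longitudinal concordance, and the log-scale agreement
#' table.  Fully deterministic given `seed`.
#'
#' @param n_subjects number of phantom subjects.
#' @param seed integer seed for every stochastic draw.
#' @param config a [run_config()].
#' @param methods named list of artifact-plan functions (default
#'   [default_method_plans()]).
#' @param artifact_plan optional override: `artifact_plan[[method]][[i]]`
#'   is the artifact list for subject `i` (missing entries fall back to
#'   `methods`).
#' @param subject_plan optional override: `subject_plan[[i]]` is a list of
#'   [phantom_spec()] arguments for subject `i` (grid/spacing/noise/seed
#'   default from `config` and the run seed; missing entries are drawn
#'   randomly).
#' @param out_dir optional directory: writes `studies.csv`,
#'   `agreement_table.csv`, `summary.json`, and per-study NIfTI volumes plus
#'   `manifest.csv` for [run_evaluation()].
#' @param verbose log per-study progress via `message()`.
#' @return a `study_report` list: `studies` (one row per study x method),
#'   `longitudinal`, `agreement` (Bland-Altman table per method x metric),
#'   `summary`, `config`.
#' @export
run_phantom_study <- function(n_subjects = 20, seed = 1,
                              config = run_config(), methods = NULL,
                              artifact_plan = NULL, subject_plan = NULL,
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"), n_subjects >= 1)
  if (is.null(methods)) methods <- default_method_plans()
  say <- function(...) if (verbose) message(...)
  all_rows <- list()
  longi <- list()
  pairs <- list()   # per method/metric accumulation for agreement stats
  manifest <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(study_seed(seed, i) + 700000L)
    has_fu <- runif(1) < config$followup_frac
    base_args <- if (!is.null(subject_plan) && length(subject_plan) >= i &&
                     !is.null(subject_plan[[i]])) {
      utils::modifyList(list(shape = config$grid_shape,
                             spacing = config$grid_spacing,
                             noise_sd = config$noise_sd,
                             seed = study_seed(seed, i)), subject_plan[[i]])
    } else draw_subject_spec(i, seed, config)
    tps <- list(baseline = base_args)
    if (has_fu)
      tps$followup <- draw_subject_spec(i, seed, config, followup = TRUE,
                                        base = base_args)
    changes <- list()
    for (tp in names(tps)) {
      args <- tps[[tp]]
      spec <- do.call(phantom_spec, args)
      ph <- make_phantom(spec)
      arts <- lapply(names(methods), function(nm) {
        ov <- artifact_plan[[nm]]
        if (!is.null(ov) && length(ov) >= i && !is.null(ov[[i]])) ov[[i]]
        else methods[[nm]](args, i, seed)
      })
      names(arts) <- names(methods)
      mu_tests <- lapply(arts, function(a) perturb_mu_map(ph, a))
      pet_tests <- lapply(mu_tests, function(mt)
        apply_ac_bias(ph$activity, ph$mu, mt, n_angles = config$n_angles))
      ev <- evaluate_study(ph$mu, mu_tests, ph$activity, pet_tests,
                           brain = ph$brain, head = ph$head,
                           roi = ph$background_roi,
                           exclusions = if (any(ph$focus_mask$data != 0))
                             list(ph$focus_mask) else list(),
                           regions = ph$regions, config = config)
      rows <- ev$rows
      rows <- cbind(data.frame(patient = i,
                               study = paste0("P", i, "_", tp),
                               timepoint = tp), rows)
      all_rows[[length(all_rows) + 1L]] <- rows
      say("subject ", i, " ", tp, ": ref BTV ",
          format(ev$btv_ref$volume_ml, digits = 3), " ml, included = ",
          ev$included)
      changes[[tp]] <- ev
      if (ev$included) {
        for (nm in names(methods)) {
          ct <- ev$details[[nm]]$clin_test
          if (is.null(ct) || ct$empty) next
          for (metric in CLINICAL_METRIC_NAMES) {
            key <- paste(nm, metric, sep = ":")
            pairs[[key]] <- rbind(pairs[[key]],
              data.frame(subject = i, ref = ev$clin_ref[[metric]],
                         test = ct[[metric]]))
          }
        }
      }
      if (!is.null(out_dir))
        manifest[[length(manifest) + 1L]] <-
          export_study(ph, mu_tests, pet_tests, i, tp, out_dir)
    }
    if (has_fu && changes$baseline$included && changes$followup$included) {
      ref_ch <- longitudinal_change(changes$baseline$clin_ref,
                                    changes$followup$clin_ref,
                                    criteria = config$criteria)
      for (nm in names(methods)) {
        cb <- changes$baseline$details[[nm]]$clin_test
        cf <- changes$followup$details[[nm]]$clin_test
        if (is.null(cb) || is.null(cf) || cb$empty || cf$empty) next
        ch <- longitudinal_change(cb, cf, ref_change = ref_ch,
                                  criteria = config$criteria)
        ch <- cbind(data.frame(patient = i, method = nm), ch)
        longi[[length(longi) + 1L]] <- ch
      }
    }
  }
  studies <- rbind_fill(all_rows)
  rownames(studies) <- NULL
  pairs <- Filter(function(p) nrow(p) >= 2 &&
                    length(unique(p$subject)) >= 2, pairs)
  agreement <- if (length(pairs)) {
    samples <- lapply(pairs, function(p)
      paired_sample(p$ref, p$test, subject = p$subject))
    bland_altman_table(samples)
  } else NULL
  longitudinal <- if (length(longi)) do.call(rbind, longi) else NULL
  inc <- studies[studies$included & !duplicated(studies$study), ]
  summary <- list(
    n_subjects = n_subjects,
    n_studies = length(unique(studies$study)),
    n_included = nrow(inc),
    n_excluded_small_btv = length(unique(studies$study)) - nrow(inc),
    exceeding = lapply(split(studies[studies$included, ],
                             studies$method[studies$included]),
                       function(s) sum(s$exceeds, na.rm = TRUE)),
    peak_within_rate = lapply(split(studies[studies$included, ],
                                    studies$method[studies$included]),
                              function(s) mean(s$peak_within, na.rm = TRUE)),
    seed = seed)
  report <- structure(list(studies = studies, longitudinal = longitudinal,
                           agreement = agreement, summary = summary,
                           config = config), class = "study_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    mf <- do.call(rbind, manifest)
    write.csv(mf, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$summary
  cat("<study_report> ", s$n_studies, " studies from ", s$n_subjects,
      " subjects; ", s$n_included, " included (BTV rule)\n", sep = "")
  for (nm in names(s$exceeding))
    cat(sprintf("  %s: %d exceeding criteria; peak within %.0f%%\n", nm,
                s$exceeding[[nm]], 100 * s$peak_within_rate[[nm]]))
  invisible(x)
}

export_study <- function(ph, mu_tests, pet_tests, i, tp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- file.path(out_dir, paste0("P", i, "_", tp))
  wv <- function(vol, suffix) {
    p <- paste0(pfx, "_", suffix, ".nii.gz")
    write_volume(vol, p)
    p
  }
  base <- data.frame(
    patient = i, study = paste0("P", i, "_", tp), timepoint = tp,
    brain = wv(ph$brain, "brain"), head = wv(ph$head, "head"),
    background_roi = wv(ph$background_roi, "bgroi"),
    exclusion = if (any(ph$focus_mask$data != 0))
      wv(ph$focus_mask, "excl") else "",
    regions = wv(ph$regions, "regions"))
  ref <- cbind(base, data.frame(method = "reference", reference = TRUE,
                                mu = wv(ph$mu, "mu_ref"),
                                pet = wv(ph$activity, "pet_ref")))
  rows <- list(ref)
  for (nm in names(mu_tests)) {
    rows[[nm]] <- cbind(base, data.frame(
      method = nm, reference = FALSE,
      mu = wv(mu_tests[[nm]], paste0("mu_", nm)),
      pet = wv(pet_tests[[nm]], paste0("pet_", nm))))
  }
  do.call(rbind, rows)
}

#' Run the evaluation pipeline on a study manifest
#'
#' The user-data twin of [run_phantom_study()]: a manifest (data.frame or
#' CSV path) lists, per study, one reference row and one row per test
#' method with NIfTI paths for mu-map, PET, and masks.  All volumes are
#' resampled onto the reference mu-map grid at entry (nearest-neighbour for
#' masks and labels, trilinear for PET and mu).  Studies whose reference
#' BTV fails the inclusion rule appear in the mu-map metrics only.
#'
#' @param manifest data.frame or CSV path with columns `patient`, `study`,
#'   `timepoint`, `method`, `reference` (logical), `mu`, `pet`, `brain`,
#'   `background_roi`, and optionally `head`, `exclusion`
#'   (semicolon-separated), `regions`, `fov`, `fallback_mu`,
#'   `artifact_category`.
#' @param config a [run_config()].
#' @param out_dir optional report output directory.
#' @param verbose log per-study progress.
#' @return a `study_report` (see [run_phantom_study()]).
#' @export
run_evaluation <- function(manifest, config = run_config(), out_dir = NULL,
                           verbose = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(inherits(config, "run_config"))
  need <- c("patient", "study", "method", "reference", "mu", "pet", "brain",
            "background_roi")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ",
                         paste(miss, collapse = ", "))
  say <- function(...) if (verbose) message(...)
  all_rows <- list()
  pairs <- list()
  longi_src <- list()
  for (sid in unique(manifest$study)) {
    rows_m <- manifest[manifest$study == sid, , drop = FALSE]
    refrow <- rows_m[as.logical(rows_m$reference), , drop = FALSE]
    if (nrow(refrow) != 1L)
      stop("study ", sid, " needs exactly one reference row")
    tests <- rows_m[!as.logical(rows_m$reference), , drop = FALSE]
    rd <- function(path) {
      if (!file.exists(path)) stop("missing file: ", path)
      read_volume(path)
    }
    mu_ref <- rd(refrow$mu)
    onto <- function(vol, kind) {
      if (identical(dim(vol$data)[1:3], dim(mu_ref$data)[1:3]) &&
          max(abs(vol$spacing - mu_ref$spacing)) < 1e-9 &&
          max(abs(vol$origin - mu_ref$origin)) < 1e-6) return(vol)
      if (kind == "mask") resample_nearest(vol, mu_ref)
      else resample_linear(vol, mu_ref)
    }
    pet_ref <- onto(rd(refrow$pet), "image")
    brain <- onto(rd(refrow$brain), "mask")
    head <- if (!is.null(refrow$head) && nzchar(refrow$head))
      onto(rd(refrow$head), "mask") else brain
    roi <- onto(rd(refrow$background_roi), "mask")
    exclusions <- list()
    if (!is.null(refrow$exclusion) && nzchar(refrow$exclusion))
      exclusions <- lapply(strsplit(refrow$exclusion, ";")[[1]],
                           function(p) onto(rd(p), "mask"))
    regions <- if (!is.null(refrow$regions) && nzchar(refrow$regions))
      onto(rd(refrow$regions), "mask") else NULL
    if (!is.null(regions)) regions$data <- round(regions$data)
    fov <- if (!is.null(refrow$fov) && nzchar(refrow$fov))
      onto(rd(refrow$fov), "mask") else NULL
    fallback <- if (!is.null(refrow$fallback_mu) &&
                    nzchar(refrow$fallback_mu))
      onto(rd(refrow$fallback_mu), "image") else NULL
    mu_tests <- list(); pet_tests <- list()
    for (k in seq_len(nrow(tests))) {
      nm <- tests$method[k]
      mt <- onto(rd(tests$mu[k]), "image")
      if (!is.null(fov) && !is.null(fallback)) {
        say("study ", sid, "/", nm, ": FOV superimposition applied")
        mt <- apply_fov_superimposition(mt, fallback, fov)
      }
      mu_tests[[nm]] <- mt
      pet_tests[[nm]] <- onto(rd(tests$pet[k]), "image")
    }
    ev <- evaluate_study(mu_ref, mu_tests, pet_ref, pet_tests, brain, head,
                         roi, exclusions, regions, config)
    say("study ", sid, ": ref BTV ",
        format(ev$btv_ref$volume_ml, digits = 3), " ml, included = ",
        ev$included)
    if (!ev$included)
      say("study ", sid, " excluded from PET evaluation (BTV <= ",
          config$min_btv_ml, " ml)")
    rows <- cbind(data.frame(patient = refrow$patient, study = sid,
                             timepoint = if (!is.null(refrow$timepoint))
                               refrow$timepoint else "baseline"), ev$rows)
    if (!is.null(refrow$artifact_category))
      rows$artifact_category <- refrow$artifact_category
    all_rows[[sid]] <- rows
    if (ev$included) {
      for (nm in names(mu_tests)) {
        ct <- ev$details[[nm]]$clin_test
        if (is.null(ct) || ct$empty) next
        for (metric in CLINICAL_METRIC_NAMES) {
          key <- paste(nm, metric, sep = ":")
          pairs[[key]] <- rbind(pairs[[key]],
            data.frame(subject = refrow$patient,
                       ref = ev$clin_ref[[metric]], test = ct[[metric]]))
        }
      }
      longi_src[[sid]] <- list(ev = ev, patient = refrow$patient,
                               timepoint = if (!is.null(refrow$timepoint))
                                 refrow$timepoint else "baseline")
    }
  }
  studies <- rbind_fill(all_rows)
  rownames(studies) <- NULL
  longi <- list()
  pats <- unique(vapply(longi_src, function(s) as.character(s$patient), ""))
  for (p in pats) {
    mine <- Filter(function(s) as.character(s$patient) == p, longi_src)
    tp <- vapply(mine, `[[`, "", "timepoint")
    if (!all(c("baseline", "followup") %in% tp)) next
    bl <- mine[[which(tp == "baseline")[1]]]$ev
    fu <- mine[[which(tp == "followup")[1]]]$ev
    ref_ch <- longitudinal_change(bl$clin_ref, fu$clin_ref,
                                  criteria = config$criteria)
    for (nm in names(bl$details)) {
      cb <- bl$details[[nm]]$clin_test
      cf <- fu$details[[nm]]$clin_test
      if (is.null(cb) || is.null(cf) || cb$empty || cf$empty) next
      ch <- longitudinal_change(cb, cf, ref_change = ref_ch,
                                criteria = config$criteria)
      longi[[length(longi) + 1L]] <-
        cbind(data.frame(patient = p, method = nm), ch)
    }
  }
  pairs <- Filter(function(p) nrow(p) >= 2 &&
                    length(unique(p$subject)) >= 2, pairs)
  agreement <- if (length(pairs))
    bland_altman_table(lapply(pairs, function(p)
      paired_sample(p$ref, p$test, subject = p$subject))) else NULL
  inc <- studies[studies$included & !duplicated(studies$study), ]
  summary <- list(
    n_studies = length(unique(studies$study)),
    n_included = nrow(inc),
    n_excluded_small_btv = length(unique(studies$study)) - nrow(inc),
    exceeding = lapply(split(studies[studies$included, ],
                             studies$method[studies$included]),
                       function(s) sum(s$exceeds, na.rm = TRUE)))
  report <- structure(list(studies = studies,
                           longitudinal = if (length(longi))
                             do.call(rbind, longi) else NULL,
                           agreement = agreement, summary = summary,
                           config = config), class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' Emits `studies.csv` (one row per study x method), `agreement_table.csv`,
#' `longitudinal.csv` when present, and `summary.json` with the full
#' configuration echoed for provenance.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$studies, file.path(out_dir, "studies.csv"),
            row.names = FALSE)
  if (!is.null(report$agreement))
    write.csv(report$agreement, file.path(out_dir, "agreement_table.csv"),
              row.names = FALSE)
  if (!is.null(report$longitudinal))
    write.csv(report$longitudinal, file.path(out_dir, "longitudinal.csv"),
              row.names = FALSE)
  cfg <- report$config
  cfg$criteria <- lapply(unclass(cfg$criteria), as.list)
  jsonlite::write_json(list(summary = report$summary,
                            config = unclass(cfg)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
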