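#' Clinical metrics within a BTV
#'
#' Mean and maximum SUV (activity concentration) and TBR over the BTV
#' voxels, plus the BTV size and peak location.  An empty BTV gives all-zero
#' metrics with `empty = TRUE`.
#'
#' @param pet PET `image_volume` (activity units).
#' @param tbr TBR `image_volume` on the same grid.
#' @param btv a `btv_result`.
#' @return a `clinical_metrics` list: `suv_mean`, `suv_max`, `tbr_mean`,
#'   `tbr_max`, `btv_ml`, `peak_location`, `empty`.
#' @export
clinical_metrics <- function(pet, tbr, btv) {
  stopifnot(is_image_volume(pet), is_image_volume(tbr),
            inherits(btv, "btv_result"))
  check_same_grid(pet, tbr, "PET vs TBR")
  m <- btv$mask$data != 0
  if (!any(m)) {
    return(structure(list(suv_mean = 0, suv_max = 0, tbr_mean = 0,
                          tbr_max = 0, btv_ml = 0, peak_location = NULL,
                          empty = TRUE), class = "clinical_metrics"))
  }
  structure(list(suv_mean = mean(pet$data[m]), suv_max = max(pet$data[m]),
                 tbr_mean = mean(tbr$data[m]), tbr_max = max(tbr$data[m]),
                 btv_ml = btv$volume_ml, peak_location = btv$peak_location,
                 empty = FALSE), class = "clinical_metrics")
}

#' @export
print.clinical_metrics <- function(x, ...) {
  cat(sprintf(
    "<clinical_metrics> TBRmean %.3f  TBRmax %.3f  BTV %.2f ml%s\n",
    x$tbr_mean, x$tbr_max, x$btv_ml, if (x$empty) "  (empty)" else ""))
  invisible(x)
}

CLINICAL_METRIC_NAMES <- c("tbr_mean", "tbr_max", "btv_ml")

#' Absolute and relative metric differences
#'
#' `abs = test - ref`; `rel = 100 (test - ref) / ref`.  A zero reference
#' with nonzero test leaves the relative difference `NA` and flags it.
#'
#' @param ref,test `clinical_metrics` objects.
#' @param metrics which metrics to difference (default TBRmean, TBRmax,
#'   BTV).
#' @return data.frame with `metric`, `ref`, `test`, `abs_diff`,
#'   `rel_diff_pct`, `rel_defined`.
#' @export
metric_differences <- function(ref, test, metrics = CLINICAL_METRIC_NAMES) {
  stopifnot(inherits(ref, "clinical_metrics"),
            inherits(test, "clinical_metrics"))
  rows <- lapply(metrics, function(m) {
    rv <- ref[[m]]; tv <- test[[m]]
    rel_ok <- rv != 0
    data.frame(metric = m, ref = rv, test = tv, abs_diff = tv - rv,
               rel_diff_pct = if (rel_ok) 100 * (tv - rv) / rv else NA_real_,
               rel_defined = rel_ok)
  })
  do.call(rbind, rows)
}

#' Clinical acceptance criteria
#'
#' Paired absolute + relative thresholds with OR-pass semantics: a metric is
#' acceptable when either its absolute difference or its relative difference
#' is within bound (a larger absolute difference is acceptable in large or
#' very active tumors).  Defaults: TBRmean +-0.05 or 5%, TBRmax +-0.1 or 5%,
#' BTV +-2 ml or 10%.
#'
#' @param tbr_mean,tbr_max,btv_ml each `c(abs_threshold, rel_threshold_pct)`.
#' @return an `acceptance_criteria` list.
#' @export
acceptance_criteria <- function(tbr_mean = c(0.05, 5), tbr_max = c(0.1, 5),
                                btv_ml = c(2, 10)) {
  cr <- list(tbr_mean = tbr_mean, tbr_max = tbr_max, btv_ml = btv_ml)
  for (m in names(cr)) {
    if (length(cr[[m]]) != 2L || any(cr[[m]] <= 0))
      stop("criteria for ", m, " must be two positive numbers (abs, rel%)")
    names(cr[[m]]) <- c("abs", "rel_pct")
  }
  structure(cr, class = "acceptance_criteria")
}

#' Check metric differences against acceptance criteria
#'
#' A metric passes iff `|abs_diff| <= abs_threshold` OR
#' `|rel_diff| <= rel_threshold`; the study exceeds the criteria iff any
#' metric fails both branches.
#'
#' @param diffs data.frame from [metric_differences()].
#' @param criteria an [acceptance_criteria()] object.
#' @return list with per-metric data.frame (`abs_pass`, `rel_pass`, `pass`)
#'   and scalar `exceeds`.
#' @export
acceptance_check <- function(diffs, criteria = acceptance_criteria()) {
  stopifnot(inherits(criteria, "acceptance_criteria"))
  diffs <- diffs[diffs$metric %in% names(criteria), , drop = FALSE]
  ap <- rp <- logical(nrow(diffs))
  for (i in seq_len(nrow(diffs))) {
    cr <- criteria[[diffs$metric[i]]]
    ap[i] <- abs(diffs$abs_diff[i]) <= cr[["abs"]]
    rp[i] <- !is.na(diffs$rel_diff_pct[i]) &&
      abs(diffs$rel_diff_pct[i]) <= cr[["rel_pct"]]
  }
  per <- cbind(diffs, abs_pass = ap, rel_pass = rp, pass = ap | rp)
  list(per_metric = per, exceeds = any(!per$pass))
}

#' Reactive / equivocal / tumor tissue classification
#'
#' TBR-band reading of a lesion: the equivocal band (TBRmax in [2.0, 2.4] or
#' TBRmean in [1.9, 2.1]) is carved out first; otherwise tumor when
#' TBRmax > 2.4 and TBRmean > 2.0, else reactive.
#'
#' @param m a `clinical_metrics` object (or list with `tbr_mean`,
#'   `tbr_max`).
#' @return one of `"reactive"`, `"equivocal"`, `"tumor"`.
#' @export
tissue_classification <- function(m) {
  tmax <- m$tbr_max; tmean <- m$tbr_mean
  if ((tmax >= 2.0 && tmax <= 2.4) || (tmean >= 1.9 && tmean <= 2.1))
    return("equivocal")
  if (tmax > 2.4 && tmean > 2.0) return("tumor")
  "reactive"
}

#' Longitudinal change and concordance with a reference change
#'
#' Absolute and percent change per metric between baseline and follow-up,
#' with direction (`up` / `down` / `stable`, dead-band on percent change).
#' Against a reference change, magnitude concordance reuses the acceptance
#' OR-semantics on the change differences (percentage points for the
#' relative branch), and direction concordance compares signs.
#'
#' @param baseline,followup `clinical_metrics` objects (baseline metrics
#'   must be positive).
#' @param ref_change optional `longitudinal_change` of the reference method.
#' @param criteria an [acceptance_criteria()] object.
#' @param stable_pct dead-band: `|percent change| < stable_pct` counts as
#'   stable (default 1).
#' @return a `longitudinal_change` data.frame; when `ref_change` is given,
#'   columns `magnitude_within` and `direction_concordant` are added.
#' @export
longitudinal_change <- function(baseline, followup, ref_change = NULL,
                                criteria = acceptance_criteria(),
                                stable_pct = 1) {
  for (m in CLINICAL_METRIC_NAMES)
    if (baseline[[m]] <= 0)
      stop("baseline ", m, " must be positive for percent change")
  rows <- lapply(CLINICAL_METRIC_NAMES, function(m) {
    ab <- followup[[m]] - baseline[[m]]
    pc <- 100 * ab / baseline[[m]]
    data.frame(metric = m, baseline = baseline[[m]],
               followup = followup[[m]], abs_change = ab,
               pct_change = pc,
               direction = if (abs(pc) < stable_pct) "stable"
                           else if (ab > 0) "up" else "down")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("longitudinal_change", class(out))
  if (!is.null(ref_change)) {
    stopifnot(inherits(ref_change, "longitudinal_change"))
    mw <- dc <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      m <- out$metric[i]
      r <- ref_change[ref_change$metric == m, ]
      cr <- criteria[[m]]
      mw[i] <- abs(out$pct_change[i] - r$pct_change) <= cr[["rel_pct"]] ||
        abs(out$abs_change[i] - r$abs_change) <= cr[["abs"]]
      dc[i] <- identical(out$direction[i], r$direction)
    }
    out$magnitude_within <- mw
    out$direction_concordant <- dc
  }
  out
}

#' Extract a time-activity curve (TAC)
#'
#' Per-frame mean activity over an ROI, with frame mid-times from the frame
#' timing.
#'
#' @param frames 4D dynamic `image_volume` with `frame_info`.
#' @param roi binary ROI mask (3D).
#' @return a `tac` data.frame with `mid_min` and `mean_activity`.
#' @export
tac_extract <- function(frames, roi) {
  stopifnot(is_image_volume(frames))
  if (is.null(frames$frame_info)) stop("dynamic series lacks frame timing")
  r <- which(mask_array(roi) != 0)
  if (!length(r)) stop("ROI is empty")
  d <- dim(frames$data)
  nf <- d[4]
  nvox <- prod(d[1:3])
  flat <- matrix(frames$data, nrow = nvox, ncol = nf)
  mids <- vapply(frames$frame_info, function(f) (f[1] + f[2] / 2) / 60, 0)
  out <- data.frame(mid_min = mids, mean_activity = colMeans(flat[r, ,
                    drop = FALSE]))
  class(out) <- c("tac", class(out))
  out
}

#' Relative absolute TAC difference
#'
#' Per-frame `100 |test - ref| / ref` plus its mean and s.d. across frames.
#'
#' @param test,ref `tac` objects on the same time grid.
#' @return list with `per_frame_pct`, `mean_pct`, `sd_pct`.
#' @export
tac_relative_abs_diff <- function(test, ref) {
  if (nrow(test) != nrow(ref) ||
      max(abs(test$mid_min - ref$mid_min)) > 1e-9)
    stop("TACs are not on the same time grid")
  if (any(ref$mean_activity <= 0)) stop("reference TAC must be positive")
  p <- 100 * abs(test$mean_activity - ref$mean_activity) / ref$mean_activity
  list(per_frame_pct = p, mean_pct = mean(p), sd_pct = sd(p))
}

#' Classify a TAC as increasing, plateau, or decreasing
#'
#' Least-squares slope of the late TAC (t >= `late_min`), normalized by the
#' late mean and expressed in %/min; slopes beyond `+-slope_pct_min` are
#' increasing/decreasing, else plateau.
#'
#' @param tac a `tac` object with at least 3 late points.
#' @param late_min start of the late phase in minutes (default 10).
#' @param slope_pct_min decision threshold in %/min (default 0.15).
#' @return list with `pattern` and `slope_pct_min`.
#' @export
tac_pattern <- function(tac, late_min = 10, slope_pct_min = 0.15) {
  late <- tac[tac$mid_min >= late_min, ]
  if (nrow(late) < 3) stop("need at least 3 TAC points after ", late_min,
                           " min")
  y <- 100 * late$mean_activity / mean(late$mean_activity)
  sl <- coef(lm(y ~ late$mid_min))[[2]]
  pattern <- if (sl > slope_pct_min) "increasing"
             else if (sl < -slope_pct_min) "decreasing"
             else "plateau"
  list(pattern = pattern, slope_pct_min = sl)
}
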