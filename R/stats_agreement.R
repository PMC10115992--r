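#' Coefficient of determination against a reference
#'
#' `R^2 = 1 - sum((ref - test)^2) / sum((ref - mean(ref))^2)`, the
#' regression-free goodness of recovery of the reference values.
#'
#' @param ref,test numeric vectors of equal length (>= 2); `ref` must not be
#'   constant.
#' @return scalar R^2 (can be negative for poor agreement).
#' @export
r2_score <- function(ref, test) {
  if (length(ref) != length(test)) stop("length mismatch")
  if (length(ref) < 2) stop("need at least 2 observations")
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) stop("reference values are constant; R^2 undefined")
  1 - sum((ref - test)^2) / ss_tot
}

#' Shapiro-Wilk normality test p-value
#'
#' Thin wrapper over [stats::shapiro.test()] (valid for 3 <= n <= 5000).
#'
#' @param x numeric vector.
#' @return the p-value.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  shapiro.test(x)$p.value
}

#' Build a paired sample for log-scale agreement analysis
#'
#' @param ref,test positive paired values (reference and test method).
#' @param subject subject identifiers grouping repeated scans; defaults to
#'   one scan per subject.
#' @param timepoint optional timepoint labels.
#' @return a `paired_sample` data.frame with the log-difference
#'   `d = log(test) - log(ref)`.
#' @export
paired_sample <- function(ref, test, subject = seq_along(ref),
                          timepoint = NULL) {
  if (length(ref) != length(test)) stop("length mismatch")
  if (any(ref <= 0) || any(test <= 0))
    stop("log-scale analysis requires strictly positive values")
  out <- data.frame(subject = as.character(subject), ref = ref, test = test,
                    d = log(test) - log(ref))
  if (!is.null(timepoint)) out$timepoint <- timepoint
  class(out) <- c("paired_sample", class(out))
  out
}

#' Paired t-test on the log scale
#'
#' One-sample two-sided t-test of `d = log(test) - log(ref)` against zero.
#' Zero variance of `d` (e.g. test identical to reference) returns `NA` with
#' a warning.
#'
#' @param sample a [paired_sample()].
#' @return the two-sided p-value.
#' @export
paired_t_log <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- sample$d
  if (length(d) < 2) stop("need at least 2 pairs")
  if (sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    warning("zero variance of log-differences; p-value undefined")
    return(NA_real_)
  }
  t.test(d)$p.value
}

# one-way ANOVA variance decomposition for repeated measures:
# total SD of d = sqrt(between-subject variance + within-subject variance),
# with the between component estimated from subject means.
repeated_measures_sd <- function(d, subject) {
  tab <- split(d, subject)
  k <- length(tab)
  m <- lengths(tab)
  N <- length(d)
  if (all(m == 1L)) return(list(sd_d = sd(d), n_subjects = k))
  dbar <- mean(d)
  means <- vapply(tab, mean, 0)
  ms_within <- sum(vapply(tab, function(x) sum((x - mean(x))^2), 0)) / (N - k)
  ms_between <- sum(m * (means - dbar)^2) / (k - 1)
  n0 <- (N^2 - sum(m^2)) / (N * (k - 1))
  var_between <- max(0, (ms_between - ms_within) / n0)
  list(sd_d = sqrt(var_between + ms_within), n_subjects = k)
}

#' Log-scale Bland-Altman agreement summary
#'
#' Mean difference, 95% CI, and 95% limits of agreement of
#' `d = log(test) - log(ref)`, exponentiated to percent differences on the
#' original scale: `100 (exp(dbar +- 1.96 SD_d / sqrt(n)) - 1)` for the CI
#' and `100 (exp(dbar +- 1.96 SD_d) - 1)` for the limits of agreement.  With
#' repeated scans per subject, `SD_d` uses the one-way ANOVA
#' (between-subject + within-subject) variance decomposition and the CI
#' denominator is the number of subjects.
#'
#' @param sample a [paired_sample()].
#' @return an `agreement_summary` list: `mean_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `loa_low_pct`, `loa_high_pct`, `p_value`, `n_obs`,
#'   `n_subjects`.
#' @export
agreement_summary <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- sample$d
  if (length(d) < 2) stop("need at least 2 observations")
  rm <- repeated_measures_sd(d, sample$subject)
  if (rm$n_subjects < 2) stop("CI undefined with a single subject")
  dbar <- mean(d)
  sdd <- rm$sd_d
  expct <- function(x) 100 * (exp(x) - 1)
  p <- suppressWarnings(paired_t_log(sample))
  structure(list(
    mean_pct = expct(dbar),
    ci_low_pct = expct(dbar - 1.96 * sdd / sqrt(rm$n_subjects)),
    ci_high_pct = expct(dbar + 1.96 * sdd / sqrt(rm$n_subjects)),
    loa_low_pct = expct(dbar - 1.96 * sdd),
    loa_high_pct = expct(dbar + 1.96 * sdd),
    p_value = p,
    n_obs = length(d),
    n_subjects = rm$n_subjects,
    mean_log = dbar, sd_log = sdd), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> mean %.2f%% (95%% CI %.2f to %.2f); LoA %.2f to %.2f; p %s; n=%d (%d subjects)\n",
    x$mean_pct, x$ci_low_pct, x$ci_high_pct, x$loa_low_pct, x$loa_high_pct,
    format.pval(x$p_value, digits = 3), x$n_obs, x$n_subjects))
  invisible(x)
}

#' Recover the mean percent difference from limits of agreement
#'
#' Algebraic inverse of the exponentiated limits-of-agreement formula: the
#' limits are `100 (exp(dbar +- 1.96 SD_d) - 1)`, so
#' `dbar = 0.5 log((1 + lo/100)(1 + hi/100))` and the mean percent
#' difference is `100 (exp(dbar) - 1)`.  Used as an internal-consistency
#' check of reported agreement tables.
#'
#' @param loa_low_pct,loa_high_pct limits of agreement in percent
#'   (`loa_low_pct > -100`).
#' @return the mean percent difference.
#' @export
invert_loa <- function(loa_low_pct, loa_high_pct) {
  if (any(loa_low_pct <= -100)) stop("lower limit must exceed -100%")
  dbar <- 0.5 * log((1 + loa_low_pct / 100) * (1 + loa_high_pct / 100))
  100 * (exp(dbar) - 1)
}

#' Bland-Altman agreement table across metrics
#'
#' One row per metric (and per method when the input is nested by method):
#' agreement summary fields plus the log-scale paired t-test p-value.  Rows
#' are ordered by the order of the input list; plot data (per-pair mean vs
#' percent difference) is attached as an attribute.
#'
#' @param samples named list of [paired_sample()] objects (names =
#'   metric/method labels).
#' @return data.frame with columns `metric`, `mean_pct`, `ci_low_pct`,
#'   `ci_high_pct`, `loa_low_pct`, `loa_high_pct`, `p_value`, `n_obs`,
#'   `n_subjects`; attribute `plot_data` holds per-observation points.
#' @export
bland_altman_table <- function(samples) {
  if (!length(samples)) stop("no samples supplied")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be a named list")
  rows <- lapply(names(samples), function(nm) {
    s <- agreement_summary(samples[[nm]])
    data.frame(metric = nm, mean_pct = s$mean_pct,
               ci_low_pct = s$ci_low_pct, ci_high_pct = s$ci_high_pct,
               loa_low_pct = s$loa_low_pct, loa_high_pct = s$loa_high_pct,
               p_value = s$p_value, n_obs = s$n_obs,
               n_subjects = s$n_subjects)
  })
  out <- do.call(rbind, rows)
  pd <- lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    data.frame(metric = nm, mean_value = (s$ref + s$test) / 2,
               diff_pct = 100 * (s$test / s$ref - 1))
  })
  attr(out, "plot_data") <- do.call(rbind, pd)
  out
}
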