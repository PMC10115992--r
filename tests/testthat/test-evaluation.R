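cm_fix <- function(tbr_mean, tbr_max, btv = 10, suv = 2) {
  structure(list(suv_mean = suv, suv_max = suv * 1.5, tbr_mean = tbr_mean,
                 tbr_max = tbr_max, btv_ml = btv,
                 peak_location = c(0, 0, 0), empty = FALSE),
            class = "clinical_metrics")
}

test_that("clinical metrics summarize the BTV voxels", {
  pet <- array(1, c(6, 6, 6)); pet[2, 2, 2] <- 5; pet[3, 3, 3] <- 4
  brain <- mk_vol(array(1, c(6, 6, 6)))
  btv <- delineate_btv(mk_vol(pet), 1, brain, threshold = 1.6)
  m <- clinical_metrics(mk_vol(pet), btv$tbr, btv)
  expect_equal(m$tbr_mean, 4.5)
  expect_equal(m$tbr_max, 5)
  expect_equal(m$btv_ml, 2 * 0.001)
  expect_false(m$empty)
  # constant uptake: mean equals max
  pet2 <- array(1, c(6, 6, 6)); pet2[2:3, 2, 2] <- 2.5
  btv2 <- delineate_btv(mk_vol(pet2), 1, brain, threshold = 1.6)
  m2 <- clinical_metrics(mk_vol(pet2), btv2$tbr, btv2)
  expect_equal(m2$tbr_mean, 2.5)
  expect_equal(m2$tbr_max, 2.5)
  # empty BTV flags out with zeroed metrics
  none <- delineate_btv(mk_vol(array(1, c(6, 6, 6))), 1, brain)
  m3 <- clinical_metrics(mk_vol(pet), none$tbr, none)
  expect_true(m3$empty)
  expect_equal(m3$tbr_max, 0)
})

test_that("metric differences reproduce the TBRmax worked example", {
  d <- metric_differences(cm_fix(1.8, 2.05), cm_fix(1.75, 1.87))
  row <- d[d$metric == "tbr_max", ]
  expect_equal(row$abs_diff, -0.18)
  expect_equal(round(row$rel_diff_pct), -9)
  expect_equal(row$rel_diff_pct, 100 * (1.87 - 2.05) / 2.05)
  z <- metric_differences(cm_fix(2, 2.5), cm_fix(2, 2.5))
  expect_true(all(z$abs_diff == 0) && all(z$rel_diff_pct == 0))
})

test_that("acceptance check uses OR-pass semantics per metric", {
  # worked case fails both branches of the TBRmax criterion
  d <- metric_differences(cm_fix(1.8, 2.05), cm_fix(1.8, 1.87))
  acc <- acceptance_check(d)
  row <- acc$per_metric[acc$per_metric$metric == "tbr_max", ]
  expect_false(row$abs_pass); expect_false(row$rel_pass); expect_false(row$pass)
  expect_true(acc$exceeds)
  # large tumor: +3 ml but only +4% passes via the relative branch
  d2 <- metric_differences(cm_fix(2, 2.5, btv = 75),
                           cm_fix(2, 2.5, btv = 78))
  acc2 <- acceptance_check(d2)
  r2 <- acc2$per_metric[acc2$per_metric$metric == "btv_ml", ]
  expect_false(r2$abs_pass); expect_true(r2$rel_pass); expect_true(r2$pass)
  # small tumor: +50% but only +1 ml passes via the absolute branch
  d3 <- metric_differences(cm_fix(2, 2.5, btv = 2), cm_fix(2, 2.5, btv = 3))
  acc3 <- acceptance_check(d3)
  r3 <- acc3$per_metric[acc3$per_metric$metric == "btv_ml", ]
  expect_true(r3$abs_pass); expect_false(r3$rel_pass); expect_true(r3$pass)
  expect_false(acc3$exceeds)
})

test_that("acceptance decisions are invariant to a common PET scale", {
  ph <- make_phantom(tiny_lesion_spec(n = 32, spacing = 2, radius = 8,
                                      noise_sd = 0.05, seed = 13))
  bg <- compute_background_mean(ph$activity, ph$background_roi)
  btv <- delineate_btv(ph$activity, bg, ph$brain)
  m1 <- clinical_metrics(ph$activity, btv$tbr, btv)
  sc <- ph$activity; sc$data <- sc$data * 4.2
  btv_s <- delineate_btv(sc, bg * 4.2, ph$brain)
  m2 <- clinical_metrics(sc, btv_s$tbr, btv_s)
  d <- metric_differences(m1, m2)
  tbr_rows <- d[d$metric %in% c("tbr_mean", "tbr_max", "btv_ml"), ]
  expect_true(all(abs(tbr_rows$abs_diff) < 1e-9))
  expect_false(acceptance_check(d)$exceeds)
})

test_that("tissue classification partitions the TBR plane with equivocal precedence", {
  expect_equal(tissue_classification(cm_fix(1.6, 1.7)), "reactive")
  expect_equal(tissue_classification(cm_fix(2.5, 3.0)), "tumor")
  expect_equal(tissue_classification(cm_fix(2.5, 2.2)), "equivocal")
  expect_equal(tissue_classification(cm_fix(2.0, 3.0)), "equivocal")
  expect_equal(tissue_classification(cm_fix(1.5, 3.0)), "reactive")
  # totality: every grid point maps to exactly one class
  for (tm in seq(1.0, 3.0, by = 0.1)) for (tx in seq(1.0, 3.6, by = 0.1)) {
    cl <- tissue_classification(cm_fix(tm, max(tm, tx)))
    expect_true(cl %in% c("reactive", "equivocal", "tumor"))
  }
})

test_that("longitudinal change reproduces the discordant-direction example", {
  # reference: BTV 5 -> 5.6 ml (increase); test: 9 -> 6 ml (3 ml decrease)
  ref <- longitudinal_change(cm_fix(2, 2.5, btv = 5),
                             cm_fix(2, 2.5, btv = 5.6))
  rrow <- ref[ref$metric == "btv_ml", ]
  expect_equal(rrow$abs_change, 0.6)
  expect_equal(rrow$direction, "up")
  tst <- longitudinal_change(cm_fix(2, 2.5, btv = 9),
                             cm_fix(2, 2.5, btv = 6), ref_change = ref)
  trow <- tst[tst$metric == "btv_ml", ]
  expect_equal(trow$abs_change, -3)
  expect_equal(trow$direction, "down")
  expect_false(trow$direction_concordant)
  # identical change is within limits and concordant
  same <- longitudinal_change(cm_fix(2, 2.5, btv = 5),
                              cm_fix(2, 2.5, btv = 5.6), ref_change = ref)
  expect_true(all(same$magnitude_within))
  expect_true(all(same$direction_concordant))
  expect_error(longitudinal_change(cm_fix(0, 2, btv = 5), cm_fix(2, 2.5)),
               "positive")
})

test_that("TAC extraction averages the ROI per frame at scheme mid-times", {
  ph <- make_phantom(tiny_lesion_spec(n = 20, spacing = 2, radius = 8))
  dyn <- make_dynamic_frames(ph, "plateau")
  tac <- tac_extract(dyn, ph$btv_true[[1]])
  expect_equal(nrow(tac), 14)
  expect_equal(tac$mid_min, frame_scheme()$mid_min)
  # single-voxel ROI equals that voxel's series
  one <- array(0, dim(ph$mu$data)); one[10, 10, 10] <- 1
  t1 <- tac_extract(dyn, mk_vol(one, c(2, 2, 2)))
  expect_equal(t1$mean_activity, as.numeric(dyn$data[10, 10, 10, ]))
  # constant frames give a constant TAC
  cd <- dyn; cd$data <- array(2.5, dim(dyn$data))
  expect_equal(unique(tac_extract(cd, ph$btv_true[[1]])$mean_activity), 2.5)
  nd <- dyn; nd$frame_info <- NULL
  expect_error(tac_extract(nd, ph$btv_true[[1]]), "timing")
})

test_that("relative absolute TAC difference is exact for scaled curves", {
  tac <- data.frame(mid_min = frame_scheme()$mid_min,
                    mean_activity = seq(2, 4, length.out = 14))
  class(tac) <- c("tac", class(tac))
  same <- tac_relative_abs_diff(tac, tac)
  expect_true(all(same$per_frame_pct == 0))
  up <- tac; up$mean_activity <- 1.02 * tac$mean_activity
  d <- tac_relative_abs_diff(up, tac)
  expect_equal(d$per_frame_pct, rep(2, 14), tolerance = 1e-12)
  expect_equal(d$mean_pct, 2, tolerance = 1e-12)
})

test_that("TAC pattern classification matches the generated shapes", {
  ph <- make_phantom(tiny_lesion_spec(n = 20, spacing = 2, radius = 8))
  lesion <- ph$btv_true[[1]]
  inc <- tac_extract(make_dynamic_frames(ph, "increasing"), lesion)
  pat <- tac_pattern(inc)
  expect_equal(pat$pattern, "increasing")
  expect_equal(pat$slope_pct_min, 0.2 / 30 * 100 / mean(
    1 + 0.2 * (inc$mid_min[inc$mid_min >= 10] - 10) / 30), tolerance = 0.01)
  expect_equal(tac_pattern(tac_extract(make_dynamic_frames(ph, "plateau"),
                                       lesion))$pattern, "plateau")
  dec <- tac_extract(make_dynamic_frames(ph, "decreasing"), lesion)
  expect_equal(tac_pattern(dec)$pattern, "decreasing")
  # time reversal flips the label
  rev_tac <- inc; rev_tac$mean_activity <- rev(inc$mean_activity)
  expect_equal(tac_pattern(rev_tac)$pattern, "decreasing")
  few <- inc[inc$mid_min < 11, ]
  expect_error(tac_pattern(few), "at least 3")
})
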