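test_that("phantom generation is deterministic given the spec seed", {
  sp <- phantom_spec(shape = c(32, 32, 32), spacing = c(4, 4, 4),
                     lesions = list(list(center = c(15, 10, 5), radius = 8,
                                         tbr = 2.5)),
                     noise_sd = 0.05, seed = 11)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$activity$data, p2$activity$data)
  expect_identical(p1$mu$data, p2$mu$data)
  expect_identical(p1$background_roi$data, p2$background_roi$data)
})

test_that("true tumor volume equals the brute-force discretized sphere", {
  ph <- make_phantom(tiny_lesion_spec(n = 48, radius = 12, tbr = 2.5))
  n_true <- sum(ph$btv_true[[1]]$data)
  expect_equal(n_true, oracle_sphere_count(48, 1, c(0, 0, 0), 12),
               ignore_attr = TRUE)
  vol <- n_true * voxel_volume_ml(ph$mu)
  expect_equal(vol, 7.2, tolerance = 0.01)   # ~7.24 ml for a 12-mm sphere
  # noiseless TBR inside the true BTV is the lesion TBR exactly
  tbr <- ph$activity_true$data / ph$spec$background_kbq
  expect_equal(unique(tbr[ph$btv_true[[1]]$data != 0]), 2.5)
})

test_that("mu-map classification reproduces the phantom label map", {
  sp <- phantom_spec(shape = c(48, 48, 48), spacing = c(4, 4, 4),
                     air_cavities = list(list(center = c(0, 40, 5),
                                              radius = 8)),
                     lesions = list(list(center = c(15, -5, 0), radius = 9,
                                         tbr = 2.2)))
  ph <- make_phantom(sp)
  cls <- classify_mu(ph$mu, ph$head)
  h <- ph$head$data != 0
  expect_identical(cls$data[h], as.integer(ph$label$data[h]))
  expect_true(all(is.na(cls$data[!h])))
})

test_that("lesions outside the brain compartment are rejected", {
  expect_error(make_phantom(phantom_spec(
    shape = c(32, 32, 32), spacing = c(5, 5, 5),
    lesions = list(list(center = c(60, 60, 60), radius = 10, tbr = 2)))),
    "outside the brain")
})

test_that("mu-map artifacts perturb exactly the intended voxels", {
  sp <- phantom_spec(shape = c(48, 48, 48), spacing = c(3, 3, 3),
                     air_cavities = list(list(center = c(0, 40, 5),
                                              radius = 8)),
                     lesions = list(list(center = c(15, -5, 0), radius = 9,
                                         tbr = 2.2)), noise_sd = 0)
  ph <- make_phantom(sp)
  expect_identical(perturb_mu_map(ph, list())$data, ph$mu$data)

  # metal void: mu = 0 in a sphere inside the head
  mv <- perturb_mu_map(ph, list(artifact_spec("metal_void",
                                              center = c(-20, 0, 0),
                                              radius = 6)))
  n_expected <- oracle_sphere_count(48, 3, c(-20, 0, 0), 6)
  head <- ph$head$data != 0
  expect_equal(sum(mv$data[head] == 0) - sum(ph$mu$data[head] == 0),
               n_expected)

  # water-filled air cavity degrades tissue Dice, leaves bone Dice at 1
  aw <- perturb_mu_map(ph, list(artifact_spec("air_filled_as_water",
                                              center = c(0, 40, 5),
                                              radius = 10)))
  cls_ref <- classify_mu(ph$mu, ph$head)
  cls_aw <- classify_mu(aw, ph$head)
  tis <- function(c) (c$data == 1) & !is.na(c$data)
  bon <- function(c) (c$data == 2) & !is.na(c$data)
  expect_lt(oracle_dice(tis(cls_ref), tis(cls_aw)), 1)
  expect_equal(oracle_dice(bon(cls_ref), bon(cls_aw)), 1)

  # skull flap: bone voxels in the sector become tissue
  fl <- perturb_mu_map(ph, list(artifact_spec("missing_skull_flap",
                                              center = c(0, 0, 70),
                                              radius = 25)))
  expect_lt(sum(fl$data > 0.1), sum(ph$mu$data > 0.1))
  expect_error(perturb_mu_map(ph, list(artifact_spec("melting"))),
               "unknown artifact kind")
})

test_that("bias field is exactly 1 for identical mu-maps", {
  mu <- mk_vol(array(runif(16^3, 0, 0.15), c(16, 16, 16)), c(3, 3, 3))
  b <- ac_bias_field(mu, mu)
  expect_identical(unique(as.numeric(b$data)), 1)
  act <- mk_vol(array(runif(16^3), c(16, 16, 16)), c(3, 3, 3))
  expect_equal(apply_ac_bias(act, mu, mu)$data, act$data, tolerance = 1e-12)
})

test_that("uniform mu excess over a 20-cm chord gives exp(0.2) center bias", {
  n <- 64; spc <- 210 / n
  cc <- (1:n - (n + 1) / 2) * spc
  dmu <- array(0, c(n, n, n))
  dmu[outer(outer(cc^2, cc^2, `+`), cc^2, `+`) <= 100^2] <- 0.01
  mu0 <- mk_vol(array(0, c(n, n, n)), rep(spc, 3))
  mu1 <- mk_vol(dmu, rep(spc, 3))
  for (k in c(1, 4)) {
    b <- ac_bias_field(mu0, mu1, n_angles = k)
    expect_equal(b$data[n / 2, n / 2, n / 2], exp(0.2), tolerance = 0.01)
  }
  b <- ac_bias_field(mu0, mu1, n_angles = 4)
  expect_true(all(b$data >= 1 - 1e-9))
  # nonnegative mu excess implies bias >= 1 on random fields too
  set.seed(5)
  dr <- array(runif(12^3, 0, 0.02), c(12, 12, 12))
  br <- ac_bias_field(mk_vol(array(0, c(12, 12, 12)), c(4, 4, 4)),
                      mk_vol(dr, c(4, 4, 4)), n_angles = 3)
  expect_true(all(br$data >= 1 - 1e-9))
})

test_that("bias field converges under sampling-step refinement", {
  # smooth mu perturbation (a blurred patch) so the integrand is smooth
  n <- 48
  cc <- (1:n - (n + 1) / 2) * 3
  patch <- array(0, c(n, n, n))
  patch[outer(outer((cc + 25)^2, cc^2, `+`), cc^2, `+`) <= 12^2] <- 0.05
  patch <- smooth_sigma_vox_test(patch)
  mu0 <- mk_vol(array(0, c(n, n, n)), c(3, 3, 3))
  mu1 <- mk_vol(patch, c(3, 3, 3))
  b1 <- ac_bias_field(mu0, mu1, n_angles = 4)
  b2 <- ac_bias_field(mu0, mu1, n_angles = 4, step = 3 / 4)
  expect_lt(max(abs(b2$data - b1$data) / b1$data), 0.001)
})

test_that("a distant artifact biases the lesion less than an adjacent one", {
  sp <- phantom_spec(shape = c(64, 64, 64), spacing = c(3, 3, 3),
                     noise_sd = 0,
                     lesions = list(list(center = c(25, 0, 0), radius = 10,
                                         tbr = 2.5)))
  ph <- make_phantom(sp)
  lesion <- ph$btv_true[[1]]$data != 0
  near <- perturb_mu_map(ph, list(artifact_spec("false_bone_patch",
                                                center = c(42, 0, 0),
                                                radius = 8)))
  far <- perturb_mu_map(ph, list(artifact_spec("false_bone_patch",
                                               center = c(-42, -40, 0),
                                               radius = 8)))
  b_near <- ac_bias_field(ph$mu, near, n_angles = 8)
  b_far <- ac_bias_field(ph$mu, far, n_angles = 8)
  expect_gt(mean(abs(b_near$data[lesion] - 1)),
            mean(abs(b_far$data[lesion] - 1)))
})

test_that("dynamic frame scheme has the canonical 14 mid-times", {
  fs <- frame_scheme()
  expect_equal(fs$mid_min,
               c(0.5, 1.5, 2.5, 3.5, 4.5, 6.5, 9.5, 12.5, 15.5, 18.5, 22.5,
                 27.5, 32.5, 37.5))
  expect_equal(sum(fs$duration_min), 40)
})

test_that("dynamic series follow the requested late pattern", {
  ph <- make_phantom(tiny_lesion_spec(n = 24, spacing = 2, radius = 10))
  lesion <- ph$btv_true[[1]]
  pl <- tac_extract(make_dynamic_frames(ph, "plateau"), lesion)
  late <- pl$mean_activity[pl$mid_min >= 10]
  expect_equal(max(abs(diff(late))), 0)
  inc <- tac_extract(make_dynamic_frames(ph, "increasing"), lesion)
  expect_gt(inc$mean_activity[14], inc$mean_activity[inc$mid_min == 12.5])
  expect_length(make_dynamic_frames(ph, "plateau")$frame_info, 14)
  expect_error(make_dynamic_frames(ph, "wavy"), "arg")
})
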