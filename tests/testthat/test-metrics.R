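test_that("mu classification follows the printed class bounds", {
  vals <- c(0, 0.03, 0.05, 0.096, 0.1, 0.1005, 0.151)
  mu <- mk_vol(array(rep(vals, length.out = 8), c(2, 2, 2)))
  head <- mk_vol(array(1, c(2, 2, 2)))
  cls <- classify_mu(mu, head)
  expect_equal(as.integer(cls$data[1:7]),
               c(0L, 0L, 1L, 1L, 1L, 2L, 2L))   # 0.05 and 0.1 are tissue
  neg <- mu; neg$data[1] <- -0.01; neg$data[2] <- -0.2
  expect_error(classify_mu(neg, head), "2 negative")
})

test_that("dice handles identity, disjointness, and hand counts", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1   # 8 voxels
  b <- array(0, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1   # 8 voxels, overlap 4
  expect_equal(dice(mk_vol(a), mk_vol(a)), 1)
  expect_equal(dice(mk_vol(a), mk_vol(1 - a)), 0)
  expect_equal(dice(mk_vol(a), mk_vol(b)), 0.5)
  expect_equal(dice(mk_vol(b), mk_vol(a)), 0.5)   # symmetry
  z <- mk_vol(array(0, c(4, 4, 4)))
  expect_equal(dice(z, z), 1)                      # both empty agree
})

test_that("proximity sphere is centered on per-component peaks", {
  pet <- array(0, c(40, 40, 40))
  pet[6, 6, 6] <- 10; pet[34, 34, 34] <- 10
  btv <- delineate_btv(mk_vol(pet), 1, mk_vol(array(1, c(40, 40, 40))))
  expect_equal(nrow(btv$components), 2)
  ps <- proximity_sphere(btv, radius_mm = 5)
  # two far-apart components: ~2 sphere volumes, no overlap
  expect_equal(sum(ps$data) * 0.001, 2 * 4 / 3 * pi * 5^3 / 1000,
               tolerance = 0.05)
  # boundary: voxel at 5 mm included (<=), farther excluded
  expect_equal(ps$data[11, 6, 6], 1)
  expect_equal(ps$data[12, 6, 6], 0)
  # tiny radius keeps only the peak voxels
  p0 <- proximity_sphere(btv, radius_mm = 0.01)
  expect_equal(sum(p0$data), 2)
  empty <- delineate_btv(mk_vol(array(0, c(4, 4, 4))), 1,
                         mk_vol(array(1, c(4, 4, 4))))
  expect_error(proximity_sphere(empty), "empty")
})

test_that("mu similarity: identity, constant shift, and SSIM oracle", {
  set.seed(21)
  a <- mk_vol(array(runif(8^3, 0, 0.15), c(8, 8, 8)))
  head <- mk_vol(array(1, c(8, 8, 8)))
  same <- mu_similarity(a, a, head)
  expect_equal(same$mae, 0)
  expect_equal(same$ssim, 1, tolerance = 1e-9)
  shifted <- a; shifted$data <- a$data + 0.01
  expect_equal(mu_similarity(a, shifted, head)$mae, 0.01, tolerance = 1e-12)
  b <- mk_vol(array(runif(8^3, 0, 0.15), c(8, 8, 8)))
  got <- mu_similarity(a, b, head)$ssim
  want <- mean(oracle_ssim(a$data, b$data, data_range = max(a$data)))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("contour agreement matches brute-force surface distances", {
  a <- array(0, c(16, 16, 16)); a[5:10, 5:10, 5:10] <- 1
  expect_equal(contour_agreement(mk_vol(a), mk_vol(a)),
               list(dice = 1, hausdorff_mm = 0))
  b <- array(0, c(16, 16, 16)); b[6:11, 5:10, 5:10] <- 1
  ca <- contour_agreement(mk_vol(a), mk_vol(b))
  expect_equal(ca$hausdorff_mm, 1)
  # isolated voxel 5 voxels beyond the cube surface
  c2 <- a; c2[5, 5, 15] <- 1
  expect_equal(contour_agreement(mk_vol(a), mk_vol(c2))$hausdorff_mm,
               oracle_hausdorff(a, c2))
  # random small masks, anisotropic spacing
  set.seed(31)
  for (rep in 1:4) {
    ra <- array(runif(10^3) < 0.2, c(10, 10, 10))
    rb <- array(runif(10^3) < 0.2, c(10, 10, 10))
    if (!any(ra) || !any(rb)) next
    sp <- c(1, 1.5, 2)
    got <- contour_agreement(mk_vol(ra, sp), mk_vol(rb, sp))
    expect_equal(got$hausdorff_mm, oracle_hausdorff(ra, rb, sp),
                 tolerance = 1e-9)
    expect_equal(got$dice, oracle_dice(ra, rb), tolerance = 1e-12)
  }
  expect_error(contour_agreement(mk_vol(a), mk_vol(array(0, c(16, 16, 16)))),
               "empty")
})

test_that("shape deviation separates focal blobs from contour shifts", {
  n <- 72
  cc <- (1:n - (n + 1) / 2)
  r2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  sph <- mk_vol((r2 <= 20^2) * 1)
  expect_equal(shape_deviation(sph, sph), 0)
  # one-voxel uniform boundary displacement: discounted entirely
  dil <- mk_vol((r2 <= 21^2) * 1)
  expect_equal(shape_deviation(sph, dil), 0)
  # disjoint 6-mm blob: core registers, bounded by the blob volume
  blob_only <- (outer(outer((cc - 30)^2, cc^2, `+`), cc^2, `+`) <= 6^2)
  blob <- mk_vol(((r2 <= 20^2) | blob_only) * 1)
  sdv <- shape_deviation(sph, blob)
  expect_gt(sdv, 0)
  expect_lte(sdv, sum(blob_only) / 1000)
  expect_lte(sdv, 0.905)
  # symmetry and the symmetric-difference bound
  expect_equal(shape_deviation(blob, sph), sdv)
  expect_lte(shape_deviation(sph, blob),
             sum(abs(sph$data - blob$data)) / 1000)
})

test_that("shape deviation agrees with dense-kernel smoothing oracle", {
  set.seed(12)
  a <- array(runif(10^3) < 0.4, c(10, 10, 10)) * 1
  b <- array(runif(10^3) < 0.4, c(10, 10, 10)) * 1
  d <- abs(a - b)
  sig <- 4 / (2 * sqrt(2 * log(2))) / c(1, 1, 1)
  want <- sum(oracle_smooth(d, sig) >= 1 - 0.02) * 0.001
  expect_equal(shape_deviation(mk_vol(a), mk_vol(b)), want,
               tolerance = 1e-9)
})

test_that("peak distance applies the strict 10-mm criterion", {
  pet <- array(1, c(24, 24, 24)); pet[5, 5, 5] <- 9
  brain <- mk_vol(array(1, c(24, 24, 24)))
  ref <- delineate_btv(mk_vol(pet), 1, brain)
  expect_equal(peak_distance(ref, ref),
               list(distance_mm = 0, within_criterion = TRUE))
  pet2 <- array(1, c(24, 24, 24)); pet2[15, 5, 5] <- 9   # 10 mm away
  tst <- delineate_btv(mk_vol(pet2), 1, brain)
  pk <- peak_distance(ref, tst)
  expect_equal(pk$distance_mm, 10)
  expect_false(pk$within_criterion)                       # strict <
  # two near-equal hot spots: a small bias flips the max 30 mm away
  pet3 <- array(1, c(44, 44, 44))
  pet3[6, 6, 6] <- 9; pet3[36, 6, 6] <- 8.9
  pet4 <- pet3
  pet4[36, 6, 6] <- 8.9 * 1.05; pet4[6, 6, 6] <- 9 * 0.99
  brain2 <- mk_vol(array(1, c(44, 44, 44)))
  r3 <- delineate_btv(mk_vol(pet3), 1, brain2)
  t3 <- delineate_btv(mk_vol(pet4), 1, brain2)
  expect_equal(peak_distance(r3, t3)$distance_mm, 30)
})

test_that("PET similarity closed forms and oracle agreement hold", {
  set.seed(41)
  ref <- mk_vol(array(runif(8^3, 1, 5), c(8, 8, 8)))
  brain <- mk_vol(array(1, c(8, 8, 8)))
  same <- pet_similarity(ref, ref, brain)
  expect_equal(same$mae, 0)
  expect_equal(same$psnr, Inf)
  expect_equal(same$ssim, 1, tolerance = 1e-9)
  cshift <- ref; cshift$data <- ref$data + 0.5
  ps <- pet_similarity(ref, cshift, brain)
  R <- max(ref$data)
  expect_equal(ps$mae, 0.5, tolerance = 1e-12)
  expect_equal(ps$psnr, 10 * log10(R^2 / 0.25), tolerance = 1e-12)
  other <- mk_vol(array(runif(8^3, 1, 5), c(8, 8, 8)))
  got <- pet_similarity(ref, other, brain)
  expect_equal(got$mae, mean(abs(ref$data - other$data)), tolerance = 1e-12)
  expect_equal(got$ssim,
               mean(oracle_ssim(ref$data, other$data, data_range = R)),
               tolerance = 1e-6)
})

test_that("regional differences equal per-label averaging oracle", {
  ph <- make_phantom(tiny_lesion_spec(n = 32, spacing = 2, radius = 8))
  ref <- ph$activity
  expect_true(all(regional_differences(ref, ref, ph$regions) == 0))
  sc <- ref; sc$data <- 1.05 * ref$data
  expect_equal(unname(regional_differences(ref, sc, ph$regions)),
               rep(5, 8), tolerance = 1e-9)
  # biased field from the attenuation model vs direct averaging
  mu_t <- perturb_mu_map(ph, list(artifact_spec("false_bone_patch",
                                                center = c(12, 0, 0),
                                                radius = 8)))
  biased <- apply_ac_bias(ref, ph$mu, mu_t, n_angles = 4)
  got <- regional_differences(ref, biased, ph$regions)
  lab <- ph$regions$data
  for (l in sort(unique(lab[lab != 0]))) {
    sel <- lab == l
    want <- 100 * (mean(biased$data[sel]) - mean(ref$data[sel])) /
      mean(ref$data[sel])
    expect_equal(unname(got[as.character(l)]), want, tolerance = 1e-12)
  }
})
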