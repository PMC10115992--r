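# Independent brute-force oracles used to cross-check the package's
# implementations on tiny fixtures.  These deliberately avoid the package's
# own code paths (direct loops and direct formulas).

mk_vol <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  image_volume(arr * 1, spacing = spacing, origin = origin)
}

oracle_dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# surface voxels by explicit 6-neighbour loop
oracle_surface <- function(m) {
  d <- dim(m)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else FALSE,
      if (i < d[1]) m[i + 1, j, k] else FALSE,
      if (j > 1) m[i, j - 1, k] else FALSE,
      if (j < d[2]) m[i, j + 1, k] else FALSE,
      if (k > 1) m[i, j, k - 1] else FALSE,
      if (k < d[3]) m[i, j, k + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- oracle_surface(a != 0)
  sb <- oracle_surface(b != 0)
  pa <- sweep(sa - 1, 2, spacing, `*`)
  pb <- sweep(sb - 1, 2, spacing, `*`)
  dmat <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) -
               2 * pa %*% t(pb))
  dmat[dmat < 0] <- 0   # numerical
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# mirror-reflection (edge duplicated) of a 1-based index vector
oracle_reflect <- function(idx, n) {
  while (any(idx < 1) || any(idx > n)) {
    idx[idx < 1] <- 1 - idx[idx < 1]
    idx[idx > n] <- 2 * n + 1 - idx[idx > n]
  }
  idx
}

# mirror-padded copy of a 3D array, radius r per axis
oracle_pad <- function(arr, r) {
  d <- dim(arr)
  arr[oracle_reflect(seq(1 - r[1], d[1] + r[1]), d[1]),
      oracle_reflect(seq(1 - r[2], d[2] + r[2]), d[2]),
      oracle_reflect(seq(1 - r[3], d[3] + r[3]), d[3])]
}

# direct per-voxel windowed sum of padded array times a separable kernel
oracle_window_sum <- function(padded, w, d, r) {
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    win <- padded[i:(i + 2 * r[1]), j:(j + 2 * r[2]), k:(k + 2 * r[3])]
    out[i, j, k] <- sum(win * w)
  }
  out
}

# direct Gaussian-window statistics SSIM (3D), sigma in voxels
oracle_ssim <- function(a, b, data_range, sigma = 1.5, K1 = 0.01,
                        K2 = 0.03) {
  d <- dim(a)
  r <- rep(max(1L, ceiling(4 * sigma)), 3)
  w1 <- dnorm(seq(-r[1], r[1]), sd = sigma); w1 <- w1 / sum(w1)
  w <- outer(outer(w1, w1), w1)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  pa <- oracle_pad(a, r); pb <- oracle_pad(b, r)
  m1 <- oracle_window_sum(pa, w, d, r)
  m2 <- oracle_window_sum(pb, w, d, r)
  v1 <- oracle_window_sum(pa^2, w, d, r) - m1^2
  v2 <- oracle_window_sum(pb^2, w, d, r) - m2^2
  cv <- oracle_window_sum(pa * pb, w, d, r) - m1 * m2
  ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
    ((m1^2 + m2^2 + C1) * (v1 + v2 + C2))
}

# direct dense-kernel Gaussian smoothing (reflection), sigma in voxels
oracle_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  r <- pmax(1L, ceiling(4 * sigma_vox))
  ws <- lapply(1:3, function(ax) {
    v <- dnorm(seq(-r[ax], r[ax]), sd = sigma_vox[ax]); v / sum(v)
  })
  w <- outer(outer(ws[[1]], ws[[2]]), ws[[3]])
  oracle_window_sum(oracle_pad(arr, r), w, d, r)
}

# discretized sphere voxel count on an isotropic grid centered like
# make_phantom's coordinates
oracle_sphere_count <- function(n, spacing, center, radius) {
  cc <- (seq_len(n) - (n + 1) / 2) * spacing
  sum(outer(outer((cc - center[1])^2, (cc - center[2])^2, `+`),
            (cc - center[3])^2, `+`) <= radius^2)
}

# blur a field with the package smoother (test plumbing, not an oracle)
smooth_sigma_vox_test <- function(arr, fwhm = 9, spacing = 3) {
  gaussian_smooth(mk_vol(arr, rep(spacing, 3)), fwhm)$data
}

# small all-brain phantom: grid entirely inside the brain compartment
# (no skull in view) - convenient for lesion-only fixtures at 1 mm iso
tiny_lesion_spec <- function(n = 48, spacing = 1, radius = 12, tbr = 2.5,
                             noise_sd = 0, seed = 1, edge_mm = NULL) {
  les <- list(center = c(0, 0, 0), radius = radius, tbr = tbr)
  if (!is.null(edge_mm)) les$edge_mm <- edge_mm
  phantom_spec(shape = rep(n, 3), spacing = rep(spacing, 3),
               lesions = list(les), noise_sd = noise_sd, seed = seed)
}
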