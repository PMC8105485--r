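test_that("FWHM matching recovers known isotropic and anisotropic blurs", {
  ph <- small_hoffman(1)
  img <- gaussian_postfilter(ph$volume, 8, 8)
  est <- estimate_fwhm(img, ph$volume, c(3, 15, 0.5))
  expect_equal(est$fwhm_xy_mm, 8, tolerance = 0.5 / 8)
  expect_equal(est$fwhm_z_mm, 8, tolerance = 0.5 / 8)
  expect_gt(est$peak_correlation, 0.999)
  aniso <- gaussian_postfilter(ph$volume, 6, 10)
  est2 <- estimate_fwhm(aniso, ph$volume, c(3, 15, 0.5))
  expect_equal(est2$fwhm_xy_mm, 6, tolerance = 0.5 / 6)
  expect_equal(est2$fwhm_z_mm, 10, tolerance = 0.5 / 10)
  # an unblurred image correlates best with the least-blurred template
  # (scaled mode, so the phantom varies over its own support)
  phs <- generate_hoffman_surrogate(
    hoffman_surrogate_spec(wm_activity_mode = "scaled", seed = 1),
    voxel_grid(c(64, 64, 16), c(3, 3, 4)))
  est0 <- estimate_fwhm(phs$volume, phs$volume, c(3, 9, 1))
  expect_equal(est0$fwhm_xy_mm, 3)
  expect_equal(est0$fwhm_z_mm, 3)
  # estimates must lie on the search grid
  expect_true(est$fwhm_xy_mm %in% seq(3, 15, 0.5))
  expect_error(
    estimate_fwhm(image_volume(array(1, dim(ph$volume$voxels)),
                               ph$volume$voxel_size), ph$volume),
    "zero variance")
})

test_that("estimated FWHM is monotone under additional blur", {
  ph <- small_hoffman(1)
  prev <- -Inf
  for (f in c(5, 8, 12)) {
    est <- estimate_fwhm(gaussian_postfilter(ph$volume, f, f), ph$volume,
                         c(3, 15, 0.5))
    expect_gte(est$fwhm_xy_mm, prev)
    prev <- est$fwhm_xy_mm
  }
})

test_that("sequential FWHM search agrees with the joint search on clean blur", {
  ph <- small_hoffman(1)
  img <- gaussian_postfilter(ph$volume, 7, 11)
  sq <- estimate_fwhm(img, ph$volume, c(3, 15, 0.5), method = "sequential")
  jt <- estimate_fwhm(img, ph$volume, c(3, 15, 0.5), method = "joint")
  expect_equal(sq$fwhm_xy_mm, jt$fwhm_xy_mm, tolerance = 0.51 / 7)
  expect_equal(sq$fwhm_z_mm, jt$fwhm_z_mm, tolerance = 0.51 / 11)
})

test_that("uniformity percentage SD follows its definition", {
  lab <- label_volume(array(rep(c(1L, 0L), c(8, 8 * 8 * 2 - 8)), c(8, 8, 2)),
                      c(putamen_R = 1L))
  mk <- function(vals) {
    a <- array(0, c(8, 8, 2)); a[seq_along(vals)] <- vals
    image_volume(a, c(1, 1, 1))
  }
  expect_equal(uniformity_percent_sd(mk(rep(4, 8)), lab)$percent_sd, 0)
  u <- uniformity_percent_sd(mk(rep(c(9, 11), 4)), lab)
  expect_equal(u$C_P, 10)
  expect_equal(u$sigma_p, 1)
  expect_equal(u$percent_sd, 10)
  # sampling oracle: 2400 draws of N(4, 0.48^2) give ~12%
  set.seed(3)
  draws <- rnorm(2400, 4, 0.48)
  big <- image_volume(array(c(draws, rep(0, 544)), c(32, 46, 2)), c(1, 1, 1))
  biglab <- label_volume(array(rep(c(1L, 0L), c(2400, 544)), c(32, 46, 2)),
                         c(putamen_R = 1L))
  se <- 12 / sqrt(2 * 2399)
  expect_lt(abs(uniformity_percent_sd(big, biglab)$percent_sd - 12), 3 * se)
  # scale invariance
  expect_equal(uniformity_percent_sd(mk(rep(c(9, 11), 4) * 5), lab)$percent_sd,
               10)
  expect_error(uniformity_percent_sd(mk(rep(0, 8)), lab), "zero")
})

test_that("SNR follows its definition and invariances", {
  dims <- c(8, 8, 2)
  lab <- label_volume(array(rep(c(1L, 2L, 0L), c(8, 8, 112)), dims),
                      c(putamen_R = 1L, wm_background_voi = 2L))
  mk <- function(sig, bg) {
    a <- array(0, dims); a[1:8] <- sig; a[9:16] <- bg
    image_volume(a, c(1, 1, 1))
  }
  bgv <- c(1.5, 2.5, 1.5, 2.5, 1.5, 2.5, 1.5, 2.5)  # mean 2, sd ~0.53
  s0 <- snr(mk(rep(mean(bgv), 8), bgv), lab)
  expect_equal(s0$snr, 0)
  v <- mk(rep(10, 8), bgv)
  s1 <- snr(v, lab)
  expect_equal(s1$snr, (10 - 2) / sd(bgv))
  # background constructed with sample SD exactly 1: C_P 10, C_W 2 -> SNR 8
  unit_sd_bg <- 2 + rep(c(-1, 1), 4) * sqrt(7 / 8)
  expect_equal(snr(mk(rep(10, 8), unit_sd_bg), lab)$snr, 8)
  # invariant under positive rescaling and under global offsets
  va <- image_volume(v$voxels * 2.5, v$voxel_size)
  vo <- image_volume(v$voxels + 7, v$voxel_size)
  expect_equal(snr(va, lab)$snr, s1$snr, tolerance = 1e-12)
  expect_equal(snr(vo, lab)$snr, s1$snr, tolerance = 1e-12)
  # degenerate background is flagged, not infinite
  expect_error(snr(mk(rep(10, 8), rep(2, 8)), lab), "undefined SNR")
})
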