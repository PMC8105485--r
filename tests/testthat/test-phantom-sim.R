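test_that("NEMA phantom encodes the 4:1 hot-to-background filling scheme", {
  g <- voxel_grid(c(128, 128, 40), c(3, 3, 3))
  ph <- generate_nema_phantom(nema_iq_spec(), g)
  vox <- ph$volume$voxels
  lab <- ph$labels
  expect_equal(max(vox[label_mask(lab, "sphere_1")]) /
                 vox[label_mask(lab, "background")][1], 4.0)
  expect_equal(unique(vox[label_mask(lab, "background")]), 5.6)
  # cold spheres (two largest) carry zero activity
  expect_equal(max(vox[label_mask(lab, "sphere_5")]), 0)
  expect_equal(max(vox[label_mask(lab, "sphere_6")]), 0)
  # unity ratio makes hot spheres indistinguishable from background
  ph1 <- generate_nema_phantom(nema_iq_spec(hot_to_background_ratio = 1 + 1e-12), g)
  hot <- ph1$volume$voxels[label_mask(ph1$labels, "sphere_1")]
  expect_lt(max(abs(hot - 5.6)), 1e-9)
})

test_that("voxelized sphere volume matches the analytic ball volume", {
  # 39 mm sphere on a 1 mm grid: (pi/6) * 39^3 = 31059 voxels within 5%
  sp <- nema_iq_spec(sphere_diameters_mm = 39, cold_sphere_indices = integer(0),
                     ring_radius_mm = 0, body_semiaxes_mm = c(28, 28))
  ph <- generate_nema_phantom(sp, voxel_grid(c(64, 64, 48), c(1, 1, 1)))
  n <- sum(ph$labels$labels == 2L)
  expect_lt(abs(n - pi / 6 * 39^3) / (pi / 6 * 39^3), 0.05)
  # convergence: the coarser voxelization is farther from the analytic value
  ph2 <- generate_nema_phantom(sp, voxel_grid(c(32, 32, 24), c(2, 2, 2)))
  n2 <- sum(ph2$labels$labels == 2L) * 8
  expect_lt(abs(n - pi / 6 * 39^3), abs(n2 - pi / 6 * 39^3) + 1e-9)
})

test_that("sphere ring outside the body or field of view is a geometry error", {
  expect_error(
    generate_nema_phantom(nema_iq_spec(ring_radius_mm = 140),
                          voxel_grid(c(128, 128, 8), c(3, 3, 3))),
    "geometry error")
  expect_error(
    generate_nema_phantom(nema_iq_spec(), voxel_grid(c(32, 32, 8), c(1, 1, 1))),
    "geometry error")
})

test_that("Hoffman surrogate is deterministic and structured as specified", {
  ph <- small_hoffman(1)
  ph2 <- generate_hoffman_surrogate(hoffman_surrogate_spec(seed = 1),
                                    voxel_grid(c(64, 64, 16), c(3, 3, 4)))
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  expect_identical(ph$labels$labels, ph2$labels$labels)
  # devoid mode: white matter and the background VOI carry exactly zero
  expect_equal(max(ph$volume$voxels[label_mask(ph$labels, "white")]), 0)
  expect_equal(max(ph$volume$voxels[label_mask(ph$labels, "wm_background_voi")]), 0)
  # a different seed folds the cortex differently
  ph3 <- generate_hoffman_surrogate(hoffman_surrogate_spec(seed = 2),
                                    voxel_grid(c(64, 64, 16), c(3, 3, 4)))
  expect_false(identical(ph$labels$labels, ph3$labels$labels))
})

test_that("Hoffman gray/white contrast and putamen volume match the request", {
  g <- voxel_grid(c(160, 176, 48), c(1, 1, 2.78))
  ph <- generate_hoffman_surrogate(
    hoffman_surrogate_spec(wm_activity_mode = "scaled", seed = 2), g)
  gm <- mean(ph$volume$voxels[label_mask(ph$labels, "gray")])
  wm <- mean(ph$volume$voxels[label_mask(ph$labels, "white")])
  expect_equal(gm / wm, 4.0)
  # putamen VOI within one voxel shell of 2400 mm^3 on 1 x 1 x 2.78 mm voxels
  nvox <- sum(ph$labels$labels == 3L)
  vol <- nvox * prod(g$voxel_size)
  # shell tolerance: ellipsoid surface area x largest voxel extent
  s <- (2400 * 3 / (4 * pi * 1.6 * 0.75))^(1 / 3)
  ax <- s * c(1.6, 1, 0.75)
  p <- 1.6075
  area <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                       ax[2]^p * ax[3]^p) / 3)^(1 / p)
  expect_lt(abs(vol - 2400), area * max(g$voxel_size))
  # oversized putamen request is a spec error
  expect_error(generate_hoffman_surrogate(
    hoffman_surrogate_spec(putamen_volume_mm3 = 4e5), g), "spec error")
})

test_that("forward projection conserves activity and matches chord lengths", {
  vol <- disk_volume()
  sino <- disk_sino()
  # unit radial bins: per-slice sinogram total = n_angles * activity total
  expect_equal(sum(sino$counts[, , 1]), 180 * sum(vol$voxels[, , 1]),
               tolerance = 0.01)
  # every view of a centred disk equals the chord-length profile
  nr <- dim(sino$counts)[2]
  s <- (seq_len(nr) - (nr + 1) / 2) * sino$radial_spacing_mm
  chord <- 2 * sqrt(pmax(20^2 - s^2, 0)) * 2.5
  interior <- abs(s) < 0.7 * 20
  rel <- abs(sweep(t(sino$counts[, interior, 1]), 1, chord[interior], "-")) /
    chord[interior]
  expect_lt(max(rel), 0.02)
  # a single central voxel peaks at radial offset zero for every view
  pt <- array(0, c(65, 65, 1)); pt[33, 33, 1] <- 1
  ps <- forward_project(image_volume(pt, c(1, 1, 1)), 32)
  ctr <- (dim(ps$counts)[2] + 1) / 2
  expect_true(all(apply(ps$counts[, , 1], 1, which.max) == ctr))
})

test_that("projection is linear and zero maps to zero", {
  set.seed(42)
  a <- image_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), c(2, 2, 2))
  b <- image_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), c(2, 2, 2))
  comb <- image_volume(3 * a$voxels + 0.5 * b$voxels, c(2, 2, 2))
  pa <- forward_project(a, 24)$counts
  pb <- forward_project(b, 24)$counts
  pc <- forward_project(comb, 24)$counts
  expect_equal(pc, 3 * pa + 0.5 * pb, tolerance = 1e-12)
  z <- image_volume(array(0, c(32, 32, 2)), c(2, 2, 2))
  expect_true(all(forward_project(z, 24)$counts == 0))
  expect_error(forward_project(a, 8), "16")
  expect_error(
    forward_project(image_volume(array(1, c(16, 16, 1)), c(1, 2, 1)), 32),
    "unsupported geometry")
})

test_that("Poisson noise preserves the expected total and is seed-reproducible", {
  vol <- disk_volume(n = 24, nz = 1, r = 8, d = 1)
  sino <- forward_project(vol, 24)
  totals <- vapply(seq_len(1000), function(s)
    sum(add_poisson_noise(sino, 1e6, s)$counts), numeric(1))
  expect_lt(abs(mean(totals) - 1e6) / 1e6, 0.005)
  n1 <- add_poisson_noise(sino, 1e4, 7)
  n2 <- add_poisson_noise(sino, 1e4, 7)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts == round(n1$counts)))
  # all-zero input stays all-zero; invalid count level errors
  z <- sinogram(array(0, c(24, 5, 1)), sino$angles[1:24], 1)
  expect_true(all(add_poisson_noise(z, 1e6, 1)$counts == 0))
  expect_error(add_poisson_noise(sino, -1, 1), "positive")
  # the caller's RNG stream is not disturbed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(add_poisson_noise(sino, 1e4, 99)); after <- runif(1)
  expect_identical(before, after)
})
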