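test_that("FBP recovers a uniform disk and is linear", {
  g <- voxel_grid(c(64, 64, 4), c(1, 1, 1))
  sino <- disk_sino()
  cfg <- recon_config("FBP", post_filter_fwhm_mm = 0)
  rec <- fbp_reconstruct(sino, cfg, g)
  interior <- disk_interior_mask()
  expect_lt(abs(mean(rec$voxels[, , 2][interior]) - 2.5) / 2.5, 0.03)
  # all-zero sinogram reconstructs to an all-zero image
  z <- sinogram(array(0, dim(sino$counts)), sino$angles, sino$radial_spacing_mm)
  expect_true(all(fbp_reconstruct(z, cfg, g)$voxels == 0))
  # linearity: doubling the sinogram doubles the image
  s2 <- sinogram(2 * sino$counts, sino$angles, sino$radial_spacing_mm)
  expect_equal(fbp_reconstruct(s2, cfg, g)$voxels, 2 * rec$voxels,
               tolerance = 1e-10)
  expect_error(recon_config("FBP", post_filter_fwhm_mm = -1), "config error")
})

test_that("wider FBP post-filters measure as wider FWHM", {
  g <- voxel_grid(c(64, 64, 4), c(1, 1, 1))
  sino <- disk_sino()
  f5 <- fbp_reconstruct(sino, recon_config("FBP", post_filter_fwhm_mm = 5), g)
  f15 <- fbp_reconstruct(sino, recon_config("FBP", post_filter_fwhm_mm = 15), g)
  digital <- disk_volume()
  e5 <- estimate_fwhm(f5, digital, c(2, 20, 0.5))
  e15 <- estimate_fwhm(f15, digital, c(2, 20, 0.5))
  expect_gt(e15$fwhm_xy_mm, e5$fwhm_xy_mm)
})

test_that("OSEM recovers the disk, stays non-negative, needs positive init", {
  g <- voxel_grid(c(64, 64, 4), c(1, 1, 1))
  sino <- disk_sino()
  cfg <- recon_config("OSEM", iterations = 4, subsets = 9,
                      post_filter_fwhm_mm = 0)
  rec <- osem_reconstruct(sino, cfg, g)
  interior <- disk_interior_mask()
  expect_lt(abs(mean(rec$voxels[, , 2][interior]) - 2.5) / 2.5, 0.03)
  expect_true(all(rec$voxels >= 0))
  # the multiplicative update has a fixed point at zero: an all-zero
  # sinogram keeps the ones-initialized image at zero counts everywhere,
  # while positive data must yield positive activity (ones init, not zeros)
  z <- sinogram(array(0, dim(sino$counts)), sino$angles, sino$radial_spacing_mm)
  expect_true(all(osem_reconstruct(z, cfg, g)$voxels == 0))
  expect_gt(max(rec$voxels), 0)
  expect_error(
    osem_reconstruct(sino, recon_config("OSEM", subsets = 7), g),
    "config error")
})

test_that("OSEM with one subset is exactly MLEM", {
  # independent MLEM oracle assembled from the public projection operators
  g <- voxel_grid(c(32, 32, 2), c(2, 2, 2))
  vol <- disk_volume(n = 32, nz = 2, r = 18, value = 1.4, d = 2)
  sino <- forward_project(vol, 24)
  n_it <- 5
  ones_sino <- sinogram(array(1, dim(sino$counts)), sino$angles,
                        sino$radial_spacing_mm)
  sens <- backproject(ones_sino, g)$voxels
  X <- array(1, g$dim)
  for (it in seq_len(n_it)) {
    ybar <- forward_project(image_volume(X, g$voxel_size), 24)$counts
    ratio <- sino$counts / pmax(ybar, 1e-12)
    bp <- backproject(sinogram(ratio, sino$angles, sino$radial_spacing_mm),
                      g)$voxels
    X <- X * bp / sens
  }
  osem1 <- osem_reconstruct(sino, recon_config("OSEM", iterations = n_it,
                                               subsets = 1,
                                               post_filter_fwhm_mm = 0), g)
  expect_equal(osem1$voxels, X, tolerance = 1e-10)
})

test_that("BSREM with zero penalty reduces to OSEM", {
  g <- voxel_grid(c(64, 64, 4), c(1, 1, 1))
  sino <- disk_sino()
  os <- osem_reconstruct(
    sino, recon_config("OSEM", iterations = 4, subsets = 9,
                       post_filter_fwhm_mm = 0), g)
  bs <- bsrem_reconstruct(
    sino, recon_config("BSREM", iterations = 4, subsets = 9, beta = 0,
                       relaxation_decay = 0), g)
  expect_equal(bs$voxels, os$voxels, tolerance = 1e-9)
})

test_that("BSREM output is non-negative and its objective is non-decreasing", {
  sim <- hoffman_sim(1)
  cfg <- recon_config("BSREM", iterations = 8, subsets = 12, beta = 400)
  rec <- bsrem_reconstruct(sim$sino, cfg, sim$grid)
  expect_true(all(rec$voxels >= 0))
  obj <- attr(rec, "objective")
  expect_length(obj, 8)
  # ascent within relaxation tolerance (relative dips below 1e-6 allowed)
  expect_true(all(diff(obj) > -1e-6 * abs(obj[-length(obj)])))
  expect_error(recon_config("BSREM", rdp_gamma = -1), "config error")
})

test_that("on noiseless data all three algorithms recover the disk interior", {
  g <- voxel_grid(c(64, 64, 4), c(1, 1, 1))
  sino <- disk_sino()
  interior <- disk_interior_mask()
  recs <- list(
    fbp_reconstruct(sino, recon_config("FBP", post_filter_fwhm_mm = 0), g),
    osem_reconstruct(sino, recon_config("OSEM", iterations = 4, subsets = 9,
                                        post_filter_fwhm_mm = 0), g),
    bsrem_reconstruct(sino, recon_config("BSREM", iterations = 4, subsets = 9,
                                         beta = 100), g))
  for (r in recs)
    expect_lt(abs(mean(r$voxels[, , 2][interior]) - 2.5) / 2.5, 0.03)
})

test_that("Gaussian post-filter has the stated width, identity and cascade", {
  # zero FWHM is the identity
  v <- disk_volume(n = 32, nz = 2)
  expect_identical(gaussian_postfilter(v, 0, 0)$voxels, v$voxels)
  # a blurred delta has the requested FWHM (half-maximum crossing oracle)
  dl <- array(0, c(65, 65, 33)); dl[33, 33, 17] <- 1
  dvol <- image_volume(dl, c(1, 1, 1))
  bl <- gaussian_postfilter(dvol, 8, 8)
  expect_equal(profile_fwhm(bl$voxels[, 33, 17]), 8, tolerance = 0.1 / 8)
  expect_equal(profile_fwhm(bl$voxels[33, 33, ]), 8, tolerance = 0.1 / 8)
  # total activity conserved away from boundaries
  expect_equal(sum(bl$voxels), 1, tolerance = 1e-3)
  # two 6 mm passes equal one sqrt(72) = 8.49 mm pass
  two <- gaussian_postfilter(gaussian_postfilter(dvol, 6, 6), 6, 6)
  one <- gaussian_postfilter(dvol, sqrt(72), sqrt(72))
  expect_lt(max(abs(two$voxels - one$voxels)) / max(one$voxels), 0.005)
})
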