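# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# uniform disk of given radius (mm) and activity on an isotropic grid;
# edge voxels carry their subpixel coverage fraction so the digital disk is
# a faithful discretization of the analytic disk (oracle comparisons then
# probe the projector, not the phantom voxelization)
disk_volume <- function(n = 64, nz = 4, r = 20, value = 2.5, d = 1, ss = 4) {
  fine <- (seq_len(n * ss) - (n * ss + 1) / 2) * d / ss
  finem <- outer(fine^2, fine^2, "+") <= r^2
  blocks <- array(finem, c(ss, n, ss, n))
  cov <- apply(blocks, c(2, 4), mean)
  image_volume(array(rep(cov * value, nz), dim = c(n, n, nz)), c(d, d, d))
}

disk_interior_mask <- function(n = 64, r_in = 14, d = 1) {
  cc <- (seq_len(n) - (n + 1) / 2) * d
  outer(cc^2, cc^2, "+") <= r_in^2
}

# small Hoffman surrogate for metric tests (fast)
small_hoffman <- function(seed = 1) {
  cached(paste0("hoff", seed), {
    g <- voxel_grid(c(64, 64, 16), c(3, 3, 4))
    generate_hoffman_surrogate(hoffman_surrogate_spec(seed = seed), g)
  })
}

# noiseless disk sinogram reused across reconstruction tests
disk_sino <- function() {
  cached("disk_sino", forward_project(disk_volume(), 180))
}

# noisy NEMA simulation at the default study conditions (moderate grid)
nema_sim <- function() {
  cached("nema_sim", {
    g <- voxel_grid(c(128, 128, 32), c(3, 3, 3))
    spec <- nema_iq_spec()
    ph <- generate_nema_phantom(spec, g)
    sino <- add_poisson_noise(forward_project(ph$volume, 180), 5e6, 1)
    list(grid = g, spec = spec, phantom = ph, sino = sino)
  })
}

# noisy Hoffman simulation for the beta-trend suite
hoffman_sim <- function(seed) {
  cached(paste0("hoffsim", seed), {
    g <- voxel_grid(c(96, 96, 24), c(2, 2, 5))
    ph <- generate_hoffman_surrogate(hoffman_surrogate_spec(seed = seed), g)
    sino <- add_poisson_noise(forward_project(ph$volume, 180), 5e6, seed)
    list(grid = g, phantom = ph, sino = sino)
  })
}

# independent 1D Gaussian-profile FWHM fit (half-maximum crossing with
# linear interpolation), used as an oracle for the filter module
profile_fwhm <- function(profile, spacing = 1) {
  pk <- which.max(profile)
  half <- profile[pk] / 2
  cross <- function(idx) {
    for (i in idx) {
      j <- i + sign(idx[2] - idx[1])
      if ((profile[i] - half) * (profile[j] - half) <= 0 && profile[i] != profile[j])
        return(i + (half - profile[i]) / (profile[j] - profile[i]) * sign(j - i))
    }
    NA_real_
  }
  left <- cross(seq(pk, 2))
  right <- cross(seq(pk, length(profile) - 1))
  (right - left) * spacing
}
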