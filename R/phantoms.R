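#' NEMA image-quality phantom specification
#'
#' Describes the digital NEMA IQ phantom: six fillable spheres on a ring in a
#' warm elliptical-cylinder background. Defaults follow the filling scheme of
#' a 4:1 hot-sphere-to-background study (22.4 vs 5.6 kBq/mL) with the two
#' largest spheres cold.
#'
#' @param sphere_diameters_mm strictly increasing sphere diameters (mm).
#' @param cold_sphere_indices indices (into `sphere_diameters_mm`) of cold,
#'   water-filled spheres; default the two largest.
#' @param background_concentration warm background activity, kBq/mL.
#' @param hot_to_background_ratio hot-sphere activity relative to background
#'   (> 1).
#' @param ring_radius_mm radius of the circle of sphere centres.
#' @param center_slice_mm axial position of the sphere-centre plane (mm,
#'   0 = grid centre).
#' @param body_semiaxes_mm in-plane semi-axes of the elliptical phantom body.
#' @return An object of class `nema_iq_spec`.
#' @export
nema_iq_spec <- function(sphere_diameters_mm = c(10, 13, 17, 22, 30, 39),
                         cold_sphere_indices = NULL,
                         background_concentration = 5.6,
                         hot_to_background_ratio = 4,
                         ring_radius_mm = 57.2,
                         center_slice_mm = 0,
                         body_semiaxes_mm = c(150, 110)) {
  d <- as.numeric(sphere_diameters_mm)
  if (length(d) < 1L || any(diff(d) <= 0))
    stop("sphere diameters must be strictly increasing")
  if (is.null(cold_sphere_indices)) {
    cold_sphere_indices <- if (length(d) >= 2L)
      c(length(d) - 1L, length(d)) else integer(0)
  }
  cold_sphere_indices <- as.integer(cold_sphere_indices)
  if (length(cold_sphere_indices) &&
      (any(cold_sphere_indices < 1L) || any(cold_sphere_indices > length(d))))
    stop("cold sphere indices must index the sphere diameter list")
  if (hot_to_background_ratio <= 1)
    stop("hot_to_background_ratio must exceed 1")
  if (background_concentration <= 0)
    stop("background_concentration must be positive")
  structure(list(
    sphere_diameters_mm = d,
    cold_sphere_indices = cold_sphere_indices,
    background_concentration = background_concentration,
    hot_to_background_ratio = hot_to_background_ratio,
    ring_radius_mm = ring_radius_mm,
    center_slice_mm = center_slice_mm,
    body_semiaxes_mm = as.numeric(body_semiaxes_mm)
  ), class = "nema_iq_spec")
}

# angular position (radians) of each sphere centre on the ring
nema_sphere_angles <- function(n) (seq_len(n) - 1L) * 2 * pi / n

#' Generate the digital NEMA IQ phantom
#'
#' Voxelizes the warm body and the six spheres on the requested grid using
#' the voxel-centre-inside rule. Hot spheres carry
#' `hot_to_background_ratio` times the background activity; cold spheres
#' carry zero.
#'
#' @param spec a [nema_iq_spec()].
#' @param grid a [voxel_grid()]; the sphere ring must fit inside both the
#'   grid extent and the phantom body.
#' @return list with elements `volume` ([image_volume()]) and `labels`
#'   ([label_volume()]; legend: `background` plus `sphere_1` ...
#'   `sphere_n` in diameter order).
#' @export
generate_nema_phantom <- function(spec, grid) {
  stopifnot(inherits(spec, "nema_iq_spec"), inherits(grid, "voxel_grid"))
  cc <- grid_coords(grid)
  nd <- length(spec$sphere_diameters_mm)
  rmax <- max(spec$sphere_diameters_mm) / 2
  ext <- c(max(abs(cc$x)), max(abs(cc$y)))
  if (spec$ring_radius_mm + rmax > min(spec$body_semiaxes_mm))
    stop("geometry error: sphere ring does not fit inside the phantom body")
  if (spec$ring_radius_mm + rmax > min(ext))
    stop("geometry error: sphere ring extends outside the field of view")
  zc <- spec$center_slice_mm
  if (zc + rmax > max(cc$z) + grid$voxel_size[3] / 2 ||
      zc - rmax < min(cc$z) - grid$voxel_size[3] / 2)
    stop("geometry error: spheres extend outside the axial field of view")

  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  X <- array(cc$x, dim = grid$dim)
  Y <- array(rep(cc$y, each = nx), dim = grid$dim)
  Z <- array(rep(cc$z, each = nx * ny), dim = grid$dim)

  body <- (X / spec$body_semiaxes_mm[1])^2 +
          (Y / spec$body_semiaxes_mm[2])^2 <= 1
  act <- ifelse(body, spec$background_concentration, 0)
  lab <- array(0L, grid$dim)
  lab[body] <- 1L

  ang <- nema_sphere_angles(nd)
  hot_value <- spec$background_concentration * spec$hot_to_background_ratio
  for (k in seq_len(nd)) {
    ctr <- c(spec$ring_radius_mm * cos(ang[k]),
             spec$ring_radius_mm * sin(ang[k]), zc)
    r <- spec$sphere_diameters_mm[k] / 2
    inside <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= r^2
    act[inside] <- if (k %in% spec$cold_sphere_indices) 0 else hot_value
    lab[inside] <- k + 1L
  }

  legend <- c(background = 1L,
              stats::setNames(seq_len(nd) + 1L, paste0("sphere_", seq_len(nd))))
  list(volume = image_volume(act, grid$voxel_size),
       labels = label_volume(lab, legend))
}

#' Hoffman-surrogate brain phantom specification
#'
#' The true Hoffman 3D atlas is proprietary; this surrogate is a procedurally
#' generated brain-like label map — a folded gray-matter shell around a white
#' interior, two ellipsoidal "putamina", and a white-matter background VOI —
#' preserving the metric-relevant structure (gray/white contrast, a small
#' bright nucleus, a zero-activity region) without external data.
#'
#' @param gm_wm_ratio gray-to-white activity ratio (>= 1).
#' @param putamen_volume_mm3 target putamen VOI volume (mm^3).
#' @param wm_activity_mode `"devoid"` (white matter carries zero activity,
#'   matching a water-only background region) or `"scaled"` (white matter at
#'   `1/gm_wm_ratio` of gray).
#' @param seed integer seed controlling the cortical folding pattern.
#' @param brain_semiaxes_mm outer brain ellipsoid semi-axes (mm).
#' @return An object of class `hoffman_surrogate_spec`.
#' @export
hoffman_surrogate_spec <- function(gm_wm_ratio = 4,
                                   putamen_volume_mm3 = 2400,
                                   wm_activity_mode = c("devoid", "scaled"),
                                   seed = 1L,
                                   brain_semiaxes_mm = c(70, 85, 60)) {
  wm_activity_mode <- match.arg(wm_activity_mode)
  if (gm_wm_ratio < 1) stop("gm_wm_ratio must be >= 1")
  if (putamen_volume_mm3 <= 0) stop("putamen_volume_mm3 must be positive")
  structure(list(
    gm_wm_ratio = gm_wm_ratio,
    putamen_volume_mm3 = putamen_volume_mm3,
    wm_activity_mode = wm_activity_mode,
    seed = as.integer(seed),
    brain_semiaxes_mm = as.numeric(brain_semiaxes_mm)
  ), class = "hoffman_surrogate_spec")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the Hoffman-surrogate brain phantom
#'
#' Deterministic for a fixed spec seed. Gray-matter voxels carry
#' `gm_wm_ratio` (arbitrary units); white matter carries 1 in `"scaled"`
#' mode or exactly 0 in `"devoid"` mode. Both putamina carry the gray value.
#' A `wm_background_voi` region inside white matter always carries activity
#' exactly equal to the white-matter value (0 in devoid mode).
#'
#' @param spec a [hoffman_surrogate_spec()].
#' @param grid a [voxel_grid()] large enough to host the brain and the
#'   requested putamen volume.
#' @return list with `volume` and `labels`; label legend: `gray`, `white`,
#'   `putamen_R`, `putamen_L`, `wm_background_voi`.
#' @export
generate_hoffman_surrogate <- function(spec, grid) {
  stopifnot(inherits(spec, "hoffman_surrogate_spec"), inherits(grid, "voxel_grid"))
  ax <- spec$brain_semiaxes_mm
  brain_vol <- 4 / 3 * pi * prod(ax)
  if (spec$putamen_volume_mm3 > 0.10 * brain_vol)
    stop("spec error: requested putamen volume exceeds 10% of the brain region")
  cc <- grid_coords(grid)
  if (max(abs(cc$x)) < 0.7 * ax[1] || max(abs(cc$y)) < 0.7 * ax[2])
    stop("grid too small to host the brain phantom")

  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  X <- array(cc$x, dim = grid$dim)
  Y <- array(rep(cc$y, each = nx), dim = grid$dim)
  Z <- array(rep(cc$z, each = nx * ny), dim = grid$dim)

  U1 <- X / ax[1]; U2 <- Y / ax[2]; U3 <- Z / ax[3]
  rho <- sqrt(U1^2 + U2^2 + U3^2)
  az <- atan2(U2, U1)
  el <- asin(pmin(1, pmax(-1, ifelse(rho > 0, U3 / pmax(rho, 1e-12), 0))))

  # seeded cortical "folding": smooth angular modulation of the gray/white
  # interface radius
  fold <- with_seed(spec$seed, {
    nh <- 4L
    kk <- sample(3:8, nh, replace = TRUE)
    ll <- sample(1:4, nh, replace = TRUE)
    ph <- stats::runif(nh, 0, 2 * pi)
    qh <- stats::runif(nh, 0, 2 * pi)
    amp <- stats::runif(nh, 0.5, 1)
    amp <- amp / sum(amp) * 0.06
    m <- 0
    for (h in seq_len(nh))
      m <- m + amp[h] * sin(kk[h] * az + ph[h]) * cos(ll[h] * el + qh[h])
    m
  })
  rho_wm <- pmin(0.92, pmax(0.60, 0.78 + fold))

  gray <- rho <= 1 & rho > rho_wm
  white <- rho <= rho_wm

  lab <- array(0L, grid$dim)
  lab[white] <- 2L
  lab[gray] <- 1L

  # two ellipsoidal putamina of the requested volume, axes ratio 1.6:1:0.75
  s <- (spec$putamen_volume_mm3 * 3 / (4 * pi * 1.6 * 0.75))^(1 / 3)
  pax <- s * c(1.6, 1, 0.75)
  put_ctr <- list(putamen_R = c(26, 10, -5), putamen_L = c(-26, 10, -5))
  for (nm in names(put_ctr)) {
    p <- put_ctr[[nm]]
    inside <- ((X - p[1]) / pax[1])^2 + ((Y - p[2]) / pax[2])^2 +
              ((Z - p[3]) / pax[3])^2 <= 1
    lab[inside] <- if (nm == "putamen_R") 3L else 4L
  }
  if (!any(lab == 3L))
    stop("grid too small or too coarse to host the putamen VOI")

  # white-matter background VOI, fully interior to the white region
  wvoi <- ((X - 0) / 14)^2 + ((Y + 25) / 11)^2 + ((Z - 0) / 9)^2 <= 1 &
          lab == 2L
  lab[wvoi] <- 5L

  wm_value <- if (spec$wm_activity_mode == "devoid") 0 else 1
  gm_value <- spec$gm_wm_ratio * max(wm_value, 1)
  act <- array(0, grid$dim)
  act[lab == 2L | lab == 5L] <- wm_value
  act[lab == 1L] <- gm_value
  act[lab == 3L | lab == 4L] <- gm_value

  legend <- c(gray = 1L, white = 2L, putamen_R = 3L, putamen_L = 4L,
              wm_background_voi = 5L)
  list(volume = image_volume(act, grid$voxel_size),
       labels = label_volume(lab, legend))
}
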