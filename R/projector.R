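#' Sinogram container
#'
#' Projection-space counts from slice-wise parallel-beam acquisition.
#'
#' @param counts array of dimension `n_angles x n_radial x n_slices`,
#'   non-negative.
#' @param angles projection angles in radians, strictly increasing, uniform
#'   over `[0, pi)`.
#' @param radial_spacing_mm radial bin width (mm).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(counts, angles, radial_spacing_mm) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L) stop("`counts` must be a 3D array")
  if (any(counts < 0)) stop("sinogram counts must be non-negative")
  angles <- as.numeric(angles)
  if (length(angles) != dim(counts)[1] || any(diff(angles) <= 0))
    stop("`angles` must be strictly increasing and match dim(counts)[1]")
  if (radial_spacing_mm <= 0) stop("radial spacing must be positive")
  structure(list(counts = counts, angles = angles,
                 radial_spacing_mm = radial_spacing_mm), class = "sinogram")
}

#' @exportS3Method print sinogram
print.sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sinogram> %d angles x %d radial bins x %d slices, ds = %.3g mm, total = %.4g\n",
              d[1], d[2], d[3], x$radial_spacing_mm, sum(x$counts)))
  invisible(x)
}

# session cache for projection geometries (keyed by geometry parameters)
.petiq_geom_cache <- new.env(parent = emptyenv())

#' Parallel-beam projection geometry (sparse system matrix)
#'
#' Builds (and caches per session) the pixel-driven slice-wise parallel-beam
#' system matrix: each pixel is split into `supersample^2` equal-area
#' subpixels, each subpixel centre is projected onto the radial axis of each
#' view, and its weight is split between the two adjacent radial bins by
#' linear interpolation (supersampling suppresses the lattice ripple of
#' plain pixel-driven projection at oblique views). With the physical scale
#' factor `dx * dy / radial_spacing` applied in [forward_project()],
#' sinogram values approximate line integrals in mm x activity units.
#'
#' @param nx,ny in-plane grid dimensions.
#' @param dx in-plane voxel size (mm; isotropic in-plane only).
#' @param n_angles number of views over `[0, pi)` (>= 16).
#' @param radial_spacing_mm radial bin width; defaults to `dx`.
#' @param n_radial number of radial bins; default covers the grid diagonal.
#' @param supersample subpixel linear subdivision factor (default 3).
#' @return list with the sparse matrix `A` (`n_angles * n_radial` rows,
#'   `nx * ny` columns; row index `(angle - 1) * n_radial + bin`), `angles`,
#'   `n_radial`, `radial_spacing_mm`, and the intensity scale `scale`.
#' @keywords internal
projection_geometry <- function(nx, ny, dx, n_angles,
                                radial_spacing_mm = dx, n_radial = NULL,
                                supersample = 3L) {
  if (n_angles < 16L) stop("at least 16 projection angles are required")
  if (is.null(n_radial)) {
    n_radial <- ceiling(sqrt((nx * dx)^2 + (ny * dx)^2) / radial_spacing_mm) + 3L
    if (n_radial %% 2L == 0L) n_radial <- n_radial + 1L
  }
  key <- paste(nx, ny, signif(dx, 10), n_angles,
               signif(radial_spacing_mm, 10), n_radial, supersample, sep = "|")
  hit <- .petiq_geom_cache[[key]]
  if (!is.null(hit)) return(hit)

  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dx
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  npix <- nx * ny
  ctr <- (n_radial + 1) / 2
  sub <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * dx
  subw <- 1 / supersample^2

  ii <- vector("list", n_angles)
  jj <- vector("list", n_angles)
  xx <- vector("list", n_angles)
  jall <- seq_len(npix)
  for (a in seq_len(n_angles)) {
    ia <- ja <- wa <- vector("list", supersample^2)
    m <- 0L
    for (ox in sub) for (oy in sub) {
      m <- m + 1L
      s <- (px + ox) * cos(angles[a]) + (py + oy) * sin(angles[a])
      tf <- s / radial_spacing_mm + ctr
      i0 <- floor(tf)
      w1 <- 1 - (tf - i0)
      keep0 <- i0 >= 1 & i0 <= n_radial
      keep1 <- (i0 + 1) >= 1 & (i0 + 1) <= n_radial
      ia[[m]] <- c(i0[keep0], i0[keep1] + 1L)
      ja[[m]] <- c(jall[keep0], jall[keep1])
      wa[[m]] <- c(w1[keep0], 1 - w1[keep1]) * subw
    }
    off <- (a - 1L) * n_radial
    ii[[a]] <- off + unlist(ia)
    jj[[a]] <- unlist(ja)
    xx[[a]] <- unlist(wa)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_angles * n_radial, npix)
  )
  geom <- list(A = A, angles = angles, n_radial = n_radial,
               radial_spacing_mm = radial_spacing_mm,
               scale = dx * dx / radial_spacing_mm,
               nx = nx, ny = ny, dx = dx, n_angles = n_angles)
  .petiq_geom_cache[[key]] <- geom
  geom
}

check_inplane_isotropic <- function(vol) {
  if (abs(vol$voxel_size[1] - vol$voxel_size[2]) > 1e-9)
    stop("unsupported geometry: in-plane voxels must be isotropic")
}

#' Forward projection (simulated acquisition)
#'
#' Slice-wise parallel-beam line-integral projection of an activity volume,
#' the stand-in for scanner acquisition.
#'
#' @param vol an [image_volume()] with isotropic in-plane voxels.
#' @param n_angles number of uniformly spaced views over `[0, pi)` (>= 16).
#' @param radial_spacing_mm radial bin width; defaults to the in-plane voxel
#'   size.
#' @return a [sinogram()].
#' @export
forward_project <- function(vol, n_angles = 180L,
                            radial_spacing_mm = vol$voxel_size[1]) {
  stopifnot(inherits(vol, "image_volume"))
  check_inplane_isotropic(vol)
  d <- dim(vol$voxels)
  geom <- projection_geometry(d[1], d[2], vol$voxel_size[1], n_angles,
                              radial_spacing_mm)
  X <- matrix(vol$voxels, nrow = d[1] * d[2], ncol = d[3])
  P <- as.matrix(geom$A %*% X) * geom$scale
  counts <- aperm(array(P, dim = c(geom$n_radial, n_angles, d[3])), c(2, 1, 3))
  sinogram(counts, geom$angles, radial_spacing_mm)
}

#' Backprojection (adjoint of [forward_project()])
#'
#' Plain interpolating backprojection (no filtering), exposed because
#' iterative reconstruction and its tests are built from the
#' forward/backprojection pair.
#'
#' @param sino a [sinogram()].
#' @param grid the target [voxel_grid()] (isotropic in-plane).
#' @return an [image_volume()] (values may be interpreted as the adjoint
#'   image, not activity).
#' @export
backproject <- function(sino, grid) {
  stopifnot(inherits(sino, "sinogram"), inherits(grid, "voxel_grid"))
  if (abs(grid$voxel_size[1] - grid$voxel_size[2]) > 1e-9)
    stop("unsupported geometry: in-plane voxels must be isotropic")
  d <- dim(sino$counts)
  geom <- projection_geometry(grid$dim[1], grid$dim[2], grid$voxel_size[1],
                              d[1], sino$radial_spacing_mm, n_radial = d[2])
  Y <- matrix(aperm(sino$counts, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  B <- as.matrix(Matrix::crossprod(geom$A, Y)) * geom$scale
  image_volume(array(B, dim = grid$dim), grid$voxel_size, check = FALSE)
}

#' Add Poisson count noise to a sinogram
#'
#' Scales the noiseless sinogram to the requested expected total count and
#' draws independent Poisson counts; the returned sinogram is on the count
#' scale (integer-valued). Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param sino a [sinogram()].
#' @param expected_total_counts expected total counts over the whole
#'   sinogram (> 0).
#' @param seed integer seed.
#' @return a [sinogram()] of integer counts.
#' @export
add_poisson_noise <- function(sino, expected_total_counts, seed) {
  stopifnot(inherits(sino, "sinogram"))
  if (expected_total_counts <= 0)
    stop("expected_total_counts must be positive")
  tot <- sum(sino$counts)
  if (tot == 0) return(sino)
  lam <- sino$counts * (expected_total_counts / tot)
  noisy <- with_seed(seed, stats::rpois(length(lam), lam))
  sinogram(array(as.numeric(noisy), dim = dim(sino$counts)),
           sino$angles, sino$radial_spacing_mm)
}
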