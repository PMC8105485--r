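#' Estimate image resolution by digital-phantom convolution matching
#'
#' Convolves the noiseless digital phantom with separable Gaussians over an
#' exhaustive 2D grid of (in-plane, axial) FWHM values, computes the Pearson
#' correlation with the measured image over the phantom support (voxels
#' where the digital phantom is positive), and returns the grid pair with
#' the highest correlation. The in-plane blur is shared between x and y.
#'
#' @param image measured/reconstructed [image_volume()].
#' @param digital noiseless digital phantom on the same voxel grid.
#' @param grid_mm `c(min, max, step)` of the FWHM search grid (mm), step
#'   > 0; default `c(3, 18, 0.5)`.
#' @param method `"joint"` (default: exhaustive 2D search) or
#'   `"sequential"` (in-plane FWHM first with the axial blur fixed at the
#'   grid midpoint, then axial given the in-plane optimum).
#' @param return_surface if `TRUE`, attach the full correlation surface
#'   (matrix, in-plane x axial) as attribute `"surface"`.
#' @return list of class `fwhm_estimate`: `fwhm_xy_mm`, `fwhm_z_mm`,
#'   `peak_correlation`, `search_grid`.
#' @export
estimate_fwhm <- function(image, digital, grid_mm = c(3, 18, 0.5),
                          method = c("joint", "sequential"),
                          return_surface = FALSE) {
  stopifnot(inherits(image, "image_volume"), inherits(digital, "image_volume"))
  method <- match.arg(method)
  if (!identical(dim(image$voxels), dim(digital$voxels)))
    stop("image and digital phantom must share one voxel grid")
  if (length(grid_mm) != 3L || grid_mm[3] <= 0 || grid_mm[2] < grid_mm[1])
    stop("grid_mm must be c(min, max, step) with step > 0")
  fvals <- seq(grid_mm[1], grid_mm[2], by = grid_mm[3])
  mask <- digital$voxels > 0
  y <- image$voxels[mask]
  if (stats::sd(y) == 0)
    stop("correlation undefined: image has zero variance over the phantom")
  vs <- image$voxel_size
  d <- dim(digital$voxels)

  cor_with <- function(blurred) stats::cor(blurred[mask], y)

  if (method == "sequential") {
    mid_z <- fvals[ceiling(length(fvals) / 2)]
    r_xy <- vapply(fvals, function(fxy)
      cor_with(blur_array(digital$voxels, vs, fxy, mid_z)), numeric(1))
    best_xy <- fvals[which.max(r_xy)]
    dxy <- blur_array(digital$voxels, vs, best_xy, 0)
    r_z <- vapply(fvals, function(fz)
      cor_with(blur_array(dxy, vs, 0, fz)), numeric(1))
    best_z <- fvals[which.max(r_z)]
    res <- list(fwhm_xy_mm = best_xy, fwhm_z_mm = best_z,
                peak_correlation = max(r_z),
                search_grid = grid_mm, method = method)
    class(res) <- "fwhm_estimate"
    return(res)
  }

  surface <- matrix(NA_real_, length(fvals), length(fvals),
                    dimnames = list(fvals, fvals))
  for (i in seq_along(fvals)) {
    dxy <- blur_array(digital$voxels, vs, fvals[i], 0)
    Mxy <- matrix(dxy, d[1] * d[2], d[3])
    for (j in seq_along(fvals)) {
      Kz <- gauss_axis_matrix(d[3], vs[3], fvals[j])
      b <- if (is.null(Kz)) dxy else array(Mxy %*% Kz, dim = d)
      surface[i, j] <- cor_with(b)
    }
  }
  best <- arrayInd(which.max(surface), dim(surface))
  res <- list(fwhm_xy_mm = fvals[best[1]], fwhm_z_mm = fvals[best[2]],
              peak_correlation = surface[best],
              search_grid = grid_mm, method = method)
  if (return_surface) attr(res, "surface") <- surface
  class(res) <- "fwhm_estimate"
  res
}

#' @exportS3Method print fwhm_estimate
print.fwhm_estimate <- function(x, ...) {
  cat(sprintf("<fwhm_estimate> FWHM(x,y) = %.1f mm, FWHM(z) = %.1f mm (r = %.4f)\n",
              x$fwhm_xy_mm, x$fwhm_z_mm, x$peak_correlation))
  invisible(x)
}

#' Axial uniformity as percentage standard deviation of a VOI
#'
#' `100 * sigma_p / C_P` over the voxels of the named VOI, with the
#' population (N) standard deviation.
#'
#' @param image an [image_volume()].
#' @param labels paired [label_volume()].
#' @param voi_label VOI name in the legend (default `"putamen_R"`).
#' @return list of class `uniformity_result`: `percent_sd`, `C_P`,
#'   `sigma_p`, `voi_volume_mm3`.
#' @export
uniformity_percent_sd <- function(image, labels, voi_label = "putamen_R") {
  stopifnot(inherits(image, "image_volume"), inherits(labels, "label_volume"))
  v <- image$voxels[label_mask(labels, voi_label)]
  if (!length(v)) stop("empty VOI: ", voi_label)
  C_P <- mean(v)
  if (C_P == 0) stop("C_P is zero; percentage SD undefined")
  sigma_p <- sqrt(mean((v - C_P)^2))
  structure(list(percent_sd = 100 * sigma_p / C_P, C_P = C_P,
                 sigma_p = sigma_p,
                 voi_volume_mm3 = length(v) * prod(image$voxel_size)),
            class = "uniformity_result")
}

#' Signal-to-noise ratio between a signal VOI and a background VOI
#'
#' `(C_P - C_W) / sigma_W`, with `sigma_W` the sample (N - 1) standard
#' deviation of the background VOI voxels.
#'
#' @param image an [image_volume()].
#' @param labels paired [label_volume()].
#' @param signal_label signal VOI name (default `"putamen_R"`).
#' @param background_label background VOI name (default
#'   `"wm_background_voi"`).
#' @return list of class `snr_result`: `snr`, `C_P`, `C_W`, `sigma_W`.
#' @export
snr <- function(image, labels, signal_label = "putamen_R",
                background_label = "wm_background_voi") {
  stopifnot(inherits(image, "image_volume"), inherits(labels, "label_volume"))
  p <- image$voxels[label_mask(labels, signal_label)]
  w <- image$voxels[label_mask(labels, background_label)]
  if (!length(p)) stop("empty VOI: ", signal_label)
  if (length(w) < 2L) stop("background VOI too small: ", background_label)
  sigma_W <- stats::sd(w)
  if (sigma_W == 0) stop("undefined SNR: background VOI has zero variance")
  structure(list(snr = (mean(p) - mean(w)) / sigma_W,
                 C_P = mean(p), C_W = mean(w), sigma_W = sigma_W),
            class = "snr_result")
}

#' Full Hoffman-phantom analysis of one reconstruction
#'
#' Resolution by [estimate_fwhm()] against the digital phantom, axial
#' uniformity by [uniformity_percent_sd()], and [snr()].
#'
#' @param image reconstructed [image_volume()].
#' @param digital noiseless digital phantom ([image_volume()]).
#' @param labels paired [label_volume()].
#' @param fwhm_grid_mm FWHM search grid, see [estimate_fwhm()].
#' @return one-row data.frame: `fwhm_xy_mm`, `fwhm_z_mm`,
#'   `uniformity_percent_sd`, `snr`.
#' @export
analyze_hoffman <- function(image, digital, labels,
                            fwhm_grid_mm = c(3, 18, 0.5)) {
  fw <- estimate_fwhm(image, digital, fwhm_grid_mm)
  un <- uniformity_percent_sd(image, labels)
  sn <- snr(image, labels)
  data.frame(fwhm_xy_mm = fw$fwhm_xy_mm, fwhm_z_mm = fw$fwhm_z_mm,
             uniformity_percent_sd = un$percent_sd, snr = sn$snr)
}
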