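#' Default in-plane background ROI positions
#'
#' Twelve in-plane centre positions (mm, relative to the phantom centre) for
#' the NEMA background ROIs, chosen to clear every sphere on the default
#' 57.2 mm ring by at least the sum of the largest sphere and ROI radii and
#' to stay >= 15 mm inside the elliptical body. The exact coordinates are a
#' package default in the spirit of the NEMA NU 2-2012 schematic and can be
#' replaced by the user.
#'
#' @return a 12 x 2 numeric matrix with columns `x`, `y` (mm).
#' @export
nema_background_positions <- function() {
  m <- rbind(
    c( 115,   0), c(-115,   0),
    c( 105,  20), c( 105, -20), c(-105,  20), c(-105, -20),
    c(  90,  40), c(  90, -40), c( -90,  40), c( -90, -40),
    c(   0,  20), c(   0, -20))
  colnames(m) <- c("x", "y")
  m
}

# nearest slice index to physical z position; ties round toward the centre
# slice
nearest_slice <- function(z_target, z_coords, center_idx) {
  d <- abs(z_coords - z_target)
  cand <- which(d == min(d))
  if (length(cand) > 1L) cand <- cand[which.min(abs(cand - center_idx))]
  cand
}

# voxel-centre-inside-circle membership on one slice
disk_indices <- function(cc, center_xy, radius) {
  dx2 <- (cc$x - center_xy[1])^2
  dy2 <- (cc$y - center_xy[2])^2
  which(outer(dx2, dy2, "+") <= radius^2)
}

#' Sphere ROI means (NEMA hot/cold sphere analysis)
#'
#' Draws, on the sphere-centre slice, a circular 2D ROI equal in diameter to
#' each sphere (voxel-centre-inside rule) and returns the mean counts.
#' Sphere centres are taken from the label volume (synthetic mode).
#'
#' @param vol reconstructed [image_volume()].
#' @param labels paired [label_volume()] carrying `sphere_k` labels.
#' @param spec the [nema_iq_spec()] used to generate the phantom.
#' @return data.frame with one row per sphere: `sphere_diameter_mm`, `kind`
#'   (`"hot"`/`"cold"`), `mean` (C_H or C_C), `n_voxels`, `cx`, `cy`, `cz`
#'   (ROI centre, mm).
#' @export
place_sphere_rois <- function(vol, labels, spec) {
  stopifnot(inherits(vol, "image_volume"), inherits(labels, "label_volume"),
            inherits(spec, "nema_iq_spec"))
  grid <- volume_grid(vol)
  cc <- grid_coords(grid)
  nd <- length(spec$sphere_diameters_mm)
  out <- vector("list", nd)
  for (k in seq_len(nd)) {
    mask <- label_mask(labels, paste0("sphere_", k))
    if (!any(mask)) stop("sphere_", k, " has no labelled voxels")
    idx <- which(mask, arr.ind = TRUE)
    ctr <- c(mean(cc$x[idx[, 1]]), mean(cc$y[idx[, 2]]), mean(cc$z[idx[, 3]]))
    iz <- nearest_slice(ctr[3], cc$z, (grid$dim[3] + 1) / 2)
    if (iz < 1 || iz > grid$dim[3])
      stop("geometry error: sphere centre slice outside the volume")
    roi <- disk_indices(cc, ctr[1:2], spec$sphere_diameters_mm[k] / 2)
    if (!length(roi)) stop("geometry error: empty ROI for sphere_", k)
    slice <- vol$voxels[, , iz]
    out[[k]] <- data.frame(
      sphere_diameter_mm = spec$sphere_diameters_mm[k],
      kind = if (k %in% spec$cold_sphere_indices) "cold" else "hot",
      mean = mean(slice[roi]), n_voxels = length(roi),
      cx = ctr[1], cy = ctr[2], cz = cc$z[iz])
  }
  do.call(rbind, out)
}

#' Background ROI sets (60 ROIs per sphere size)
#'
#' Places 12 fixed in-plane positions times 5 slices (the sphere-centre
#' slice and +/- 1 cm and +/- 2 cm, rounded to the nearest slice with ties
#' toward the centre) of circular background ROIs, concentric across sphere
#' sizes. Every ROI must lie entirely on warm background (no sphere labels)
#' and keep a 15 mm margin to the phantom edge.
#'
#' @inheritParams place_sphere_rois
#' @param positions in-plane ROI centres (mm), a matrix with columns `x`,
#'   `y`; defaults to [nema_background_positions()].
#' @param slice_offsets_mm axial ROI-plane offsets (mm) from the
#'   sphere-centre plane.
#' @param edge_margin_mm minimum distance from any ROI edge to the phantom
#'   boundary.
#' @return named list (one element per sphere size, names the diameters)
#'   with fields `sphere_diameter_mm`, `roi_means` (length 60 by default),
#'   `C_B`, `layout` (`c(n_positions, n_slices)`).
#' @export
place_background_rois <- function(vol, labels, spec,
                                  positions = nema_background_positions(),
                                  slice_offsets_mm = c(0, 10, -10, 20, -20),
                                  edge_margin_mm = 15) {
  stopifnot(inherits(vol, "image_volume"), inherits(labels, "label_volume"),
            inherits(spec, "nema_iq_spec"))
  grid <- volume_grid(vol)
  cc <- grid_coords(grid)
  center_idx <- nearest_slice(spec$center_slice_mm, cc$z, (grid$dim[3] + 1) / 2)
  slices <- vapply(slice_offsets_mm, function(off)
    nearest_slice(cc$z[center_idx] + off, cc$z, center_idx), integer(1))
  bg_label <- labels$legend[["background"]]

  res <- list()
  for (k in seq_along(spec$sphere_diameters_mm)) {
    d <- spec$sphere_diameters_mm[k]
    r <- d / 2
    means <- numeric(0)
    for (p in seq_len(nrow(positions))) {
      roi <- disk_indices(cc, positions[p, ], r)
      # margin check: a ring at radius r + margin must still be warm phantom
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      ring_x <- positions[p, 1] + (r + edge_margin_mm) * cos(th)
      ring_y <- positions[p, 2] + (r + edge_margin_mm) * sin(th)
      ring_ix <- round(ring_x / grid$voxel_size[1] + (grid$dim[1] + 1) / 2)
      ring_iy <- round(ring_y / grid$voxel_size[2] + (grid$dim[2] + 1) / 2)
      if (any(ring_ix < 1 | ring_ix > grid$dim[1] |
              ring_iy < 1 | ring_iy > grid$dim[2]))
        stop("placement error: background ROI position (",
             positions[p, 1], ", ", positions[p, 2],
             ") too close to the field-of-view edge")
      for (iz in slices) {
        lab_slice <- labels$labels[, , iz]
        if (any(lab_slice[roi] != bg_label))
          stop("placement error: background ROI at (",
               positions[p, 1], ", ", positions[p, 2], "), slice ", iz,
               " overlaps a sphere or leaves the phantom")
        if (any(lab_slice[cbind(ring_ix, ring_iy)] == 0L))
          stop("placement error: background ROI at (",
               positions[p, 1], ", ", positions[p, 2],
               ") is within ", edge_margin_mm, " mm of the phantom edge")
        slice <- vol$voxels[, , iz]
        means <- c(means, mean(slice[roi]))
      }
    }
    res[[as.character(d)]] <- list(
      sphere_diameter_mm = d,
      roi_means = means,
      C_B = mean(means),
      layout = c(n_positions = nrow(positions), n_slices = length(slices)))
  }
  res
}

#' Percentage contrast for a hot sphere
#'
#' `100 * ((C_H / C_B) - 1) / ((a_H / a_B) - 1)`: measured sphere-to-
#' background contrast relative to the true activity ratio.
#'
#' @param C_H mean ROI counts in the hot sphere.
#' @param C_B mean of the background ROI means for the same sphere size
#'   (> 0).
#' @param a_H,a_B true activity concentrations in sphere and background
#'   (kBq/mL); their ratio must differ from 1.
#' @return percent contrast (scalar).
#' @export
percent_contrast_hot <- function(C_H, C_B, a_H, a_B) {
  if (C_B <= 0) stop("C_B must be positive")
  if (a_H == a_B) stop("undefined contrast: a_H equals a_B")
  100 * ((C_H / C_B) - 1) / ((a_H / a_B) - 1)
}

#' Percentage contrast for a cold sphere
#'
#' `100 * (1 - C_C / C_B)`.
#'
#' @param C_C mean ROI counts in the cold sphere.
#' @param C_B mean background ROI counts for the same sphere size (> 0).
#' @return percent contrast (scalar).
#' @export
percent_contrast_cold <- function(C_C, C_B) {
  if (C_B <= 0) stop("C_B must be positive")
  100 * (1 - C_C / C_B)
}

#' Background variability
#'
#' Sample standard deviation (K - 1 denominator) of the K background ROI
#' means and the percent background variability `100 * SD / C_B`.
#'
#' @param roi_means background ROI means (K >= 2).
#' @param C_B their average; recomputed when `NULL`.
#' @return list with `sd` and `percent_bv`.
#' @export
background_variability <- function(roi_means, C_B = NULL) {
  if (length(roi_means) < 2L) stop("at least 2 background ROI means required")
  if (is.null(C_B)) C_B <- mean(roi_means)
  if (C_B == 0) stop("C_B must be nonzero")
  s <- sqrt(sum((roi_means - C_B)^2) / (length(roi_means) - 1))
  list(sd = s, percent_bv = 100 * s / C_B)
}

#' Full NEMA image-quality analysis of one reconstruction
#'
#' Combines [place_sphere_rois()], [place_background_rois()],
#' [percent_contrast_hot()] / [percent_contrast_cold()] and
#' [background_variability()] into a tidy per-sphere table.
#'
#' @inheritParams place_background_rois
#' @return data.frame with one row per sphere: `sphere_diameter_mm`, `kind`,
#'   `contrast_percent`, `bv_percent`, `C_sphere`, `C_B`.
#' @export
analyze_nema <- function(vol, labels, spec,
                         positions = nema_background_positions()) {
  rois <- place_sphere_rois(vol, labels, spec)
  bg <- place_background_rois(vol, labels, spec, positions = positions)
  a_B <- spec$background_concentration
  a_H <- a_B * spec$hot_to_background_ratio
  out <- lapply(seq_len(nrow(rois)), function(k) {
    b <- bg[[as.character(rois$sphere_diameter_mm[k])]]
    contrast <- if (rois$kind[k] == "hot")
      percent_contrast_hot(rois$mean[k], b$C_B, a_H, a_B)
    else
      percent_contrast_cold(rois$mean[k], b$C_B)
    bv <- background_variability(b$roi_means, b$C_B)
    data.frame(sphere_diameter_mm = rois$sphere_diameter_mm[k],
               kind = rois$kind[k],
               contrast_percent = contrast,
               bv_percent = bv$percent_bv,
               C_sphere = rois$mean[k], C_B = b$C_B)
  })
  do.call(rbind, out)
}
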