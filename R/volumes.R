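#' Voxel grid description
#'
#' A voxel grid pairs an array dimension with a physical voxel size. Voxel
#' centres are placed symmetrically about the physical origin: the centre of
#' voxel `i` along an axis with `n` voxels of size `d` mm sits at
#' `(i - (n + 1) / 2) * d` mm. The third axis is axial.
#'
#' @param dim integer vector of length 3, array dimensions (x, y, z).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(128, 128, 40), c(3, 3, 3))
voxel_grid <- function(dim, voxel_size) {
  dim <- as.integer(dim)
  voxel_size <- as.numeric(voxel_size)
  if (length(dim) != 3L || length(voxel_size) != 3L)
    stop("`dim` and `voxel_size` must have length 3")
  if (any(dim < 1L)) stop("grid dimensions must be positive")
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(dim = dim, voxel_size = voxel_size), class = "voxel_grid")
}

#' Physical coordinates of voxel centres along each axis
#' @param grid a [voxel_grid()].
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @keywords internal
grid_coords <- function(grid) {
  cc <- function(n, d) (seq_len(n) - (n + 1) / 2) * d
  list(
    x = cc(grid$dim[1], grid$voxel_size[1]),
    y = cc(grid$dim[2], grid$voxel_size[2]),
    z = cc(grid$dim[3], grid$voxel_size[3])
  )
}

#' Image volume
#'
#' The universal currency between pipeline stages: a 3D array of non-negative
#' activity values (arbitrary units or kBq/mL) together with its physical
#' voxel size.
#'
#' @param voxels 3D numeric array of activity values.
#' @param voxel_size numeric length-3, voxel edge lengths (dx, dy, dz) in mm.
#' @param frame axis-order convention tag; the default `"xyz-axial"` means
#'   the third array axis is the scanner (axial) axis.
#' @param check if `TRUE`, enforce non-negativity (reconstruction by filtered
#'   back-projection legitimately produces negative voxels and passes
#'   `check = FALSE`).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, voxel_size, frame = "xyz-axial", check = TRUE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array")
  if (any(dim(voxels)[1:2] < 8L) || dim(voxels)[3] < 1L)
    stop("volume shape must be at least 8 x 8 x 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive lengths in mm")
  if (check && any(voxels < 0)) stop("activity voxels must be non-negative")
  structure(list(voxels = voxels, voxel_size = voxel_size, frame = frame),
            class = "image_volume")
}

#' @exportS3Method print image_volume
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm  [%.4g, %.4g]\n",
    dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @exportS3Method dim image_volume
dim.image_volume <- function(x) dim(x$voxels)

#' @exportS3Method as.array image_volume
as.array.image_volume <- function(x, ...) x$voxels

#' Grid of an image volume
#' @param vol an [image_volume()].
#' @return the matching [voxel_grid()].
#' @export
volume_grid <- function(vol) voxel_grid(dim(vol$voxels), vol$voxel_size)

#' Label volume
#'
#' Integer labels on the same grid as a paired [image_volume()], with a legend
#' mapping region names to label codes. Label 0 is "outside / unlabelled".
#'
#' @param labels 3D integer array.
#' @param legend named integer vector, `name -> label code`; must cover every
#'   nonzero label present.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  legend <- vapply(legend, as.integer, integer(1))
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% legend))
    stop("legend does not cover labels: ",
         paste(setdiff(present, legend), collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_volume")
}

#' @exportS3Method print label_volume
print.label_volume <- function(x, ...) {
  cat("<label_volume>", paste(names(x$legend), x$legend, sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Mask of a named region in a label volume
#' @param labels a [label_volume()].
#' @param name region name present in the legend.
#' @return logical array.
#' @export
label_mask <- function(labels, name) {
  if (!name %in% names(labels$legend))
    stop("no label named '", name, "' in legend")
  labels$labels == labels$legend[[name]]
}

#' Read / write image volumes as NIfTI-1
#'
#' Voxel data and voxel sizes round-trip exactly for double-precision data
#' (volumes are written as FLOAT64).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an [image_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
  vs <- RNifti::pixdim(img)[1:3]
  if (any(vs <= 0)) stop("non-positive voxel dimensions in NIfTI header: ", path)
  image_volume(arr, vs, check = FALSE)
}

#' @rdname read_volume
#' @param vol an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(structure(vol$voxels, pixdim = vol$voxel_size),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}
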