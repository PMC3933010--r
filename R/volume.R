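# Gray-level volume container and voxel-grid helpers. Voxel (1,1,1) sits at
# `origin` (pixel-center convention); the orientation matrix maps image axes
# to patient axes (the ICS->PCS role). All modeling operates in the
# de-rotated patient frame where the orientation is the identity.

#' Image volume
#'
#' @param voxels 3D numeric array of gray levels.
#' @param spacing positive length-3 voxel size (mm).
#' @param origin length-3 patient-space position of the first voxel center (mm).
#' @param orientation 3 x 3 orthonormal direction matrix (image axes to
#'   patient axes).
#' @return An object of class `"image_volume"`.
#' @export
image_volume <- function(voxels, spacing, origin, orientation = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_input("voxels must be a 3D array")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop_input("spacing must be three positive voxel sizes")
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin)))
    stop_input("origin must be a finite numeric 3-vector")
  if (!is.matrix(orientation) || any(dim(orientation) != 3L) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop_input("orientation must be a 3 x 3 orthonormal matrix")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), orientation = orientation),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_volume: %d x %d x %d voxels, spacing (%.3f, %.3f, %.3f) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume geometry without voxel data
#'
#' @inheritParams image_volume
#' @param shape integer length-3 grid dimensions.
#' @return An object of class `"volume_geometry"`.
#' @export
volume_geometry <- function(origin, spacing, shape) {
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop_input("spacing must be three positive voxel sizes")
  if (!is.numeric(origin) || length(origin) != 3L || !all(is.finite(origin)))
    stop_input("origin must be a finite numeric 3-vector")
  if (length(shape) != 3L || any(shape < 1))
    stop_input("shape must be three positive dimensions")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = as.integer(shape)), class = "volume_geometry")
}

geometry_of <- function(x) {
  if (inherits(x, "volume_geometry")) return(x)
  if (inherits(x, "image_volume"))
    return(volume_geometry(x$origin, x$spacing, dim(x$voxels)))
  stop_input("expected an image_volume or volume_geometry")
}

#' Slice z positions of a volume grid
#' @param x an [image_volume()] or [volume_geometry()].
#' @return Numeric vector of slice positions (mm), in the grid frame.
#' @export
slice_positions <- function(x) {
  g <- geometry_of(x)
  g$origin[3] + (seq_len(g$shape[3]) - 1L) * g$spacing[3]
}

in_plane_grid <- function(x) {
  g <- geometry_of(x)
  plane_grid(g$origin[1:2], g$spacing[1:2], g$shape[1:2])
}

#' ICS -> PCS affine of a volume
#'
#' The 4 x 4 affine mapping 0-based voxel indices to patient-space mm
#' (orientation times spacing, plus origin).
#'
#' @param x an [image_volume()] or [volume_geometry()].
#' @return 4 x 4 numeric matrix.
#' @export
volume_affine <- function(x) {
  g <- geometry_of(x)
  orient <- if (inherits(x, "image_volume")) x$orientation else diag(3)
  m <- diag(4)
  m[1:3, 1:3] <- orient %*% diag(g$spacing)
  m[1:3, 4] <- g$origin
  m
}

# Map each stack slice to a volume slice index; z must land within half a
# slice spacing of a grid slice.
match_slices <- function(stack_z, x, tol = NULL) {
  g <- geometry_of(x)
  zg <- slice_positions(g)
  tol <- tol %||% (0.5 * g$spacing[3] + 1e-6)
  vapply(stack_z, function(z) {
    k <- which.min(abs(zg - z))
    if (abs(zg[k] - z) > tol)
      stop_input("slice z = %.3f mm does not lie on the volume grid", z)
    as.integer(k)
  }, integer(1))
}

#' Rasterize an ellipse stack on a volume grid
#'
#' Fills, for every stack slice, the pixels whose centers lie inside the
#' slice ellipse (pixel-center rule); all other slices are `FALSE`.
#'
#' @param stack an [ellipse_stack()] whose slice z positions lie on the grid.
#' @param x an [image_volume()] or [volume_geometry()].
#' @param dilate_mm optional isotropic enlargement of every slice ellipse's
#'   semi-axes (mm) before rasterization.
#' @return Logical 3D array with the grid's dimensions.
#' @export
rasterize_stack <- function(stack, x, dilate_mm = 0) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  g <- geometry_of(x)
  ks <- match_slices(stack$z, g)
  mask <- array(FALSE, g$shape)
  pg <- in_plane_grid(g)
  for (i in seq_along(ks)) {
    p <- stack$params[[i]]
    if (dilate_mm != 0) p <- ellipse(p$theta, p$alpha + dilate_mm, p$phi)
    mask[, , ks[i]] <- rasterize_ellipse(p, pg)
  }
  mask
}
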