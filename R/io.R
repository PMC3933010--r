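# File interfaces: versioned JSON documents for contours, control points,
# stacks, shape models and volume geometry (explicit mm units), NIfTI volume
# I/O, and de-rotation into the aligned patient frame.

FORMAT_VERSION <- "1.0"

write_json_doc <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_json_doc <- function(path, kind) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_input("cannot parse %s: %s", path,
                                                 conditionMessage(e)))
  if (!identical(doc$kind, kind))
    stop_input("%s is not a '%s' document", path, kind)
  doc
}

#' Write / read contours as JSON
#'
#' Contours are stored with explicit mm units and one record per slice; on
#' reading they are sorted by z regardless of file order.
#'
#' @param contours list of [slice_contour()].
#' @param path file path.
#' @return `read_contours()` returns a list of [slice_contour()].
#' @export
write_contours <- function(contours, path) {
  write_json_doc(list(
    kind = "contours", version = FORMAT_VERSION, units = "mm",
    slices = lapply(contours, function(ct)
      list(z = ct$z, points = unname(ct$points)))), path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  doc <- read_json_doc(path, "contours")
  contours <- lapply(seq_along(doc$slices$z), function(i) {
    pts <- doc$slices$points[[i]]
    if (is.null(dim(pts)))
      stop_input("%s: slice %d has malformed points", path, i)
    slice_contour(doc$slices$z[i], matrix(as.numeric(pts), ncol = 2L))
  })
  contours[order(vapply(contours, function(ct) ct$z, numeric(1)))]
}

#' Write / read control points as JSON
#'
#' @param cp a [control_points()] object.
#' @param path file path.
#' @return `read_control_points()` returns a [control_points()] object.
#' @export
write_control_points <- function(cp, path) {
  write_json_doc(list(
    kind = "control_points", version = FORMAT_VERSION, units = "mm",
    groups = lapply(unclass(cp), unname)), path)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  doc <- read_json_doc(path, "control_points")
  g <- lapply(doc$groups, function(m) matrix(as.numeric(m), ncol = 3L))
  control_points(g$first, g$center, g$last)
}

#' Write / read an ellipse stack as JSON
#'
#' @param stack an [ellipse_stack()].
#' @param path file path.
#' @return `read_stack()` returns an [ellipse_stack()].
#' @export
write_stack <- function(stack, path) {
  m <- stack_matrix(stack)
  write_json_doc(list(
    kind = "ellipse_stack", version = FORMAT_VERSION, units = "mm",
    z = stack$z,
    theta = unname(m[, 1:2, drop = FALSE]),
    alpha = unname(m[, 3:4, drop = FALSE]),
    phi = m[, 5L]), path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  doc <- read_json_doc(path, "ellipse_stack")
  matrix_stack(as.numeric(doc$z),
               cbind(matrix(as.numeric(doc$theta), ncol = 2L),
                     matrix(as.numeric(doc$alpha), ncol = 2L),
                     as.numeric(doc$phi)))
}

#' Write / read a trained shape model as JSON
#'
#' All per-slice moments, the canonical slice count, the training size and
#' the position mode are stored; the loader re-validates the invariants.
#'
#' @param model a [fit_shape_model()] result.
#' @param path file path.
#' @return `read_shape_model()` returns a `shape_model`.
#' @export
write_shape_model <- function(model, path) {
  if (!inherits(model, "shape_model")) stop_input("expected a shape_model")
  doc <- lapply(unclass(model), unname)
  # the per-slice center covariances are stored flat (column-major, L x 3 x 3)
  doc$Sigma_theta <- as.numeric(model$Sigma_theta)
  doc$kind <- "shape_model"
  doc$version <- FORMAT_VERSION
  write_json_doc(doc, path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  doc <- read_json_doc(path, "shape_model")
  L <- as.integer(doc$L)
  mat <- function(x, k) matrix(as.numeric(unlist(x)), L, k, byrow = is.list(x))
  Sigma <- array(as.numeric(unlist(doc$Sigma_theta)), c(L, 3L, 3L))
  model <- structure(list(
    L = L, n_train = as.integer(doc$n_train), mode = doc$mode,
    z = as.numeric(doc$z),
    mu_eta = mat(doc$mu_eta, 2L), sigma_eta = mat(doc$sigma_eta, 2L),
    mu_theta = mat(doc$mu_theta, 3L), sigma_theta = mat(doc$sigma_theta, 3L),
    Sigma_theta = Sigma,
    mu_a = mat(doc$mu_a, 2L), sigma_a = mat(doc$sigma_a, 2L),
    mu_phi = as.numeric(doc$mu_phi), sigma_phi = as.numeric(doc$sigma_phi)
  ), class = "shape_model")
  if (any(model$sigma_eta < 0) || any(model$sigma_a < 0) ||
      any(model$sigma_phi < 0) || any(!is.finite(exp(model$mu_a))))
    stop_input("%s: invalid shape-model moments", path)
  for (l in seq_len(L)) {
    S <- model$Sigma_theta[l, , ]
    if (max(abs(S - t(S))) > 1e-8 || any(eigen(S, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-8))
      stop_input("%s: Sigma_theta is not symmetric positive semi-definite", path)
  }
  model
}

#' Write / read volume geometry as JSON
#'
#' @param geometry a [volume_geometry()] (or [image_volume()], whose
#'   geometry is stored).
#' @param path file path.
#' @return `read_geometry()` returns a [volume_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  g <- geometry_of(geometry)
  write_json_doc(list(kind = "volume_geometry", version = FORMAT_VERSION,
                      units = "mm", origin = g$origin, spacing = g$spacing,
                      shape = g$shape), path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  doc <- read_json_doc(path, "volume_geometry")
  volume_geometry(as.numeric(doc$origin), as.numeric(doc$spacing),
                  as.integer(doc$shape))
}

#' Write / read a gray-level volume as NIfTI
#'
#' Geometry (spacing, origin, orientation) is carried in the NIfTI sform;
#' voxel data are stored as float64. Note NIfTI-1 stores the affine in
#' single precision, so geometry round-trips to about 1e-7 relative.
#'
#' @param volume an [image_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns an [image_volume()].
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "image_volume")) stop_input("expected an image_volume")
  img <- RNifti::asNifti(volume$voxels, datatype = "double")
  aff <- volume_affine(volume)
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  dirs <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(dirs^2))
  if (any(spacing <= 0)) stop_input("%s: non-positive voxel spacing", path)
  orientation <- sweep(dirs, 2L, spacing, "/")
  image_volume(array(as.numeric(img), dim(img)), spacing, aff[1:3, 4],
               orientation)
}

#' De-rotate into the aligned patient frame
#'
#' Applies the inverse of the volume's direction matrix about `origin` so
#' that slice planes align with the grid axes. Point sets (n x 3 matrices),
#' contour lists, control points and volumes are supported; de-rotating a
#' volume resets its orientation to the identity (voxels are untouched).
#'
#' @param x object to de-rotate.
#' @param orientation 3 x 3 orthonormal direction matrix (for volumes the
#'   volume's own orientation is used).
#' @param origin rotation center (mm), default the zero vector.
#' @return The de-rotated object of the same type.
#' @export
derotate <- function(x, orientation, origin = c(0, 0, 0)) UseMethod("derotate")

check_orientation <- function(orientation) {
  if (!is.matrix(orientation) || any(dim(orientation) != 3L) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop_input("orientation must be a 3 x 3 orthonormal matrix")
  orientation
}

#' @export
derotate.matrix <- function(x, orientation, origin = c(0, 0, 0)) {
  check_orientation(orientation)
  check_numeric_matrix(x, 3L, "points")
  sweep(sweep(x, 2L, origin) %*% orientation, 2L, origin, "+")
}

#' @export
derotate.list <- function(x, orientation, origin = c(0, 0, 0)) {
  lapply(x, function(ct) {
    if (!inherits(ct, "slice_contour"))
      stop_input("derotate.list expects slice_contour elements")
    p3 <- derotate(cbind(ct$points, ct$z), orientation, origin)
    if (diff(range(p3[, 3])) > 1e-6)
      stop_input("de-rotated contour is no longer planar in z")
    slice_contour(mean(p3[, 3]), p3[, 1:2, drop = FALSE])
  })
}

#' @export
derotate.control_points <- function(x, orientation, origin = c(0, 0, 0)) {
  control_points(derotate(x$first, orientation, origin),
                 derotate(x$center, orientation, origin),
                 derotate(x$last, orientation, origin))
}

#' @export
derotate.image_volume <- function(x, orientation = x$orientation,
                                  origin = c(0, 0, 0)) {
  check_orientation(orientation)
  image_volume(x$voxels, x$spacing,
               as.numeric(derotate(matrix(x$origin, 1L, 3L),
                                   orientation, origin)),
               t(orientation) %*% x$orientation)
}
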