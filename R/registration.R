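# Control points and registration into the common sample space: the
# similarity-type transform derived from the 18 control points (translation,
# one isotropic in-plane scale, one in-plane rotation, one z-scale), and the
# quadratic center curve through the three control-point group centroids.

#' Control-point set
#'
#' 18 labeled boundary points: 6 on each of the organ's first, center and
#' last contour slices. Points are 3-vectors in patient-space mm; within a
#' group all points share the slice z (coplanarity is enforced), and the
#' three group z values must be distinct and strictly increasing.
#'
#' @param first,center,last numeric 6 x 3 matrices (mm).
#' @return An object of class `"control_points"`.
#' @export
control_points <- function(first, center, last) {
  groups <- list(first = first, center = center, last = last)
  for (g in names(groups)) {
    m <- groups[[g]]
    check_numeric_matrix(m, 3L, sprintf("control-point group '%s'", g))
    if (nrow(m) != 6L)
      stop_input("control-point group '%s' must contain exactly 6 points", g)
    if (diff(range(m[, 3])) > 1e-6)
      stop_input("control-point group '%s' is not coplanar in z", g)
  }
  z <- vapply(groups, function(m) mean(m[, 3]), numeric(1))
  if (any(diff(z) <= 0))
    stop_input("control-point groups must have distinct, increasing z")
  structure(groups, class = "control_points")
}

#' @export
print.control_points <- function(x, ...) {
  z <- cp_z(x)
  cat(sprintf("control_points: 6 points each at z = %.2f, %.2f, %.2f mm\n",
              z[1], z[2], z[3]))
  invisible(x)
}

cp_z <- function(cp) vapply(cp, function(m) mean(m[, 3]), numeric(1))

cp_all <- function(cp) rbind(cp$first, cp$center, cp$last)

cp_centroids <- function(cp) {
  t(vapply(cp, function(m) colMeans(m), numeric(3)))
}

#' Place control points automatically on a fitted stack
#'
#' Emulates manual control-point definition: 6 points on the ellipse boundary
#' of the first, center (`ceiling(L/2)`) and last slices, at parametric
#' angles 0, 60, ..., 300 degrees measured from the first principal axis,
#' optionally jittered in-plane by isotropic Gaussian noise to mimic manual
#' placement.
#'
#' @param stack an [ellipse_stack()] with at least 3 slices.
#' @param jitter_sd in-plane jitter standard deviation (mm, default 0).
#' @param seed optional RNG seed for the jitter (the caller's random stream
#'   is left untouched when a seed is given).
#' @return A [control_points()] object.
#' @export
auto_control_points <- function(stack, jitter_sd = 0, seed = NULL) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  L <- length(stack)
  if (L < 3L) stop_input("automatic control points need at least 3 slices")
  idx <- c(1L, as.integer(ceiling(L / 2)), L)
  ang <- 2 * pi * (0:5) / 6
  make_group <- function(i) {
    b <- ellipse_boundary(stack$params[[i]], angles = ang)
    cbind(b, stack$z[i])
  }
  groups <- lapply(idx, make_group)
  if (jitter_sd > 0) {
    groups <- with_seed(seed, lapply(groups, function(g) {
      g[, 1:2] <- g[, 1:2] + matrix(stats::rnorm(12L, sd = jitter_sd), 6L, 2L)
      g
    }))
  }
  control_points(groups[[1L]], groups[[2L]], groups[[3L]])
}

#' Sample-space transform derived from control points
#'
#' @param translation numeric length-3 (mm), subtracted first.
#' @param scale positive isotropic in-plane scale factor applied after
#'   translation and rotation.
#' @param rotation in-plane rotation (radians) applied about the origin.
#' @param z_scale positive scale applied to the translated z coordinate.
#' @return An object of class `"sample_transform"`.
#' @export
sample_transform <- function(translation, scale, rotation, z_scale) {
  if (!is.numeric(translation) || length(translation) != 3L ||
      !all(is.finite(translation)))
    stop_input("translation must be a finite numeric 3-vector")
  if (!is_number(scale) || scale <= 0) stop_input("scale must be positive")
  if (!is_number(rotation)) stop_input("rotation must be a finite angle")
  if (!is_number(z_scale) || z_scale <= 0)
    stop_input("z_scale must be positive")
  structure(list(translation = as.numeric(translation), scale = scale,
                 rotation = rotation, z_scale = z_scale),
            class = "sample_transform")
}

#' @export
print.sample_transform <- function(x, ...) {
  cat(sprintf(
    "sample_transform: shift (%.2f, %.2f, %.2f) mm, scale %.4f, rotation %.4f rad, z-scale %.4f\n",
    x$translation[1], x$translation[2], x$translation[3],
    x$scale, x$rotation, x$z_scale))
  invisible(x)
}

#' Compute the control-point normalization transform
#'
#' Maps a de-rotated case into the common sample space: the centroid of all
#' 18 control points goes to the origin; the z span between the first and
#' last group maps to 1; the root-mean-square in-plane radius of the
#' center-slice group (about its own in-plane centroid) maps to 1; and the
#' dominant in-plane direction of the center group (first principal direction
#' of its 6 points, sign fixed towards the group's first labeled point) is
#' rotated onto the x-axis.
#'
#' @param cp a [control_points()] object.
#' @return A [sample_transform()].
#' @export
compute_transform <- function(cp) {
  if (!inherits(cp, "control_points")) stop_input("expected control_points")
  P <- cp_all(cp)
  ctr <- colMeans(P)
  q <- cp$center[, 1:2, drop = FALSE]
  qc <- colMeans(q)
  rms <- sqrt(mean(rowSums(sweep(q, 2L, qc)^2)))
  if (!is.finite(rms) || rms < 1e-6)
    stop_input("degenerate control points: coincident center-slice group")
  v <- eigen(stats::cov(q), symmetric = TRUE)$vectors[, 1L]
  d1 <- q[1L, ] - qc
  if (sum(v * d1) < 0) v <- -v # sign fixed by the labeled first point
  psi <- -atan2(v[2], v[1])
  z <- cp_z(cp)
  zspan <- z[3L] - z[1L]
  if (zspan <= 1e-9) stop_input("degenerate control points: zero z span")
  sample_transform(ctr, 1 / rms, psi, 1 / zspan)
}

# Forward map of an n x 3 point matrix into the sample space.
transform_points <- function(t, pts) {
  check_numeric_matrix(pts, 3L, "pts")
  xy <- sweep(pts[, 1:2, drop = FALSE], 2L, t$translation[1:2])
  xy <- (xy %*% t(rot2(t$rotation))) * t$scale
  z <- (pts[, 3] - t$translation[3]) * t$z_scale
  cbind(xy, z)
}

inverse_points <- function(t, pts) {
  check_numeric_matrix(pts, 3L, "pts")
  xy <- (pts[, 1:2, drop = FALSE] / t$scale) %*% rot2(t$rotation)
  xy <- sweep(xy, 2L, t$translation[1:2], "+")
  z <- pts[, 3] / t$z_scale + t$translation[3]
  cbind(xy, z)
}

#' Apply a sample-space transform to control points
#' @param cp a [control_points()] object.
#' @param t a [sample_transform()].
#' @param inverse map back from the sample space.
#' @return The transformed [control_points()].
#' @export
transform_control_points <- function(cp, t, inverse = FALSE) {
  f <- if (inverse) inverse_points else transform_points
  control_points(f(t, cp$first), f(t, cp$center), f(t, cp$last))
}

#' Map an ellipse stack into the sample space
#'
#' Centers are translated/rotated/scaled, semi-axes multiplied by the
#' in-plane scale, rotations incremented by the in-plane rotation (wrapped to
#' `(-pi, pi]`), and slice positions mapped by the z translation and scale.
#' The map is exactly invertible by [from_sample_space()].
#'
#' @param stack an [ellipse_stack()].
#' @param t a [sample_transform()].
#' @return The transformed [ellipse_stack()].
#' @export
to_sample_space <- function(stack, t) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  if (!inherits(t, "sample_transform")) stop_input("expected a sample_transform")
  m <- stack_matrix(stack)
  p3 <- transform_points(t, cbind(m[, 1:2], stack$z))
  m[, 1:2] <- p3[, 1:2]
  m[, 3:4] <- m[, 3:4] * t$scale
  m[, 5L] <- wrap_pi(m[, 5L] + t$rotation)
  matrix_stack(p3[, 3], m)
}

#' Map an ellipse stack back from the sample space
#' @inheritParams to_sample_space
#' @return The back-transformed [ellipse_stack()].
#' @export
from_sample_space <- function(stack, t) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  if (!inherits(t, "sample_transform")) stop_input("expected a sample_transform")
  m <- stack_matrix(stack)
  p3 <- inverse_points(t, cbind(m[, 1:2], stack$z))
  m[, 1:2] <- p3[, 1:2]
  m[, 3:4] <- m[, 3:4] / t$scale
  m[, 5L] <- wrap_pi(m[, 5L] - t$rotation)
  matrix_stack(p3[, 3], m)
}

#' Center curve through the control-point group centroids
#'
#' The unique in-plane quadratic in z through the three group centroids:
#' each in-plane component is `c0 + c1 z + c2 z^2`. The curve passes exactly
#' through the three centroids; per-slice ellipse centers are modeled as
#' curve value plus a per-slice offset eta.
#'
#' @param cp a [control_points()] object.
#' @return An object of class `"center_curve"` (coefficients plus the cp z
#'   range); evaluate with [predict.center_curve()].
#' @export
center_curve <- function(cp) {
  if (!inherits(cp, "control_points")) stop_input("expected control_points")
  G <- cp_centroids(cp)
  z <- G[, 3]
  if (min(diff(sort(z))) < 1e-9)
    stop_input("degenerate control points: duplicate group z")
  A <- cbind(1, z, z^2)
  coef <- solve(A, G[, 1:2, drop = FALSE])
  structure(list(coef = coef, z_range = range(z)), class = "center_curve")
}

#' Evaluate a center curve
#' @param object a [center_curve()].
#' @param z slice positions (mm).
#' @param ... unused.
#' @return Numeric `length(z) x 2` matrix of in-plane curve points (mm).
#' @export
predict.center_curve <- function(object, z, ...) {
  cbind(1, z, z^2) %*% object$coef
}

#' Center-curve intersection points at canonical slices
#'
#' Evaluates the quadratic center curve at `L` equally spaced slice positions
#' across the control-point z span.
#'
#' @param cp a [control_points()] object.
#' @param L number of canonical slices (>= 3).
#' @return Numeric `L x 2` matrix.
#' @export
center_curve_points <- function(cp, L) {
  if (!is_number(L) || L < 3) stop_input("L must be >= 3")
  curve <- center_curve(cp)
  z <- seq(curve$z_range[1], curve$z_range[2], length.out = as.integer(L))
  predict(curve, z)
}

#' Normalize one case into the sample space
#'
#' The full per-case pipeline: fit per-slice ellipses, establish axis
#' correspondence (reorder, relax near-circular rotations, smooth), derive
#' the control-point transform, map into the sample space, and resample to
#' `L` canonical slices. Training cases without manual control points get
#' automatic ones ([auto_control_points()]).
#'
#' @param contours list of [slice_contour()] sorted by z.
#' @param cp optional [control_points()]; placed automatically when `NULL`.
#' @param L canonical slice count (default 11).
#' @param circ_threshold,window forwarded to [relax_circular()] and
#'   [smooth_rotation()].
#' @param cp_jitter_sd,seed jitter for automatic control points.
#' @return A list with `stack` (sample-space [ellipse_stack()] of length `L`),
#'   `xi` (`L x 2` center-curve values at the canonical slices), `curve`,
#'   `transform`, `cp` and `bfe` (the processed patient-frame stack).
#' @export
normalize_case <- function(contours, cp = NULL, L = 11L,
                           circ_threshold = 0.95, window = 3L,
                           cp_jitter_sd = 0, seed = NULL) {
  bfe <- fit_stack(contours)
  bfe <- smooth_rotation(relax_circular(reorder_axes(bfe), circ_threshold),
                         window)
  if (is.null(cp))
    cp <- auto_control_points(bfe, jitter_sd = cp_jitter_sd, seed = seed)
  tr <- compute_transform(cp)
  ss <- resample_stack(canonicalize_labels(to_sample_space(bfe, tr)), L)
  cp_ss <- transform_control_points(cp, tr)
  curve <- center_curve(cp_ss)
  list(stack = ss, xi = predict(curve, ss$z), curve = curve,
       transform = tr, cp = cp, bfe = bfe)
}
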