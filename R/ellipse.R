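# Ellipse primitives: parameter container, boundary, orthogonal projection,
# geometric (orthogonal-distance) error, and rasterization on a pixel grid.
# All coordinates are continuous millimetres in the de-rotated patient frame.

#' In-slice ellipse parameters
#'
#' An ellipse in a slice is uniquely described by its center `theta` (mm), the
#' two semi-axis lengths `alpha` (mm) and the rotation `phi` (radians) of the
#' first axis relative to the in-slice x-axis. The boundary is
#' \deqn{C(\rho) = \{ R_\phi x + \theta :
#'       x_1^2/\alpha_1^2 + x_2^2/\alpha_2^2 = 1 \}.}
#' `alpha[1]` is the axis along direction `phi`; no magnitude ordering is
#' implied (axis labels are assigned by the correspondence step, see
#' [reorder_axes()]).
#'
#' @param theta numeric length-2 center (mm).
#' @param alpha numeric length-2 strictly positive semi-axis lengths (mm).
#' @param phi   finite rotation angle (radians).
#' @return An object of class `"ellipse"`.
#' @examples
#' e <- ellipse(c(5, -2), c(3, 1), 0)
#' ellipse_boundary(e, 4)
#' @export
ellipse <- function(theta, alpha, phi) {
  if (!is.numeric(theta) || length(theta) != 2L || !all(is.finite(theta)))
    stop_input("theta must be a finite numeric 2-vector")
  if (!is.numeric(alpha) || length(alpha) != 2L || !all(is.finite(alpha)) ||
      any(alpha <= 0))
    stop_input("alpha must contain two strictly positive finite lengths")
  if (!is_number(phi))
    stop_input("phi must be a single finite angle")
  structure(
    list(theta = as.numeric(theta), alpha = as.numeric(alpha),
         phi = as.numeric(phi)),
    class = "ellipse"
  )
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf(
    "ellipse: center (%.3f, %.3f) mm, semi-axes (%.3f, %.3f) mm, phi %.4f rad\n",
    x$theta[1], x$theta[2], x$alpha[1], x$alpha[2], x$phi))
  invisible(x)
}

is_ellipse <- function(x) inherits(x, "ellipse")

assert_ellipse <- function(x) {
  if (!is_ellipse(x)) stop_input("expected an 'ellipse' object")
  if (any(x$alpha <= 0)) stop_input("ellipse semi-axes must be positive")
  invisible(x)
}

#' Sample points on an ellipse boundary
#'
#' Returns `n_points` boundary points uniformly spaced in the parametric angle
#' `t`, i.e. `theta + R_phi (alpha_1 cos t, alpha_2 sin t)`.
#'
#' @param params an [ellipse()].
#' @param n_points number of points (>= 3) when `angles` is `NULL`.
#' @param angles optional explicit parametric angles (radians).
#' @return Numeric matrix with one `(x, y)` row per point (mm).
#' @export
ellipse_boundary <- function(params, n_points = 360L, angles = NULL) {
  assert_ellipse(params)
  if (is.null(angles)) {
    if (!is_number(n_points) || n_points < 3)
      stop_input("n_points must be at least 3")
    angles <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  }
  local <- cbind(params$alpha[1] * cos(angles), params$alpha[2] * sin(angles))
  sweep(local %*% t(rot2(params$phi)), 2L, params$theta, "+")
}

# Value of the implicit form (u1/a1)^2 + (u2/a2)^2 at points (rows of `pts`);
# equals 1 on the boundary, < 1 inside.
ellipse_implicit <- function(params, pts) {
  u <- sweep(pts, 2L, params$theta) %*% rot2(params$phi)
  (u[, 1] / params$alpha[1])^2 + (u[, 2] / params$alpha[2])^2
}

# Vectorized orthogonal projection of points onto the ellipse boundary.
# Strategy: coarse parametric scan (32 angles) for a global bracket, then a
# clamped Newton iteration on the orthogonality condition
#   E(t) = (a2^2 - a1^2) sin t cos t + u1 a1 sin t - u2 a2 cos t = 0,
# with a dense-scan + local refinement fallback for non-converged points.
project_points <- function(params, pts, tol = 1e-12, max_iter = 100L) {
  assert_ellipse(params)
  check_numeric_matrix(pts, 2L, "pts")
  a1 <- params$alpha[1]; a2 <- params$alpha[2]
  u <- sweep(pts, 2L, params$theta) %*% rot2(params$phi)
  n <- nrow(u)

  dist2_at <- function(t, u1, u2) (a1 * cos(t) - u1)^2 + (a2 * sin(t) - u2)^2
  # coarse global scan
  tt <- 2 * pi * (0:31) / 32
  d2 <- outer(u[, 1], a1 * cos(tt), "-")^2 + outer(u[, 2], a2 * sin(tt), "-")^2
  t <- tt[max.col(-d2, ties.method = "first")]
  # degenerate query: center of a circle, every boundary point equidistant;
  # the first-axis endpoint (t = 0) is the documented deterministic choice
  degen <- abs(a1 - a2) < 1e-12 * max(a1, a2) &
    sqrt(rowSums(u^2)) < 1e-9 * max(a1, a2)
  t[degen] <- 0

  scale <- max(a1, a2) * (max(a1, a2) + sqrt(max(rowSums(u^2), 1)))
  E_fun <- function(t) {
    (a2^2 - a1^2) * sin(t) * cos(t) + u[, 1] * a1 * sin(t) -
      u[, 2] * a2 * cos(t)
  }
  Ep_fun <- function(t) {
    (a2^2 - a1^2) * cos(2 * t) + u[, 1] * a1 * cos(t) + u[, 2] * a2 * sin(t)
  }
  for (it in seq_len(max_iter)) {
    E <- E_fun(t)
    if (all(abs(E) <= tol * scale)) break
    Ep <- Ep_fun(t)
    step <- ifelse(abs(Ep) > 1e-300, E / Ep, 0)
    step <- pmin(pmax(step, -0.3), 0.3)
    t <- t - step
  }
  bad <- which(abs(E_fun(t)) > tol * scale)
  for (i in bad) { # dense fallback, per straggler
    tt2 <- 2 * pi * (0:4095) / 4096
    dd <- dist2_at(tt2, u[i, 1], u[i, 2])
    t0 <- tt2[which.min(dd)]
    opt <- stats::optimize(dist2_at, interval = c(t0 - 2 * pi / 4096,
                                                  t0 + 2 * pi / 4096),
                           u1 = u[i, 1], u2 = u[i, 2], tol = 1e-14)
    t[i] <- opt$minimum
  }
  # guard against a Newton step having left the global basin
  d2_new <- dist2_at(t, u[, 1], u[, 2])
  d2_coarse <- d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))]
  worse <- which(d2_new > d2_coarse + tol * scale)
  for (i in worse) {
    tt2 <- 2 * pi * (0:4095) / 4096
    dd <- dist2_at(tt2, u[i, 1], u[i, 2])
    t0 <- tt2[which.min(dd)]
    opt <- stats::optimize(dist2_at, interval = c(t0 - 2 * pi / 4096,
                                                  t0 + 2 * pi / 4096),
                           u1 = u[i, 1], u2 = u[i, 2], tol = 1e-14)
    t[i] <- opt$minimum
  }

  local <- cbind(a1 * cos(t), a2 * sin(t))
  foot <- sweep(local %*% t(rot2(params$phi)), 2L, params$theta, "+")
  list(foot = foot, distance = sqrt(rowSums((pts - foot)^2)), t = t)
}

#' Orthogonal projection of a point onto an ellipse
#'
#' Finds the nearest boundary point (the foot of the orthogonal projection)
#' and the Euclidean distance to it. For the degenerate query at the center of
#' a circle every boundary point is equidistant; the first-axis endpoint
#' (parametric angle 0) is returned deterministically.
#'
#' @param params an [ellipse()].
#' @param point numeric length-2 query point (mm).
#' @return A list with `foot` (length-2, on the boundary) and `distance` (mm).
#' @export
project_point_to_ellipse <- function(params, point) {
  if (!is.numeric(point) || length(point) != 2L || !all(is.finite(point)))
    stop_input("point must be a finite numeric 2-vector")
  pr <- project_points(params, matrix(point, 1L, 2L))
  list(foot = as.numeric(pr$foot[1L, ]), distance = pr$distance[1L])
}

#' Per-slice contour
#'
#' A closed in-plane polyline (last vertex connects to the first) at stack
#' position `z`.
#'
#' @param z slice position along the stack axis (mm).
#' @param points numeric matrix, one `(x, y)` vertex per row (mm).
#' @return An object of class `"slice_contour"`.
#' @export
slice_contour <- function(z, points) {
  if (!is_number(z)) stop_input("z must be a single finite position")
  check_numeric_matrix(points, 2L, "points")
  structure(list(z = as.numeric(z), points = points), class = "slice_contour")
}

#' @export
print.slice_contour <- function(x, ...) {
  cat(sprintf("slice_contour: z = %.3f mm, %d vertices\n", x$z, nrow(x$points)))
  invisible(x)
}

#' Orthogonal-distance error of an ellipse against a contour
#'
#' The geometric objective of the best-fitting-ellipse problem: the sum of
#' squared orthogonal distances of all contour vertices to the ellipse
#' boundary.
#'
#' @param params an [ellipse()].
#' @param contour a [slice_contour()].
#' @return Non-negative scalar (mm^2).
#' @export
geometric_error <- function(params, contour) {
  if (!inherits(contour, "slice_contour"))
    stop_input("contour must be a 'slice_contour'")
  sum(project_points(params, contour$points)$distance^2)
}

#' In-plane pixel grid specification
#'
#' Pixel index `(1, 1)` maps to `origin` (the center of the first pixel);
#' pixel `(i, j)` sits at `origin + ((i, j) - 1) * spacing`.
#'
#' @param origin numeric length-2 (mm), center of the first pixel.
#' @param spacing numeric length-2 positive pixel size (mm).
#' @param shape integer length-2 grid dimensions.
#' @return An object of class `"plane_grid"`.
#' @export
plane_grid <- function(origin, spacing, shape) {
  if (!is.numeric(origin) || length(origin) != 2L || !all(is.finite(origin)))
    stop_input("origin must be a finite numeric 2-vector")
  if (!is.numeric(spacing) || length(spacing) != 2L || any(spacing <= 0))
    stop_input("spacing must be two positive pixel sizes")
  if (length(shape) != 2L || any(shape < 1))
    stop_input("shape must be two positive dimensions")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = as.integer(shape)), class = "plane_grid")
}

grid_axis <- function(grid, k) {
  grid$origin[k] + (seq_len(grid$shape[k]) - 1L) * grid$spacing[k]
}

#' Rasterize an ellipse on a pixel grid
#'
#' A pixel belongs to the mask iff its center satisfies the implicit
#' inequality `(u1/a1)^2 + (u2/a2)^2 <= 1` (pixel-center rule, no partial-area
#' weighting). An ellipse entirely outside the grid yields an all-`FALSE`
#' mask.
#'
#' @param params an [ellipse()].
#' @param grid a [plane_grid()].
#' @return Logical matrix of dimension `grid$shape`.
#' @export
rasterize_ellipse <- function(params, grid) {
  assert_ellipse(params)
  if (!inherits(grid, "plane_grid")) stop_input("grid must be a 'plane_grid'")
  x <- grid_axis(grid, 1L)
  y <- grid_axis(grid, 2L)
  ct <- cos(params$phi); st <- sin(params$phi)
  dx <- x - params$theta[1]; dy <- y - params$theta[2]
  # u = R^T (p - theta), expanded over the separable grid
  u1 <- outer(dx * ct, dy * st, "+")
  u2 <- outer(-dx * st, dy * ct, "+")
  (u1 / params$alpha[1])^2 + (u2 / params$alpha[2])^2 <= 1
}

#' Ordered stack of per-slice ellipses
#'
#' @param z strictly increasing slice positions (mm).
#' @param params list of [ellipse()] objects, one per slice.
#' @return An object of class `"ellipse_stack"`.
#' @export
ellipse_stack <- function(z, params) {
  if (!is.numeric(z) || !all(is.finite(z))) stop_input("z must be finite")
  if (length(z) != length(params))
    stop_input("z and params must have equal length")
  if (length(z) > 1L && any(diff(z) <= 0))
    stop_input("slice positions z must be strictly increasing")
  lapply(params, assert_ellipse)
  structure(list(z = as.numeric(z), params = params), class = "ellipse_stack")
}

#' @export
length.ellipse_stack <- function(x) length(x$z)

#' @export
print.ellipse_stack <- function(x, ...) {
  cat(sprintf("ellipse_stack: %d slices, z in [%.2f, %.2f] mm\n",
              length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

# (L x 5) parameter matrix view: theta1, theta2, alpha1, alpha2, phi.
stack_matrix <- function(stack) {
  t(vapply(stack$params, function(p) c(p$theta, p$alpha, p$phi), numeric(5)))
}

matrix_stack <- function(z, m) {
  ellipse_stack(z, lapply(seq_len(nrow(m)), function(i)
    ellipse(m[i, 1:2], m[i, 3:4], m[i, 5])))
}

#' @export
plot.ellipse_stack <- function(x, n_points = 200L, ...) {
  b <- lapply(x$params, ellipse_boundary, n_points = n_points)
  rng <- apply(do.call(rbind, b), 2L, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  for (bb in b) graphics::lines(rbind(bb, bb[1L, , drop = FALSE]))
  invisible(x)
}
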