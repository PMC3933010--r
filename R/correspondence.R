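# Parameter correspondence across slices: axis reordering anchored at the
# center slice, rotation relaxation for near-circular slices, inter-slice
# rotation smoothing, and cubic resampling to a common slice count.

# The four equivalent labelings of one ellipse: keep axes with phi + k*pi, or
# swap axes with phi + pi/2 + k*pi. Given the already-reordered neighbor angle
# `ref`, return the representation minimizing |phi - ref| (ties keep labels).
nearest_representation <- function(alpha, phi, ref) {
  best <- NULL
  for (swap in c(FALSE, TRUE)) {
    base <- if (swap) phi + pi / 2 else phi
    k <- round((ref - base) / pi)
    ang <- base + k * pi
    delta <- abs(ang - ref)
    if (is.null(best) || delta < best$delta - 1e-15) {
      best <- list(alpha = if (swap) rev(alpha) else alpha,
                   phi = ang, delta = delta)
    }
  }
  best
}

#' Reorder principal axes across a stack
#'
#' Establishes axis correspondence between adjacent slices: the center slice
#' `M = ceiling(L/2)` is the basis and left unchanged; proceeding outward
#' slice by slice, each slice's labeling is chosen among the four equivalent
#' representations (axis swap and/or rotation by multiples of `pi/2`) to
#' minimize the rotation difference to its already-reordered neighbor. Every
#' slice's boundary point set is unchanged; only the parametrization moves.
#'
#' @param stack an [ellipse_stack()] with at least 2 slices.
#' @return The reordered [ellipse_stack()].
#' @export
reorder_axes <- function(stack) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  L <- length(stack)
  if (L < 2L) return(stack)
  m <- stack_matrix(stack)
  M <- as.integer(ceiling(L / 2))
  chain <- function(indices) {
    ref <- m[M, 5L]
    for (i in indices) {
      rep <- nearest_representation(m[i, 3:4], m[i, 5L], ref)
      m[i, 3:4] <<- rep$alpha
      m[i, 5L] <<- rep$phi
      ref <- rep$phi
    }
  }
  if (M < L) chain((M + 1L):L)
  if (M > 1L) chain((M - 1L):1L)
  # fold any residual drift back into (-pi, pi] by ellipse-invariant pi shifts
  # (phi and phi + pi describe the same boundary with the same axis labels);
  # among the two in-range representatives keep the one nearest the basis angle
  out <- which(m[, 5L] <= -pi | m[, 5L] > pi)
  for (i in out) {
    cand <- wrap_half_pi(m[i, 5L]) + c(-pi, 0, pi)
    cand <- cand[cand > -pi & cand <= pi]
    m[i, 5L] <- cand[which.min(abs(cand - m[M, 5L]))]
  }
  matrix_stack(stack$z, m)
}

#' Canonicalize axis labels of a sample-space stack
#'
#' [reorder_axes()] makes labels consistent *within* one stack but leaves the
#' center slice's labeling arbitrary, so two registered cases can still carry
#' swapped labels (rotations differing by `pi/2`). In the sample space the
#' registration has aligned each case's dominant direction with the x-axis;
#' relabeling the center slice to the equivalent representation whose angle
#' is nearest 0 (and re-chaining the other slices) therefore puts all cases'
#' labels in correspondence. Boundaries are unchanged.
#'
#' @param stack a registered (sample-space) [ellipse_stack()].
#' @param ref reference angle for the center slice (default 0).
#' @return The relabeled [ellipse_stack()].
#' @export
canonicalize_labels <- function(stack, ref = 0) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  m <- stack_matrix(stack)
  M <- as.integer(ceiling(length(stack) / 2))
  rep <- nearest_representation(m[M, 3:4], m[M, 5L], ref)
  m[M, 3:4] <- rep$alpha
  m[M, 5L] <- rep$phi
  reorder_axes(matrix_stack(stack$z, m))
}

circularity <- function(alpha) min(alpha) / max(alpha)

#' Relax the rotation of near-circular slices
#'
#' A near-circular ellipse has an ill-determined orientation; its fitted
#' rotation is noise. For slices with circularity `c = min(alpha)/max(alpha)`
#' above `circ_threshold`, the angle is blended towards the mean angle of the
#' adjacent slices: `phi <- (1 - w) phi + w phi_neighbors` with
#' `w = (c - circ_threshold) / (1 - circ_threshold)`. Neighbor angles are
#' taken from the input stack (ends use their single neighbor). Non-circular
#' slices and single-slice stacks are returned unchanged.
#'
#' @param stack a reordered [ellipse_stack()].
#' @param circ_threshold circularity ratio in (0, 1) above which relaxation
#'   starts (default 0.95).
#' @return The relaxed [ellipse_stack()].
#' @export
relax_circular <- function(stack, circ_threshold = 0.95) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  if (!is_number(circ_threshold) || circ_threshold <= 0 || circ_threshold >= 1)
    stop_input("circ_threshold must lie in (0, 1)")
  L <- length(stack)
  if (L < 2L) return(stack)
  m <- stack_matrix(stack)
  phi <- m[, 5L]
  new_phi <- phi
  for (i in seq_len(L)) {
    cc <- circularity(m[i, 3:4])
    if (cc <= circ_threshold) next
    nb <- c(if (i > 1L) phi[i - 1L], if (i < L) phi[i + 1L])
    w <- (cc - circ_threshold) / (1 - circ_threshold)
    new_phi[i] <- (1 - w) * phi[i] + w * mean(nb)
  }
  m[, 5L] <- new_phi
  matrix_stack(stack$z, m)
}

#' Smooth the rotation sequence of a stack
#'
#' Replaces the rotation sequence by a centered moving average of the
#' unwrapped angles (window clipped at the stack ends); centers and semi-axes
#' are untouched. Smoothing suppresses spurious forward/backward rotations
#' between neighboring slices and never increases the total variation of the
#' angle sequence.
#'
#' @param stack a reordered [ellipse_stack()].
#' @param window odd positive window length (default 3).
#' @return The smoothed [ellipse_stack()].
#' @export
smooth_rotation <- function(stack, window = 3L) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  if (!is_number(window) || window < 1 || window %% 2 != 1)
    stop_input("window must be an odd positive integer")
  L <- length(stack)
  if (L < 2L || window == 1L) return(stack)
  m <- stack_matrix(stack)
  m[, 5L] <- moving_average(unwrap_angles(m[, 5L]), as.integer(window))
  matrix_stack(stack$z, m)
}

#' Resample a stack to a common slice count
#'
#' Interpolates each parameter (`theta1`, `theta2`, `alpha1`, `alpha2`,
#' unwrapped `phi`) independently as a one-dimensional cubic function of the
#' normalized slice position `t in [0, 1]` of the original z span, evaluated
#' at `t = 0, 1/(L-1), ..., 1`. The cubic is an interpolating spline
#' (Forsythe-Malcolm-Moler end conditions, which reproduce cubic
#' polynomials); original knots are reproduced exactly. Stacks with fewer
#' than 4 slices degrade to linear interpolation. Interpolated semi-axes are
#' floored at `1e-6` mm with a warning.
#'
#' @param stack an [ellipse_stack()] with at least 2 slices.
#' @param L target slice count (>= 3).
#' @return An [ellipse_stack()] with `L` slices spanning the original z range.
#' @export
resample_stack <- function(stack, L) {
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  if (!is_number(L) || L < 3) stop_input("target slice count L must be >= 3")
  L <- as.integer(L)
  n <- length(stack)
  if (n < 2L) stop_input("resampling needs at least 2 slices")
  z <- stack$z
  t_in <- (z - z[1L]) / (z[n] - z[1L])
  t_out <- seq(0, 1, length.out = L)
  m <- stack_matrix(stack)
  m[, 5L] <- unwrap_angles(m[, 5L])
  out <- matrix(NA_real_, L, 5L)
  for (j in 1:5) {
    out[, j] <- if (n >= 4L) {
      stats::spline(t_in, m[, j], xout = t_out, method = "fmm")$y
    } else {
      stats::approx(t_in, m[, j], xout = t_out)$y
    }
  }
  if (any(out[, 3:4] < 1e-6)) {
    warning("interpolated semi-axis below 1e-6 mm floored", call. = FALSE)
    out[, 3:4][out[, 3:4] < 1e-6] <- 1e-6
  }
  z_out <- z[1L] + t_out * (z[n] - z[1L])
  matrix_stack(z_out, out)
}
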