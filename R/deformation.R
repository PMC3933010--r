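# Deformation of the trained mean shape into a new case from its 18 control
# points: the method's primary semiautomatic output. Deterministic; no
# sampling is involved.

# Shared frame for deformation and posterior refinement: the control-point
# transform, the case's spanned slice grid, the sample-space center curve,
# and the mean shape (with per-slice prior moments) resampled to the case's
# slice count.
deform_frame <- function(model, cp, slice_z, tol = 1e-3) {
  if (!inherits(model, "shape_model")) stop_input("expected a shape_model")
  if (!inherits(cp, "control_points")) stop_input("expected control_points")
  if (!is.numeric(slice_z) || length(slice_z) < 3L || any(diff(slice_z) <= 0))
    stop_input("slice_z must be at least 3 strictly increasing positions")
  zcp <- cp_z(cp)
  for (z in zcp) {
    if (min(abs(slice_z - z)) > tol)
      stop_input("control-point slice z = %.3f mm does not lie on the case grid", z)
  }
  sel <- which(slice_z >= zcp[1] - tol & slice_z <= zcp[3] + tol)
  if (length(sel) < 3L)
    stop_input("insufficient span: control points cover %d case slice(s), need >= 3",
               length(sel))
  z_case <- slice_z[sel]
  L_c <- length(z_case)

  tr <- compute_transform(cp)
  zbar <- (z_case - tr$translation[3]) * tr$z_scale
  ms <- resample_stack(mean_shape(model), L_c)
  msm <- stack_matrix(ms)

  cp_ss <- transform_control_points(cp, tr)
  curve <- center_curve(cp_ss)
  xi_ss <- predict(curve, zbar)

  centers_ss <- if (model$mode == "eta") xi_ss + msm[, 1:2] else msm[, 1:2]
  ss_stack <- matrix_stack(zbar, cbind(centers_ss, msm[, 3:5]))
  out <- from_sample_space(ss_stack, tr)
  out$z <- z_case # grid positions are authoritative

  # prior moments interpolated to the case's slice count (linear in t)
  t_in <- seq(0, 1, length.out = model$L)
  t_out <- seq(0, 1, length.out = L_c)
  interp <- function(v) stats::approx(t_in, v, xout = t_out)$y
  interp2 <- function(m2) apply(m2, 2L, interp)
  sigma <- list(position = interp2(if (model$mode == "eta") model$sigma_eta
                                   else model$sigma_theta[, 1:2]),
                a = interp2(model$sigma_a), phi = interp(model$sigma_phi))
  mu <- list(position = msm[, 1:2], a = log(msm[, 3:4]), phi = msm[, 5L])

  list(stack = out, transform = tr, curve = curve, zbar = zbar,
       xi_ss = xi_ss, mu = mu, sigma = sigma, sel = sel, z_case = z_case)
}

#' Deform the mean shape into a new case
#'
#' Produces the deformed mean shape for a new case from its control points:
#' (1) the control points define the normalization transform and the center
#' curve; (2) the sample-space mean shape is resampled to the number of case
#' slices spanned (inclusively) by the first and last control-point slices;
#' (3) per-slice centers are set to center curve plus mean offset; (4) the
#' result is mapped through the inverse transform onto the case's slice
#' grid. Deterministic; no extrapolation beyond the control-point span.
#'
#' @param model a trained [fit_shape_model()].
#' @param cp a [control_points()] object whose slice z values lie on the
#'   case's slice grid.
#' @param slice_z the case's (equidistant) slice positions (mm).
#' @return An [ellipse_stack()] on the case's slice grid covering exactly the
#'   control-point span.
#' @export
deform_mean_shape <- function(model, cp, slice_z) {
  deform_frame(model, cp, slice_z)$stack
}

#' One-call case prediction
#'
#' Deforms the mean shape into a new case and optionally refines it against
#' the image gray levels by MCMC; per-slice masks rasterized on the volume
#' grid are returned when a volume is supplied.
#'
#' @inheritParams deform_mean_shape
#' @param volume an [image_volume()] (required when `refine = TRUE`; its
#'   slice grid is used when `slice_z` is missing).
#' @param slice_z case slice positions; defaults to the volume's.
#' @param refine run [mcmc_refine()].
#' @param config an [mcmc_config()] used when refining.
#' @return A list with `stack` (the deformed, possibly refined
#'   [ellipse_stack()]), `masks` (logical array, `NULL` without a volume),
#'   `refined`, and `diagnostics` (MCMC diagnostics or `NULL`).
#' @export
predict_case <- function(model, cp, volume = NULL, slice_z = NULL,
                         refine = FALSE, config = mcmc_config()) {
  if (refine && is.null(volume))
    stop_input("refinement requires an image volume")
  if (is.null(slice_z)) {
    if (is.null(volume))
      stop_input("either a volume or explicit slice_z is required")
    slice_z <- slice_positions(volume)
  }
  diagnostics <- NULL
  if (refine) {
    ref <- mcmc_refine(volume, model, cp, config)
    stack <- ref$stack
    diagnostics <- ref$diagnostics
  } else {
    stack <- deform_mean_shape(model, cp, slice_z)
  }
  masks <- if (!is.null(volume)) rasterize_stack(stack, volume) else NULL
  list(stack = stack, masks = masks, refined = refine,
       diagnostics = diagnostics)
}
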