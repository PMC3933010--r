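# Per-slice statistical shape model: means, variances and covariances of the
# normalized ellipse parameters over a training population, with Gaussian
# priors for positions/offsets/rotation and log-normal priors for the
# semi-axis lengths.

#' Fit a per-slice stacked-ellipse shape model
#'
#' Estimates, for each of the `L` canonical slices, the mean and variance of
#' the normalized ellipse parameters over a training population of
#' sample-space stacks: the center offsets `eta = theta - xi` from the
#' control-point center curve (or absolute centers `theta` in `"theta"`
#' mode), the log semi-axis lengths `a = log(alpha)` (so `alpha` is
#' log-normal and the mean length is geometric), and the unwrapped rotation
#' `phi` (linear, non-circular moments; the registered rotations have small
#' spread). Variances use the `1/(N-1)` estimator and the full per-slice
#' covariance of the centers is retained alongside the component-wise
#' variances.
#'
#' @param stacks list of `N >= 2` sample-space [ellipse_stack()] objects, all
#'   resampled to the same slice count `L`.
#' @param xi optional list of `L x 2` center-curve matrices aligned with
#'   `stacks` (required for `"eta"` mode; see [normalize_case()]).
#' @param mode `"eta"` (default, offsets from the center curve) or `"theta"`
#'   (absolute centers).
#' @return An object of class `"shape_model"`; see [mean_shape()],
#'   [sample_prior()], [prior_logdensity()], [predict.shape_model()].
#' @export
fit_shape_model <- function(stacks, xi = NULL, mode = c("eta", "theta")) {
  mode <- match.arg(mode)
  if (!is.list(stacks) || length(stacks) < 2L)
    stop_input("training a shape model needs at least 2 stacks (variance undefined for N = 1)")
  N <- length(stacks)
  Ls <- vapply(stacks, length, integer(1))
  if (length(unique(Ls)) != 1L)
    stop_input("shape mismatch: all training stacks must share one slice count (got %s)",
               paste(unique(Ls), collapse = ", "))
  L <- Ls[1L]
  if (L < 3L) stop_input("training stacks must have at least 3 slices")
  if (mode == "eta") {
    if (is.null(xi) || length(xi) != N)
      stop_input("mode 'eta' needs one xi matrix per training stack")
    lapply(xi, check_numeric_matrix, ncol = 2L, what = "xi")
  }

  theta <- array(NA_real_, c(N, L, 3L))
  a <- array(NA_real_, c(N, L, 2L))
  phi <- matrix(NA_real_, N, L)
  eta <- array(NA_real_, c(N, L, 2L))
  for (n in seq_len(N)) {
    m <- stack_matrix(stacks[[n]])
    theta[n, , ] <- cbind(m[, 1:2], stacks[[n]]$z)
    if (any(m[, 3:4] <= 0)) stop_input("non-positive semi-axis in stack %d", n)
    a[n, , ] <- log(m[, 3:4])
    ph <- unwrap_angles(m[, 5L])
    ph <- ph - pi * round(mean(ph) / pi) # common branch across cases
    phi[n, ] <- ph
    eta[n, , ] <- if (mode == "eta") m[, 1:2] - xi[[n]] else m[, 1:2]
  }

  mean2 <- function(arr) apply(arr, 2:3, mean)
  sd2 <- function(arr) apply(arr, 2:3, stats::sd)
  Sigma_theta <- array(NA_real_, c(L, 3L, 3L))
  for (l in seq_len(L)) Sigma_theta[l, , ] <- stats::cov(theta[, l, ])

  structure(list(
    L = L, n_train = N, mode = mode,
    z = colMeans(theta[, , 3L]),
    mu_eta = mean2(eta), sigma_eta = sd2(eta),
    mu_theta = mean2(theta), sigma_theta = sd2(theta),
    Sigma_theta = Sigma_theta,
    mu_a = mean2(a), sigma_a = sd2(a),
    mu_phi = colMeans(phi), sigma_phi = apply(phi, 2L, stats::sd)
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "shape_model: %d canonical slices, trained on %d cases, position mode '%s'\n",
    x$L, x$n_train, x$mode))
  cat(sprintf("  mean semi-axes (geometric, sample space): %.3f / %.3f\n",
              mean(exp(x$mu_a[, 1])), mean(exp(x$mu_a[, 2]))))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  out <- data.frame(
    slice = seq_len(object$L),
    mu_eta1 = object$mu_eta[, 1], mu_eta2 = object$mu_eta[, 2],
    sd_eta1 = object$sigma_eta[, 1], sd_eta2 = object$sigma_eta[, 2],
    alpha1 = exp(object$mu_a[, 1]), alpha2 = exp(object$mu_a[, 2]),
    sd_a1 = object$sigma_a[, 1], sd_a2 = object$sigma_a[, 2],
    mu_phi = object$mu_phi, sd_phi = object$sigma_phi)
  class(out) <- c("summary.shape_model", "data.frame")
  out
}

#' @export
coef.shape_model <- function(object, ...) {
  cbind(eta1 = object$mu_eta[, 1], eta2 = object$mu_eta[, 2],
        a1 = object$mu_a[, 1], a2 = object$mu_a[, 2], phi = object$mu_phi)
}

#' Mean shape of a trained model
#'
#' The per-slice mean ellipses in the sample space: semi-axes
#' `exp(mu_a)` (geometric means), rotation `mu_phi`, and centers
#' `xi + mu_eta` in offset mode (zero curve when `xi` is omitted) or
#' `mu_theta` in absolute mode.
#'
#' @param model a [fit_shape_model()] result.
#' @param xi optional `L x 2` center-curve matrix (mm).
#' @return An [ellipse_stack()] with `model$L` slices.
#' @export
mean_shape <- function(model, xi = NULL) {
  if (!inherits(model, "shape_model")) stop_input("expected a shape_model")
  centers <- if (model$mode == "eta") {
    base <- if (is.null(xi)) matrix(0, model$L, 2L) else
      check_numeric_matrix(xi, 2L, "xi")
    base + model$mu_eta
  } else {
    model$mu_theta[, 1:2, drop = FALSE]
  }
  matrix_stack(model$z, cbind(centers, exp(model$mu_a), model$mu_phi))
}

#' Draw one stack from the shape prior
#'
#' Independent draws per slice and parameter from the prior families:
#' Gaussian for the center offsets (or centers) and the rotation, log-normal
#' for the semi-axis lengths.
#'
#' @inheritParams mean_shape
#' @param seed optional RNG seed (caller's random stream preserved).
#' @return An [ellipse_stack()].
#' @export
sample_prior <- function(model, seed = NULL, xi = NULL) {
  if (!inherits(model, "shape_model")) stop_input("expected a shape_model")
  L <- model$L
  with_seed(seed, {
    pos <- if (model$mode == "eta") {
      base <- if (is.null(xi)) matrix(0, L, 2L) else xi
      base + model$mu_eta +
        matrix(stats::rnorm(2L * L), L, 2L) * model$sigma_eta
    } else {
      model$mu_theta[, 1:2] +
        matrix(stats::rnorm(2L * L), L, 2L) * model$sigma_theta[, 1:2]
    }
    alpha <- exp(model$mu_a + matrix(stats::rnorm(2L * L), L, 2L) * model$sigma_a)
    phi <- stats::rnorm(L, model$mu_phi, model$sigma_phi)
    matrix_stack(model$z, cbind(pos, alpha, phi))
  })
}

#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL, xi = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sample_prior(object, seed = NULL, xi = xi)))
}

# One Gaussian log-density term with point-mass sentinel for degenerate
# (zero-variance) slices: such terms contribute 0 when the value matches the
# mean to 1e-9 and -Inf otherwise, never NaN.
norm_term <- function(x, mu, sd) {
  degen <- sd < 1e-12
  out <- numeric(length(x))
  out[degen] <- ifelse(abs(x[degen] - mu[degen]) <= 1e-9, 0, -Inf)
  out[!degen] <- stats::dnorm(x[!degen], mu[!degen], sd[!degen], log = TRUE)
  out
}

#' Prior log-density of a stack under a shape model
#'
#' Sum over slices and parameters of the log prior densities: Gaussian for
#' the center offsets (or centers) and rotation, log-normal for the
#' semi-axis lengths (evaluated on `alpha` with the Jacobian of
#' `a = log(alpha)`). Non-positive semi-axes are outside the support and give
#' `-Inf`. Zero-variance (degenerate) slices act as point masses: they
#' contribute 0 at the mean and `-Inf` away from it.
#'
#' @inheritParams mean_shape
#' @param stack an [ellipse_stack()] with `model$L` slices.
#' @param center optional re-centering of the prior means: a list with any of
#'   `position` (`L x 2`), `a` (`L x 2`), `phi` (length `L`); standard
#'   deviations always come from the model. Used by the posterior refinement
#'   to center the prior on the deformed template.
#' @return A scalar log density (may be `-Inf`).
#' @export
prior_logdensity <- function(model, stack, xi = NULL, center = NULL) {
  if (!inherits(model, "shape_model")) stop_input("expected a shape_model")
  if (!inherits(stack, "ellipse_stack")) stop_input("expected an ellipse_stack")
  L <- model$L
  if (length(stack) != L)
    stop_input("stack has %d slices but the model expects %d", length(stack), L)
  m <- stack_matrix(stack)
  if (any(m[, 3:4] <= 0)) return(-Inf)

  if (model$mode == "eta") {
    base <- if (is.null(xi)) matrix(0, L, 2L) else xi
    pos <- m[, 1:2] - base
    mu_pos <- center$position %||% model$mu_eta
    sd_pos <- model$sigma_eta
  } else {
    pos <- m[, 1:2]
    mu_pos <- center$position %||% model$mu_theta[, 1:2]
    sd_pos <- model$sigma_theta[, 1:2]
  }
  mu_a <- center$a %||% model$mu_a
  mu_phi <- center$phi %||% model$mu_phi
  a <- log(m[, 3:4])
  phi <- unwrap_angles(m[, 5L])
  phi <- phi - pi * round(mean(phi - mu_phi) / pi)

  sum(norm_term(pos, mu_pos, sd_pos)) +
    sum(norm_term(a, mu_a, model$sigma_a) - a) + # log-normal Jacobian
    sum(norm_term(phi, mu_phi, model$sigma_phi))
}

#' Deform the mean shape into a new case
#'
#' `predict()` on a trained shape model is the method's primary semiautomatic
#' output: the mean shape deformed into a new patient from 18 control points.
#' See [deform_mean_shape()] for the procedure, and [predict_case()] for the
#' variant returning rasterized masks and optional MCMC refinement.
#'
#' @param object a [fit_shape_model()] result.
#' @param cp a [control_points()] object for the new case.
#' @param slice_z the case's slice positions (mm), or an `image_volume` /
#'   `volume_geometry` whose slice positions are used.
#' @param refine run posterior refinement against `volume` gray levels.
#' @param volume an [image_volume()] (required when `refine = TRUE`).
#' @param ... forwarded to [predict_case()] when `refine` or `volume` is set.
#' @return An [ellipse_stack()] on the case's slice grid, or the
#'   [predict_case()] list when a volume is supplied.
#' @export
predict.shape_model <- function(object, cp, slice_z = NULL, refine = FALSE,
                                volume = NULL, ...) {
  if (!is.null(volume) || refine)
    return(predict_case(object, cp, volume = volume, refine = refine, ...))
  if (inherits(slice_z, "image_volume") || inherits(slice_z, "volume_geometry"))
    slice_z <- slice_positions(slice_z)
  deform_mean_shape(object, cp, slice_z)
}

#' @export
plot.shape_model <- function(x, ...) {
  plot(mean_shape(x), main = "sample-space mean shape", ...)
  invisible(x)
}
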