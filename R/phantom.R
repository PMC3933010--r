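# Synthetic phantom populations with the acquisition geometry and the
# statistical structure the method assumes: elliptical cross sections,
# smooth inter-slice variation, two-population gray levels. Every stage of
# the pipeline is testable against the generated ground truth.

#' Phantom population specification
#'
#' Defaults emulate the axial MR acquisition the method targets: in-plane
#' spacing 0.559 mm on a 288 x 288 grid, 3.3 mm slice distance, 7-14 contour
#' slices per case (mean 10.5), mid-slice semi-axes 15-30 mm with end-slice
#' tapering, smooth center drift and small smooth rotation profiles, inside /
#' outside gray means 200/100 with noise sd 10. `bumpy` adds low-order
#' angular perturbations to the contours so they are no longer exact
#' ellipses, emulating the residual between real organ outlines and their
#' best-fitting ellipses.
#'
#' @param n_cases number of cases in the population.
#' @param L_range inclusive range of contour-slice counts per case.
#' @param spacing in-plane pixel size (mm).
#' @param slice_distance distance between slices (mm).
#' @param grid_shape in-plane grid dimensions.
#' @param alpha_mid_range range of mid-slice semi-axis lengths (mm).
#' @param taper_range range of the end-slice tapering strength `lambda` in
#'   `alpha(t) = alpha_mid * sqrt(1 - lambda (2t-1)^2)`.
#' @param center_sd sd of the case-level quadratic center-curve coefficients
#'   (mm; constant, linear, quadratic terms).
#' @param eta_sd sd of the smooth per-slice center offsets from the case's
#'   center curve (mm).
#' @param phi0_sd sd of the case-level mean rotation (radians).
#' @param phi_wobble_sd sd of the smooth per-slice rotation wobble (radians).
#' @param mu_in,mu_out,noise_sd gray-level model (inside mean, outside mean,
#'   additive Gaussian noise sd).
#' @param contour_points vertices per generated contour.
#' @param contour_jitter_sd isotropic jitter of contour vertices (mm).
#' @param cp_jitter_sd in-plane jitter of the control points (mm).
#' @param bumpy add low-order angular perturbations to contours.
#' @param bump_sd sd of each bump harmonic's relative amplitude (orders 2-4).
#' @param with_volume generate gray-level volumes (disable for shape-only
#'   experiments).
#' @param margin_slices empty slices added before/after the contoured range.
#' @param seed population seed (case seeds derive from it).
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_cases = 33L, L_range = c(7L, 14L),
                         spacing = c(0.559, 0.559), slice_distance = 3.3,
                         grid_shape = c(288L, 288L),
                         alpha_mid_range = c(15, 30),
                         taper_range = c(0.80, 0.92),
                         center_sd = c(4, 4, 6), eta_sd = 1.0,
                         phi0_sd = 0.25, phi_wobble_sd = 0.04,
                         mu_in = 200, mu_out = 100, noise_sd = 10,
                         contour_points = 96L, contour_jitter_sd = 0.3,
                         cp_jitter_sd = 1.0,
                         bumpy = FALSE, bump_sd = 0.02,
                         with_volume = TRUE, margin_slices = 2L, seed = 1L) {
  if (any(L_range < 4L) || any(L_range > 20L))
    stop_input("L_range must lie within [4, 20]")
  if (L_range[1] > L_range[2]) stop_input("L_range must be increasing")
  sds <- c(eta_sd, phi0_sd, phi_wobble_sd, noise_sd, contour_jitter_sd,
           cp_jitter_sd, bump_sd)
  if (any(sds < 0)) stop_input("all standard deviations must be >= 0")
  spec <- list(n_cases = as.integer(n_cases), L_range = as.integer(L_range),
               spacing = spacing, slice_distance = slice_distance,
               grid_shape = as.integer(grid_shape),
               alpha_mid_range = alpha_mid_range, taper_range = taper_range,
               center_sd = rep_len(center_sd, 3L), eta_sd = eta_sd,
               phi0_sd = phi0_sd, phi_wobble_sd = phi_wobble_sd,
               mu_in = mu_in, mu_out = mu_out, noise_sd = noise_sd,
               contour_points = as.integer(contour_points),
               contour_jitter_sd = contour_jitter_sd,
               cp_jitter_sd = cp_jitter_sd,
               bumpy = isTRUE(bumpy), bump_sd = bump_sd,
               with_volume = isTRUE(with_volume),
               margin_slices = as.integer(margin_slices),
               seed = as.integer(seed))
  # tapering must keep end-slice axes above 1 mm for the smallest mid axis
  end_frac <- sqrt(1 - max(spec$taper_range))
  if (min(spec$alpha_mid_range) * end_frac <= 1)
    stop_input("taper_range too strong: end-slice semi-axes would fall below 1 mm")
  structure(spec, class = "phantom_spec")
}

# Low-order angular bump field, relative radial perturbation at parametric
# angle t: 1 + sum_k c_k cos(k t + psi_k), orders 2-4.
bump_factor <- function(t, coefs, phases) {
  f <- rep(1, length(t))
  for (i in seq_along(coefs)) f <- f + coefs[i] * cos((i + 1L) * t + phases[i])
  f
}

#' Generate one phantom case
#'
#' Draws a ground-truth ellipse stack from the spec's smooth per-slice
#' generators, samples contours on (optionally bumpy) truth boundaries with
#' vertex jitter, places jittered control points on the truth ellipses, and
#' optionally fills a gray-level volume (inside `mu_in`, background
#' `mu_out`, additive Gaussian noise). Fully reproducible from
#' `(spec, case_seed)`; the caller's random stream is untouched.
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer seed for this case.
#' @return A list with `volume` ([image_volume()] or `NULL`), `contours`
#'   (list of [slice_contour()]), `cp` ([control_points()]), `truth`
#'   ([ellipse_stack()]) and `case_seed`.
#' @export
generate_case <- function(spec, case_seed) {
  if (!inherits(spec, "phantom_spec")) stop_input("expected a phantom_spec")
  with_seed(case_seed, {
    Ls <- seq(spec$L_range[1], spec$L_range[2])
    L <- if (length(Ls) == 1L) Ls else sample(Ls, 1L)
    z0 <- stats::runif(1, -2, 2)
    z <- z0 + (seq_len(L) - 1L) * spec$slice_distance
    t <- seq(0, 1, length.out = L)

    alpha_mid <- stats::runif(2, spec$alpha_mid_range[1], spec$alpha_mid_range[2])
    lambda <- stats::runif(1, spec$taper_range[1], spec$taper_range[2])
    prof <- sqrt(1 - lambda * (2 * t - 1)^2)
    alpha <- outer(prof, alpha_mid)

    cc <- matrix(stats::rnorm(6, sd = rep(spec$center_sd, each = 2L)), 2L, 3L)
    curve <- cbind(cc[1, 1] + cc[1, 2] * (t - 0.5) + cc[1, 3] * (t - 0.5)^2,
                   cc[2, 1] + cc[2, 2] * (t - 0.5) + cc[2, 3] * (t - 0.5)^2)
    eta <- apply(matrix(stats::rnorm(2L * L, sd = spec$eta_sd * sqrt(3)), L, 2L),
                 2L, moving_average, window = 3L)
    theta <- curve + eta

    phi0 <- stats::rnorm(1, 0, spec$phi0_sd)
    wob <- moving_average(stats::rnorm(L, sd = spec$phi_wobble_sd * sqrt(3)), 3L)
    phi <- phi0 + wob

    truth <- matrix_stack(z, cbind(theta, alpha, phi))

    bump <- if (spec$bumpy)
      list(coefs = stats::rnorm(3, sd = spec$bump_sd),
           phases = stats::runif(3, 0, 2 * pi))
    else NULL

    boundary_at <- function(l, tt) {
      p <- truth$params[[l]]
      r <- if (is.null(bump)) 1 else bump_factor(tt, bump$coefs, bump$phases)
      local <- cbind(p$alpha[1] * cos(tt) * r, p$alpha[2] * sin(tt) * r)
      sweep(local %*% t(rot2(p$phi)), 2L, p$theta, "+")
    }
    K <- spec$contour_points
    contours <- lapply(seq_len(L), function(l) {
      tt <- 2 * pi * (seq_len(K) - 1L) / K + stats::runif(1, 0, 2 * pi / K)
      pts <- boundary_at(l, tt)
      if (spec$contour_jitter_sd > 0)
        pts <- pts + matrix(stats::rnorm(2L * K, sd = spec$contour_jitter_sd),
                            K, 2L)
      slice_contour(z[l], pts)
    })

    cp <- auto_control_points(truth, jitter_sd = spec$cp_jitter_sd)

    volume <- NULL
    if (spec$with_volume) {
      H <- L + 2L * spec$margin_slices
      shp <- c(spec$grid_shape, H)
      origin <- c(-(spec$grid_shape - 1) / 2 * spec$spacing,
                  z[1] - spec$margin_slices * spec$slice_distance)
      vox <- array(spec$mu_out, shp)
      pg <- plane_grid(origin[1:2], spec$spacing, spec$grid_shape)
      for (l in seq_len(L)) {
        k <- spec$margin_slices + l
        msk <- if (is.null(bump)) {
          rasterize_ellipse(truth$params[[l]], pg)
        } else {
          rasterize_polygon(boundary_at(l, 2 * pi * (0:255) / 256), pg)
        }
        sl <- vox[, , k]
        sl[msk] <- spec$mu_in
        vox[, , k] <- sl
      }
      if (spec$noise_sd > 0)
        vox <- vox + array(stats::rnorm(prod(shp), sd = spec$noise_sd), shp)
      volume <- image_volume(vox, c(spec$spacing, spec$slice_distance), origin)
    }

    list(volume = volume, contours = contours, cp = cp, truth = truth,
         case_seed = case_seed)
  })
}

case_seeds <- function(spec) {
  as.integer((as.numeric(spec$seed) * 1009 + seq_len(spec$n_cases) * 7919) %%
               2147483629)
}

#' Generate a phantom population with a train/test split
#'
#' @param spec a [phantom_spec()].
#' @param n_train,n_test split sizes (defaults 23/10).
#' @param mode `"sequential"` (first `n_train` cases train, mirroring a
#'   split by order of acquisition) or `"permutation"` (seeded random split
#'   for robustness experiments).
#' @param split_seed seed of the permutation split (defaults to the spec
#'   seed).
#' @return A list with `cases` (list of [generate_case()] results),
#'   `train` and `test` (index vectors).
#' @export
generate_population <- function(spec, n_train = 23L, n_test = 10L,
                                mode = c("sequential", "permutation"),
                                split_seed = NULL) {
  mode <- match.arg(mode)
  if (spec$n_cases < n_train + n_test)
    stop_input("spec has %d cases but the split needs %d",
               spec$n_cases, n_train + n_test)
  seeds <- case_seeds(spec)
  cases <- lapply(seeds, function(s) generate_case(spec, s))
  idx <- if (mode == "sequential") seq_len(spec$n_cases) else
    with_seed(split_seed %||% spec$seed, sample(spec$n_cases))
  list(cases = cases,
       train = idx[seq_len(n_train)],
       test = idx[n_train + seq_len(n_test)])
}
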