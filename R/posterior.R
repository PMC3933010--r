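# Empirical-Bayes posterior refinement: a two-class Gaussian gray-level
# likelihood whose parameters are estimated from the deformed template
# itself, combined with the shape prior re-centered on the template, sampled
# by component-blocked random-walk Metropolis (one slice per block).

#' Two-class gray-level likelihood model
#'
#' @param mu_in,sd_in mean/sd of gray levels inside the organ.
#' @param mu_out,sd_out mean/sd in the outside shell.
#' @param band_mm width of the outside shell (mm).
#' @return An object of class `"likelihood_model"`.
#' @export
likelihood_model <- function(mu_in, sd_in, mu_out, sd_out, band_mm = 5) {
  for (v in list(mu_in, sd_in, mu_out, sd_out, band_mm))
    if (!is_number(v)) stop_input("likelihood parameters must be finite scalars")
  if (sd_in <= 0 || sd_out <= 0) stop_input("likelihood sds must be positive")
  structure(list(mu_in = mu_in, sd_in = sd_in, mu_out = mu_out,
                 sd_out = sd_out, band_mm = band_mm),
            class = "likelihood_model")
}

#' @export
print.likelihood_model <- function(x, ...) {
  cat(sprintf(
    "likelihood_model: inside %.1f +/- %.1f, outside %.1f +/- %.1f (shell %.1f mm)\n",
    x$mu_in, x$sd_in, x$mu_out, x$sd_out, x$band_mm))
  invisible(x)
}

#' Estimate the gray-level likelihood from a segmented volume
#'
#' Empirical-Bayes step: the inside mean/sd come from voxels inside the
#' rasterized stack; the outside mean/sd from a shell of width `band_mm`
#' around it (each slice ellipse enlarged by `band_mm`, minus the inside).
#' Standard deviations are floored at `1e-6` gray units.
#'
#' @param volume an [image_volume()] in the de-rotated frame.
#' @param stack an [ellipse_stack()] on the volume's slice grid.
#' @param band_mm shell width (mm).
#' @return A [likelihood_model()].
#' @export
estimate_likelihood_params <- function(volume, stack, band_mm = 5) {
  if (!inherits(volume, "image_volume")) stop_input("expected an image_volume")
  inside <- rasterize_stack(stack, volume)
  if (!any(inside)) stop_input("stack rasterizes to an empty inside region")
  shell <- rasterize_stack(stack, volume, dilate_mm = band_mm) & !inside
  if (!any(shell))
    stop_input("shell undefined: no voxels in the %.2f mm outside band", band_mm)
  v <- volume$voxels
  likelihood_model(
    mu_in = mean(v[inside]), sd_in = max(stats::sd(v[inside]), 1e-6),
    mu_out = mean(v[shell]), sd_out = max(stats::sd(v[shell]), 1e-6),
    band_mm = band_mm)
}

#' Gray-level log-likelihood of a stack
#'
#' Sum of Gaussian log densities over the voxel set defined by the
#' rasterized stack: inside voxels scored under the inside distribution,
#' shell voxels (within `band_mm` outside) under the outside distribution.
#'
#' @inheritParams estimate_likelihood_params
#' @param lik a [likelihood_model()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(volume, stack, lik) {
  if (!inherits(lik, "likelihood_model")) stop_input("expected a likelihood_model")
  inside <- rasterize_stack(stack, volume)
  shell <- rasterize_stack(stack, volume, dilate_mm = lik$band_mm) & !inside
  v <- volume$voxels
  sum(stats::dnorm(v[inside], lik$mu_in, lik$sd_in, log = TRUE)) +
    sum(stats::dnorm(v[shell], lik$mu_out, lik$sd_out, log = TRUE))
}

#' MCMC configuration
#'
#' @param n_iter number of sweeps (each sweep updates every slice block).
#' @param burn_in sweeps discarded before summarizing (0 < burn_in < n_iter).
#' @param proposal_scale Gaussian proposal sd as a fraction of the prior sd
#'   per parameter.
#' @param seed RNG seed; identical configurations give identical chains.
#' @param estimator `"posterior_mean"` (default; semi-axes averaged on the
#'   log scale, then exponentiated) or `"map"` (highest-posterior sweep).
#' @param band_mm likelihood shell width (mm).
#' @param use_likelihood set `FALSE` for prior-only (flat-likelihood) chains.
#' @param adapt adapt per-block proposal scales during burn-in (stochastic
#'   approximation towards an acceptance rate of about 0.3; the kernel is
#'   frozen after burn-in so the summarized chain is a valid fixed-kernel
#'   Metropolis sample).
#' @param roi_margin half-width margin (mm) added around the template when
#'   precomputing each slice's candidate voxel set.
#' @param keep_chain retain the full parameter chain in the diagnostics.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 20000L, burn_in = 5000L,
                        proposal_scale = 0.25, seed = 1L,
                        estimator = c("posterior_mean", "map"),
                        band_mm = 5, use_likelihood = TRUE,
                        adapt = TRUE, roi_margin = 10, keep_chain = FALSE) {
  estimator <- match.arg(estimator)
  if (!is_number(n_iter) || !is_number(burn_in) ||
      burn_in <= 0 || burn_in >= n_iter)
    stop_input("need 0 < burn_in < n_iter")
  if (!is_number(proposal_scale) || proposal_scale <= 0)
    stop_input("proposal_scale must be positive")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale, seed = seed,
                 estimator = estimator, band_mm = band_mm,
                 use_likelihood = isTRUE(use_likelihood),
                 adapt = isTRUE(adapt),
                 roi_margin = roi_margin, keep_chain = isTRUE(keep_chain)),
            class = "mcmc_config")
}

#' Random-walk Metropolis chain
#'
#' Plain Gaussian random-walk Metropolis on an arbitrary log-target;
#' exported as a small building block (the slice-blocked refinement uses the
#' same kernel per block) and for direct validation of posterior sampling on
#' low-dimensional targets.
#'
#' @param logpost function taking a parameter vector, returning a log density
#'   (may be `-Inf`).
#' @param init numeric initial state with finite log density.
#' @param scale per-component proposal standard deviations.
#' @param n_iter number of iterations.
#' @param seed optional RNG seed.
#' @return A list with `samples` (`n_iter x d` matrix), `logpost` (vector)
#'   and `acceptance` (scalar rate).
#' @export
mh_chain <- function(logpost, init, scale, n_iter, seed = NULL) {
  d <- length(init)
  scale <- rep_len(scale, d)
  lp <- logpost(init)
  if (!is.finite(lp)) stop_input("initial state has non-finite log density")
  with_seed(seed, {
    samples <- matrix(NA_real_, n_iter, d)
    lps <- numeric(n_iter)
    x <- init
    acc <- 0L
    for (i in seq_len(n_iter)) {
      prop <- x + stats::rnorm(d) * scale
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        x <- prop
        lp <- lp_prop
        acc <- acc + 1L
      }
      samples[i, ] <- x
      lps[i] <- lp
    }
    list(samples = samples, logpost = lps, acceptance = acc / n_iter)
  })
}

#' Posterior refinement of the deformed template by MCMC
#'
#' Samples the empirical-Bayes posterior (gray-level likelihood times the
#' shape prior re-centered on the deformed template) by component-blocked
#' random-walk Metropolis: one slice per block over the sample-space
#' parameters (eta1, eta2, a1 = log alpha1, a2, phi), Gaussian proposals at
#' `proposal_scale` times the (interpolated) prior sd. The log
#' parametrization keeps the semi-axes structurally positive.
#'
#' @param volume an [image_volume()] in the de-rotated frame (identity
#'   orientation).
#' @param model a trained [fit_shape_model()].
#' @param cp the case's [control_points()].
#' @param config an [mcmc_config()].
#' @param lik optional [likelihood_model()]; estimated from the template via
#'   [estimate_likelihood_params()] when `NULL`.
#' @return A list with `stack` (the refined [ellipse_stack()]), `template`
#'   (the unrefined deformed mean shape), `lik`, and `diagnostics`
#'   (`acceptance` per slice, `trace` of the log posterior per sweep, and the
#'   chain when `keep_chain`).
#' @export
mcmc_refine <- function(volume, model, cp, config = mcmc_config(), lik = NULL) {
  if (!inherits(volume, "image_volume")) stop_input("expected an image_volume")
  if (!inherits(config, "mcmc_config")) stop_input("expected an mcmc_config")
  if (max(abs(volume$orientation - diag(3))) > 1e-6)
    stop_input("volume must be de-rotated (identity orientation); see derotate()")

  fr <- deform_frame(model, cp, slice_positions(volume))
  template <- fr$stack
  L <- length(template)
  if (config$use_likelihood && is.null(lik))
    lik <- estimate_likelihood_params(volume, template, config$band_mm)

  tr <- fr$transform
  ks <- match_slices(template$z, volume)
  pg <- in_plane_grid(volume)
  xs <- grid_axis(pg, 1L)
  ys <- grid_axis(pg, 2L)

  # Per-slice scored voxel set, held FIXED during sampling so likelihoods of
  # different states are comparable (a state-dependent voxel set would reward
  # shrinking the region): the template ellipse dilated by the shell width.
  # The current ellipse only decides which class scores each voxel, so the
  # per-proposal cost reduces to one implicit evaluation over the set.
  roi <- vector("list", L)
  if (config$use_likelihood) {
    for (l in seq_len(L)) {
      p <- template$params[[l]]
      half <- max(p$alpha) + lik$band_mm + config$roi_margin
      ix <- which(xs >= p$theta[1] - half & xs <= p$theta[1] + half)
      iy <- which(ys >= p$theta[2] - half & ys <= p$theta[2] + half)
      if (!length(ix) || !length(iy))
        stop_input("template slice %d lies outside the volume grid", l)
      px <- cbind(rep(xs[ix], times = length(iy)),
                  rep(ys[iy], each = length(ix)))
      vals <- as.numeric(volume$voxels[ix, iy, ks[l]])
      keep <- ellipse_implicit(ellipse(p$theta, p$alpha + lik$band_mm, p$phi),
                               px) <= 1
      ld_in <- stats::dnorm(vals[keep], lik$mu_in, lik$sd_in, log = TRUE)
      ld_out <- stats::dnorm(vals[keep], lik$mu_out, lik$sd_out, log = TRUE)
      roi[[l]] <- list(px = px[keep, , drop = FALSE],
                       ld_diff = ld_in - ld_out, base = sum(ld_out))
    }
  }

  # slice state (eta1, eta2, a1, a2, phi) -> patient-frame ellipse
  slice_ellipse <- function(l, x) {
    th_ss <- fr$xi_ss[l, ] + x[1:2]
    th <- as.numeric((th_ss / tr$scale) %*% rot2(tr$rotation)) +
      tr$translation[1:2]
    ellipse(th, exp(x[3:4]) / tr$scale, x[5] - tr$rotation)
  }
  slice_loglik <- function(l, x) {
    if (!config$use_likelihood) return(0)
    e <- slice_ellipse(l, x)
    r <- roi[[l]]
    inside <- ellipse_implicit(e, r$px) <= 1
    r$base + sum(r$ld_diff[inside])
  }
  mu <- fr$mu
  sig <- fr$sigma
  slice_logprior <- function(l, x) {
    sum(norm_term(x[1:2], mu$position[l, ], sig$position[l, ])) +
      sum(norm_term(x[3:4], mu$a[l, ], sig$a[l, ])) +
      norm_term(x[5], mu$phi[l], sig$phi[l])
  }

  prop_sd <- config$proposal_scale *
    cbind(pmax(sig$position, 1e-3), pmax(sig$a, 1e-4), pmax(sig$phi, 1e-4))

  state <- cbind(mu$position, mu$a, mu$phi)
  lp <- vapply(seq_len(L), function(l) slice_logprior(l, state[l, ]), numeric(1))
  ll <- vapply(seq_len(L), function(l) slice_loglik(l, state[l, ]), numeric(1))

  n_iter <- config$n_iter
  chain <- if (config$keep_chain) array(NA_real_, c(n_iter, L, 5L)) else NULL
  trace <- numeric(n_iter)
  sum_state <- matrix(0, L, 5L)
  n_kept <- 0L
  best <- list(lp = -Inf, state = state)
  accept <- integer(L)      # post-burn-in acceptances (fixed kernel)
  acc_window <- integer(L)  # burn-in window counts driving the adaptation
  scale_fac <- rep(1, L)
  adapt_every <- 25L

  with_seed(config$seed, {
    for (it in seq_len(n_iter)) {
      for (l in seq_len(L)) {
        prop <- state[l, ] + stats::rnorm(5L) * (scale_fac[l] * prop_sd[l, ])
        ok <- FALSE
        lp_p <- slice_logprior(l, prop)
        if (is.finite(lp_p)) {
          ll_p <- slice_loglik(l, prop)
          if (log(stats::runif(1)) < (lp_p + ll_p) - (lp[l] + ll[l])) {
            state[l, ] <- prop
            lp[l] <- lp_p
            ll[l] <- ll_p
            ok <- TRUE
          }
        }
        if (it > config$burn_in) accept[l] <- accept[l] + ok
        else acc_window[l] <- acc_window[l] + ok
      }
      if (config$adapt && it <= config$burn_in && it %% adapt_every == 0L) {
        rate <- acc_window / adapt_every
        scale_fac <- pmin(pmax(scale_fac * exp(2 * (rate - 0.3)), 1e-4), 100)
        acc_window[] <- 0L
      }
      total <- sum(lp) + sum(ll)
      trace[it] <- total
      if (config$keep_chain) chain[it, , ] <- state
      if (it > config$burn_in) {
        sum_state <- sum_state + state
        n_kept <- n_kept + 1L
        if (total > best$lp) best <- list(lp = total, state = state)
      }
    }
  })

  if (all(accept == 0L))
    warning("stuck chain: no proposal accepted in any slice block after burn-in",
            call. = FALSE)

  est <- if (config$estimator == "map") best$state else sum_state / n_kept
  out <- matrix_stack(template$z, t(vapply(seq_len(L), function(l) {
    e <- slice_ellipse(l, est[l, ])
    c(e$theta, e$alpha, e$phi)
  }, numeric(5))))

  list(stack = out, template = template, lik = lik,
       diagnostics = list(acceptance = accept / (n_iter - config$burn_in),
                          proposal_factor = scale_fac, trace = trace,
                          chain = chain, n_kept = n_kept))
}
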