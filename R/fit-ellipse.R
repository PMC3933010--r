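# Best-fitting ellipse per contour slice: direct algebraic least squares
# (ellipse-constrained conic) for initialization, then Levenberg-Marquardt on
# the orthogonal-distance objective.

# Halir & Flusser's numerically stable variant of the direct ellipse-specific
# conic fit. Points are centered and scaled first for conditioning. Returns an
# "ellipse", or signals a degenerate-contour error when no elliptic solution
# exists (collinear points, hyperbolic algebraic optimum, ...).
fit_conic_algebraic <- function(pts) {
  ctr <- colMeans(pts)
  sc <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
  if (!is.finite(sc) || sc < 1e-9)
    stop_input("degenerate contour: points are (nearly) coincident")
  x <- (pts[, 1] - ctr[1]) / sc
  y <- (pts[, 2] - ctr[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop_input(
                   "degenerate contour: collinear or rank-deficient points"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0L)
    stop_input("degenerate contour: no elliptic algebraic solution")
  a1 <- V[, idx[1L]]
  cf <- c(a1, as.numeric(Tm %*% a1)) # A, B, C, D, E, F in the scaled frame
  e <- conic_to_ellipse(cf)
  ellipse(ctr + sc * e$theta, sc * e$alpha, e$phi)
}

# Convert conic coefficients A x^2 + B xy + C y^2 + D x + E y + F = 0 to
# center/axes/angle form. Errors if the conic is not an ellipse.
conic_to_ellipse <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  M2 <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  if (det(M2) <= 0) stop_input("degenerate contour: conic is not an ellipse")
  ctr <- tryCatch(solve(rbind(c(2 * A, B), c(B, 2 * C)), -c(D, E)),
                  error = function(e) stop_input("degenerate conic center"))
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F
  ev <- eigen(M2, symmetric = TRUE)
  if (any(ev$values * -F0 <= 0))
    stop_input("degenerate contour: conic is not a real ellipse")
  axes <- sqrt(-F0 / ev$values)
  v1 <- ev$vectors[, 1L]
  phi <- wrap_half_pi(atan2(v1[2], v1[1]))
  ellipse(ctr, axes, phi)
}

# Signed orthogonal distances (positive outside) of contour points; the
# smooth residual vector of the geometric objective.
signed_distances <- function(params, pts) {
  pr <- project_points(params, pts)
  s <- sign(ellipse_implicit(params, pts) - 1)
  s[s == 0] <- 1
  pr$distance * s
}

#' Fit the best-fitting ellipse (BFE) of a contour slice
#'
#' Minimizes the sum of squared orthogonal distances of the contour vertices
#' to the ellipse boundary. The fit is initialized by a direct algebraic
#' least-squares conic fit constrained to ellipses and refined by
#' Levenberg-Marquardt on the orthogonal-distance residuals, with the
#' semi-axes log-parametrized so positivity is structural. The returned
#' rotation is normalized to `(-pi/2, pi/2]` with `alpha[1]` labeled as the
#' axis along direction `phi` (no magnitude ordering; see [reorder_axes()]).
#'
#' @param contour a [slice_contour()] with at least 5 non-collinear vertices.
#' @param refine refine the algebraic initializer on the geometric objective
#'   (default `TRUE`).
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return An object of classes `"bfe"` and `"ellipse"` with a `fit` element
#'   carrying `geometric_error`, `converged`, `iterations` and `n`.
#' @examples
#' e <- ellipse(c(10, -5), c(20, 12), 0.4)
#' ct <- slice_contour(0, ellipse_boundary(e, 100))
#' fit_ellipse(ct)
#' @export
fit_ellipse <- function(contour, refine = TRUE, max_iter = 200L) {
  if (!inherits(contour, "slice_contour"))
    stop_input("contour must be a 'slice_contour'")
  pts <- contour$points
  if (nrow(pts) < 5L)
    stop_input("insufficient data: ellipse fitting needs at least 5 points (got %d)",
               nrow(pts))
  init <- fit_conic_algebraic(pts)
  g0 <- sum(signed_distances(init, pts)^2)
  est <- init
  converged <- TRUE
  iterations <- 0L
  if (refine) {
    par0 <- c(init$theta, log(init$alpha), init$phi)
    res_fn <- function(par) {
      signed_distances(ellipse(par[1:2], exp(pmin(par[3:4], 50)), par[5]), pts)
    }
    fit <- minpack.lm::nls.lm(
      par = par0, fn = res_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0))
    iterations <- fit$niter
    converged <- fit$info %in% 1:4
    if (!converged)
      warning("ellipse fit did not fully converge; returning best iterate",
              call. = FALSE)
    p <- fit$par
    cand <- ellipse(p[1:2], exp(p[3:4]), wrap_half_pi(p[5]))
    g1 <- sum(signed_distances(cand, pts)^2)
    if (g1 <= g0) { # refinement never worsens the objective
      est <- cand
      g0 <- g1
    }
  }
  est$phi <- wrap_half_pi(est$phi)
  est$fit <- list(geometric_error = g0, converged = converged,
                  iterations = iterations, n = nrow(pts))
  class(est) <- c("bfe", "ellipse")
  attr(est, "contour") <- contour
  est
}

#' @export
print.bfe <- function(x, ...) {
  NextMethod()
  cat(sprintf("  orthogonal-distance error %.4g mm^2 over %d points (%s)\n",
              x$fit$geometric_error, x$fit$n,
              if (x$fit$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.bfe <- function(object, ...) {
  c(theta1 = object$theta[1], theta2 = object$theta[2],
    alpha1 = object$alpha[1], alpha2 = object$alpha[2], phi = object$phi)
}

#' @export
residuals.bfe <- function(object, ...) {
  ct <- attr(object, "contour")
  if (is.null(ct)) stop_input("fit does not carry its contour")
  signed_distances(object, ct$points)
}

#' Fit best-fitting ellipses for a whole contour stack
#'
#' Fits each slice independently and assembles the per-case [ellipse_stack()].
#' Slices whose fit fails are reported by slice index and z-position in a
#' single error; no slice is silently dropped.
#'
#' @param contours list of [slice_contour()] sorted by increasing `z`.
#' @param ... forwarded to [fit_ellipse()].
#' @return An [ellipse_stack()] in z order.
#' @export
fit_stack <- function(contours, ...) {
  if (!is.list(contours) || length(contours) < 1L)
    stop_input("contours must be a non-empty list of slice_contour objects")
  z <- vapply(contours, function(ct) ct$z, numeric(1))
  if (any(diff(z) <= 0))
    stop_input("contours must be sorted by strictly increasing z")
  fits <- vector("list", length(contours))
  failures <- character(0)
  for (i in seq_along(contours)) {
    fits[[i]] <- tryCatch(fit_ellipse(contours[[i]], ...), error = function(e) {
      failures <<- c(failures,
                     sprintf("slice %d (z = %.2f mm): %s", i, z[i],
                             conditionMessage(e)))
      NULL
    })
  }
  if (length(failures))
    stop_input("ellipse fit failed for %d slice(s):\n  %s",
               length(failures), paste(failures, collapse = "\n  "))
  ellipse_stack(z, lapply(fits, function(f) ellipse(f$theta, f$alpha, f$phi)))
}
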