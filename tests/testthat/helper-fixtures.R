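# Shared fixtures: dense-sampling oracles, random generators, a constructed
# self-normalized shape model, and a cached phantom population for the
# expensive end-to-end checks.

stack_matrix_ <- ellipstack:::stack_matrix
matrix_stack_ <- ellipstack:::matrix_stack

random_ellipse <- function() {
  ellipse(stats::runif(2, -20, 20),
          sort(stats::runif(2, 2, 25), decreasing = sample(c(TRUE, FALSE), 1)),
          stats::runif(1, -pi / 2, pi / 2))
}

# Brute-force nearest-point oracle: dense boundary sampling.
oracle_project <- function(params, point, n = 1e6) {
  b <- ellipse_boundary(params, n)
  d2 <- (b[, 1] - point[1])^2 + (b[, 2] - point[2])^2
  i <- which.min(d2)
  list(foot = b[i, ], distance = sqrt(d2[i]))
}

# Smooth random stack of ellipses (patient frame).
random_stack <- function(L = 9, seed = NULL) {
  ellipstack:::with_seed(seed, {
    t <- seq(0, 1, length.out = L)
    prof <- sqrt(1 - 0.85 * (2 * t - 1)^2)
    a <- outer(prof, stats::runif(2, 12, 25))
    th <- cbind(stats::rnorm(1, 0, 5) + 3 * sin(pi * t) + stats::rnorm(L, 0, 0.3),
                stats::rnorm(1, 0, 5) + 2 * cos(pi * t) + stats::rnorm(L, 0, 0.3))
    phi <- stats::rnorm(1, 0, 0.4) + 0.1 * sin(2 * pi * t)
    matrix_stack_(3.3 * (seq_len(L) - 1L), cbind(th, a, phi))
  })
}

# A shape model whose mean shape (plus the returned xi curve) is exactly
# self-normalized: the 18 automatic control points of mean_shape(model, xi)
# yield the identity sample-space transform, and the mean center offsets
# vanish on the three control-point slices. Instantiates the premise of the
# deformation fixed point exactly.
toy_self_normalized_model <- function(L = 11) {
  stopifnot(L %% 2L == 1L)
  t <- seq(0, 1, length.out = L)
  z <- seq(-0.5, 0.5, length.out = L)
  A <- sqrt(2 / (1 + 0.8^2)) # center-slice RMS radius = 1
  a1 <- A * sqrt(1 - 0.85 * (2 * t - 1)^2)
  a2 <- 0.8 * a1
  c2 <- c(0.3, -0.2); c1 <- c(0.1, 0.05); c0 <- -c2 / 6 # anchor centroid 0
  xi <- cbind(c0[1] + c1[1] * z + c2[1] * z^2,
              c0[2] + c1[2] * z + c2[2] * z^2)
  eta <- cbind(0.02 * sin(2 * pi * t), -0.015 * sin(2 * pi * t)) # 0 at anchors
  model <- structure(list(
    L = L, n_train = 23L, mode = "eta", z = z,
    mu_eta = eta, sigma_eta = matrix(0.03, L, 2),
    mu_theta = cbind(xi + eta, z), sigma_theta = matrix(0.03, L, 3),
    Sigma_theta = array(rep(diag(3) * 9e-4, each = L), c(L, 3, 3)),
    mu_a = log(cbind(a1, a2)), sigma_a = matrix(0.08, L, 2),
    mu_phi = rep(0, L), sigma_phi = rep(0.05, L)), class = "shape_model")
  list(model = model, xi = xi)
}

# Reference shape model with known moments for estimator-recovery checks.
toy_reference_model <- function(L = 9) {
  t <- seq(0, 1, length.out = L)
  structure(list(
    L = L, n_train = 23L, mode = "eta", z = seq(-0.5, 0.5, length.out = L),
    mu_eta = cbind(0.05 * sin(2 * pi * t), -0.04 * cos(pi * t)),
    sigma_eta = cbind(rep(0.04, L), rep(0.05, L)),
    mu_theta = cbind(0, 0, seq(-0.5, 0.5, length.out = L)),
    sigma_theta = matrix(0.05, L, 3),
    Sigma_theta = array(rep(diag(3) * 2.5e-3, each = L), c(L, 3, 3)),
    mu_a = cbind(log(0.9 * sqrt(1 - 0.8 * (2 * t - 1)^2)),
                 log(0.7 * sqrt(1 - 0.8 * (2 * t - 1)^2))),
    sigma_a = matrix(0.1, L, 2),
    mu_phi = rep(0.05, L), sigma_phi = rep(0.06, L)), class = "shape_model")
}

phantom_case_geometry <- function(spec, cs) {
  volume_geometry(
    c(-(spec$grid_shape - 1) / 2 * spec$spacing, cs$truth$z[1]),
    c(spec$spacing, spec$slice_distance),
    c(spec$grid_shape, length(cs$truth$z)))
}

# Lazily computed, cached expensive fixtures shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The study-scale phantom population (33 cases, default spec, no volumes)
# with all cases normalized to the canonical slice count.
default_population <- function() {
  cached("default_population", {
    spec <- phantom_spec(with_volume = FALSE)
    pop <- generate_population(spec)
    norm <- lapply(pop$cases, function(cs)
      normalize_case(cs$contours, cp = cs$cp, L = 11L))
    list(spec = spec, pop = pop, norm = norm)
  })
}

# Small phantom population with volumes for likelihood/MCMC checks.
mcmc_population <- function() {
  cached("mcmc_population", {
    spec <- phantom_spec(n_cases = 6, seed = 3)
    pop <- generate_population(spec, n_train = 5, n_test = 1)
    norm <- lapply(pop$cases[pop$train], function(cs)
      normalize_case(cs$contours, cp = cs$cp, L = 11L))
    model <- fit_shape_model(lapply(norm, `[[`, "stack"),
                             xi = lapply(norm, `[[`, "xi"))
    list(spec = spec, pop = pop, model = model,
         test_case = pop$cases[[pop$test]])
  })
}
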