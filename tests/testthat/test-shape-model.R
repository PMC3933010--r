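# Shape-model estimation, mean shape, prior sampling and log density.

make_stack_list <- function(mats, z = NULL) {
  L <- nrow(mats[[1]])
  z <- z %||% seq(-0.5, 0.5, length.out = L)
  lapply(mats, function(m) matrix_stack_(z, m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical training stacks give their parameters back with zero spread", {
  m <- matrix(rep(c(0.1, -0.2, 0.9, 0.7, 0.05), each = 5), 5, 5)
  stacks <- make_stack_list(rep(list(m), 4))
  xi <- replicate(4, matrix(0, 5, 2), simplify = FALSE)
  model <- fit_shape_model(stacks, xi = xi)
  expect_equal(model$mu_eta, matrix(c(0.1, -0.2), 5, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(max(model$sigma_eta, model$sigma_a, model$sigma_phi), 0)
  ms <- mean_shape(model)
  expect_lt(max(abs(stack_matrix_(ms) - m)), 1e-12)
})

test_that("axis lengths are averaged geometrically (log scale)", {
  m1 <- matrix(rep(c(0, 0, 2, 1, 0), each = 3), 3, 5)
  m2 <- matrix(rep(c(0, 0, 8, 1, 0), each = 3), 3, 5)
  model <- fit_shape_model(make_stack_list(list(m1, m2)),
                           xi = replicate(2, matrix(0, 3, 2), simplify = FALSE))
  expect_equal(model$mu_a[, 1], rep(log(4), 3))
  expect_equal(exp(model$mu_a[1, 1]), 4)
})

test_that("training is permutation-invariant and validates inputs", {
  set.seed(51)
  mats <- replicate(5, {
    m <- matrix(stats::rnorm(15, sd = 0.1), 3, 5)
    m[, 3:4] <- exp(m[, 3:4]); m
  }, simplify = FALSE)
  xi <- replicate(5, matrix(0, 3, 2), simplify = FALSE)
  a <- fit_shape_model(make_stack_list(mats), xi = xi)
  b <- fit_shape_model(make_stack_list(mats[c(3, 1, 5, 2, 4)]),
                       xi = xi)
  expect_equal(a[setdiff(names(a), "")], b[setdiff(names(b), "")])

  expect_error(fit_shape_model(make_stack_list(mats[1])),
               class = "ellipstack_input_error")
  bad <- make_stack_list(mats)
  bad[[2]] <- matrix_stack_(c(0, 1), mats[[2]][1:2, ])
  expect_error(fit_shape_model(bad, xi = xi), "slice count",
               class = "ellipstack_input_error")
})

test_that("training on draws from a known model recovers its moments", {
  truth <- toy_reference_model(L = 9)
  N <- 23L
  mu_ok <- mu_n <- sig_ok <- sig_n <- 0
  for (r in 1:20) {
    stacks <- ellipstack:::with_seed(5000 + r,
      lapply(seq_len(N), function(i) sample_prior(truth)))
    fit <- fit_shape_model(stacks,
                           xi = replicate(N, matrix(0, 9, 2), simplify = FALSE))
    mu_hat <- cbind(fit$mu_eta, fit$mu_a, fit$mu_phi)
    mu_true <- cbind(truth$mu_eta, truth$mu_a, truth$mu_phi)
    sd_true <- cbind(truth$sigma_eta, truth$sigma_a, truth$sigma_phi)
    mu_ok <- mu_ok + sum(abs(mu_hat - mu_true) <= 3 * sd_true / sqrt(N))
    mu_n <- mu_n + length(mu_hat)
    band <- stats::qchisq(c(0.005, 0.995), N - 1) / (N - 1)
    ratio <- cbind(fit$sigma_eta, fit$sigma_a, fit$sigma_phi)^2 / sd_true^2
    sig_ok <- sig_ok + sum(ratio >= band[1] & ratio <= band[2])
    sig_n <- sig_n + length(ratio)
  }
  # nominal coverage 99.7% (3 SE) and 99% (chi-square band)
  expect_gte(mu_ok / mu_n, 0.98)
  expect_gte(sig_ok / sig_n, 0.975)
})

test_that("estimation error shrinks when the training population grows", {
  truth <- toy_reference_model(L = 9)
  err <- sapply(c(23L, 230L), function(N) {
    med <- sapply(1:20, function(r) {
      stacks <- ellipstack:::with_seed(7000 + 97 * r + N,
        lapply(seq_len(N), function(i) sample_prior(truth)))
      fit <- fit_shape_model(stacks,
        xi = replicate(N, matrix(0, 9, 2), simplify = FALSE))
      stats::median(abs(cbind(fit$mu_eta, fit$mu_a, fit$mu_phi) -
                          cbind(truth$mu_eta, truth$mu_a, truth$mu_phi)))
    })
    stats::median(med)
  })
  expect_lt(err[2], 0.55 * err[1]) # expect roughly sqrt(10) improvement
})

test_that("prior samples follow the stated families", {
  truth <- toy_reference_model(L = 9)
  # zero-variance model collapses onto the mean shape
  degen <- truth
  degen$sigma_eta[] <- 0; degen$sigma_a[] <- 0; degen$sigma_phi[] <- 0
  s <- sample_prior(degen, seed = 1)
  expect_lt(max(abs(stack_matrix_(s) - stack_matrix_(mean_shape(degen)))),
            1e-12)

  draws <- ellipstack:::with_seed(99, replicate(10000,
    log(sample_prior(truth)$params[[5]]$alpha[1])))
  se <- truth$sigma_a[5, 1] / sqrt(10000)
  expect_lt(abs(mean(draws) - truth$mu_a[5, 1]), 4 * se)
  expect_gt(min(exp(draws)), 0)

  expect_equal(stack_matrix_(sample_prior(truth, seed = 7)),
               stack_matrix_(sample_prior(truth, seed = 7)))
  sims <- simulate(toy_reference_model(), nsim = 3, seed = 2)
  expect_length(sims, 3)
})

test_that("prior log density matches closed forms and shifts quadratically", {
  truth <- toy_reference_model(L = 9)
  ms <- mean_shape(truth)
  base <- prior_logdensity(truth, ms)
  # at the mean: each Gaussian term contributes -log(sqrt(2 pi) sigma), the
  # log-normal terms additionally -mu_a (the Jacobian at alpha = exp(mu_a))
  closed <- sum(-log(sqrt(2 * pi) * truth$sigma_eta)) +
    sum(-log(sqrt(2 * pi) * truth$sigma_a) - truth$mu_a) +
    sum(-log(sqrt(2 * pi) * truth$sigma_phi))
  expect_equal(base, closed, tolerance = 1e-12)

  # shifting one center component by k sigma costs k^2/2 in log density
  for (k in c(1, 2.5)) {
    m <- stack_matrix_(ms)
    m[4, 1] <- m[4, 1] + k * truth$sigma_eta[4, 1]
    expect_equal(base - prior_logdensity(truth, matrix_stack_(ms$z, m)),
                 k^2 / 2, tolerance = 1e-9)
  }

  # non-positive axis: outside the support
  m <- stack_matrix_(ms); m[2, 3] <- -1
  expect_error(matrix_stack_(ms$z, m), class = "ellipstack_input_error")

  # agreement with a brute-force product of standard density calls
  set.seed(52)
  s <- sample_prior(truth)
  sm <- stack_matrix_(s)
  brute <- sum(stats::dnorm(sm[, 1:2], truth$mu_eta, truth$sigma_eta,
                            log = TRUE)) +
    sum(stats::dlnorm(sm[, 3:4], truth$mu_a, truth$sigma_a, log = TRUE)) +
    sum(stats::dnorm(sm[, 5], truth$mu_phi, truth$sigma_phi, log = TRUE))
  expect_equal(prior_logdensity(truth, s), brute, tolerance = 1e-9)
})

test_that("degenerate zero-variance slices act as documented point masses", {
  truth <- toy_reference_model(L = 9)
  degen <- truth
  degen$sigma_eta[] <- 0; degen$sigma_a[] <- 0; degen$sigma_phi[] <- 0
  ms <- mean_shape(degen)
  expect_equal(prior_logdensity(degen, ms), sum(-degen$mu_a))
  m <- stack_matrix_(ms); m[3, 1] <- m[3, 1] + 0.1
  off <- prior_logdensity(degen, matrix_stack_(ms$z, m))
  expect_identical(off, -Inf)
  expect_false(is.nan(off))
})

test_that("model summaries expose the per-slice moments", {
  truth <- toy_reference_model(L = 9)
  expect_output(print(truth), "9 canonical slices")
  cf <- coef(truth)
  expect_equal(dim(cf), c(9L, 5L))
  expect_equal(cf[, "phi"], truth$mu_phi, ignore_attr = TRUE)
  sm <- summary(truth)
  expect_equal(nrow(sm), 9L)
})
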