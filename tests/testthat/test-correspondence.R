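# Axis reordering, circularity relaxation, rotation smoothing, resampling.

boundary_hausdorff <- function(p1, p2, n = 360) {
  hausdorff_slice(ellipse_boundary(p1, n), ellipse_boundary(p2, n))
}

test_that("reordering keeps identical stacks identical and preserves boundaries", {
  m <- cbind(1, -2, 8, 5, 0.3)[rep(1, 5), ]
  s <- matrix_stack_(0:4, m)
  expect_equal(stack_matrix_(reorder_axes(s)), stack_matrix_(s))

  set.seed(31)
  for (i in 1:10) {
    s <- random_stack(L = 7)
    # scramble representations: random swaps and pi/2 shifts per slice
    m <- stack_matrix_(s)
    for (l in 1:7) {
      if (stats::runif(1) < 0.5) {
        m[l, 3:4] <- rev(m[l, 3:4]); m[l, 5] <- m[l, 5] + pi / 2
      }
      m[l, 5] <- m[l, 5] + pi * sample(-1:1, 1)
    }
    scr <- matrix_stack_(s$z, m)
    re <- reorder_axes(scr)
    for (l in 1:7)
      expect_lt(boundary_hausdorff(scr$params[[l]], re$params[[l]]), 1e-9)
  }
})

test_that("reordered angles minimize adjacent rotation differences", {
  set.seed(32)
  for (i in 1:20) {
    s <- random_stack(L = 9)
    m <- stack_matrix_(s)
    m[, 5] <- stats::runif(9, -pi / 2, pi / 2) # incoherent fit-time angles
    re <- stack_matrix_(reorder_axes(matrix_stack_(s$z, m)))
    phi <- re[, 5]
    M <- 5L
    expect_equal(re[M, ], m[M, ]) # basis unchanged
    # brute force: every adjacent step must be minimal over the 4 representations
    for (l in c(4:1, 6:9)) {
      prev <- if (l < M) phi[l + 1L] else phi[l - 1L]
      cand <- c(m[l, 5] + pi * (-2:2), m[l, 5] + pi / 2 + pi * (-2:2))
      expect_lte(abs(phi[l] - prev), min(abs(cand - prev)) + 1e-12)
      expect_lte(abs(phi[l] - prev), pi / 4 + 1e-12)
    }
    expect_true(all(phi > -pi & phi <= pi))
    expect_lte(max(abs(phi - phi[M])), pi)
  }
})

test_that("circularity relaxation blends angles as specified", {
  # perfect circle takes its neighbors' angle
  m <- rbind(c(0, 0, 2, 1, 0.3), c(0, 0, 1.5, 1.5, 0.9), c(0, 0, 2, 1, 0.3))
  r <- stack_matrix_(relax_circular(matrix_stack_(0:2, m), 0.95))
  expect_equal(r[2, 5], 0.3)

  # below the threshold: unchanged
  m2 <- rbind(c(0, 0, 2, 1, 0.3), c(0, 0, 2, 1.2, 0.9), c(0, 0, 2, 1, 0.3))
  r2 <- stack_matrix_(relax_circular(matrix_stack_(0:2, m2), 0.95))
  expect_equal(r2[2, 5], 0.9)

  # c = 0.975, threshold 0.95, phi 0.8, neighbor mean 0.2 -> w = 0.5 -> 0.5
  m3 <- rbind(c(0, 0, 2, 1, 0.2), c(0, 0, 2, 1.95, 0.8), c(0, 0, 2, 1, 0.2))
  r3 <- stack_matrix_(relax_circular(matrix_stack_(0:2, m3), 0.95))
  expect_equal(r3[2, 5], 0.5, tolerance = 1e-12)

  # single-slice stack unchanged
  s1 <- matrix_stack_(0, rbind(c(0, 0, 1, 1, 0.7)))
  expect_equal(stack_matrix_(relax_circular(s1)), stack_matrix_(s1))
})

test_that("rotation smoothing averages with clipped windows and contracts variation", {
  s <- matrix_stack_(0:2, cbind(0, 0, 2, 1, c(0, 0.3, 0)))
  expect_equal(stack_matrix_(smooth_rotation(s, 3))[, 5], c(0.15, 0.1, 0.15))

  const <- matrix_stack_(0:4, cbind(0, 0, 2, 1, rep(0.4, 5)))
  expect_equal(stack_matrix_(smooth_rotation(const, 3))[, 5], rep(0.4, 5))
  expect_error(smooth_rotation(const, 4), class = "ellipstack_input_error")

  tv <- function(x) sum(abs(diff(x)))
  set.seed(33)
  for (i in 1:100) {
    phi <- stats::rnorm(8, sd = 0.4)
    s <- matrix_stack_(0:7, cbind(0, 0, 2, 1, phi))
    sm <- stack_matrix_(smooth_rotation(s, 3))[, 5]
    expect_lte(tv(sm), tv(phi) + 1e-12)
  }
})

test_that("smoothing leaves centers and axes untouched", {
  s <- random_stack(L = 6, seed = 34)
  sm <- smooth_rotation(s, 3)
  expect_equal(stack_matrix_(sm)[, 1:4], stack_matrix_(s)[, 1:4])
})

test_that("resampling reproduces knots, linear and cubic parameter curves", {
  s <- random_stack(L = 8, seed = 35)
  same <- resample_stack(s, 8)
  expect_lt(max(abs(stack_matrix_(same) - stack_matrix_(s))), 1e-10)
  expect_equal(same$z, s$z)

  # linear-in-t parameters are reproduced exactly at any L
  t8 <- seq(0, 1, length.out = 8)
  lin <- matrix_stack_(s$z, cbind(1 + 2 * t8, -t8, 5 + t8, 4 - t8, 0.1 * t8))
  out <- resample_stack(lin, 15)
  t15 <- seq(0, 1, length.out = 15)
  expect_lt(max(abs(stack_matrix_(out) -
                      cbind(1 + 2 * t15, -t15, 5 + t15, 4 - t15, 0.1 * t15))),
            1e-10)

  # cubic polynomial curves sampled at 11 knots, resampled to 21
  t11 <- seq(0, 1, length.out = 11)
  cub <- function(t) cbind(1 + t - 2 * t^3, t^2, 6 + t^3, 5 - t + t^2 / 2,
                           0.2 * t^3 - 0.1 * t)
  s11 <- matrix_stack_(10 * t11, cub(t11))
  out21 <- resample_stack(s11, 21)
  t21 <- seq(0, 1, length.out = 21)
  expect_lt(max(abs(stack_matrix_(out21) - cub(t21))), 1e-8)

  expect_error(resample_stack(s, 2), class = "ellipstack_input_error")
})

test_that("resampling commutes with translation of the centers", {
  s <- random_stack(L = 7, seed = 36)
  sh <- c(12.3, -4.5)
  m <- stack_matrix_(s); m[, 1:2] <- sweep(m[, 1:2], 2, sh, "+")
  a <- stack_matrix_(resample_stack(matrix_stack_(s$z, m), 13))
  b <- stack_matrix_(resample_stack(s, 13))
  b[, 1:2] <- sweep(b[, 1:2], 2, sh, "+")
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("reorder then relax then smooth is idempotent", {
  set.seed(37)
  for (i in 1:5) {
    s <- random_stack(L = 9)
    # keep every slice clearly non-circular: a blended relaxation re-applied
    # to a still-circular slice is not a fixed point by design
    m <- stack_matrix_(s)
    m[, 4] <- pmin(m[, 4], 0.9 * m[, 3])
    s <- matrix_stack_(s$z, m)
    once <- smooth_rotation(relax_circular(reorder_axes(s), 0.95), 3)
    # reordering and relaxation leave an already-processed stack alone
    again <- relax_circular(reorder_axes(once), 0.95)
    expect_lt(max(abs(stack_matrix_(again) - stack_matrix_(once))), 1e-9)
    # smoothing is only asserted to contract the angle total variation
    sm2 <- smooth_rotation(again, 3)
    tv <- function(x) sum(abs(diff(x)))
    expect_lte(tv(stack_matrix_(sm2)[, 5]),
               tv(stack_matrix_(once)[, 5]) + 1e-12)
  }
})

test_that("canonicalized labels make the center-slice angle near zero", {
  set.seed(38)
  for (i in 1:5) {
    s <- random_stack(L = 7)
    m <- stack_matrix_(s)
    m[, 5] <- m[, 5] + pi / 2 # push labels away from the canonical branch
    m[, 3:4] <- m[, c(4, 3)] # swap axes accordingly
    can <- canonicalize_labels(matrix_stack_(s$z, m))
    cm <- stack_matrix_(can)
    expect_lte(abs(cm[4, 5]), pi / 4 + 1e-12)
    for (l in 1:7)
      expect_lt(boundary_hausdorff(s$params[[l]], can$params[[l]]), 1e-9)
  }
})
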