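# Control points, the sample-space similarity transform, the center curve,
# and the per-case normalization pipeline.

test_that("control point validation enforces structure", {
  g <- function(z) cbind(matrix(stats::rnorm(12), 6, 2), z)
  set.seed(41)
  expect_s3_class(control_points(g(0), g(3.3), g(6.6)), "control_points")
  expect_error(control_points(g(0)[1:5, ], g(3.3), g(6.6)),
               "exactly 6", class = "ellipstack_input_error")
  expect_error(control_points(g(0), g(0), g(6.6)),
               "increasing", class = "ellipstack_input_error")
  bad <- g(0); bad[3, 3] <- 0.5
  expect_error(control_points(bad, g(3.3), g(6.6)),
               "coplanar", class = "ellipstack_input_error")
})

test_that("automatic control points sit on the slice ellipses at 60-degree steps", {
  circ <- matrix_stack_(c(0, 3.3, 6.6),
                        cbind(0, 0, 10, 10, rep(0, 3)))
  cp <- auto_control_points(circ)
  r <- sqrt(rowSums(cp$center[, 1:2]^2))
  expect_equal(r, rep(10, 6), tolerance = 1e-9)
  ang <- sort(atan2(cp$center[, 2], cp$center[, 1]) %% (2 * pi))
  expect_equal(diff(ang), rep(pi / 3, 5), tolerance = 1e-9)

  s <- random_stack(L = 7, seed = 42)
  cp2 <- auto_control_points(s)
  for (g in seq_along(cp2)) {
    idx <- c(1L, 4L, 7L)[g]
    imp <- ellipstack:::ellipse_implicit(s$params[[idx]],
                                         cp2[[g]][, 1:2, drop = FALSE])
    expect_lt(max(abs(imp - 1)), 1e-9)
    expect_equal(unique(cp2[[g]][, 3]), s$z[idx])
  }
})

test_that("control-point jitter has the configured spread and leaves z alone", {
  s <- random_stack(L = 7, seed = 43)
  clean <- auto_control_points(s)
  devs <- replicate(200, {
    cp <- auto_control_points(s, jitter_sd = 1, seed = NULL)
    cp$center[, 1:2] - clean$center[, 1:2]
  })
  # 2400 N(0,1) draws: sd within 3 binomial-ish sigmas, mean near 0
  expect_lt(abs(stats::sd(devs) - 1), 0.06)
  expect_lt(abs(mean(devs)), 0.07)
  cp <- auto_control_points(s, jitter_sd = 1, seed = 5)
  expect_equal(cp$first[, 3], clean$first[, 3])
  # seeded jitter is reproducible
  expect_equal(auto_control_points(s, jitter_sd = 1, seed = 5), cp)
})

test_that("the normalization transform satisfies its defining postconditions", {
  set.seed(44)
  for (i in 1:10) {
    s <- random_stack(L = 9)
    cp <- auto_control_points(s, jitter_sd = 0.5, seed = i)
    tr <- compute_transform(cp)
    tcp <- transform_control_points(cp, tr)
    P <- rbind(tcp$first, tcp$center, tcp$last)
    expect_lt(max(abs(colMeans(P))), 1e-9)
    q <- tcp$center[, 1:2]
    expect_equal(sqrt(mean(rowSums(sweep(q, 2, colMeans(q))^2))), 1,
                 tolerance = 1e-9)
    expect_equal(mean(tcp$last[, 3]) - mean(tcp$first[, 3]), 1,
                 tolerance = 1e-9)
    v <- eigen(stats::cov(q), symmetric = TRUE)$vectors[, 1]
    expect_lt(abs(v[2]), 1e-9) # dominant direction on the x-axis
    # round trip
    back <- transform_control_points(tcp, tr, inverse = TRUE)
    expect_lt(max(abs(rbind(back$first, back$center, back$last) -
                        rbind(cp$first, cp$center, cp$last))), 1e-9)
  }
})

test_that("transforms are translation-equivariant and invertible on stacks", {
  s <- random_stack(L = 7, seed = 45)
  cp <- auto_control_points(s)
  tr <- compute_transform(cp)
  sh <- c(10, 20, 5)
  cp_sh <- control_points(sweep(cp$first, 2, sh, "+"),
                          sweep(cp$center, 2, sh, "+"),
                          sweep(cp$last, 2, sh, "+"))
  tr_sh <- compute_transform(cp_sh)
  expect_equal(tr_sh$translation, tr$translation + sh, tolerance = 1e-9)
  expect_equal(tr_sh$scale, tr$scale, tolerance = 1e-12)
  expect_equal(tr_sh$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(tr_sh$z_scale, tr$z_scale, tolerance = 1e-12)

  rt <- from_sample_space(to_sample_space(s, tr), tr)
  expect_lt(max(abs(stack_matrix_(rt) - stack_matrix_(s))), 1e-9)
  expect_lt(max(abs(rt$z - s$z)), 1e-9)

  # identity transform leaves a stack alone; pure scale doubles theta and alpha
  id <- sample_transform(c(0, 0, 0), 1, 0, 1)
  expect_equal(stack_matrix_(to_sample_space(s, id)), stack_matrix_(s))
  sc <- sample_transform(c(0, 0, 0), 2, 0, 1)
  m2 <- stack_matrix_(to_sample_space(s, sc))
  expect_equal(m2[, 1:4], stack_matrix_(s)[, 1:4] * 2)
})

test_that("degenerate control points are rejected", {
  z <- c(0, 3.3, 6.6)
  pt <- cbind(matrix(1, 6, 2), 0)
  expect_error(compute_transform(control_points(
    pt, cbind(matrix(1, 6, 2), 3.3), cbind(matrix(1, 6, 2), 6.6))),
    class = "ellipstack_input_error")
})

test_that("the center curve is the quadratic through the group centroids", {
  mkgrp <- function(ctr, z)
    cbind(ellipse_boundary(ellipse(ctr, c(2, 1), 0.2),
                           angles = 2 * pi * (0:5) / 6), z)
  cp <- control_points(mkgrp(c(0, 0), 0), mkgrp(c(1, 0), 0.5),
                       mkgrp(c(0, 0), 1))
  curve <- center_curve(cp)
  expect_equal(as.numeric(predict(curve, 0.25)), c(0.75, 0), tolerance = 1e-9)
  expect_equal(as.numeric(predict(curve, c(0, 0.5, 1))),
               c(0, 1, 0, 0, 0, 0), tolerance = 1e-9)

  # collinear centroids: the curve is the line
  cp2 <- control_points(mkgrp(c(0, 0), 0), mkgrp(c(1, 1), 0.5),
                        mkgrp(c(2, 2), 1))
  expect_equal(as.numeric(predict(center_curve(cp2), 0.5)), c(1, 1),
               tolerance = 1e-9)

  pts <- center_curve_points(cp, 5)
  expect_equal(dim(pts), c(5L, 2L))
  expect_equal(unname(pts[c(1, 3, 5), ]), rbind(c(0, 0), c(1, 0), c(0, 0)),
               tolerance = 1e-9)
})

test_that("cases differing by an in-plane similarity normalize identically", {
  spec <- phantom_spec(n_cases = 1, contour_jitter_sd = 0, cp_jitter_sd = 0,
                       with_volume = FALSE, seed = 10)
  cs <- generate_case(spec, 55)
  n1 <- normalize_case(cs$contours, cp = cs$cp, L = 9)

  dd <- 0.8; sc <- 1.6; sh <- c(25, -12)
  R <- ellipstack:::rot2(dd)
  contours2 <- lapply(cs$contours, function(ct)
    slice_contour(ct$z, sweep(sc * ct$points %*% t(R), 2, sh, "+")))
  mvg <- function(g) cbind(sweep(sc * g[, 1:2] %*% t(R), 2, sh, "+"), g[, 3])
  cp2 <- control_points(mvg(cs$cp$first), mvg(cs$cp$center), mvg(cs$cp$last))
  n2 <- normalize_case(contours2, cp = cp2, L = 9)
  expect_lt(max(abs(stack_matrix_(n1$stack) - stack_matrix_(n2$stack))), 1e-6)
  expect_lt(max(abs(n1$xi - n2$xi)), 1e-6)
})

test_that("offsets vanish for centers lying exactly on the control-point curve", {
  # stack whose centers follow a quadratic in z; automatic cps anchor the
  # curve at the ellipse centers of the first/center/last slices
  L <- 9
  z <- 3.3 * (seq_len(L) - 1L)
  t <- seq(0, 1, length.out = L)
  centers <- cbind(2 + 3 * t - 2 * t^2, -1 + t + t^2)
  a <- outer(sqrt(1 - 0.8 * (2 * t - 1)^2), c(20, 14))
  s <- matrix_stack_(z, cbind(centers, a, rep(0.1, L)))
  cp <- auto_control_points(s)
  tr <- compute_transform(cp)
  ss <- to_sample_space(s, tr)
  curve <- center_curve(transform_control_points(cp, tr))
  eta <- stack_matrix_(ss)[, 1:2] - predict(curve, ss$z)
  expect_lt(max(abs(eta)), 1e-9)
})
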