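# Evaluation metrics: slice-wise Hausdorff distance between contour point
# sets, 3D aggregation, voxel-count Dice and accuracy, the 3 mm exceedance
# count, and cohort median/MAD summaries.

#' Hausdorff distance between two point sets
#'
#' `max( max_x min_y d(x,y), max_y min_x d(x,y) )` in mm. Contours should be
#' densified (e.g. [densify_contour()] to >= 360 points) before calling so
#' the point-set distance approximates the curve distance.
#'
#' @param x_points,y_points non-empty numeric matrices of `(x, y)` points (mm).
#' @return Scalar distance (mm); symmetric in its arguments.
#' @export
hausdorff_slice <- function(x_points, y_points) {
  check_numeric_matrix(x_points, 2L, "x_points")
  check_numeric_matrix(y_points, 2L, "y_points")
  if (nrow(x_points) == 0L || nrow(y_points) == 0L)
    stop_input("Hausdorff distance needs non-empty point sets")
  d2 <- outer(x_points[, 1], y_points[, 1], "-")^2 +
    outer(x_points[, 2], y_points[, 2], "-")^2
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

#' Aggregate per-slice Hausdorff distances to 3D
#'
#' Mean or median over the slices where both contours exist (`NA` entries
#' mark slices without a counterpart and are dropped).
#'
#' @param per_slice numeric vector of per-slice distances (mm), `NA` allowed.
#' @param agg `"mean"` or `"median"`.
#' @return Scalar aggregate (mm).
#' @export
hausdorff_3d <- function(per_slice, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (length(per_slice) < 1L) stop_input("need at least one slice value")
  v <- per_slice[!is.na(per_slice)]
  if (length(v) == 0L)
    stop_input("undefined metric: no slice has both contours")
  if (agg == "mean") mean(v) else stats::median(v)
}

#' Dice volume overlap
#'
#' `2|X intersect Y| / (|X| + |Y|)` on voxel masks of a common grid.
#'
#' @param mask_x,mask_y logical arrays of identical dimension.
#' @return Overlap ratio in `[0, 1]`.
#' @export
dice <- function(mask_x, mask_y) {
  if (!identical(dim(mask_x), dim(mask_y)))
    stop_input("masks must share one grid")
  nx <- sum(mask_x); ny <- sum(mask_y)
  if (nx + ny == 0L) stop_input("undefined metric: both masks are empty")
  2 * sum(mask_x & mask_y) / (nx + ny)
}

#' Segmentation accuracy against a reference mask
#'
#' `1 - (|FP| + |FN|) / (|TP| + |FN|)` with the reference `X`:
#' `TP = X & Y`, `FN = X & !Y`, `FP = !X & Y` (the denominator is `|X|`).
#' The value can be negative when the false-positive volume exceeds the
#' reference volume; that sign behavior is preserved.
#'
#' @param mask_x logical reference mask (non-empty).
#' @param mask_y logical test mask on the same grid.
#' @return Scalar accuracy (at most 1; may be negative).
#' @export
accuracy <- function(mask_x, mask_y) {
  if (!identical(dim(mask_x), dim(mask_y)))
    stop_input("masks must share one grid")
  nx <- sum(mask_x)
  if (nx == 0L) stop_input("undefined metric: empty reference mask")
  fp <- sum(!mask_x & mask_y)
  fn <- sum(mask_x & !mask_y)
  1 - (fp + fn) / nx
}

#' Count slices exceeding a Hausdorff threshold
#'
#' @param per_slice numeric per-slice distances (mm).
#' @param threshold clinical acceptability threshold (default 3 mm).
#' @return A list with `count` (slices strictly above the threshold) and
#'   `total`.
#' @export
count_hd_exceed <- function(per_slice, threshold = 3) {
  if (length(per_slice) < 1L) stop_input("need at least one slice value")
  v <- per_slice[!is.na(per_slice)]
  list(count = sum(v > threshold), total = length(v))
}

#' Cohort summary: median and MAD per metric
#'
#' The median absolute deviation is unscaled (no consistency factor):
#' `median(|x - median(x)|)`.
#'
#' @param metrics data frame with one row per case; all numeric columns are
#'   summarized.
#' @return Data frame with columns `metric`, `median`, `mad`.
#' @export
summarize_cohort <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) < 1L)
    stop_input("metrics must be a data frame with at least one case")
  num <- vapply(metrics, is.numeric, logical(1))
  cols <- names(metrics)[num]
  med <- vapply(metrics[cols], stats::median, numeric(1))
  mad <- vapply(metrics[cols], function(x) stats::median(abs(x - stats::median(x))),
                numeric(1))
  data.frame(metric = cols, median = unname(med), mad = unname(mad))
}

#' Resample a closed contour to equal arc-length spacing
#'
#' @param points numeric matrix of polyline vertices (closed implicitly).
#' @param n number of output points (default 360).
#' @return `n x 2` matrix.
#' @export
densify_contour <- function(points, n = 360L) {
  check_numeric_matrix(points, 2L, "points")
  closed <- rbind(points, points[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_input("contour has zero length")
  target <- total * (seq_len(n) - 1L) / n
  cbind(stats::approx(s, closed[, 1], xout = target)$y,
        stats::approx(s, closed[, 2], xout = target)$y)
}

#' Rasterize a closed polygon on a pixel grid (even-odd rule)
#'
#' @param points polygon vertices, closed implicitly.
#' @param grid a [plane_grid()].
#' @return Logical matrix of dimension `grid$shape`.
#' @export
rasterize_polygon <- function(points, grid) {
  check_numeric_matrix(points, 2L, "points")
  if (!inherits(grid, "plane_grid")) stop_input("grid must be a 'plane_grid'")
  x <- grid_axis(grid, 1L)
  y <- grid_axis(grid, 2L)
  centers <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  bnd <- rbind(points, points[1L, , drop = FALSE])
  matrix(mgcv::in.out(bnd, centers), grid$shape[1L], grid$shape[2L])
}

# 3D mask of a contour list on a volume grid.
rasterize_contours <- function(contours, x) {
  g <- geometry_of(x)
  z <- vapply(contours, function(ct) ct$z, numeric(1))
  ks <- match_slices(z, g)
  mask <- array(FALSE, g$shape)
  pg <- in_plane_grid(g)
  for (i in seq_along(ks))
    mask[, , ks[i]] <- rasterize_polygon(contours[[i]]$points, pg)
  mask
}

#' Evaluate a delineation against reference contours
#'
#' Computes the three cohort metrics for one case: 3D Dice and accuracy on
#' masks rasterized on the case's voxel grid (reference contours by even-odd
#' polygon fill, the model stack by the pixel-center ellipse rule), and the
#' per-slice Hausdorff distances between the densified reference contour and
#' the ellipse boundary (360 points each) on slices where both exist,
#' aggregated by the mean, plus the 3 mm exceedance count.
#'
#' @param ref_contours list of reference [slice_contour()] (the expert
#'   delineation).
#' @param stack the delineation under test, an [ellipse_stack()].
#' @param geometry an [image_volume()] or [volume_geometry()] defining the
#'   voxel grid.
#' @param hd_points densification count per contour (default 360).
#' @return A list with `dice`, `accuracy`, `hd_mean`, `hd_median`,
#'   `hd_per_slice`, `exceed` (`count`, `total`).
#' @export
evaluate_case <- function(ref_contours, stack, geometry, hd_points = 360L) {
  g <- geometry_of(geometry)
  ref_mask <- rasterize_contours(ref_contours, g)
  test_mask <- rasterize_stack(stack, g)
  ref_z <- vapply(ref_contours, function(ct) ct$z, numeric(1))
  hd <- rep(NA_real_, length(ref_z))
  for (i in seq_along(ref_z)) {
    j <- which(abs(stack$z - ref_z[i]) <= 0.5 * g$spacing[3] + 1e-6)
    if (length(j) != 1L) next
    hd[i] <- hausdorff_slice(
      densify_contour(ref_contours[[i]]$points, hd_points),
      ellipse_boundary(stack$params[[j]], hd_points))
  }
  list(dice = dice(ref_mask, test_mask),
       accuracy = accuracy(ref_mask, test_mask),
       hd_mean = hausdorff_3d(hd, "mean"),
       hd_median = hausdorff_3d(hd, "median"),
       hd_per_slice = hd,
       exceed = count_hd_exceed(hd))
}
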