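#' Saturation-threshold grid
#'
#' The grid over which characteristic and ULBP curves are sampled: by default
#' 21 thresholds from 0.10 to 0.50 in steps of 0.02.
#'
#' @param t_min,t_max,t_step grid limits and spacing, fractions in \[0, 1\].
#' @return strictly increasing numeric vector of thresholds.
#' @export
#' @examples
#' length(threshold_grid())  # 21
threshold_grid <- function(t_min = 0.10, t_max = 0.50, t_step = 0.02) {
  stopifnot(t_min >= 0, t_max <= 1, t_step > 0, t_min < t_max)
  g <- seq(t_min, t_max, by = t_step)
  stopifnot(length(g) >= 2, all(diff(g) > 0))
  g
}

# Shared guard: per-tile HSV + ROI with an explicit empty-ROI error.
tile_hsv_roi <- function(tile, config) {
  hsv <- rgb_to_hsv(tile)
  roi <- roi_mask(hsv, config$roi.bg_sat_max, config$roi.bg_val_min)
  if (!any(roi))
    stop("no tissue in tile '", tile$id, "': ROI is empty")
  list(hsv = hsv, roi = roi)
}

# Stained-pixel counts over the grid, from precomputed hsv/roi.
stain_counts <- function(hsv, roi, grid, config) {
  band <- c(config$stain.hue_low_deg, config$stain.hue_high_deg)
  vapply(grid, function(t)
    sum(stain_mask(hsv, roi, t, band, config$stain.val_max)), numeric(1))
}

#' Characteristic curve of a tile
#'
#' The percentage of ROI pixels that are DAB-stained, as a function of the
#' saturation threshold.  Because stain masks nest with increasing threshold,
#' every characteristic curve is non-increasing.
#'
#' @param tile a [her2_tile()] with non-empty ROI.
#' @param grid threshold grid, see [threshold_grid()].
#' @param config a [her2_config()].
#' @return object of class `her2_curve`: list with `t` (thresholds), `p`
#'   (percentages in \[0, 100\]) and `tile_id`.
#' @export
characteristic_curve <- function(tile, grid = threshold_grid(),
                                 config = her2_config()) {
  x <- tile_hsv_roi(tile, config)
  n_roi <- sum(x$roi)
  p <- 100 * stain_counts(x$hsv, x$roi, grid, config) / n_roi
  structure(list(t = grid, p = p, tile_id = tile$id), class = "her2_curve")
}

#' @export
print.her2_curve <- function(x, ...) {
  cat(sprintf("characteristic curve of '%s' (%d thresholds %.2f-%.2f)\n",
              x$tile_id, length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  p(t): %.1f%% at t=%.2f down to %.1f%% at t=%.2f; area %.2f\n",
              x$p[1], x$t[1], x$p[length(x$p)], x$t[length(x$t)],
              area_under_curve(x)))
  invisible(x)
}

#' @export
plot.her2_curve <- function(x, ...) {
  graphics::plot(x$t, x$p, type = "b", pch = 16, ylim = c(0, 100),
                 xlab = "saturation threshold",
                 ylab = "% stained ROI pixels",
                 main = x$tile_id, ...)
  invisible(x)
}

#' Area under a characteristic curve
#'
#' Trapezoidal integral of `p` over the threshold range, a single-number
#' shape summary with good inter-class separation.
#'
#' @param curve a `her2_curve`.
#' @return area in percent x saturation units (constant 100 over
#'   \[0.1, 0.5\] gives 40).
#' @export
area_under_curve <- function(curve) {
  stopifnot(inherits(curve, "her2_curve"))
  t <- curve$t; p <- curve$p
  sum(diff(t) * (head(p, -1) + p[-1]) / 2)
}

#' Evenly spaced downsampling indices
#'
#' Index rule shared by curve downsampling: `n` positions
#' `round(k * (m - 1) / (n - 1))`, `k = 0..n-1`, on a length-`m` curve
#' (1-based on return).  Always keeps both endpoints; for `n = 10` on the
#' default 21-point grid this selects every second point starting at the
#' first.
#'
#' @param m curve length.
#' @param n number of points to keep, `2 <= n <= m`.
#' @return integer vector of 1-based indices.
#' @export
downsample_indices <- function(m, n) {
  if (n < 2 || n > m) stop("n_points must be between 2 and the curve length")
  unique(round((0:(n - 1)) * (m - 1) / (n - 1))) + 1L
}

# Index rule for characteristic-curve downsampling: every second grid point
# starting at the first (0, 2, ..., 2(n-1)) whenever that fits on the grid —
# this keeps the low-threshold points, which carry the most staining signal —
# falling back to evenly spaced indices (which for n = 2 yields the two
# endpoints) otherwise.
cc_downsample_indices <- function(m, n) {
  if (n < 2 || n > m) stop("n_points must be between 2 and the curve length")
  if (n > 2 && 2 * (n - 1) <= m - 1) seq(1L, by = 2L, length.out = n)
  else downsample_indices(m, n)
}

#' Downsample a characteristic curve
#'
#' Reduces the curve to `n_points` values (default 10), exploiting the
#' smoothness of characteristic curves.  For the default 10-of-21 reduction
#' this keeps every second grid point starting at t = 0.10; `n_points = 2`
#' keeps the two endpoints.
#'
#' @param curve a `her2_curve`.
#' @param n_points number of retained points.
#' @return numeric vector of length `n_points` (named `cc_00`, `cc_01`, ...).
#' @export
downsample_curve <- function(curve, n_points = 10) {
  stopifnot(inherits(curve, "her2_curve"))
  idx <- cc_downsample_indices(length(curve$p), n_points)
  setNames(curve$p[idx], sprintf("cc_%02d", seq_along(idx) - 1))
}

#' Export curves as a long-format data frame
#'
#' @param curves list of `her2_curve` objects.
#' @return data frame with columns `tile_id`, `t`, `p`, suitable for CSV
#'   export and plotting.
#' @export
curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cv)
    data.frame(tile_id = cv$tile_id, t = cv$t, p = cv$p)))
}

#' Classification accuracy versus curve sampling density
#'
#' For each candidate number of retained curve points, trains a one-vs-all
#' logistic regression on characteristic-curve features alone, repeating a
#' random stratified 70/30 split, and reports the mean held-out accuracy.
#' Used to choose how many of the 21 grid points the final descriptor keeps.
#'
#' @param curve_matrix numeric matrix, one row per sample, columns = the full
#'   grid values of the characteristic curve.
#' @param labels factor (or coercible) of HER2 scores, one per row.
#' @param n_points_list candidate numbers of retained points.
#' @param repeats number of random splits per candidate.
#' @param train_frac training fraction of each split.
#' @param seed master seed; all randomness derives from it.
#' @param config a [her2_config()].
#' @return data frame with columns `n_points`, `mean_accuracy`, `sd_accuracy`.
#' @export
sampling_sweep <- function(curve_matrix, labels,
                           n_points_list = c(3, 5, 10, 21),
                           repeats = 200, train_frac = 0.7, seed = 1,
                           config = her2_config()) {
  curve_matrix <- as.matrix(curve_matrix)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("sampling sweep needs at least 2 classes")
  stopifnot(nrow(curve_matrix) == length(labels))
  m <- ncol(curve_matrix)
  out <- lapply(n_points_list, function(np) {
    idx <- cc_downsample_indices(m, np)
    x <- curve_matrix[, idx, drop = FALSE]
    acc <- vapply(seq_len(repeats), function(r) {
      sp <- stratified_split_idx(labels, train_frac,
                                 seed = derive_seed(seed, np, r))
      fit <- her2_ova(x[sp$train, , drop = FALSE], labels[sp$train],
                      learner = "logreg", config = config)
      mean(predict(fit, x[sp$test, , drop = FALSE]) == labels[sp$test])
    }, numeric(1))
    data.frame(n_points = np, mean_accuracy = mean(acc), sd_accuracy = sd(acc))
  })
  do.call(rbind, out)
}
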