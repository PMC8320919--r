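#' Default synthetic-class parameters
#'
#' Per-class generator settings emulating how membrane-like DAB staining
#' differs across HER2 scores: the stained fraction of tissue, the
#' saturation distribution of stained pixels, and the spatial correlation
#' length (which controls how connected the stained regions are) all
#' increase with the score.  Score-0 tiles stain about 5% of the ROI at low
#' saturation, so their characteristic curves sit below the 10% line;
#' score-3+ tiles stain over half the ROI at high saturation, keeping their
#' curves above the 30% line over the whole threshold grid.
#'
#' @param label HER2 score, one of `"0"`, `"1+"`, `"2+"`, `"3+"`.
#' @param ... overrides of individual fields.
#' @return list of generator parameters.
#' @export
her2_class_params <- function(label = c("0", "1+", "2+", "3+"), ...) {
  label <- match.arg(label)
  base <- switch(label,
    "0"  = list(stain_frac = 0.05, sat_mean = 0.20, sat_spread = 0.06,
                connectivity_scale = 4),
    "1+" = list(stain_frac = 0.15, sat_mean = 0.30, sat_spread = 0.08,
                connectivity_scale = 8),
    "2+" = list(stain_frac = 0.30, sat_mean = 0.50, sat_spread = 0.10,
                connectivity_scale = 12),
    "3+" = list(stain_frac = 0.55, sat_mean = 0.75, sat_spread = 0.10,
                connectivity_scale = 16)
  )
  p <- c(base, list(
    hue_center = 30, hue_spread = 15,      # DAB brown sector
    sat_min = 0.13,                        # keeps stained pixels above t = 0.10
    counter_hue = 220, counter_sat = 0.18, counter_sat_sd = 0.04,
    bg_frac = 0.10
  ))
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown class parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  stopifnot(p$stain_frac >= 0, p$stain_frac <= 1,
            p$sat_mean > 0, p$sat_mean <= 1, p$connectivity_scale >= 1)
  p$label <- label
  p
}

# Smooth random scalar field: uniform noise low-pass filtered by a Gaussian
# of standard deviation `scale` pixels (circular convolution via FFT, so the
# field is stationary with no edge artefacts).
smooth_field <- function(n, scale) {
  noise <- matrix(runif(n * n), n, n)
  d <- c(0:(n %/% 2), -rev(seq_len(ceiling(n / 2) - 1)))  # circular distance
  g <- exp(-d^2 / (2 * scale^2))
  k <- outer(g, g); k <- k / sum(k)
  Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) / n^2
}

# Vectorized HSV (h in degrees, s, v in [0,1]) to RGB in [0,1].
hsv_to_rgb01 <- function(h, s, v) {
  h <- (h %% 360) / 60
  c_ <- v * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- v - c_
  sector <- floor(h) %% 6
  r <- g <- b <- numeric(length(h))
  sel <- function(i) sector == i
  r[sel(0)] <- c_[sel(0)]; g[sel(0)] <- x[sel(0)]
  r[sel(1)] <- x[sel(1)];  g[sel(1)] <- c_[sel(1)]
  g[sel(2)] <- c_[sel(2)]; b[sel(2)] <- x[sel(2)]
  g[sel(3)] <- x[sel(3)];  b[sel(3)] <- c_[sel(3)]
  r[sel(4)] <- x[sel(4)];  b[sel(4)] <- c_[sel(4)]
  r[sel(5)] <- c_[sel(5)]; b[sel(5)] <- x[sel(5)]
  cbind(r + m, g + m, b + m)
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Generate a synthetic IHC-like tile
#'
#' Draws a smooth random scalar field at the class's correlation length,
#' thresholds it at the exact quantile that stains the target fraction of
#' tissue, and colours the three pixel populations: stained pixels get DAB
#' brown hues with class-dependent saturation, the remaining tissue a
#' low-saturation bluish counterstain, and a background fraction is painted
#' near-white.  The ground-truth record reports the stain fraction achieved
#' at every grid threshold (measured on the final 8-bit tile) and the
#' largest-connected-component fraction.
#'
#' @param label HER2 score label.
#' @param seed tile seed; identical `(label, seed, params, size)` reproduce
#'   byte-identical tiles.
#' @param params class parameters, see [her2_class_params()].
#' @param size tile side in pixels (>= 64).
#' @param id tile identifier.
#' @return list with `tile` (a [her2_tile()]) and `truth` (list: `label`,
#'   `stain_frac` target, `grid`, `achieved` stained fraction per threshold,
#'   `largest_cc_frac`, `roi_frac`).
#' @export
generate_tile <- function(label, seed = 1, params = her2_class_params(label),
                          size = 128, id = NULL) {
  stopifnot(size >= 64)
  if (is.null(id)) id <- sprintf("synth_%s_seed%d", gsub("\\+", "p", label), seed)
  n <- size * size
  with_seed(seed, {
    field <- smooth_field(size, params$connectivity_scale)
    bgfield <- smooth_field(size, 8)

    n_bg <- round(params$bg_frac * n)
    if (n_bg >= n) stop("background fraction leaves no tissue")
    bg_idx <- order(bgfield)[seq_len(n_bg)]
    roi_idx <- setdiff(seq_len(n), bg_idx)
    n_roi <- length(roi_idx)

    k <- round(params$stain_frac * n_roi)
    if (k > n_roi) stop("infeasible stain fraction for this background fraction")
    stain_idx <- roi_idx[order(field[roi_idx], decreasing = TRUE)[seq_len(k)]]
    counter_idx <- setdiff(roi_idx, stain_idx)

    h <- s <- v <- numeric(n)
    # background: near-white
    h[bg_idx] <- runif(n_bg, 0, 360)
    s[bg_idx] <- runif(n_bg, 0, 0.04)
    v[bg_idx] <- runif(n_bg, 0.96, 1.00)
    # counterstain: bluish, low saturation, clearly tissue
    nc <- length(counter_idx)
    h[counter_idx] <- rnorm(nc, params$counter_hue, 10) %% 360
    s[counter_idx] <- rnorm_clip(nc, params$counter_sat, params$counter_sat_sd,
                                 0.10, 0.50)
    v[counter_idx] <- rnorm_clip(nc, 0.75, 0.06, 0.40, 0.89)
    # DAB stain: brown, class-dependent saturation
    h[stain_idx] <- rnorm_clip(k, params$hue_center, params$hue_spread / 2,
                               params$hue_center - params$hue_spread,
                               params$hue_center + params$hue_spread)
    s[stain_idx] <- rnorm_clip(k, params$sat_mean, params$sat_spread,
                               params$sat_min, 1)
    v[stain_idx] <- rnorm_clip(k, 0.70, 0.08, 0.35, 0.92)

    rgb <- hsv_to_rgb01(h, s, v)
    px <- array(round(rgb * 255), dim = c(size, size, 3))
    tile <- her2_tile(px, id = id)

    # achieved staining measured on the quantized tile
    mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
    mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
    s_q <- ifelse(mx == 0, 0, 1 - mn / mx)
    grid <- threshold_grid()
    region <- matrix(FALSE, size, size); region[stain_idx] <- TRUE
    achieved <- vapply(grid, function(t) sum(region & s_q >= t) / n_roi,
                       numeric(1))
    cc_frac <- largest_component_size(region & s_q >= grid[1], 8) / n_roi

    list(tile = tile,
         truth = list(tile_id = id, label = label,
                      stain_frac = params$stain_frac, grid = grid,
                      achieved = achieved, largest_cc_frac = cc_frac,
                      roi_frac = n_roi / n))
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_per_class` tiles per HER2 class with per-tile seeds derived
#' from the master seed.  Returns the tiles in memory; when `dir` is given,
#' additionally writes PNG tiles plus `labels.csv` (tile_id, label) and
#' `truth.csv` (per-threshold achieved stain fractions and the
#' largest-component fraction).
#'
#' @param n_per_class tiles per class (>= 1).
#' @param seed master seed.
#' @param params optional named list of per-class parameter lists
#'   (names `"0"`, `"1+"`, `"2+"`, `"3+"`).
#' @param size tile side in pixels.
#' @param dir optional output directory (created if missing).
#' @return list with `tiles` (list of [her2_tile()]), `labels` (data frame
#'   `tile_id`, `label`) and `truth` (data frame, one row per tile).
#' @export
generate_dataset <- function(n_per_class = 200, seed = 1, params = NULL,
                             size = 128, dir = NULL) {
  stopifnot(n_per_class >= 1)
  tiles <- list(); truth_rows <- list()
  for (ci in seq_along(HER2_LEVELS)) {
    cl <- HER2_LEVELS[ci]
    pp <- if (!is.null(params)) params[[cl]] else her2_class_params(cl)
    for (i in seq_len(n_per_class)) {
      id <- sprintf("tile_%d%s_%04d", ci - 1,
                    ifelse(cl == "0", "", "p"), i)
      g <- generate_tile(cl, seed = derive_seed(seed, ci, i), params = pp,
                         size = size, id = id)
      tiles[[id]] <- g$tile
      tr <- g$truth
      truth_rows[[id]] <- data.frame(
        tile_id = id, label = cl, stain_frac = tr$stain_frac,
        largest_cc_frac = tr$largest_cc_frac, roi_frac = tr$roi_frac,
        t(setNames(tr$achieved, sprintf("achieved_%02d",
                                        seq_along(tr$achieved) - 1))))
    }
  }
  labels <- data.frame(tile_id = names(tiles),
                       label = rep(HER2_LEVELS, each = n_per_class),
                       stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory ", dir)
    for (id in names(tiles))
      write_tile(tiles[[id]], file.path(dir, paste0(id, ".png")))
    write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(tiles = unname(tiles), labels = labels, truth = truth)
}
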