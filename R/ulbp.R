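# Neighbour ring offsets (row, col), circular order around the centre pixel.
LBP_OFFSETS <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                    c(1, 1), c(1, 0), c(1, -1), c(0, -1))

# Lookup tables over the 256 8-bit codes: number of set bits, and uniformity
# (circular 0<->1 transition count <= 2).  Built once per session.
.lbp_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      codes <- 0:255
      bits <- t(vapply(codes, function(cd) as.integer(intToBits(cd)[1:8]),
                       integer(8)))
      nbits <- rowSums(bits)
      trans <- rowSums(bits != bits[, c(2:8, 1)])
      cache <<- list(nbits = nbits, uniform = trans <= 2)
    }
    cache
  }
})

# 8-bit LBP codes for all interior pixels of a numeric matrix: bit k set iff
# neighbour k >= centre.  Returns an (h-2) x (w-2) integer matrix.
lbp_codes <- function(img) {
  h <- nrow(img); w <- ncol(img)
  rows <- 2:(h - 1); cols <- 2:(w - 1)
  ctr <- img[rows, cols]
  code <- matrix(0L, h - 2, w - 2)
  for (k in seq_along(LBP_OFFSETS)) {
    d <- LBP_OFFSETS[[k]]
    nb <- img[rows + d[1], cols + d[2]]
    code <- code + bitwShiftL(1L, k - 1L) * (nb >= ctr)
  }
  code
}

#' Rotation-invariant uniform LBP histogram
#'
#' Scans every interior pixel inside the ROI, forms the 8-bit local binary
#' pattern over the radius-1, 8-neighbour ring (bit set iff neighbour >=
#' centre; ties count as 1), and bins uniform patterns (at most 2 circular
#' 0-1 transitions) by their number of set bits into components `U0..U8`.
#' Non-uniform patterns fall into a separate bin.  All fractions are
#' normalised by the number of evaluated pixels, so
#' `U0 + ... + U8 + nonuniform = 1`.
#'
#' A constant region — fully stained or fully unstained — yields all-255
#' codes and lands in `U8`, which is why `U8` is discarded from the feature
#' set as a background indicator.
#'
#' @param img numeric matrix: the binary stain mask (default substrate) or a
#'   saturation image.
#' @param roi logical ROI matrix of the same shape; only interior pixels with
#'   `roi == TRUE` are evaluated.
#' @return object of class `ulbp_histogram`: list with `u` (named fractions
#'   `U0..U8`), `nonuniform`, `n_evaluated`, and `empty` (TRUE iff no pixel
#'   was evaluated, in which case all fractions are zero).
#' @export
ulbp_histogram <- function(img, roi) {
  img <- if (is.logical(img)) img + 0 else img
  stopifnot(is.matrix(img), is.logical(roi), all(dim(img) == dim(roi)),
            nrow(img) >= 3, ncol(img) >= 3)
  h <- nrow(img); w <- ncol(img)
  interior <- roi[2:(h - 1), 2:(w - 1)]
  n_eval <- sum(interior)
  u <- setNames(numeric(9), paste0("U", 0:8))
  if (n_eval == 0)
    return(structure(list(u = u, nonuniform = 0, n_evaluated = 0L,
                          empty = TRUE), class = "ulbp_histogram"))
  code <- lbp_codes(img)[interior]
  tabs <- .lbp_tables()
  counts <- tabulate(code + 1L, nbins = 256L)
  for (m in 0:8)
    u[m + 1] <- sum(counts[tabs$uniform & tabs$nbits == m]) / n_eval
  nonuniform <- sum(counts[!tabs$uniform]) / n_eval
  structure(list(u = u, nonuniform = nonuniform,
                 n_evaluated = as.integer(n_eval), empty = FALSE),
            class = "ulbp_histogram")
}

#' @export
print.ulbp_histogram <- function(x, ...) {
  cat(sprintf("ULBP histogram over %d pixels%s\n", x$n_evaluated,
              if (x$empty) " (empty)" else ""))
  print(round(c(x$u, nonuniform = x$nonuniform), 4))
  invisible(x)
}

#' ULBP feature curves of a tile
#'
#' For each saturation threshold on the grid, computes the stain mask and its
#' ULBP histogram over the tile's ROI, collecting components `U0..U7` into 8
#' per-threshold feature curves (`U8` is discarded as a constant-background
#' indicator).  With the default 21-point grid the full set has dimension
#' 8 x 21 = 168.
#'
#' As the threshold passes the most saturated in-band pixel the mask empties,
#' every evaluated pattern becomes constant, and all of `U0..U7` drop to 0.
#'
#' @param tile a [her2_tile()] with non-empty ROI.
#' @param grid threshold grid.
#' @param config a [her2_config()]; `ulbp.substrate` selects whether codes
#'   are computed on the binary mask (default) or on the saturation channel
#'   zeroed outside the mask.
#' @return object of class `ulbp_curves`: list with `t`, `curves` (8 x
#'   length(t) matrix, rows `U0..U7`) and `tile_id`.
#' @export
ulbp_curves <- function(tile, grid = threshold_grid(),
                        config = her2_config()) {
  x <- tile_hsv_roi(tile, config)
  band <- c(config$stain.hue_low_deg, config$stain.hue_high_deg)
  curves <- vapply(grid, function(t) {
    m <- stain_mask(x$hsv, x$roi, t, band, config$stain.val_max)
    substrate <- if (config$ulbp.substrate == "mask") m + 0 else x$hsv$s * m
    ulbp_histogram(substrate, x$roi)$u[1:8]
  }, numeric(8))
  rownames(curves) <- paste0("U", 0:7)
  structure(list(t = grid, curves = curves, tile_id = tile$id),
            class = "ulbp_curves")
}

#' @export
print.ulbp_curves <- function(x, ...) {
  cat(sprintf("ULBP curve set of '%s': %d curves x %d thresholds\n",
              x$tile_id, nrow(x$curves), ncol(x$curves)))
  invisible(x)
}

#' Line fit of a feature curve
#'
#' Ordinary least-squares first-order approximation of a low-curvature
#' feature curve, parameterised as slope (per unit saturation) and
#' y-intercept (value at t = 0).  Used to embed ULBP curves in 2-D.
#'
#' @param values curve values.
#' @param t threshold grid of the same length (>= 2).
#' @return named numeric `c(slope =, intercept =)`.
#' @export
linear_parameterize <- function(values, t = threshold_grid()) {
  stopifnot(length(values) == length(t), length(values) >= 2)
  tc <- t - mean(t)
  slope <- sum(tc * (values - mean(values))) / sum(tc^2)
  c(slope = slope, intercept = mean(values) - slope * mean(t))
}

#' Pairwise similarity of ULBP component curves
#'
#' For each pair of components `(Ui, Uj)`, computes the Pearson correlation
#' of their curves within each sample and averages over samples; samples
#' where either curve is constant are skipped for that pair.  Pairs whose
#' mean correlation reaches `threshold` are reported as redundant — the
#' evidence behind merging the 8 component curves down to 5.
#'
#' @param curvesets list of `ulbp_curves` objects (>= 2 samples).
#' @param threshold redundancy threshold on the mean correlation.
#' @return list with `similarity` (8 x 8 symmetric matrix, unit diagonal,
#'   `NA` where every sample was degenerate), `redundant` (data frame of
#'   reported pairs) and `n_samples`.
#' @export
pairwise_curve_similarity <- function(curvesets, threshold = 0.95) {
  stopifnot(length(curvesets) >= 2)
  comp <- rownames(curvesets[[1]]$curves)
  k <- length(comp)
  sim <- matrix(NA_real_, k, k, dimnames = list(comp, comp))
  diag(sim) <- 1
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    rs <- vapply(curvesets, function(cs) {
      a <- cs$curves[i, ]; b <- cs$curves[j, ]
      if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    }, numeric(1))
    sim[i, j] <- sim[j, i] <-
      if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  }
  pairs <- which(upper.tri(sim) & !is.na(sim) & sim >= threshold,
                 arr.ind = TRUE)
  redundant <- data.frame(curve_a = comp[pairs[, 1]],
                          curve_b = comp[pairs[, 2]],
                          similarity = sim[pairs])
  list(similarity = sim, redundant = redundant,
       n_samples = length(curvesets))
}

#' Reduce a ULBP curve set to the 25-component descriptor
#'
#' Keeps components `U0..U4` only (the similarity analysis shows `U5..U7`
#' duplicate curves already retained) and samples each retained curve at 5
#' evenly spaced grid indices, giving 5 x 5 = 25 values in curve-major order.
#'
#' @param curveset an `ulbp_curves` object on the full grid.
#' @return named numeric vector of length 25 (`ulbp_00` .. `ulbp_24`),
#'   ordered `U0` points first, then `U1`, etc.
#' @export
reduce_ulbp <- function(curveset) {
  stopifnot(inherits(curveset, "ulbp_curves"), nrow(curveset$curves) == 8)
  idx <- downsample_indices(ncol(curveset$curves), 5)
  vals <- as.vector(t(curveset$curves[paste0("U", 0:4), idx]))
  setNames(vals, sprintf("ulbp_%02d", 0:24))
}

#' Flatten a full ULBP curve set to the 168-value diagnostic vector
#'
#' @param curveset an `ulbp_curves` object.
#' @return named numeric vector (`ulbp_full_U0_00`, ...), curve-major.
#' @export
ulbp_full_vector <- function(curveset) {
  stopifnot(inherits(curveset, "ulbp_curves"))
  nt <- ncol(curveset$curves)
  nm <- as.vector(t(outer(rownames(curveset$curves),
                          sprintf("%02d", seq_len(nt) - 1),
                          function(a, b) paste0("ulbp_full_", a, "_", b))))
  setNames(as.vector(t(curveset$curves)), nm)
}
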