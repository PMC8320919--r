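#' Convert a tile to HSV
#'
#' Standard RGB to HSV conversion.  Hue is returned in degrees in \[0, 360);
#' achromatic pixels (R = G = B) have hue 0 and saturation 0.  Saturation and
#' value are fractions in \[0, 1\].
#'
#' @param tile a [her2_tile()].
#' @return an object of class `her2_hsv`: list of matrices `h`, `s`, `v`,
#'   each with the tile's height x width shape.
#' @export
#' @examples
#' tile <- her2_tile(array(c(255L, 0L, 0L), dim = c(1, 1, 3))[rep(1, 4), rep(1, 4), ])
#' hsv <- rgb_to_hsv(tile)
#' hsv$h[1, 1]  # 0 degrees: pure red
rgb_to_hsv <- function(tile) {
  stopifnot(inherits(tile, "her2_tile"))
  d <- dim(tile$px)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(tile$px[, , 1]),
    g = as.vector(tile$px[, , 2]),
    b = as.vector(tile$px[, , 3]),
    maxColorValue = 255
  )
  structure(list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]) %% 360,
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  ), class = "her2_hsv")
}

#' Convert a tile to CIE-Lab
#'
#' sRGB to CIE-Lab (D65 white point).  White maps to L ~ 100, a ~ 0, b ~ 0;
#' the b axis is the blue (negative) to yellow/brown (positive) opponent
#' axis that carries the counterstain-vs-DAB contrast.
#'
#' @param tile a [her2_tile()].
#' @return an object of class `her2_lab`: list of matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(tile) {
  stopifnot(inherits(tile, "her2_tile"))
  d <- dim(tile$px)
  rgb01 <- cbind(as.vector(tile$px[, , 1]),
                 as.vector(tile$px[, , 2]),
                 as.vector(tile$px[, , 3])) / 255
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  structure(list(
    L = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  ), class = "her2_lab")
}

#' Region-of-interest (tissue) mask
#'
#' Slide background is near-white: low saturation and high value.  A pixel is
#' background iff `S < bg_sat_max` AND `V > bg_val_min`; the ROI (tissue,
#' whether counterstained or DAB-stained) is the complement.
#'
#' @param hsv a `her2_hsv` image (see [rgb_to_hsv()]).
#' @param bg_sat_max,bg_val_min background thresholds, fractions in \[0, 1\].
#' @return a logical matrix with attribute `role = "roi"`.
#' @export
roi_mask <- function(hsv, bg_sat_max = 0.08, bg_val_min = 0.90) {
  stopifnot(inherits(hsv, "her2_hsv"),
            bg_sat_max >= 0, bg_sat_max <= 1,
            bg_val_min >= 0, bg_val_min <= 1)
  m <- !(hsv$s < bg_sat_max & hsv$v > bg_val_min)
  attr(m, "role") <- "roi"
  m
}

# Hue-band membership, modulo 360 so bands may wrap through 0.
hue_in_band <- function(h, lo, hi) {
  lo <- lo %% 360; hi <- hi %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' DAB stain mask at a saturation threshold
#'
#' A pixel is stained iff it lies in the ROI, its hue falls in the DAB brown
#' band, its saturation is at least `t` (inclusive, so masks nest exactly:
#' `t2 >= t1` implies `stain_mask(t2)` is a subset of `stain_mask(t1)`), and
#' its value does not exceed `val_max` (glare exclusion).
#'
#' @param hsv a `her2_hsv` image.
#' @param roi the ROI mask from [roi_mask()].
#' @param t saturation threshold in \[0, 1\].
#' @param hue_band numeric length 2, hue interval in degrees (may wrap).
#' @param val_max maximum value (brightness) of a stained pixel.
#' @return a logical matrix with attribute `role = "stain"`.
#' @export
stain_mask <- function(hsv, roi, t, hue_band = c(10, 50), val_max = 0.98) {
  stopifnot(inherits(hsv, "her2_hsv"), is.logical(roi),
            all(dim(roi) == dim(hsv$s)),
            t >= 0, t <= 1, length(hue_band) == 2)
  m <- roi & hue_in_band(hsv$h, hue_band[1], hue_band[2]) &
    hsv$s >= t & hsv$v <= val_max
  attr(m, "role") <- "stain"
  m
}

#' ROI pixel fraction of a tile
#'
#' @param tile a [her2_tile()].
#' @param config a [her2_config()].
#' @return fraction of tile pixels classified as tissue, in \[0, 1\].
#' @export
roi_fraction <- function(tile, config = her2_config()) {
  hsv <- rgb_to_hsv(tile)
  mean(roi_mask(hsv, config$roi.bg_sat_max, config$roi.bg_val_min))
}

#' Filter tiles by ROI coverage
#'
#' Tiles whose tissue fraction falls below `min_roi_frac` (boundary kept:
#' comparison is `>=`) are discarded; order is preserved.
#'
#' @param tiles list of [her2_tile()] objects.
#' @param min_roi_frac minimum ROI fraction in \[0, 1\].
#' @param config a [her2_config()] supplying the background thresholds.
#' @return the retained sublist.
#' @export
filter_tiles <- function(tiles, min_roi_frac = 0.40, config = her2_config()) {
  stopifnot(min_roi_frac >= 0, min_roi_frac <= 1)
  if (!length(tiles)) return(tiles)
  keep <- vapply(tiles, function(tl) roi_fraction(tl, config) >= min_roi_frac,
                 logical(1))
  tiles[keep]
}
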