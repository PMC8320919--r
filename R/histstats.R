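#' Grey-level histogram of the CIE-Lab b* channel
#'
#' Converts the tile to CIE-Lab and maps the b* (blue-yellow) channel to an
#' 8-bit grey level `g = clamp(round(b* + 128), 0, 255)`, then forms the
#' normalised 256-bin histogram over the whole tile.  In IHC tiles the
#' colours of interest fall along the blue-yellow axis: the haematoxylin
#' counterstain sits below 128, DAB brown above it.
#'
#' @param tile a [her2_tile()].
#' @return object of class `grey_histogram`: list with `p` (256 fractions
#'   summing to 1, bins for grey levels 0..255) and `n_pixels`.
#' @export
bstar_histogram <- function(tile) {
  lab <- rgb_to_lab(tile)
  g <- pmin(pmax(round(lab$b + 128), 0), 255)
  p <- tabulate(as.integer(g) + 1L, nbins = 256L)
  n <- length(g)
  structure(list(p = p / n, n_pixels = n), class = "grey_histogram")
}

#' @export
print.grey_histogram <- function(x, ...) {
  nz <- which(x$p > 0)
  cat(sprintf("b* grey-level histogram over %d pixels: %d non-empty bins (%d-%d)\n",
              x$n_pixels, length(nz), min(nz) - 1, max(nz) - 1))
  cat(sprintf("  entropy %.3f bits, energy %.5f\n",
              hist_entropy(x), hist_energy(x)))
  invisible(x)
}

#' Histogram entropy
#'
#' Shannon entropy of the grey-level distribution, in bits:
#' `H = -sum p_i log2 p_i` with `0 log 0 := 0`.  Ranges from 0 (single bin)
#' to 8 bits (uniform over 256 bins); grows with the colour spread that
#' accompanies heavier DAB staining.
#'
#' @param hist a `grey_histogram` (or any non-negative probability vector).
#' @return entropy in bits.
#' @export
hist_entropy <- function(hist) {
  p <- if (inherits(hist, "grey_histogram")) hist$p else hist
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Histogram energy
#'
#' `E = sum p_i^2`, the concentration of the grey-level distribution: 1 for
#' a single occupied bin, 1/256 for a uniform histogram.  Varies inversely
#' with entropy.
#'
#' @inheritParams hist_entropy
#' @return energy in (0, 1\].
#' @export
hist_energy <- function(hist) {
  p <- if (inherits(hist, "grey_histogram")) hist$p else hist
  sum(p^2)
}
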