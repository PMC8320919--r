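#' Connected-component sizes of a binary mask
#'
#' Labels maximal sets of true pixels mutually reachable under 4- or
#' 8-adjacency and returns their sizes.  Implemented as graph components
#' over the pixel adjacency structure.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return integer vector of component sizes (possibly empty), descending.
#' @export
component_sizes <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  on <- which(mask)
  if (!length(on)) return(integer(0))
  # forward shifts only, so each undirected adjacency appears once
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(-1, 1)))
  id <- match(seq_len(h * w), on)      # linear pixel index -> vertex id
  edges <- integer(0)
  for (d in shifts) {
    r <- ((on - 1) %% h) + 1L
    cc <- ((on - 1) %/% h) + 1L
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    src <- id[on[ok]]; dst <- id[nb]
    keep <- !is.na(dst)
    edges <- c(edges, rbind(src[keep], dst[keep]))
  }
  g <- igraph::make_graph(edges, n = length(on), directed = FALSE)
  sort(igraph::components(g)$csize, decreasing = TRUE)
}

#' Size of the largest connected component
#'
#' @inheritParams component_sizes
#' @return pixel count of the largest component; 0 for an empty mask.
#' @export
largest_component_size <- function(mask, connectivity = 8) {
  cs <- component_sizes(mask, connectivity)
  if (!length(cs)) 0L else as.integer(cs[1])
}

#' Region-connectedness measure of a tile
#'
#' The stain mask is taken at the lowest saturation threshold (default 0.10),
#' and the size of its largest connected component is expressed as a
#' percentage of the ROI pixel count.  Strong, complete membrane staining
#' yields a single dominant component and a high value; scattered weak
#' staining fragments into many small components.
#'
#' The measure can never exceed the characteristic-curve value at the same
#' threshold, since the largest component is a subset of all stained pixels.
#'
#' @param tile a [her2_tile()] with non-empty ROI.
#' @param t0 saturation threshold of the binarisation.
#' @param config a [her2_config()]; `conn.connectivity` selects adjacency.
#' @return connectedness percentage in \[0, 100\].
#' @export
connectedness <- function(tile, t0 = 0.10, config = her2_config()) {
  x <- tile_hsv_roi(tile, config)
  m <- stain_mask(x$hsv, x$roi, t0,
                  c(config$stain.hue_low_deg, config$stain.hue_high_deg),
                  config$stain.val_max)
  100 * largest_component_size(m, config$conn.connectivity) / sum(x$roi)
}

#' Connectedness diagnostic record
#'
#' Mirrors the overlay-style inspection of the connectedness computation:
#' returns the ROI pixel count, largest-component size and the percentage,
#' plus a pseudo-colour overlay tile (stained pixels yellow, unstained ROI
#' cyan, background white).
#'
#' @inheritParams connectedness
#' @return list with `roi_pixels`, `largest_cc`, `connectedness_pct`, and
#'   `overlay` (a [her2_tile()]).
#' @export
connectedness_diagnostic <- function(tile, t0 = 0.10, config = her2_config()) {
  x <- tile_hsv_roi(tile, config)
  m <- stain_mask(x$hsv, x$roi, t0,
                  c(config$stain.hue_low_deg, config$stain.hue_high_deg),
                  config$stain.val_max)
  lc <- largest_component_size(m, config$conn.connectivity)
  d <- dim(m)
  px <- array(255L, dim = c(d, 3L))
  px[, , 3][m] <- 0L                      # stained -> yellow (B = 0)
  px[, , 1][x$roi & !m] <- 0L             # unstained ROI -> cyan (R = 0)
  list(roi_pixels = sum(x$roi), largest_cc = lc,
       connectedness_pct = 100 * lc / sum(x$roi),
       overlay = her2_tile(px, id = paste0(tile$id, "_overlay")))
}
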