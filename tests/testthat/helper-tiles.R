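# Tile fixtures built in code.

# A tile filled with a single RGB colour.
uniform_tile <- function(r, g, b, h = 8, w = 8, id = "uniform") {
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  her2_tile(px, id = id)
}

# A tile whose pixels are one of several RGB colours, assigned by index list.
# colours: list of c(r, g, b); assign: integer matrix h x w of colour indices.
mosaic_tile <- function(colours, assign, id = "mosaic") {
  h <- nrow(assign); w <- ncol(assign)
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) {
    look <- vapply(colours, `[`, numeric(1), ch)
    px[, , ch] <- matrix(look[assign], h, w)
  }
  her2_tile(px, id = id)
}

# Frequently used colours (integer RGB) with exact HSV values:
COL_WHITE <- c(255, 255, 255)                  # background: S = 0, V = 1
COL_BROWN_S06 <- c(204, 143, 82)               # H = 30, S ~ 0.598, V = 0.8
COL_BROWN_S03 <- c(200, 170, 140)              # H = 30, S = 0.30 exactly
COL_BROWN_S005 <- c(200, 195, 190)             # H = 30, S = 0.05 exactly
COL_BLUE_TISSUE <- c(140, 160, 200)            # H = 220, S = 0.30: ROI, out of band
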