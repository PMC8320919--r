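# Independent oracles, hand-coded from first principles, used to cross-check
# the implementation.  They share no code with the package internals.

# Scalar RGB (0..255) -> HSV (degrees, fractions), textbook formulas.
hsv_oracle <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  c(h = h, s = if (mx == 0) 0 else d / mx, v = mx)
}

# Scalar sRGB (0..255) -> CIE-Lab under D65, textbook formulas.
lab_oracle <- function(r, g, b) {
  lin <- function(u) {
    u <- u / 255
    ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  }
  rgb <- c(lin(r), lin(g), lin(b))
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% rgb)
  wp <- c(0.950456, 1, 1.089058)  # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Naive per-pixel ULBP histogram: explicit loops, explicit circular
# transition counting.  img numeric matrix, roi logical matrix.
ulbp_oracle <- function(img, roi) {
  if (is.logical(img)) img <- img + 0
  h <- nrow(img); w <- ncol(img)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  u <- setNames(numeric(9), paste0("U", 0:8)); nonuni <- 0; n <- 0
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    if (!roi[i, j]) next
    n <- n + 1
    bits <- vapply(offs, function(d) img[i + d[1], j + d[2]] >= img[i, j],
                   logical(1))
    trans <- sum(bits != c(bits[-1], bits[1]))
    if (trans <= 2) u[sum(bits) + 1] <- u[sum(bits) + 1] + 1
    else nonuni <- nonuni + 1
  }
  if (n == 0) return(list(u = u, nonuniform = 0, n_evaluated = 0L))
  list(u = u / n, nonuniform = nonuni / n, n_evaluated = n)
}

# Breadth-first flood fill component sizes (queue of pixel coordinates).
flood_fill_sizes <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  sizes <- integer(0)
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (d in offs) {
        i <- p[1] + d[1]; j <- p[2] + d[2]
        if (i >= 1 && i <= h && j >= 1 && j <= w &&
            mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue <- c(queue, list(c(i, j)))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# 90-degree clockwise rotation of a matrix.
rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
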