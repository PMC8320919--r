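full_roi <- function(n) matrix(TRUE, n, n)

make_curveset <- function(curves, t = threshold_grid(), id = "manual") {
  rownames(curves) <- paste0("U", 0:(nrow(curves) - 1))
  structure(list(t = t, curves = curves, tile_id = id),
            class = "ulbp_curves")
}

test_that("constant regions land entirely in U8", {
  h <- ulbp_histogram(matrix(1, 6, 6), full_roi(6))
  expect_equal(unname(h$u["U8"]), 1)
  expect_equal(sum(h$u[1:8]), 0)

  h <- ulbp_histogram(matrix(0, 6, 6), full_roi(6))
  expect_equal(unname(h$u["U8"]), 1)  # ties compare >= and count as 1
})

test_that("a single centre pixel produces the enumerated histogram", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  h <- ulbp_histogram(m, full_roi(5))
  # 9 interior pixels: the centre sees 8 smaller neighbours (pattern 0 -> U0);
  # every other centre is 0, so with ties counting as 1 all its bits are set
  # (pattern 255 -> U8).  Values frozen from the brute-force oracle.
  expect_equal(unname(h$u["U0"]), 1 / 9)
  expect_equal(unname(h$u["U8"]), 8 / 9)
  expect_equal(unname(h$u["U1"]), 0)
  expect_equal(h$n_evaluated, 9L)

  o <- ulbp_oracle(m, full_roi(5))
  expect_equal(h$u, o$u)
  expect_equal(h$nonuniform, o$nonuniform)
})

test_that("histograms match brute-force enumeration on random masks", {
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(runif(16 * 16) < runif(1, 0.2, 0.8), 16, 16)
    roi <- if (i %% 3 == 0) matrix(runif(16 * 16) < 0.7, 16, 16) else full_roi(16)
    h <- ulbp_histogram(m, roi)
    o <- ulbp_oracle(m, roi)
    expect_equal(h$u, o$u)
    expect_equal(h$nonuniform, o$nonuniform)
    expect_equal(h$n_evaluated, o$n_evaluated)
    if (h$n_evaluated > 0)
      expect_equal(sum(h$u) + h$nonuniform, 1, tolerance = 1e-9)
  }
})

test_that("histograms are exactly invariant under square rotations", {
  set.seed(22)
  for (i in 1:20) {
    m <- matrix(runif(12 * 12) < 0.5, 12, 12)
    h0 <- ulbp_histogram(m, full_roi(12))
    m90 <- rot90(m); m180 <- rot90(m90); m270 <- rot90(m180)
    for (mr in list(m90, m180, m270)) {
      hr <- ulbp_histogram(mr, full_roi(12))
      expect_identical(hr$u, h0$u)
      expect_identical(hr$nonuniform, h0$nonuniform)
    }
  }
})

test_that("empty evaluation sets are flagged, not silently zero-divided", {
  h <- ulbp_histogram(matrix(0, 5, 5), matrix(FALSE, 5, 5))
  expect_true(h$empty)
  expect_equal(sum(h$u), 0)
  expect_equal(h$n_evaluated, 0L)
})

test_that("ULBP curves vanish without in-band staining and beyond the maximum saturation", {
  blue <- do.call(uniform_tile, as.list(COL_BLUE_TISSUE))
  cs <- ulbp_curves(blue)
  expect_equal(dim(cs$curves), c(8, 21))
  expect_true(all(cs$curves == 0))

  # all stained pixels at S = 0.30: every curve is 0 for t > 0.30
  assign <- cbind(matrix(1, 12, 6), matrix(2, 12, 6))
  tile <- mosaic_tile(list(COL_BROWN_S03, COL_BLUE_TISSUE), assign)
  cs <- ulbp_curves(tile)
  expect_true(all(cs$curves[, cs$t > 0.30] == 0))
  expect_gt(sum(cs$curves[, cs$t <= 0.30]), 0)
})

test_that("U1 equals the share of stained pixels with one stained neighbour", {
  # direct count at the lowest threshold: stained interior pixels whose
  # 8-neighbourhood holds exactly one other stained pixel
  u1_oracle <- function(tile) {
    hsv <- rgb_to_hsv(tile)
    roi <- roi_mask(hsv)
    m <- stain_mask(hsv, roi, 0.10) + 0
    n <- nrow(m)
    cnt <- 0
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
      if (roi[i, j] && m[i, j] == 1 &&
          sum(m[(i - 1):(i + 1), (j - 1):(j + 1)]) == 2)
        cnt <- cnt + 1
    }
    cnt / sum(roi[2:(n - 1), 2:(n - 1)])
  }
  u1_impl <- function(tile) unname(ulbp_curves(tile)$curves["U1", 1])
  ga <- generate_tile("1+", seed = 5, size = 96)$tile
  gb <- generate_tile("3+", seed = 5, size = 96)$tile
  expect_equal(u1_impl(ga), u1_oracle(ga), tolerance = 1e-12)
  expect_equal(u1_impl(gb), u1_oracle(gb), tolerance = 1e-12)
  # fragmented low-grade staining shows more isolated boundary pixels than
  # the coalesced 3+ pattern, in implementation and oracle alike
  expect_equal(u1_impl(ga) > u1_impl(gb), u1_oracle(ga) > u1_oracle(gb))
})

test_that("line fits recover slopes and intercepts", {
  t <- threshold_grid()
  expect_equal(linear_parameterize(rep(3, 21), t),
               c(slope = 0, intercept = 3))
  expect_equal(linear_parameterize(2 * t + 1, t),
               c(slope = 2, intercept = 1))
  # closed-form OLS on 3 points
  fit <- linear_parameterize(c(0.30, 0.20, 0.10), t = c(0.1, 0.3, 0.5))
  expect_equal(fit, c(slope = -0.5, intercept = 0.35))
  # cross-check against lm
  lmfit <- stats::lm(y ~ x, data.frame(x = c(0.1, 0.3, 0.5),
                                       y = c(0.30, 0.20, 0.10)))
  expect_equal(unname(fit["slope"]), unname(coef(lmfit)[2]))
  expect_equal(unname(fit["intercept"]), unname(coef(lmfit)[1]))
})

test_that("pairwise similarity flags duplicated curves and only those", {
  set.seed(23)
  t <- threshold_grid()
  sets <- lapply(1:20, function(s) {
    cur <- matrix(runif(8 * 21), 8)
    cur[7, ] <- cur[3, ]  # U6 duplicates U2 in every sample
    make_curveset(cur, t)
  })
  sim <- pairwise_curve_similarity(sets, threshold = 0.95)
  expect_equal(sim$similarity["U2", "U6"], 1)
  expect_true(any(sim$redundant$curve_a == "U2" & sim$redundant$curve_b == "U6"))
  expect_identical(sim$similarity, t(sim$similarity))
  expect_equal(unname(diag(sim$similarity)), rep(1, 8))

  # independent random curves: no pair reported at 0.95
  sets <- lapply(1:500, function(s) make_curveset(matrix(runif(8 * 21), 8), t))
  sim <- pairwise_curve_similarity(sets, threshold = 0.95)
  expect_equal(nrow(sim$redundant), 0)
  off <- sim$similarity[upper.tri(sim$similarity)]
  expect_lt(max(abs(off)), 0.5)

  # degenerate pairs are undefined, never silently zero
  sets <- lapply(1:3, function(s) {
    cur <- matrix(runif(8 * 21), 8)
    cur[1, ] <- 0.5
    make_curveset(cur, t)
  })
  sim <- pairwise_curve_similarity(sets)
  expect_true(all(is.na(sim$similarity["U0", paste0("U", 1:7)])))
})

test_that("reduce_ulbp keeps U0..U4 at five evenly spaced thresholds", {
  t <- threshold_grid()
  expect_equal(unname(reduce_ulbp(make_curveset(matrix(0, 8, 21), t))),
               rep(0, 25))

  cur <- matrix(0, 8, 21); cur[1, ] <- 1
  expect_equal(unname(reduce_ulbp(make_curveset(cur, t))),
               c(rep(1, 5), rep(0, 20)))

  # grid indices {0, 5, 10, 15, 20}, curve-major order
  cur <- matrix(rep(1:8, 21), 8) * 100 + matrix(rep(0:20, each = 8), 8)
  red <- reduce_ulbp(make_curveset(cur, t))
  expect_length(red, 25)
  expect_named(red, sprintf("ulbp_%02d", 0:24))
  expect_equal(unname(red),
               as.vector(t(cur[1:5, c(1, 6, 11, 16, 21)])))
  expect_equal(unname(red[1:5]), 100 + c(0, 5, 10, 15, 20))
})

test_that("the full diagnostic vector has dimension 168", {
  cs <- ulbp_curves(generate_tile("2+", seed = 2, size = 64)$tile)
  v <- ulbp_full_vector(cs)
  expect_length(v, 168)
  expect_equal(unname(v[1:21]), unname(cs$curves["U0", ]))
})
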