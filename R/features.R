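# Canonical column order of the 38-feature descriptor.
feature_names <- function() {
  c(sprintf("cc_%02d", 0:9), sprintf("ulbp_%02d", 0:24),
    "conn", "entropy", "energy")
}

#' Assemble the 38-dimensional feature vector of a tile
#'
#' Concatenates the four feature families in fixed column order:
#' 10 characteristic-curve points (`cc_00..cc_09`), 25 reduced ULBP values
#' (`ulbp_00..ulbp_24`), the connectedness percentage (`conn`), and the b*
#' histogram entropy and energy — 38 values in total.  The HSV conversion
#' and ROI mask are computed once and shared across families.
#'
#' @param tile a [her2_tile()] that passed the ROI filter.
#' @param config a [her2_config()].
#' @param diagnostics if `TRUE`, attach the area under the characteristic
#'   curve, per-curve line fits and the full 168-value ULBP vector as the
#'   attribute `"diagnostics"`.
#' @return named numeric vector of length 38 with attribute `tile_id`.
#' @export
assemble_features <- function(tile, config = her2_config(),
                              diagnostics = FALSE) {
  x <- tile_hsv_roi(tile, config)  # empty-ROI error carries the tile id
  grid <- threshold_grid(config$grid.t_min, config$grid.t_max,
                         config$grid.t_step)
  band <- c(config$stain.hue_low_deg, config$stain.hue_high_deg)
  n_roi <- sum(x$roi)

  masks <- lapply(grid, function(t)
    stain_mask(x$hsv, x$roi, t, band, config$stain.val_max))

  # characteristic curve
  p <- vapply(masks, sum, numeric(1)) * 100 / n_roi
  curve <- structure(list(t = grid, p = p, tile_id = tile$id),
                     class = "her2_curve")
  cc <- downsample_curve(curve, config$curve.n_points)

  # ULBP curves
  curves <- vapply(masks, function(m) {
    substrate <- if (config$ulbp.substrate == "mask") m + 0 else x$hsv$s * m
    ulbp_histogram(substrate, x$roi)$u[1:8]
  }, numeric(8))
  rownames(curves) <- paste0("U", 0:7)
  cs <- structure(list(t = grid, curves = curves, tile_id = tile$id),
                  class = "ulbp_curves")
  ulbp <- reduce_ulbp(cs)

  # connectedness at the lowest threshold
  t0_idx <- which.min(abs(grid - config$conn.t0))
  m0 <- if (isTRUE(all.equal(grid[t0_idx], config$conn.t0)))
    masks[[t0_idx]]
  else
    stain_mask(x$hsv, x$roi, config$conn.t0, band, config$stain.val_max)
  conn <- 100 * largest_component_size(m0, config$conn.connectivity) / n_roi

  # b* histogram statistics (whole tile, not ROI)
  hst <- bstar_histogram(tile)

  out <- c(cc, ulbp, conn = conn,
           entropy = hist_entropy(hst), energy = hist_energy(hst))
  stopifnot(identical(names(out), feature_names()))
  attr(out, "tile_id") <- tile$id
  if (diagnostics) {
    fits <- t(apply(curves, 1, linear_parameterize, t = grid))
    attr(out, "diagnostics") <- list(
      area = area_under_curve(curve),
      line_fits = fits,
      ulbp_full = ulbp_full_vector(cs)
    )
  }
  out
}

#' Extract a feature table from a set of tiles
#'
#' Applies the ROI-coverage filter, then [assemble_features()] to each
#' retained tile.  Accepts either a directory of PNG/TIFF tiles or an
#' in-memory list of [her2_tile()] objects.  Rows are sorted by `tile_id`
#' for deterministic output; counts of kept/removed tiles are reported via
#' `message()`.
#'
#' @param tiles directory path, or list of [her2_tile()] objects.
#' @param labels optional labels: a CSV path or data frame with columns
#'   `tile_id` and `label`.  Every retained tile must have a label when
#'   labels are supplied; a mismatch is an error.
#' @param config a [her2_config()].
#' @param diagnostics add area, slope/intercept and full-ULBP columns.
#' @return data frame of class `her2_features`: `tile_id`, `label` (NA when
#'   no labels were given), and the 38 numeric feature columns (plus
#'   diagnostic columns if requested).  Attributes `config_hash` and
#'   `n_filtered` record provenance.
#' @export
extract_dataset <- function(tiles, labels = NULL, config = her2_config(),
                            diagnostics = FALSE) {
  if (is.character(tiles) && length(tiles) == 1) {
    paths <- sort(list.files(tiles, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    tiles <- list()
    for (p in paths) {
      tl <- tryCatch(read_tile(p), error = function(e) {
        warning("skipping unreadable tile ", basename(p), ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(tl)) tiles <- c(tiles, list(tl))
    }
  }
  stopifnot(is.list(tiles))
  n_in <- length(tiles)
  kept <- filter_tiles(tiles, config$tiles.min_roi_frac, config)
  message(sprintf("extract_dataset: %d/%d tiles pass the %.0f%% ROI filter",
                  length(kept), n_in, 100 * config$tiles.min_roi_frac))

  if (!is.null(labels)) {
    if (is.character(labels)) labels <- read.csv(labels, stringsAsFactors = FALSE)
    stopifnot(all(c("tile_id", "label") %in% names(labels)))
  }

  ids <- vapply(kept, function(tl) tl$id, character(1))
  ord <- order(ids)
  kept <- kept[ord]; ids <- ids[ord]

  rows <- lapply(kept, function(tl)
    assemble_features(tl, config, diagnostics = diagnostics))
  feat <- as.data.frame(do.call(rbind, rows))
  if (!nrow(feat))
    feat <- as.data.frame(matrix(numeric(0), 0, length(feature_names()),
                                 dimnames = list(NULL, feature_names())))
  if (diagnostics && length(rows)) {
    dg <- lapply(rows, attr, "diagnostics")
    feat$area <- vapply(dg, `[[`, numeric(1), "area")
    for (u in paste0("U", 0:7)) {
      feat[[paste0("slope_", u)]] <-
        vapply(dg, function(d) d$line_fits[u, "slope"], numeric(1))
      feat[[paste0("intercept_", u)]] <-
        vapply(dg, function(d) d$line_fits[u, "intercept"], numeric(1))
    }
    full <- do.call(rbind, lapply(dg, `[[`, "ulbp_full"))
    feat <- cbind(feat, as.data.frame(full))
  }

  lab <- rep(NA_character_, length(ids))
  if (!is.null(labels)) {
    idx <- match(ids, labels$tile_id)
    if (anyNA(idx))
      stop("no label for tile(s): ",
           paste(head(ids[is.na(idx)], 5), collapse = ", "))
    lab <- as.character(labels$label[idx])
  }
  out <- cbind(data.frame(tile_id = ids, label = lab,
                          stringsAsFactors = FALSE), feat)
  if (!length(ids))
    out <- cbind(data.frame(tile_id = character(0), label = character(0)),
                 feat)
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "n_filtered") <- n_in - length(kept)
  class(out) <- c("her2_features", "data.frame")
  out
}

#' Write a feature table to CSV
#'
#' Floats are written with 9 significant digits; a provenance comment line
#' (config hash) precedes the header.
#'
#' @param features a feature table from [extract_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  num <- vapply(features, is.numeric, logical(1))
  out <- features
  out[num] <- lapply(out[num], function(v) signif(v, 9))
  con <- file(path, "w")
  on.exit(close(con))
  hash <- attr(features, "config_hash")
  if (!is.null(hash)) writeLines(paste0("# config_hash=", hash), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return data frame of class `her2_features`.
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  df <- read.csv(path, skip = skip, stringsAsFactors = FALSE,
                 comment.char = "")
  if (skip == 1)
    attr(df, "config_hash") <- sub("^# config_hash=", "", first)
  df$label <- as.character(df$label)
  class(df) <- c("her2_features", "data.frame")
  df
}

# Numeric feature matrix + labels from a her2_features data frame.
features_xy <- function(features, require_labels = TRUE) {
  stopifnot(is.data.frame(features))
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  # diagnostic columns (area, line fits, full ULBP) never enter the model
  if (all(feature_names() %in% num)) num <- feature_names()
  x <- as.matrix(features[, num, drop = FALSE])
  y <- if ("label" %in% names(features)) features$label else NULL
  if (require_labels) {
    if (is.null(y) || anyNA(y))
      stop("labels are required for training/evaluation")
    y <- factor(y, levels = intersect(HER2_LEVELS, unique(y)))
    if (anyNA(y)) y <- factor(features$label)
  }
  list(x = x, y = y)
}
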