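#' Pipeline configuration
#'
#' Returns the full set of tunable parameters used throughout the feature
#' pipeline, with defaults.  Any subset can be overridden by name;
#' unrecognised keys are an error so that typos never silently fall back to
#' defaults.
#'
#' @param ... named overrides, e.g. `stain.hue_low_deg = 5`.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{`roi.bg_sat_max` (0.08), `roi.bg_val_min` (0.90)}{A pixel is slide
#'     background iff saturation < `bg_sat_max` AND value > `bg_val_min`; the
#'     region of interest (tissue) is the complement.}
#'   \item{`stain.hue_low_deg` (10), `stain.hue_high_deg` (50)}{DAB brown hue
#'     band in degrees; the band may wrap around 0.}
#'   \item{`stain.val_max` (0.98)}{stained pixels additionally require
#'     V <= `val_max`, excluding specular glare.}
#'   \item{`tiles.min_roi_frac` (0.40)}{tiles with a smaller ROI fraction are
#'     discarded before feature extraction.}
#'   \item{`grid.t_min` (0.10), `grid.t_max` (0.50), `grid.t_step` (0.02)}{the
#'     saturation-threshold grid (21 points by default).}
#'   \item{`curve.n_points` (10)}{characteristic-curve downsampling size.}
#'   \item{`ulbp.substrate` ("mask")}{"mask" computes LBP codes on the binary
#'     stain mask; "saturation" on the saturation channel zeroed outside the
#'     mask.}
#'   \item{`ulbp.similarity_threshold` (0.95)}{mean Pearson correlation above
#'     which a ULBP curve pair is reported redundant.}
#'   \item{`conn.t0` (0.10), `conn.connectivity` (8)}{threshold and pixel
#'     adjacency for the connectedness measure.}
#'   \item{`learner.logreg_C` (1.0)}{inverse regularisation strength of the
#'     ridge-penalised logistic regression.}
#'   \item{`learner.svm_cost` (1.0), `learner.svm_kernel` ("radial"),
#'     `learner.svm_gamma` (NA)}{SVM hyperparameters; `NA` gamma selects the
#'     median heuristic.}
#' }
#'
#' @return a named list of class `her2_config`.
#' @export
#' @examples
#' cfg <- her2_config(stain.hue_low_deg = 5)
#' cfg$tiles.min_roi_frac
her2_config <- function(...) {
  cfg <- list(
    roi.bg_sat_max = 0.08,
    roi.bg_val_min = 0.90,
    stain.hue_low_deg = 10,
    stain.hue_high_deg = 50,
    stain.val_max = 0.98,
    tiles.min_roi_frac = 0.40,
    grid.t_min = 0.10,
    grid.t_max = 0.50,
    grid.t_step = 0.02,
    curve.n_points = 10,
    ulbp.substrate = "mask",
    ulbp.similarity_threshold = 0.95,
    conn.t0 = 0.10,
    conn.connectivity = 8,
    learner.logreg_C = 1.0,
    learner.svm_cost = 1.0,
    learner.svm_kernel = "radial",
    learner.svm_gamma = NA_real_
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all config overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  stopifnot(cfg$tiles.min_roi_frac >= 0, cfg$tiles.min_roi_frac <= 1,
            cfg$roi.bg_sat_max >= 0, cfg$roi.bg_sat_max <= 1,
            cfg$roi.bg_val_min >= 0, cfg$roi.bg_val_min <= 1,
            cfg$conn.connectivity %in% c(4, 8),
            cfg$ulbp.substrate %in% c("mask", "saturation"))
  structure(cfg, class = "her2_config")
}

#' Load a configuration from a YAML file
#'
#' Reads a flat YAML mapping of config keys (see [her2_config()]) and merges
#' it over the defaults.  Keys given in `...` win over the file.
#'
#' @param path path to a YAML file.
#' @param ... further overrides, applied after the file.
#' @return a `her2_config` object.
#' @export
her2_config_from_yaml <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a YAML mapping")
  do.call(her2_config, utils::modifyList(vals, list(...)))
}

#' @export
print.her2_config <- function(x, ...) {
  cat("her2feat configuration:\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Short stable hash of a config, embedded in output provenance.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) format(v, digits = 12), ""),
             sep = "=", collapse = ";")
  # polynomial rolling hash over the serialized key=value string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1e9
  sprintf("%08x", as.integer(h))
}
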