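#' Construct an RGB image tile
#'
#' The unit of all feature computation: an 8-bit RGB image patch, stored as
#' an integer array `height x width x 3` with values in 0..255.  Row-major
#' convention: origin top-left, first index is the row.
#'
#' @param px numeric or integer array `h x w x 3` with values in 0..255, or
#'   in \[0, 1\] if `scale01 = TRUE`.
#' @param id tile identifier string.
#' @param scale01 if `TRUE`, `px` is interpreted as \[0, 1\] doubles (as
#'   returned by [png::readPNG()]) and rescaled to 0..255.
#' @return an object of class `her2_tile`.
#' @export
#' @examples
#' tile <- her2_tile(array(200L, dim = c(8, 8, 3)), id = "uniform_grey")
#' dim(tile$px)
her2_tile <- function(px, id = "tile", scale01 = FALSE) {
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("tile pixels must be an h x w x 3 array (exactly 3 channels)")
  if (dim(px)[1] < 3L || dim(px)[2] < 3L)
    stop("tile must be at least 3 x 3 (LBP needs an interior)")
  if (scale01) px <- round(px * 255)
  px <- array(as.integer(round(px)), dim = dim(px))
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("pixel values must lie in 0..255")
  structure(list(px = px, id = as.character(id)), class = "her2_tile")
}

#' @export
print.her2_tile <- function(x, ...) {
  d <- dim(x$px)
  cat(sprintf("her2_tile '%s': %d x %d px, 8-bit RGB\n", x$id, d[2], d[1]))
  invisible(x)
}

#' Read an image tile from disk
#'
#' Supports 8-bit RGB PNG and TIFF.  Greyscale images are expanded to three
#' equal channels; an alpha channel, if present, is dropped with a warning.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param id tile identifier; defaults to the file name without extension.
#' @return a [her2_tile()].
#' @export
read_tile <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF tiles")
      tiff::readTIFF(path)
    },
    stop("unsupported tile format '", ext, "' (expected png or tiff): ", path)
  )
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) {
    warning("dropping alpha channel of ", basename(path))
    img <- img[, , 1:3, drop = FALSE]
  }
  her2_tile(img[, , 1:3, drop = FALSE], id = id, scale01 = TRUE)
}

#' Write a tile as PNG
#'
#' @param tile a [her2_tile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "her2_tile"))
  png::writePNG(tile$px / 255, target = path)
  invisible(path)
}
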