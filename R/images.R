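#' Fundus photograph container
#'
#' A `fundus_image` is an `H x W x 3` array of 8-bit intensities (red, green,
#' blue channel order) wrapped with validation. All pipeline stages consume
#' and produce this type so that intensities stay on the 0-255 integer scale
#' throughout.
#'
#' @param pixels numeric or integer array of dimension `H x W x 3` with values
#'   in `[0, 255]`. Images smaller than 64 x 64 are rejected as they cannot
#'   carry a usable fundus field.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    ft_stop("InvalidImage", "a fundus image must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L)
    ft_stop("InvalidImage", sprintf("image %d x %d is below the 64 x 64 minimum", d[1], d[2]))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    ft_stop("InvalidImage", "intensities must lie in [0, 255]")
  px <- array(as.numeric(round(pixels)), d)
  structure(px, class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fundus_image %d x %d, mean RGB (%.1f, %.1f, %.1f)>\n",
              d[1], d[2], mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3])))
  invisible(x)
}

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

#' Binary raster mask
#'
#' Masks annotate a fundus image pixel-for-pixel. Two kinds are used: `"roi"`
#' (the imaged circular fundus field) and `"choroid"` (exposed-choroid
#' pixels). A choroid mask is always interpreted relative to, and intersected
#' with, its ROI before any area is counted.
#'
#' @param pixels logical matrix (or 0/1 numeric matrix).
#' @param kind `"roi"` or `"choroid"`.
#' @return An object of class `binary_mask`: a logical matrix with a `kind`
#'   attribute.
#' @export
binary_mask <- function(pixels, kind = c("roi", "choroid")) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels)) ft_stop("InvalidMask", "mask must be a matrix")
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(m)) ft_stop("InvalidMask", "mask contains NA")
  structure(m, kind = kind, class = "binary_mask")
}

mask_kind <- function(mask) attr(mask, "kind")

check_same_dim <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    ft_stop("MaskShapeMismatch",
            sprintf("dimensions %s vs %s do not match",
                    paste(dim(a)[1:2], collapse = "x"), paste(dim(b)[1:2], collapse = "x")))
  invisible(TRUE)
}

#' Read a fundus photograph from PNG or JPEG
#'
#' @param path file path; format is chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`). An alpha channel, if present, is dropped.
#' @return A [fundus_image()].
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) ft_stop("InvalidImage", paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        ft_stop("InvalidImage", "the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    ft_stop("InvalidImage", paste("unsupported image format:", ext))
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  fundus_image(round(px * 255))
}

#' Write a fundus image as 8-bit PNG
#' @param img a [fundus_image()]
#' @param path output path
#' @export
write_fundus <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask a [binary_mask()]
#' @param path output path
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Load a (manually corrected) exposed-choroid mask
#'
#' Reads a strictly binary 0/255 PNG mask, e.g. the product of an external
#' manual correction of an automatic label. Gray-encoded multi-channel PNGs
#' (all channels equal) are accepted and collapsed to one channel; any pixel
#' value other than 0 or 255 is rejected.
#'
#' @param path PNG path.
#' @param expect_dim optional `c(H, W)`; a mismatch raises
#'   `MaskShapeMismatch`.
#' @return A [binary_mask()] of kind `"choroid"`.
#' @export
load_corrected_mask <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) ft_stop("InvalidMask", paste("no such file:", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    ch <- dim(px)[3]
    base <- px[, , 1]
    for (k in seq_len(ch)[-1]) {
      if (k == 4) next  # tolerate an opaque alpha channel
      if (!isTRUE(all(px[, , k] == base)))
        ft_stop("NonBinaryMask", "multi-channel mask PNG with unequal channels")
    }
    px <- base
  }
  v <- round(px * 255)
  if (!all(v %in% c(0, 255)))
    ft_stop("NonBinaryMask", "mask PNG contains values other than 0 and 255")
  if (!is.null(expect_dim) && !identical(dim(v), as.integer(expect_dim)))
    ft_stop("MaskShapeMismatch",
            sprintf("mask is %s, expected %s", paste(dim(v), collapse = "x"),
                    paste(expect_dim, collapse = "x")))
  binary_mask(v == 255, kind = "choroid")
}
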