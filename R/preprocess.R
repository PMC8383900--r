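#' Preprocessing parameters
#'
#' Collects the tunables of the four preprocessing steps: frequency-domain
#' denoising, ROI extraction, LAB lightness normalization and CLAHE
#' enhancement.
#'
#' @param lowpass_cutoff Gaussian low-pass cutoff as a fraction of the Nyquist
#'   frequency, in `(0, 1]`. Frequencies below the cutoff pass unattenuated;
#'   above it the response rolls off as a Gaussian.
#' @param target_L mean lightness target on the 0-100 CIE LAB scale. A fixed
#'   target (rather than a batch mean) makes single images normalize
#'   reproducibly.
#' @param clahe_clip CLAHE clip limit (contrast restriction per tile).
#' @param clahe_tiles side of the square CLAHE tile grid.
#' @param roi_min_area_fraction minimum ROI candidate area as a fraction of
#'   the frame.
#' @param roi_circularity_min minimum circularity `4*pi*A/P^2` of an ROI
#'   candidate.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(lowpass_cutoff = 0.6, target_L = 60,
                              clahe_clip = 2, clahe_tiles = 8L,
                              roi_min_area_fraction = 0.15,
                              roi_circularity_min = 0.6) {
  ft_assert(is.numeric(lowpass_cutoff) && length(lowpass_cutoff) == 1 &&
              lowpass_cutoff > 0 && lowpass_cutoff <= 1,
            "InvalidConfig", "lowpass_cutoff must be in (0, 1]")
  ft_assert(is.numeric(target_L) && target_L > 0 && target_L < 100,
            "InvalidConfig", "target_L must be on the open 0-100 scale")
  ft_assert(clahe_clip > 0, "InvalidConfig", "clahe_clip must be positive")
  ft_assert(clahe_tiles >= 1, "InvalidConfig", "clahe_tiles must be a positive integer")
  ft_assert(roi_min_area_fraction > 0 && roi_min_area_fraction < 1,
            "InvalidConfig", "roi_min_area_fraction must be in (0, 1)")
  ft_assert(roi_circularity_min > 0 && roi_circularity_min < 1,
            "InvalidConfig", "roi_circularity_min must be in (0, 1)")
  structure(list(lowpass_cutoff = lowpass_cutoff, target_L = target_L,
                 clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 roi_min_area_fraction = roi_min_area_fraction,
                 roi_circularity_min = roi_circularity_min),
            class = "preprocess_config")
}

#' Split an RGB fundus image into its channels
#'
#' @param img a [fundus_image()]
#' @return A list with matrices `red`, `green`, `blue` (0-255 scale).
#' @export
split_channels <- function(img) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  list(red = img[, , 1], green = img[, , 2], blue = img[, , 3])
}

#' Restack channels into a fundus image
#' @param channels list with `red`, `green`, `blue` matrices
#' @return A [fundus_image()].
#' @export
restack_channels <- function(channels) {
  fundus_image(array(c(channels$red, channels$green, channels$blue),
                     c(dim(channels$red), 3L)))
}

#' Establish the fundus region of interest
#'
#' The imaged 45-degree fundus field is a bright near-circular disc on a dark
#' camera background, and the background is darkest in the red channel. The
#' red channel is therefore Otsu-thresholded; connected bright components are
#' hole-filled and screened by mean intensity (at least the global red mean),
#' area fraction, circularity and centroid location (central third of the
#' frame). The largest surviving component is the ROI.
#'
#' @param img a [fundus_image()]
#' @param cfg a [preprocess_config()]
#' @return A [binary_mask()] of kind `"roi"`: one connected hole-filled
#'   component.
#' @export
establish_roi <- function(img, cfg = preprocess_config()) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  red <- img[, , 1]
  if (max(red) == min(red)) ft_stop("NoROIFound", "flat red channel: no bright region")
  thr <- EBImage::otsu(EBImage::Image(red / 255), range = c(0, 1)) * 255
  bw <- red > thr
  if (!any(bw)) ft_stop("NoROIFound", "no pixels above the red-channel threshold")
  # bridge gaps cut into the field by dark retinal vessels before hole-filling
  closed <- EBImage::closing(EBImage::Image(bw), EBImage::makeBrush(7L, shape = "disc"))
  lab <- EBImage::bwlabel(EBImage::fillHull(closed))
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  h <- nrow(red); w <- ncol(red)
  labm <- EBImage::imageData(lab)
  keep <- integer(0)
  for (id in seq_len(nrow(shp))) {
    a <- shp[id, "s.area"]
    p <- shp[id, "s.perimeter"]
    if (a / (h * w) < cfg$roi_min_area_fraction) next
    if (mean(red[labm == id]) < mean(red)) next
    circ <- 4 * pi * a / max(p, 1)^2
    if (circ < cfg$roi_circularity_min) next
    # EBImage moments: m.cx along dim 1 (our rows), m.cy along dim 2 (columns)
    cx <- mom[id, "m.cx"]; cy <- mom[id, "m.cy"]
    if (cx < h / 3 || cx > 2 * h / 3 || cy < w / 3 || cy > 2 * w / 3) next
    keep <- c(keep, id)
  }
  if (!length(keep))
    ft_stop("NoROIFound", "no candidate component survived the morphology/location screens")
  best <- keep[which.max(shp[keep, "s.area"])]
  binary_mask(labm == best, kind = "roi")
}

# signed frequency grid (cycles per pixel) for an FFT axis of length n
fft_freq <- function(n) (((seq_len(n) - 1) + floor(n / 2)) %% n - floor(n / 2)) / n

#' Frequency-domain denoising
#'
#' Each channel is transformed to the frequency domain and multiplied by a
#' radially symmetric low-pass response: unity up to `lowpass_cutoff` (as a
#' fraction of Nyquist) and a Gaussian roll-off above it, so that
#' high-frequency acquisition noise is suppressed while the pass band is left
#' untouched. At `lowpass_cutoff = 1` the filter is the identity: the full
#' spectrum up to (and, in the corners, beyond) the Nyquist circle passes.
#'
#' @param img a [fundus_image()]
#' @param cfg a [preprocess_config()]
#' @param rolloff Gaussian roll-off width in Nyquist units.
#' @return The denoised [fundus_image()].
#' @export
denoise <- function(img, cfg = preprocess_config(), rolloff = 0.15) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  cutoff <- cfg$lowpass_cutoff
  ft_assert(cutoff > 0 && cutoff <= 1, "InvalidConfig", "lowpass_cutoff must be in (0, 1]")
  if (cutoff >= 1) return(img)
  h <- img_height(img); w <- img_width(img)
  fr <- fft_freq(h) / 0.5
  fc <- fft_freq(w) / 0.5
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  resp <- ifelse(rad <= cutoff, 1, exp(-((rad - cutoff) / rolloff)^2))
  out <- unclass(img)
  for (k in 1:3) {
    spec <- stats::fft(out[, , k]) * resp
    out[, , k] <- Re(stats::fft(spec, inverse = TRUE)) / (h * w)
  }
  fundus_image(pmin(pmax(round(out), 0), 255))
}

img_to_lab <- function(img) {
  d <- dim(img)
  rgb <- matrix(as.numeric(img) / 255, d[1] * d[2], 3)
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

lab_to_img <- function(lab, d) {
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  fundus_image(array(round(rgb * 255), c(d[1], d[2], 3)))
}

#' Lightness normalization in LAB space
#'
#' Converts to CIE LAB, shifts the L channel additively so that the mean
#' lightness (over the ROI if one is given, else the full frame) lands on
#' `target_L`, and converts back to RGB. The chromatic A/B channels are not
#' modified. Because gamut clipping on the return conversion can nudge the
#' achieved mean, the shift is refined iteratively until the mean L is within
#' 0.25 of the target (or five iterations).
#'
#' @param img a [fundus_image()]
#' @param cfg a [preprocess_config()]
#' @param roi optional [binary_mask()] restricting the mean-L computation
#' @return The normalized [fundus_image()].
#' @export
normalize_lightness <- function(img, cfg = preprocess_config(), roi = NULL) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  d <- dim(img)
  sel <- if (is.null(roi)) TRUE else {
    check_same_dim(img, roi)
    as.vector(roi)
  }
  lab0 <- img_to_lab(img)
  delta <- cfg$target_L - mean(lab0[sel, 1])
  out <- img
  for (it in 1:5) {
    lab <- lab0
    lab[, 1] <- pmin(pmax(lab[, 1] + delta, 0), 100)
    out <- lab_to_img(lab, d)
    got <- mean(img_to_lab(out)[sel, 1])
    if (abs(got - cfg$target_L) < 0.25) break
    delta <- delta + (cfg$target_L - got)
  }
  out
}

#' CLAHE enhancement of the ROI
#'
#' Applies contrast-limited adaptive histogram equalization to the lightness
#' channel: the frame is divided into a `clahe_tiles` x `clahe_tiles` grid,
#' each tile's histogram is equalized under the clip limit, and tile
#' boundaries are blended by bilinear interpolation. Pixels outside the ROI
#' are returned bit-identical to the input. A constant-lightness ROI is
#' returned unchanged (its histogram has a single occupied bin, so clipped
#' equalization is a no-op).
#'
#' @param img a [fundus_image()]
#' @param roi a [binary_mask()] of kind `"roi"`
#' @param cfg a [preprocess_config()]
#' @return The enhanced [fundus_image()].
#' @export
enhance <- function(img, roi, cfg = preprocess_config()) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  ft_assert(inherits(roi, "binary_mask") && mask_kind(roi) == "roi",
            "InvalidMask", "roi must be a binary_mask of kind 'roi'")
  check_same_dim(img, roi)
  if (!any(roi)) ft_stop("EmptyROI", "the ROI mask is empty")
  d <- dim(img)
  lab <- img_to_lab(img)
  Lm <- matrix(lab[, 1] / 100, d[1], d[2])
  if (stats::sd(Lm[as.vector(roi)]) == 0) return(img)
  Leq <- EBImage::clahe(EBImage::Image(Lm), nx = cfg$clahe_tiles, ny = cfg$clahe_tiles,
                        limit = cfg$clahe_clip, keep.range = TRUE)
  lab[, 1] <- pmin(pmax(as.vector(EBImage::imageData(Leq)), 0), 1) * 100
  out <- unclass(lab_to_img(lab, d))
  keep <- !as.vector(roi)
  for (k in 1:3) {
    ch <- out[, , k]; ch0 <- unclass(img)[, , k]
    ch[keep] <- ch0[keep]
    out[, , k] <- ch
  }
  fundus_image(out)
}

#' Full preprocessing pipeline
#'
#' Runs denoise -> ROI extraction (on the denoised image) -> lightness
#' normalization -> CLAHE enhancement, the preparation chain in front of
#' labeling and segmentation. Output dimensions always equal input
#' dimensions.
#'
#' @param img a [fundus_image()]
#' @param cfg a [preprocess_config()]
#' @return A list with elements `roi`, `enhanced`, `denoised`, `normalized`
#'   and the `config` used.
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  den <- denoise(img, cfg)
  roi <- establish_roi(den, cfg)
  nor <- normalize_lightness(den, cfg, roi)
  enh <- enhance(nor, roi, cfg)
  list(roi = roi, enhanced = enh, denoised = den, normalized = nor, config = cfg)
}
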