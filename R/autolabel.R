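#' Auto-labeling parameters
#'
#' @param subtraction_pair ordered pair of channel names; the difference image
#'   is `first - second`. Exposed choroid is red-dominant relative to the
#'   overlying retina, so `red - green` is the default.
#' @param threshold_method `"otsu"` (default) or `"percentile"`.
#' @param percentile_q percentile (0-100) used when
#'   `threshold_method = "percentile"`.
#' @param min_blob_px connected components smaller than this are discarded.
#' @param morph_radius_px radius of the disc structuring element for the
#'   morphological opening that removes threshold speckle; `0` disables it.
#' @param close_radius_px radius for a subsequent morphological closing.
#'   Defaults to `0` (off): closing re-bridges the narrow gaps between
#'   adjacent tessellation bands and biases the labeled density upward.
#' @param min_contrast minimum separation (intensity levels) between the two
#'   Otsu classes for a threshold to be accepted; below it the difference
#'   image is treated as unimodal (no tessellation) and an empty label is
#'   returned.
#' @param max_label_fraction upper bound on the fraction of the ROI the raw
#'   threshold may label. Exposed choroid is a minority class between the
#'   retinal background; a split that marks more of the ROI than this (as on
#'   an untessellated fundus, where the only bimodality is dark vessels
#'   against retina) is rejected and an empty label returned.
#' @return An `autolabel_config` list.
#' @export
autolabel_config <- function(subtraction_pair = c("red", "green"),
                             threshold_method = c("otsu", "percentile"),
                             percentile_q = 90, min_blob_px = 12L,
                             morph_radius_px = 1L, close_radius_px = 0L,
                             min_contrast = 20, max_label_fraction = 0.6) {
  threshold_method <- match.arg(threshold_method)
  ft_assert(length(subtraction_pair) == 2 &&
              all(subtraction_pair %in% c("red", "green", "blue")) &&
              subtraction_pair[1] != subtraction_pair[2],
            "InvalidConfig", "subtraction_pair must be two distinct channel names")
  ft_assert(percentile_q > 0 && percentile_q < 100, "InvalidConfig",
            "percentile_q must be in (0, 100)")
  ft_assert(min_blob_px >= 1, "InvalidConfig", "min_blob_px must be positive")
  ft_assert(morph_radius_px >= 0 && close_radius_px >= 0, "InvalidConfig",
            "morphology radii must be >= 0")
  ft_assert(max_label_fraction > 0 && max_label_fraction <= 1, "InvalidConfig",
            "max_label_fraction must be in (0, 1]")
  structure(list(subtraction_pair = subtraction_pair,
                 threshold_method = threshold_method,
                 percentile_q = percentile_q,
                 min_blob_px = as.integer(min_blob_px),
                 morph_radius_px = as.integer(morph_radius_px),
                 close_radius_px = as.integer(close_radius_px),
                 min_contrast = min_contrast,
                 max_label_fraction = max_label_fraction),
            class = "autolabel_config")
}

# Otsu threshold of a numeric sample: maximizes between-class variance on a
# fixed-width histogram. Returns the threshold and the two class means.
otsu_split <- function(v, bins = 512L) {
  rng <- range(v)
  if (diff(rng) == 0) return(list(threshold = rng[1], sep = 0))
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  k <- which.max(bcv)
  thr <- br[k + 1L]
  lo <- v <= thr
  list(threshold = thr, sep = mean(v[!lo]) - mean(v[lo]))
}

#' Automatic exposed-choroid labeling by channel subtraction
#'
#' Computes a signed difference image between two color channels of the
#' enhanced photograph (default red minus green), thresholds it inside the
#' ROI, cleans the result by morphological opening and closing and drops
#' small speckle components. The result is the automatic half of the
#' semi-automatic labeling stage and always a subset of the ROI.
#'
#' If the within-ROI difference histogram is effectively unimodal (Otsu class
#' separation below `min_contrast`), no tessellation is assumed and an empty
#' mask is returned rather than an arbitrary split of noise.
#'
#' @param img the enhanced [fundus_image()]
#' @param roi a [binary_mask()] of kind `"roi"`
#' @param cfg an [autolabel_config()]
#' @return A [binary_mask()] of kind `"choroid"`.
#' @export
auto_label <- function(img, roi, cfg = autolabel_config()) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  check_same_dim(img, roi)
  if (!any(roi)) ft_stop("EmptyROI", "the ROI mask is empty")
  ch <- split_channels(img)
  D <- ch[[cfg$subtraction_pair[1]]] - ch[[cfg$subtraction_pair[2]]]
  v <- D[roi]
  empty <- function() binary_mask(matrix(FALSE, nrow(D), ncol(D)), kind = "choroid")
  if (cfg$threshold_method == "otsu") {
    # The difference histogram can hold three classes: dark retinal vessels,
    # retinal background, and the bright tessellation bands. Tessellation is
    # a minority class, so while the upper Otsu class covers more of the ROI
    # than max_label_fraction the split separates vessels from the rest;
    # re-split the upper class until the bands (or nothing) remain.
    vc <- v
    for (it in 1:3) {
      sp <- otsu_split(vc)
      frac <- sum(v > sp$threshold) / length(v)
      if (frac <= cfg$max_label_fraction) break
      vc <- vc[vc > sp$threshold]
      if (length(vc) < 64) return(empty())
    }
    if (sum(v > sp$threshold) / length(v) > cfg$max_label_fraction) return(empty())
    if (sp$sep < cfg$min_contrast) return(empty())
    thr <- sp$threshold
  } else {
    thr <- stats::quantile(v, cfg$percentile_q / 100, names = FALSE)
  }
  bw <- D > thr & roi
  if (cfg$morph_radius_px > 0 && any(bw)) {
    brush <- EBImage::makeBrush(2L * cfg$morph_radius_px + 1L, shape = "disc")
    bw <- EBImage::imageData(EBImage::opening(EBImage::Image(bw), brush)) > 0 & roi
  }
  if (cfg$close_radius_px > 0 && any(bw)) {
    brush <- EBImage::makeBrush(2L * cfg$close_radius_px + 1L, shape = "disc")
    bw <- EBImage::imageData(EBImage::closing(EBImage::Image(bw), brush)) > 0 & roi
  }
  if (any(bw) && cfg$min_blob_px > 1) {
    labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
    sizes <- tabulate(labm[labm > 0])
    bw <- bw & matrix(sizes[pmax(labm, 1)] >= cfg$min_blob_px & labm > 0,
                      nrow(bw), ncol(bw))
  }
  binary_mask(bw, kind = "choroid")
}
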