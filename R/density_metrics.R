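#' Fundus tessellated density from masks
#'
#' FTD is the exposed-choroid area per unit fundus area:
#' `rho = S1 / S`, where `S1` is the exposed-choroid pixel count and `S` the
#' ROI pixel count. The choroid mask is intersected with the ROI before
#' counting, so stray pixels outside the imaged field never contribute.
#'
#' @param choroid a [binary_mask()] of kind `"choroid"`
#' @param roi a [binary_mask()] of kind `"roi"`
#' @return An `ftd_result` list with `rho`, `s1_px`, `s_px`.
#' @export
compute_ftd <- function(choroid, roi) {
  check_same_dim(choroid, roi)
  s <- sum(roi)
  if (s == 0) ft_stop("EmptyROI", "the ROI mask is empty")
  s1 <- sum(choroid & roi)
  structure(list(rho = s1 / s, s1_px = as.integer(s1), s_px = as.integer(s)),
            class = "ftd_result")
}

#' @export
print.ftd_result <- function(x, ...) {
  cat(sprintf("FTD rho = %.4f (S1 = %d px, S = %d px)\n", x$rho, x$s1_px, x$s_px))
  invisible(x)
}

#' Pixel-wise confusion counts within the ROI
#'
#' @param pred predicted [binary_mask()]
#' @param truth reference [binary_mask()]
#' @param roi evaluation region; only pixels inside it are tallied
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, roi) {
  check_same_dim(pred, truth)
  check_same_dim(pred, roi)
  r <- as.vector(roi)
  p <- as.vector(pred)[r]
  t <- as.vector(truth)[r]
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (tp + tn) / n`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`. A zero denominator raises
#' `UndefinedMetric` naming the metric concerned.
#'
#' @param counts a [confusion_counts()] result
#' @return Named list with `accuracy`, `sensitivity`, `specificity`.
#' @export
seg_metrics <- function(counts) {
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  if (n == 0) ft_stop("UndefinedMetric", "accuracy undefined: no pixels in the ROI")
  if (counts$tp + counts$fn == 0)
    ft_stop("UndefinedMetric", "sensitivity undefined: no positive truth pixels")
  if (counts$tn + counts$fp == 0)
    ft_stop("UndefinedMetric", "specificity undefined: no negative truth pixels")
  list(accuracy = (counts$tp + counts$tn) / n,
       sensitivity = counts$tp / (counts$tp + counts$fn),
       specificity = counts$tn / (counts$tn + counts$fp))
}

#' Dice overlap of two masks
#' @param a,b binary masks of equal dimension
#' @return Dice coefficient in `[0, 1]`; `1` when both masks are empty.
#' @export
dice <- function(a, b) {
  check_same_dim(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
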