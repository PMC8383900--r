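# shared fixtures and independent brute-force oracles

quick_params <- function(...) {
  args <- list(...)
  defaults <- list(size = 96L, rho_target = 0.2, seed = 7L)
  do.call(synth_image_params, utils::modifyList(defaults, args))
}

# nested-loop pixel-count oracle for FTD
bf_ftd <- function(choroid, roi) {
  s <- 0L; s1 <- 0L
  for (i in seq_len(nrow(roi))) for (j in seq_len(ncol(roi))) {
    if (roi[i, j]) {
      s <- s + 1L
      if (choroid[i, j]) s1 <- s1 + 1L
    }
  }
  list(rho = s1 / s, s1_px = s1, s_px = s)
}

# per-pixel tally oracle for the confusion matrix
bf_confusion <- function(pred, truth, roi) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(roi))) for (j in seq_len(ncol(roi))) {
    if (!roi[i, j]) next
    if (pred[i, j] && truth[i, j]) tp <- tp + 1L
    else if (!pred[i, j] && !truth[i, j]) tn <- tn + 1L
    else if (pred[i, j] && !truth[i, j]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

rand_mask <- function(h, w, p, kind = "choroid") {
  binary_mask(matrix(stats::runif(h * w) < p, h, w), kind = kind)
}

# one calibrated reference cohort shared by the statistical tests
ref_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(3074, generator_calibration(), seed = 1)
    cache
  }
})

cohort_predictors <- c("age", "sex", "bmi", "axial_length", "ppa_area", "sfct")

jaccard <- function(a, b) sum(a & b) / sum(a | b)
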