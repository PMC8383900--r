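test_that("compute_ftd is the exact pixel-count ratio", {
  roi <- binary_mask(matrix(rep(c(TRUE, FALSE), c(100, 44)), 12, 12), "roi")
  ch <- matrix(FALSE, 12, 12); ch[seq_len(14)] <- TRUE
  r <- compute_ftd(binary_mask(ch, "choroid"), roi)
  expect_identical(r$s_px, 100L)
  expect_identical(r$s1_px, 14L)
  expect_equal(r$rho, 0.14)

  empty <- binary_mask(matrix(FALSE, 12, 12), "choroid")
  expect_equal(compute_ftd(empty, roi)$rho, 0)
  full <- binary_mask(matrix(TRUE, 12, 12), "choroid")
  expect_equal(compute_ftd(full, roi)$rho, 1)

  expect_error(compute_ftd(empty, binary_mask(matrix(FALSE, 12, 12), "roi")),
               class = "EmptyROI")
  expect_error(compute_ftd(binary_mask(matrix(FALSE, 5, 5), "choroid"), roi),
               class = "MaskShapeMismatch")
})

test_that("compute_ftd matches the nested-loop oracle on random masks", {
  set.seed(42)
  for (i in 1:50) {
    roi <- rand_mask(10, 10, 0.8, "roi")
    if (!any(roi)) next
    ch <- rand_mask(10, 10, runif(1, 0.1, 0.6))
    got <- compute_ftd(ch, roi)
    want <- bf_ftd(ch, roi)
    expect_identical(got$s1_px, want$s1_px)
    expect_identical(got$s_px, want$s_px)
    expect_equal(got$rho, want$rho)
  }
})

test_that("confusion counts match a per-pixel tally and partition the ROI", {
  set.seed(7)
  for (i in 1:20) {
    roi <- rand_mask(8, 8, 0.9, "roi")
    pred <- rand_mask(8, 8, 0.4)
    truth <- rand_mask(8, 8, 0.3)
    got <- confusion_counts(pred, truth, roi)
    want <- bf_confusion(pred, truth, roi)
    expect_identical(got[c("tp", "tn", "fp", "fn")], want)
    expect_identical(got$tp + got$tn + got$fp + got$fn, sum(roi))
  }
  roi <- binary_mask(matrix(TRUE, 8, 8), "roi")
  m <- rand_mask(8, 8, 0.5)
  same <- confusion_counts(m, m, roi)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  inv <- confusion_counts(m, binary_mask(!unclass(m), "choroid"), roi)
  expect_identical(c(inv$tp, inv$tn), c(0L, 0L))
})

test_that("metrics follow their closed forms and flag undefined cases", {
  m <- seg_metrics(structure(list(tp = 50, tn = 30, fp = 10, fn = 10),
                             class = "confusion_counts"))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 50 / 60)
  expect_equal(m$specificity, 0.75)

  perfect <- seg_metrics(structure(list(tp = 5, tn = 5, fp = 0, fn = 0),
                                   class = "confusion_counts"))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))

  expect_error(seg_metrics(structure(list(tp = 0, tn = 9, fp = 1, fn = 0),
                                     class = "confusion_counts")),
               class = "UndefinedMetric")
  expect_error(seg_metrics(structure(list(tp = 9, tn = 0, fp = 0, fn = 1),
                                     class = "confusion_counts")),
               class = "UndefinedMetric")
})

test_that("FTD is a pure area measure: permutation-invariant and monotone", {
  set.seed(11)
  roi <- rand_mask(10, 10, 0.7, "roi")
  ch <- rand_mask(10, 10, 0.3)
  perm <- sample(100)
  roi_p <- binary_mask(matrix(as.vector(roi)[perm], 10, 10), "roi")
  ch_p <- binary_mask(matrix(as.vector(ch)[perm], 10, 10), "choroid")
  expect_equal(compute_ftd(ch, roi)$rho, compute_ftd(ch_p, roi_p)$rho)

  a <- unclass(ch) & rand_mask(10, 10, 0.5)  # a is nested inside ch
  expect_lte(compute_ftd(binary_mask(a, "choroid"), roi)$rho,
             compute_ftd(ch, roi)$rho)
})
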