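test_that("channel split restacks to the identical image", {
  g <- generate_fundus_image(quick_params())
  ch <- split_channels(g$image)
  expect_equal(unclass(restack_channels(ch)), unclass(g$image))

  pure_red <- fundus_image(array(rep(c(255, 0, 0), each = 64 * 64), c(64, 64, 3)))
  chr <- split_channels(pure_red)
  expect_true(all(chr$red == 255) && all(chr$green == 0) && all(chr$blue == 0))

  # generator paints the fundus field in red-dominant hues
  ch2 <- split_channels(g$image)
  expect_gt(mean(ch2$red[g$roi]), mean(ch2$blue[g$roi]))
  expect_error(split_channels(array(0, c(64, 64, 2))), class = "InvalidImage")
})

test_that("ROI extraction recovers the fundus disc and is deterministic", {
  for (s in c(3L, 7L, 21L)) {
    g <- generate_fundus_image(quick_params(size = 128L, seed = s,
                                            disc_radius_frac = 0.38))
    roi <- establish_roi(g$image)
    expect_identical(attr(roi, "kind"), "roi")
    true_area <- pi * g$disc$r^2
    expect_lt(abs(sum(roi) - true_area) / true_area, 0.02)
    expect_gte(jaccard(roi, g$roi), 0.95)
  }
  g <- generate_fundus_image(quick_params(size = 128L))
  expect_identical(which(establish_roi(g$image)), which(establish_roi(g$image)))
})

test_that("ROI screens reject degenerate inputs and off-center blobs", {
  black <- fundus_image(array(0, c(96, 96, 3)))
  expect_error(establish_roi(black), class = "NoROIFound")

  # true centered disc plus a bright corner blob: the blob fails the
  # location/area screens and only the disc is returned
  s <- 128
  img <- array(10, c(s, s, 3))
  ii <- matrix(rep(1:s, s), s, s); jj <- t(ii)
  disc <- (ii - 64.5)^2 + (jj - 64.5)^2 <= 45^2
  for (k in 1:3) {
    ch <- img[, , k]
    ch[disc] <- c(210, 100, 50)[k]
    ch[1:14, 1:14] <- 250
    img[, , k] <- ch
  }
  roi <- establish_roi(fundus_image(img))
  expect_false(roi[7, 7])
  expect_gte(jaccard(roi, disc), 0.95)
})

test_that("frequency-domain denoising is a pass band with Gaussian roll-off", {
  cfg <- preprocess_config(lowpass_cutoff = 0.4)
  flat <- fundus_image(array(117, c(64, 64, 3)))
  expect_equal(unclass(denoise(flat, cfg)), unclass(flat))

  # pass-through limit on a smooth (noise-free) image
  g0 <- generate_fundus_image(quick_params(noise_sigma = 0))
  out <- denoise(g0$image, preprocess_config(lowpass_cutoff = 1))
  expect_lte(max(abs(unclass(out) - unclass(g0$image))), 1)

  # high-band spectral energy strictly shrinks on noisy inputs
  high_energy <- function(img, cutoff) {
    h <- dim(img)[1]; w <- dim(img)[2]
    fr <- fundtess:::fft_freq(h) / 0.5
    fc <- fundtess:::fft_freq(w) / 0.5
    hi <- sqrt(outer(fr^2, fc^2, "+")) > cutoff
    sum(vapply(1:3, function(k) sum(Mod(stats::fft(img[, , k]))[hi]^2), 0))
  }
  for (s in 1:5) {
    g <- generate_fundus_image(quick_params(seed = s, noise_sigma = 10))
    den <- denoise(g$image, cfg)
    expect_lt(high_energy(unclass(den), 0.4), high_energy(unclass(g$image), 0.4))
  }
  expect_error(denoise(g0$image, preprocess_config(lowpass_cutoff = 1.2)),
               class = "InvalidConfig")
})

test_that("lightness normalization hits the target mean L and is idempotent", {
  cfg <- preprocess_config(target_L = 60)
  g <- generate_fundus_image(quick_params())
  n1 <- normalize_lightness(g$image, cfg, g$roi)
  meanL <- function(img, roi) mean(fundtess:::img_to_lab(img)[as.vector(roi), 1])
  expect_lt(abs(meanL(n1, g$roi) - 60), 0.5)
  n2 <- normalize_lightness(n1, cfg, g$roi)
  expect_lte(max(abs(unclass(n2) - unclass(n1))), 1)

  # brightness-shifted renderings converge to the same lightness
  gd <- generate_fundus_image(quick_params(brightness_gain = 0.7))
  gb <- generate_fundus_image(quick_params(brightness_gain = 1.3))
  nd <- normalize_lightness(gd$image, cfg, gd$roi)
  nb <- normalize_lightness(gb$image, cfg, gb$roi)
  expect_lt(abs(meanL(nd, gd$roi) - meanL(nb, gb$roi)), 1.0)
})

test_that("CLAHE enhancement is masked, entropy-preserving and guarded", {
  g <- generate_fundus_image(quick_params(brightness_gain = 0.85, noise_sigma = 4))
  enh <- enhance(g$image, g$roi)
  # outside the ROI: bit-identical
  out <- !g$roi
  for (k in 1:3)
    expect_identical(unclass(enh)[, , k][out], unclass(g$image)[, , k][out])
  # within the ROI the lightness histogram does not lose entropy
  entr <- function(img) {
    L <- round(fundtess:::img_to_lab(img)[as.vector(g$roi), 1])
    p <- tabulate(L + 1, 101); p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }
  expect_gte(entr(enh), entr(g$image) - 0.02)

  flat <- fundus_image(array(90, c(96, 96, 3)))
  roi <- binary_mask(matrix(TRUE, 96, 96), "roi")
  expect_equal(unclass(enhance(flat, roi)), unclass(flat))
  expect_error(enhance(flat, binary_mask(matrix(FALSE, 96, 96), "roi")),
               class = "EmptyROI")
})

test_that("preprocess composes the stages in order with unchanged dimensions", {
  cfg <- preprocess_config()
  g <- generate_fundus_image(quick_params(size = 128L))
  pp <- preprocess(g$image, cfg)
  den <- denoise(g$image, cfg)
  roi <- establish_roi(den, cfg)
  manual <- enhance(normalize_lightness(den, cfg, roi), roi, cfg)
  expect_equal(unclass(pp$enhanced), unclass(manual))
  expect_identical(dim(pp$enhanced), dim(g$image))
  expect_identical(dim(pp$roi), dim(g$image)[1:2])
})
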