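test_that("the generator is byte-deterministic and hits its density target", {
  p <- quick_params(size = 128L, rho_target = 0.2, seed = 7L)
  g1 <- generate_fundus_image(p)
  g2 <- generate_fundus_image(p)
  expect_identical(unclass(g1$image), unclass(g2$image))
  expect_identical(which(g1$truth), which(g2$truth))

  expect_gte(g1$achieved_rho, 0.19)
  expect_lte(g1$achieved_rho, 0.21)
  expect_true(all(which(g1$truth) %in% which(g1$roi)))  # truth inside the disc

  g0 <- generate_fundus_image(quick_params(rho_target = 0))
  expect_identical(sum(g0$truth), 0L)
})

test_that("generated ground truth reproduces through compute_ftd exactly", {
  g <- generate_fundus_image(quick_params(size = 128L, rho_target = 0.27))
  expect_equal(compute_ftd(g$truth, g$roi)$rho, g$achieved_rho)
})

test_that("dataset generation writes a consistent, reproducible manifest", {
  dir1 <- withr::local_tempdir()
  man <- generate_fundus_dataset(5, file.path(dir1, "a"), quick_params(),
                                 rho_range = c(0.1, 0.3), seed = 9)
  expect_identical(nrow(man), 5L)
  for (i in 1:5) {
    expect_true(file.exists(file.path(dir1, "a", man$image[i])))
    mask <- load_corrected_mask(file.path(dir1, "a", man$mask[i]))
    roi <- png::readPNG(file.path(dir1, "a", man$roi[i])) == 1
    expect_equal(sum(mask) / sum(roi), man$achieved_rho[i])
    expect_lte(abs(man$achieved_rho[i] - man$rho_target[i]), 0.01)
  }
  man2 <- generate_fundus_dataset(5, file.path(dir1, "b"), quick_params(),
                                  rho_range = c(0.1, 0.3), seed = 9)
  expect_equal(man, man2)
  expect_error(generate_fundus_dataset(2, file.path(dir1, "a")),
               class = "RefusingOverwrite")
})

test_that("parameter validation guards the generator", {
  expect_error(synth_image_params(rho_target = 0.7), class = "InvalidConfig")
  expect_error(synth_image_params(disc_radius_frac = 0.6), class = "InvalidConfig")
  expect_error(synth_image_params(size = 32), class = "InvalidConfig")
})
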