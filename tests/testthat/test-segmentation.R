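make_pairs <- function(n, size = 64L, seed = 1L) {
  lapply(seq_len(n), function(i) {
    g <- generate_fundus_image(synth_image_params(
      size = size, rho_target = 0.1 + 0.02 * i, seed = seed + i))
    list(image = g$image, mask = g$truth, roi = g$roi)
  })
}

test_that("threshold segmentation nests and validates", {
  map <- structure(matrix(0.6, 8, 8), class = "confidence_map")
  expect_true(all(threshold_confidence(map, 0.5)))
  set.seed(3)
  rmap <- structure(matrix(runif(400), 20, 20), class = "confidence_map")
  m3 <- threshold_confidence(rmap, 0.3)
  m7 <- threshold_confidence(rmap, 0.7)
  expect_true(all(which(m7) %in% which(m3)))
  bin <- structure(matrix(sample(0:1, 64, TRUE), 8, 8), class = "confidence_map")
  expect_equal(unname(which(threshold_confidence(bin, 0.5))), which(bin == 1))
  expect_error(threshold_confidence(rmap, 0), class = "InvalidThreshold")
  expect_error(threshold_confidence(rmap, 1.2), class = "InvalidThreshold")
})

test_that("training is deterministic and reduces the loss", {
  pairs <- make_pairs(8)
  spec <- seg_model_spec(input_size = 64L, epochs = 3L, seed = 11L)
  m1 <- seg_train(pairs, spec)
  m2 <- seg_train(pairs, spec)
  expect_identical(m1$epoch_loss, m2$epoch_loss)
  expect_lt(utils::tail(m1$epoch_loss, 1), m1$epoch_loss[1])

  expect_error(seg_train(list(), spec), class = "NoTrainingData")
  bad <- pairs
  bad[[1]]$mask <- binary_mask(matrix(FALSE, 32, 32), "choroid")
  expect_error(seg_train(bad, spec), class = "MaskShapeMismatch")
})

test_that("the network can overfit a single image", {
  g <- generate_fundus_image(synth_image_params(size = 64L, rho_target = 0.25,
                                                seed = 2L))
  spec <- seg_model_spec(input_size = 64L, epochs = 120L, batch_size = 1L,
                         seed = 5L)
  m <- seg_train(list(list(image = g$image, mask = g$truth)), spec)
  pred <- threshold_confidence(predict_confidence(m, g$image), 0.5)
  expect_gte(dice(pred, g$truth), 0.90)
})

test_that("confidence maps are in range, deterministic, and survive IO", {
  pairs <- make_pairs(4)
  m <- seg_train(pairs, seg_model_spec(input_size = 64L, epochs = 2L))
  map1 <- predict_confidence(m, pairs[[1]]$image)
  map2 <- predict_confidence(m, pairs[[1]]$image)
  expect_identical(unclass(map1), unclass(map2))
  expect_gte(min(map1), 0)
  expect_lte(max(map1), 1)
  expect_identical(dim(map1), dim(pairs[[1]]$image)[1:2])

  path <- withr::local_tempfile(fileext = ".rds")
  save_seg_model(m, path)
  map3 <- predict_confidence(load_seg_model(path), pairs[[1]]$image)
  expect_identical(unclass(map1), unclass(map3))

  expect_error(predict_confidence(structure(list(), class = "seg_model"),
                                  pairs[[1]]$image),
               class = "ModelNotTrained")
})

test_that("a resnet-style encoder trains through its residual paths", {
  pairs <- make_pairs(3)
  spec <- seg_model_spec(encoder = "resnet18", input_size = 64L, epochs = 2L,
                         batch_size = 1L, seed = 4L)
  m <- seg_train(pairs, spec)
  expect_lt(m$epoch_loss[2], m$epoch_loss[1])
  map <- predict_confidence(m, pairs[[1]]$image)
  expect_true(min(map) >= 0 && max(map) <= 1)
})
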