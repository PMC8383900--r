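#' Segmentation model specification
#'
#' Hyperparameters of the encoder-decoder segmentation network that maps an
#' enhanced fundus image to a per-pixel exposed-choroid confidence map.
#' Two encoders are available: `"tiny"` (a four-convolution encoder-decoder
#' that trains in minutes on one CPU and is used throughout the test
#' benchmarks) and `"resnet18"` (an 18-convolution residual encoder with a
#' deconvolution-style decoder, the full-scale layout).
#'
#' @param encoder `"tiny"` or `"resnet18"`.
#' @param input_size square side the image is resized to for the network.
#' @param epochs,batch_size,learning_rate training schedule (Adam optimizer,
#'   per-pixel binary cross-entropy loss).
#' @param seed seed for weight initialization and batch shuffling; identical
#'   spec, data and seed reproduce identical losses.
#' @param confidence_threshold default threshold applied to confidence maps.
#' @return A `seg_model_spec` list.
#' @export
seg_model_spec <- function(encoder = c("tiny", "resnet18"), input_size = 128L,
                           epochs = 10L, batch_size = 2L,
                           learning_rate = 0.01, seed = 1L,
                           confidence_threshold = 0.5) {
  encoder <- match.arg(encoder)
  ft_assert(input_size >= 16 && input_size %% 4 == 0, "InvalidConfig",
            "input_size must be a multiple of 4 and at least 16")
  ft_assert(epochs >= 1 && batch_size >= 1, "InvalidConfig",
            "epochs and batch_size must be positive")
  ft_assert(learning_rate > 0, "InvalidConfig", "learning_rate must be positive")
  ft_assert(confidence_threshold > 0 && confidence_threshold < 1,
            "InvalidConfig", "confidence_threshold must be in (0, 1)")
  structure(list(encoder = encoder, input_size = as.integer(input_size),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 confidence_threshold = confidence_threshold),
            class = "seg_model_spec")
}

# ---- minimal convolutional network engine ---------------------------------
# 3x3 same-padding convolutions via im2col + BLAS matrix products, average
# 2x down-pooling, nearest 2x up-sampling and residual additions. Gather
# index matrices are cached per (H, W, C).

.ft_im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, c) {
  key <- paste(h, w, c, sep = "x")
  got <- .ft_im2col_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L; wp <- w + 2L
  ii <- rep(seq_len(h), w); jj <- rep(seq_len(w), each = h)
  base <- matrix(0L, h * w, 9L)
  o <- 0L
  for (dj in -1:1) for (di in -1:1) {
    o <- o + 1L
    base[, o] <- (ii + 1L + di) + (jj + dj) * hp
  }
  big <- matrix(0L, h * w, 9L * c)
  for (ch in seq_len(c))
    big[, ((ch - 1L) * 9L + 1L):(ch * 9L)] <- base + (ch - 1L) * hp * wp
  .ft_im2col_cache[[key]] <- big
  big
}

conv_forward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  idx <- im2col_index(h, w, cin)
  xc <- matrix(xp[idx], h * w, 9L * cin)
  y <- xc %*% W
  y <- y + matrix(b, h * w, length(b), byrow = TRUE)
  list(y = array(y, c(h, w, ncol(W))), xc = xc)
}

conv_backward <- function(dy, cache, W, dims) {
  h <- dims[1]; w <- dims[2]; cin <- dims[3]
  dym <- matrix(dy, h * w, dim(dy)[3])
  dW <- crossprod(cache$xc, dym)
  db <- colSums(dym)
  dxc <- dym %*% t(W)
  idx <- im2col_index(h, w, cin)
  dxp <- numeric((h + 2L) * (w + 2L) * cin)
  for (col in seq_len(ncol(idx))) {
    id <- idx[, col]
    dxp[id] <- dxp[id] + dxc[, col]
  }
  dxp <- array(dxp, c(h + 2L, w + 2L, cin))
  list(dx = dxp[2:(h + 1), 2:(w + 1), , drop = FALSE], dW = dW, db = db)
}

pool2_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  io <- seq(1L, h, 2L); jo <- seq(1L, w, 2L)
  (x[io, jo, , drop = FALSE] + x[io + 1L, jo, , drop = FALSE] +
     x[io, jo + 1L, , drop = FALSE] + x[io + 1L, jo + 1L, , drop = FALSE]) / 4
}

pool2_backward <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE] / 4
}

up2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

up2_backward <- function(dy) {
  d <- dim(dy); h <- d[1]; w <- d[2]
  io <- seq(1L, h, 2L); jo <- seq(1L, w, 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

conv_param <- function(cin, cout) {
  list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))), 9L * cin, cout),
       b = numeric(cout))
}

# Architectures are flat op lists; "conv" ops carry an index into the shared
# parameter list, "save"/"add" implement residual skips (with an optional
# projection conv on the skip path).
arch_tiny <- function() {
  list(ops = list(list(op = "conv", p = 1L), list(op = "relu"),
                  list(op = "pool2"),
                  list(op = "conv", p = 2L), list(op = "relu"),
                  list(op = "conv", p = 3L), list(op = "relu"),
                  list(op = "up2"),
                  list(op = "conv", p = 4L)),
       shapes = list(c(3L, 8L), c(8L, 16L), c(16L, 16L), c(16L, 1L)))
}

arch_resnet18 <- function(width = 16L) {
  w1 <- width; w2 <- 2L * width; w3 <- 4L * width
  shapes <- list()
  ops <- list()
  pid <- 0L
  conv <- function(cin, cout) {
    pid <<- pid + 1L
    shapes[[pid]] <<- c(cin, cout)
    list(op = "conv", p = pid)
  }
  block <- function(cin, cout) {
    proj <- if (cin != cout) conv(cin, cout) else NULL
    c(list(list(op = "save", proj = proj)),
      list(conv(cin, cout), list(op = "relu"), conv(cout, cout)),
      list(list(op = "add")), list(list(op = "relu")))
  }
  ops <- c(list(conv(3L, w1), list(op = "relu")),
           block(w1, w1), block(w1, w1),
           list(list(op = "pool2")),
           block(w1, w2), block(w2, w2),
           list(list(op = "pool2")),
           block(w2, w3), block(w3, w3),
           list(list(op = "up2")), list(conv(w3, w2), list(op = "relu")),
           list(list(op = "up2")), list(conv(w2, w1), list(op = "relu")),
           list(conv(w1, 1L)))
  list(ops = ops, shapes = shapes)
}

net_init <- function(encoder) {
  arch <- if (encoder == "tiny") arch_tiny() else arch_resnet18()
  params <- lapply(arch$shapes, function(s) conv_param(s[1], s[2]))
  list(arch = arch, params = params)
}

net_forward <- function(net, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$arch$ops)) else NULL
  stack <- list()
  for (k in seq_along(net$arch$ops)) {
    o <- net$arch$ops[[k]]
    if (o$op == "conv") {
      pr <- net$params[[o$p]]
      cf <- conv_forward(x, pr$W, pr$b)
      if (keep_cache) caches[[k]] <- list(xc = cf$xc, dims = dim(x))
      x <- cf$y
    } else if (o$op == "relu") {
      if (keep_cache) caches[[k]] <- x > 0
      x <- pmax(x, 0)
    } else if (o$op == "pool2") {
      x <- pool2_forward(x)
    } else if (o$op == "up2") {
      x <- up2_forward(x)
    } else if (o$op == "save") {
      skip <- x
      skip_cache <- NULL
      if (!is.null(o$proj)) {
        pr <- net$params[[o$proj$p]]
        cf <- conv_forward(skip, pr$W, pr$b)
        skip_cache <- list(xc = cf$xc, dims = dim(skip))
        skip <- cf$y
      }
      stack[[length(stack) + 1L]] <- skip
      if (keep_cache) caches[[k]] <- skip_cache
    } else if (o$op == "add") {
      x <- x + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    }
  }
  list(y = x, caches = caches)
}

net_backward <- function(net, fw, dy) {
  grads <- lapply(net$params, function(p) list(W = p$W * 0, b = p$b * 0))
  ops <- net$arch$ops
  skip_grads <- list()
  for (k in rev(seq_along(ops))) {
    o <- ops[[k]]
    if (o$op == "conv") {
      ca <- fw$caches[[k]]
      bk <- conv_backward(dy, ca, net$params[[o$p]]$W, ca$dims)
      grads[[o$p]]$W <- grads[[o$p]]$W + bk$dW
      grads[[o$p]]$b <- grads[[o$p]]$b + bk$db
      dy <- bk$dx
    } else if (o$op == "relu") {
      dy <- dy * fw$caches[[k]]
    } else if (o$op == "pool2") {
      dy <- pool2_backward(dy)
    } else if (o$op == "up2") {
      dy <- up2_backward(dy)
    } else if (o$op == "add") {
      skip_grads[[length(skip_grads) + 1L]] <- dy
    } else if (o$op == "save") {
      ds <- skip_grads[[length(skip_grads)]]
      skip_grads[[length(skip_grads)]] <- NULL
      if (!is.null(o$proj)) {
        ca <- fw$caches[[k]]
        bk <- conv_backward(ds, ca, net$params[[o$proj$p]]$W, ca$dims)
        grads[[o$proj$p]]$W <- grads[[o$proj$p]]$W + bk$dW
        grads[[o$proj$p]]$b <- grads[[o$proj$p]]$b + bk$db
        ds <- bk$dx
      }
      dy <- dy + ds
    }
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# stable mean binary cross-entropy of logits z against labels y in {0,1}
bce_loss <- function(z, y) mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))

prep_pair <- function(img, mask, input_size) {
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  check_same_dim(img, mask)
  x <- unclass(img) / 255
  y <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (dim(x)[1] != input_size || dim(x)[2] != input_size) {
    x <- EBImage::imageData(EBImage::resize(EBImage::Image(x, colormode = "Color"),
                                            input_size, input_size))
    y <- EBImage::imageData(EBImage::resize(EBImage::Image(y), input_size, input_size,
                                            filter = "none"))
  }
  list(x = x, y = array(y, c(input_size, input_size, 1L)))
}

#' Train the exposed-choroid segmentation network
#'
#' Trains the encoder-decoder on (enhanced image, choroid mask) pairs with
#' per-pixel binary cross-entropy and the Adam optimizer. Training is fully
#' deterministic given the spec seed: reported per-epoch losses reproduce
#' exactly for identical data, spec and seed.
#'
#' @param pairs list of `list(image =, mask =)` pairs; masks must match their
#'   image dimensions.
#' @param spec a [seg_model_spec()]
#' @param quiet suppress the per-epoch loss message.
#' @return A `seg_model` with the trained parameters, the spec, the per-epoch
#'   loss trace and a digest of the training data.
#' @export
seg_train <- function(pairs, spec = seg_model_spec(), quiet = TRUE) {
  if (length(pairs) < 1) ft_stop("NoTrainingData", "the training set is empty")
  data <- lapply(pairs, function(p) {
    if (is.null(p$image) || is.null(p$mask))
      ft_stop("NoTrainingData", "each pair needs an image and a mask")
    prep_pair(p$image, p$mask, spec$input_size)
  })
  digest <- sprintf("n=%d;px=%.6f", length(data),
                    sum(vapply(data, function(d) sum(d$x) + sum(d$y), 0)))
  with_local_seed(spec$seed, {
    net <- net_init(spec$encoder)
    mom <- lapply(net$params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                               mb = p$b * 0, vb = p$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    n <- length(data)
    epoch_loss <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(n)
      bs <- spec$batch_size
      for (b0 in seq(1, n, bs)) {
        idx <- ord[b0:min(b0 + bs - 1, n)]
        acc <- NULL
        for (i in idx) {
          d <- data[[i]]
          fw <- net_forward(net, d$x, keep_cache = TRUE)
          z <- fw$y
          losses[match(i, ord)] <- bce_loss(z, d$y)
          dz <- (sigmoid(z) - d$y) / length(z)
          g <- net_backward(net, fw, dz)
          acc <- if (is.null(acc)) g else
            mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   acc, g, SIMPLIFY = FALSE)
        }
        t <- t + 1
        corr <- sqrt(1 - b2^t) / (1 - b1^t)
        for (k in seq_along(net$params)) {
          gW <- acc[[k]]$W / length(idx); gb <- acc[[k]]$b / length(idx)
          mom[[k]]$mW <- b1 * mom[[k]]$mW + (1 - b1) * gW
          mom[[k]]$vW <- b2 * mom[[k]]$vW + (1 - b2) * gW^2
          mom[[k]]$mb <- b1 * mom[[k]]$mb + (1 - b1) * gb
          mom[[k]]$vb <- b2 * mom[[k]]$vb + (1 - b2) * gb^2
          net$params[[k]]$W <- net$params[[k]]$W -
            spec$learning_rate * corr * mom[[k]]$mW / (sqrt(mom[[k]]$vW) + eps)
          net$params[[k]]$b <- net$params[[k]]$b -
            spec$learning_rate * corr * mom[[k]]$mb / (sqrt(mom[[k]]$vb) + eps)
        }
      }
      epoch_loss[ep] <- mean(losses)
      if (!quiet) message(sprintf("epoch %d/%d loss %.5f", ep, spec$epochs, epoch_loss[ep]))
    }
    structure(list(spec = spec, arch = net$arch, params = net$params,
                   epoch_loss = epoch_loss, data_digest = digest),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s, input %d, %d epochs, final loss %.5f>\n",
              x$spec$encoder, x$spec$input_size, length(x$epoch_loss),
              utils::tail(x$epoch_loss, 1)))
  invisible(x)
}

#' Per-pixel exposed-choroid confidence map
#'
#' Applies the trained network to an image (resized to the training input
#' size if needed) and returns the sigmoid confidence of each pixel belonging
#' to exposed choroid, mapped back to the original resolution by
#' nearest-neighbor upsampling. Inference is deterministic.
#'
#' @param model a trained `seg_model`
#' @param img a [fundus_image()], preprocessed the same way as the training
#'   images.
#' @return A `confidence_map`: an `H x W` matrix with values in `[0, 1]`.
#' @export
predict_confidence <- function(model, img) {
  if (!inherits(model, "seg_model") || is.null(model$params))
    ft_stop("ModelNotTrained", "predict_confidence needs a trained seg_model")
  if (!inherits(img, "fundus_image")) img <- fundus_image(img)
  h <- img_height(img); w <- img_width(img)
  d <- prep_pair(img, matrix(FALSE, h, w), model$spec$input_size)
  z <- net_forward(list(arch = model$arch, params = model$params), d$x)$y
  conf <- sigmoid(z[, , 1])
  if (nrow(conf) != h || ncol(conf) != w) {
    ri <- pmin(pmax(round(seq(1, nrow(conf), length.out = h)), 1), nrow(conf))
    rj <- pmin(pmax(round(seq(1, ncol(conf), length.out = w)), 1), ncol(conf))
    conf <- conf[ri, rj]
  }
  structure(conf, class = "confidence_map")
}

#' Threshold a confidence map into a choroid mask
#'
#' Pixels with confidence at or above `t` become exposed-choroid pixels;
#' thresholds nest (a higher threshold yields a subset).
#'
#' @param map a `confidence_map` (or plain matrix of values in `[0, 1]`)
#' @param t threshold in `(0, 1)`
#' @return A [binary_mask()] of kind `"choroid"`.
#' @export
threshold_confidence <- function(map, t = 0.5) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t <= 0 || t >= 1)
    ft_stop("InvalidThreshold", "threshold must be a number in (0, 1)")
  binary_mask(unclass(map) >= t, kind = "choroid")
}

#' Save / load a segmentation model
#'
#' The checkpoint is a single serialized file accompanied by a JSON sidecar
#' recording the spec and the training-data digest. A save/load round trip
#' reproduces bit-identical confidence maps.
#'
#' @param model a `seg_model`
#' @param path checkpoint path (the sidecar is written to `<path>.json`)
#' @return `path`, invisibly (for `save_seg_model`); the model (for
#'   `load_seg_model`).
#' @export
save_seg_model <- function(model, path) {
  saveRDS(model, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(spec = unclass(model$spec), data_digest = model$data_digest,
                 epoch_loss = model$epoch_loss)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "seg_model")) ft_stop("ModelNotTrained", "not a seg_model checkpoint")
  m
}

#' End-to-end synthetic segmentation benchmark
#'
#' Generates a seeded synthetic dataset, preprocesses every image, trains the
#' tiny-encoder network on the first `n_train` enhanced images with their
#' ground-truth masks, and evaluates the pooled within-ROI pixel confusion on
#' the held-out remainder at the given threshold. This is the package's
#' reference evaluation of the segmentation stage.
#'
#' @param n total number of images; the last `n - n_train` are held out.
#' @param n_train number of training images.
#' @param size image side in pixels.
#' @param epochs training epochs.
#' @param seed master seed for data generation (the model seed is derived).
#' @param threshold confidence threshold for the final masks.
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `mean_dice`,
#'   the pooled `counts`, `n_eval_px`, and the trained `model`.
#' @export
seg_benchmark <- function(n = 240L, n_train = 200L, size = 128L, epochs = 10L,
                          seed = 1L, threshold = 0.5) {
  ft_assert(n_train < n, "InvalidConfig", "need held-out images: n_train < n")
  base <- synth_image_params(size = size)
  draws <- synth_param_draws(n, base, rho_range = c(0.05, 0.35), seed = seed)
  cfg <- preprocess_config()
  prepped <- lapply(draws, function(p) {
    g <- generate_fundus_image(p)
    pp <- preprocess(g$image, cfg)
    list(image = pp$enhanced, roi = pp$roi, truth = g$truth)
  })
  spec <- seg_model_spec(encoder = "tiny", input_size = size, epochs = epochs,
                         seed = seed %% 1000L + 7L)
  model <- seg_train(lapply(prepped[seq_len(n_train)],
                            function(d) list(image = d$image, mask = d$truth)),
                     spec)
  tot <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  dices <- numeric(n - n_train)
  for (i in seq(n_train + 1L, n)) {
    d <- prepped[[i]]
    pred <- threshold_confidence(predict_confidence(model, d$image), threshold)
    cc <- confusion_counts(pred, d$truth, d$roi)
    tot <- list(tp = tot$tp + cc$tp, tn = tot$tn + cc$tn,
                fp = tot$fp + cc$fp, fn = tot$fn + cc$fn)
    dices[i - n_train] <- dice(pred & d$roi, d$truth)
  }
  m <- seg_metrics(structure(tot, class = "confusion_counts"))
  c(m, list(mean_dice = mean(dices), counts = tot,
            n_eval_px = tot$tp + tot$tn + tot$fp + tot$fn, model = model))
}
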