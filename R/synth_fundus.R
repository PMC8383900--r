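#' Synthetic fundus image parameters
#'
#' The generator emulates the aspects of a tessellated 45-degree fundus
#' photograph that the measurement pipeline depends on: a bright, red-dominant
#' circular fundus field on a dark camera background; exposed choroid rendered
#' as branching curvilinear bands of a more saturated red/orange hue (choroidal
#' vessels seen through thinned overlying layers); an optional darker retinal
#' vessel tree that occludes the choroid and is excluded from the ground
#' truth; mild radial shading; and Gaussian pixel noise.
#'
#' @param size image side in pixels (square image).
#' @param disc_radius_frac fundus-field radius as a fraction of `size`, in
#'   `(0.25, 0.48)`.
#' @param rho_target ground-truth tessellated density in `[0, 0.5]`; the band
#'   area is grown stamp by stamp and trimmed so the achieved density is
#'   within 0.01 of this target.
#' @param n_choroid_vessels number of seed walks per growth round.
#' @param vessel_width_px length-2 range of band widths in pixels.
#' @param retinal_vessel_tree draw a dark retinal vessel tree (excluded from
#'   the truth mask).
#' @param brightness_gain global multiplicative brightness factor.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise in
#'   intensity levels.
#' @param seed RNG seed; identical parameters and seed reproduce identical
#'   image bytes.
#' @return A `synth_image_params` list.
#' @export
synth_image_params <- function(size = 128L, disc_radius_frac = 0.4,
                               rho_target = 0.2, n_choroid_vessels = 12L,
                               vessel_width_px = c(2, 5),
                               retinal_vessel_tree = TRUE,
                               brightness_gain = 1, noise_sigma = 8,
                               seed = 1L) {
  ft_assert(size >= 64, "InvalidConfig", "size must be at least 64")
  ft_assert(disc_radius_frac > 0.25 && disc_radius_frac < 0.48,
            "InvalidConfig", "disc_radius_frac must be in (0.25, 0.48)")
  ft_assert(rho_target >= 0 && rho_target <= 0.5,
            "InvalidConfig", "rho_target must be in [0, 0.5]")
  ft_assert(n_choroid_vessels >= 1, "InvalidConfig", "n_choroid_vessels must be positive")
  ft_assert(length(vessel_width_px) == 2 && all(vessel_width_px >= 1) &&
              vessel_width_px[1] <= vessel_width_px[2],
            "InvalidConfig", "vessel_width_px must be an increasing length-2 range")
  ft_assert(brightness_gain > 0, "InvalidConfig", "brightness_gain must be positive")
  ft_assert(noise_sigma >= 0, "InvalidConfig", "noise_sigma must be non-negative")
  structure(list(size = as.integer(size), disc_radius_frac = disc_radius_frac,
                 rho_target = rho_target,
                 n_choroid_vessels = as.integer(n_choroid_vessels),
                 vessel_width_px = vessel_width_px,
                 retinal_vessel_tree = isTRUE(retinal_vessel_tree),
                 brightness_gain = brightness_gain, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_image_params")
}

# disc-shaped stamp offsets for a band of the given width
stamp_offsets <- function(width) {
  r <- max(width / 2, 0.6)
  ir <- ceiling(r)
  g <- expand.grid(di = -ir:ir, dj = -ir:ir)
  g <- g[g$di^2 + g$dj^2 <= r^2, ]
  list(di = g$di, dj = g$dj)
}

# Random smooth walk rasterized as successive stamps; returns an ordered list
# of linear pixel indices (with repeats) restricted to the frame.
walk_stamps <- function(s, start, heading, n_steps, off) {
  i <- start[1]; j <- start[2]
  turn <- stats::rnorm(n_steps, 0, 0.18)
  out <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    heading <- heading + turn[k]
    i <- i + sin(heading); j <- j + cos(heading)
    ii <- round(i) + off$di; jj <- round(j) + off$dj
    ok <- ii >= 1 & ii <= s & jj >= 1 & jj <= s
    out[[k]] <- ii[ok] + (jj[ok] - 1L) * s
  }
  out
}

#' Generate one synthetic fundus image with ground truth
#'
#' Bands are added stamp by stamp while counting only pixels that are inside
#' the fundus disc and not occluded by the retinal vessel tree; growth stops
#' the moment the target pixel count is reached and the final stamp is
#' trimmed, so the achieved density matches `rho_target` to within one pixel.
#'
#' @param p a [synth_image_params()]
#' @return A list: `image` ([fundus_image()]), `truth` (choroid
#'   [binary_mask()]), `roi` (disc [binary_mask()]), `achieved_rho`,
#'   `disc` (list with `cx`, `cy`, `r`), and `params`.
#' @export
generate_fundus_image <- function(p) {
  if (!inherits(p, "synth_image_params")) p <- do.call(synth_image_params, p)
  with_local_seed(p$seed, {
    s <- p$size
    cx <- (s + 1) / 2; cy <- (s + 1) / 2
    r <- p$disc_radius_frac * s
    ii <- matrix(rep(seq_len(s), s), s, s)
    jj <- t(ii)
    d2 <- (ii - cx)^2 + (jj - cy)^2
    disc <- d2 <= r^2
    disc_area <- sum(disc)

    # retinal vessel tree: dark walks radiating from a nasal origin
    vessel <- matrix(FALSE, s, s)
    if (p$retinal_vessel_tree) {
      org <- c(cx, cy + 0.45 * r)
      n_main <- 5L
      for (v in seq_len(n_main)) {
        ang <- stats::runif(1, 0, 2 * pi)
        offv <- stamp_offsets(stats::runif(1, 1.5, 2.5))
        stamps <- walk_stamps(s, org + stats::rnorm(2, 0, 2), ang,
                              n_steps = round(1.8 * r), offv)
        for (st in stamps) vessel[st] <- TRUE
      }
      vessel <- vessel & disc
    }

    # choroid bands grown to the target density
    band <- matrix(FALSE, s, s)
    target_px <- round(p$rho_target * disc_area)
    countable <- disc & !vessel
    if (target_px > sum(countable))
      ft_stop("DensityUnreachable",
              "rho_target exceeds the countable disc area under the vessel tree")
    cur <- 0L
    rounds <- 0L
    while (cur < target_px) {
      rounds <- rounds + 1L
      if (rounds > 400L)
        ft_stop("DensityUnreachable", "band growth failed to reach rho_target")
      for (v in seq_len(p$n_choroid_vessels)) {
        if (cur >= target_px) break
        ang0 <- stats::runif(1, 0, 2 * pi)
        rr <- r * sqrt(stats::runif(1, 0.05, 0.95))
        start <- c(cx + rr * sin(ang0), cy + rr * cos(ang0))
        wdt <- stats::runif(1, p$vessel_width_px[1], p$vessel_width_px[2])
        offb <- stamp_offsets(wdt)
        stamps <- walk_stamps(s, start, stats::runif(1, 0, 2 * pi),
                              n_steps = round(stats::runif(1, 0.6, 1.6) * r), offb)
        for (st in stamps) {
          new <- st[countable[st] & !band[st]]
          if (!length(new)) next
          new <- unique(new)
          if (cur + length(new) > target_px)
            new <- new[seq_len(target_px - cur)]  # trim the closing stamp
          band[new] <- TRUE
          cur <- cur + length(new)
          if (cur >= target_px) break
        }
      }
    }
    truth <- band & countable

    # compose the image: background, shaded retina, bands, vessels
    retina <- c(205, 96, 46) + stats::rnorm(3, 0, 4)
    choroid <- c(238, 66, 34) + stats::rnorm(3, 0, 4)
    dark_vessel <- c(80, 30, 22)
    backgr <- c(18, 14, 12)
    shade <- 1 - 0.12 * pmin(d2 / r^2, 1)
    img <- array(0, c(s, s, 3))
    for (k in 1:3) {
      ch <- matrix(backgr[k], s, s)
      ch[disc] <- retina[k] * shade[disc]
      ch[band & disc] <- choroid[k] * shade[band & disc]
      ch[vessel] <- dark_vessel[k] * shade[vessel]
      img[, , k] <- ch
    }
    img <- img * p$brightness_gain
    if (p$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, p$noise_sigma), dim(img))
    img <- pmin(pmax(round(img), 0), 255)

    list(image = fundus_image(img),
         truth = binary_mask(truth, kind = "choroid"),
         roi = binary_mask(disc, kind = "roi"),
         achieved_rho = sum(truth) / disc_area,
         disc = list(cx = cx, cy = cy, r = r),
         params = p)
  })
}

# deterministic per-image parameter draws for a dataset
synth_param_draws <- function(n, base, rho_range, seed) {
  with_local_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    rhos <- stats::runif(n, rho_range[1], rho_range[2])
    lapply(seq_len(n), function(i) {
      p <- unclass(base)
      p$seed <- seeds[i]
      p$rho_target <- rhos[i]
      do.call(synth_image_params, p)
    })
  })
}

#' Generate a directory of synthetic fundus images with a manifest
#'
#' Writes `img_###.png`, `mask_###.png` (ground-truth exposed choroid) and
#' `roi_###.png` triples plus `manifest.csv` recording the file names,
#' per-image seeds, target and achieved densities and disc geometry.
#'
#' @param n number of images (>= 1)
#' @param out_dir output directory; must not already contain files.
#' @param base a [synth_image_params()] template (its `seed`/`rho_target` are
#'   redrawn per image).
#' @param rho_range interval from which each image's `rho_target` is drawn
#'   uniformly.
#' @param seed master seed controlling all per-image draws.
#' @return The manifest as a data frame, invisibly.
#' @export
generate_fundus_dataset <- function(n, out_dir, base = synth_image_params(),
                                    rho_range = c(0.05, 0.35), seed = 1L) {
  ft_assert(n >= 1, "InvalidConfig", "n must be at least 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0)
    ft_stop("RefusingOverwrite", paste("output directory is not empty:", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- synth_param_draws(n, base, rho_range, seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_fundus_image(draws[[i]])
    fi <- sprintf("img_%03d.png", i)
    fm <- sprintf("mask_%03d.png", i)
    fr <- sprintf("roi_%03d.png", i)
    write_fundus(g$image, file.path(out_dir, fi))
    write_mask(g$truth, file.path(out_dir, fm))
    write_mask(g$roi, file.path(out_dir, fr))
    rows[[i]] <- data.frame(image = fi, mask = fm, roi = fr,
                            seed = draws[[i]]$seed,
                            rho_target = draws[[i]]$rho_target,
                            achieved_rho = g$achieved_rho,
                            size = draws[[i]]$size,
                            disc_radius_frac = draws[[i]]$disc_radius_frac)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
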