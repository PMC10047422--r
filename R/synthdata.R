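#' Specification of one synthetic endoscopy-like frame
#'
#' Describes a frame in one of the four quality categories used for
#' narrow-band laryngoscopy frame triage: blurred (`"B"`), informative
#' (`"I"`), specular/saliva (`"S"`) and underexposed (`"U"`). Each category
#' has a machine-checkable pixel criterion, enforced by [generate_frame()]:
#' `I` frames carry at most 10% bright specular area, `S` frames at least
#' half, `U` frames are at least 90% dark. Thresholds are operational:
#' a pixel is "bright" when its maximum channel is >= 230 and "dark" when
#' its maximum channel is < 40 (intensity units on the 0-255 scale).
#'
#' @param category one of `"B"`, `"I"`, `"S"`, `"U"`.
#' @param width,height frame size in pixels.
#' @param reflection_fraction fraction of the image area covered by bright
#'   specular blobs, in `[0, 1]`. Defaults: 0.05 for `I`, 0.6 for `S`,
#'   0 otherwise.
#' @param dark_fraction fraction of pixels below the darkness threshold,
#'   in `[0, 1]`. Default 0.95 for `U`, 0 otherwise.
#' @param blur_sigma Gaussian blur scale in pixels. Default 6 for `B`,
#'   0 otherwise.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `frame_spec`.
#' @export
#' @examples
#' spec <- frame_spec("S", 64, 64, seed = 1)
#' img <- generate_frame(spec)
#' frame_stats(img)$bright_fraction  # >= 0.5
frame_spec <- function(category, width = 128, height = 128,
                       reflection_fraction = NULL, dark_fraction = NULL,
                       blur_sigma = NULL, seed = 1) {
  .assert(length(category) == 1 && category %in% FRAME_CATEGORIES,
          "category must be one of 'I', 'B', 'S', 'U'")
  .assert(is.numeric(width) && is.numeric(height) && width >= 8 && height >= 8,
          "width and height must be >= 8 pixels")
  if (is.null(reflection_fraction))
    reflection_fraction <- switch(category, I = 0.05, S = 0.6, 0)
  if (is.null(dark_fraction))
    dark_fraction <- switch(category, U = 0.95, 0)
  if (is.null(blur_sigma))
    blur_sigma <- switch(category, B = 6, 0)
  .assert(reflection_fraction >= 0 && reflection_fraction <= 1 &&
          dark_fraction >= 0 && dark_fraction <= 1,
          "fractions must lie in [0, 1]")
  .assert(blur_sigma >= 0, "blur_sigma must be non-negative")
  if (category == "I")
    .assert(reflection_fraction <= 0.10,
            "informative frames allow at most 10% specular area")
  if (category == "S")
    .assert(reflection_fraction >= 0.50,
            "specular frames require at least half the image area covered")
  if (category == "U")
    .assert(dark_fraction >= 0.90,
            "underexposed frames require at least 90% dark pixels")
  structure(list(category = category, width = as.integer(width),
                 height = as.integer(height),
                 reflection_fraction = reflection_fraction,
                 dark_fraction = dark_fraction,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "frame_spec")
}

# Gaussian blur with the kernel capped to the image size (EBImage's
# default brush can exceed tiny test frames)
#' @noRd
.gblur_safe <- function(x, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(x)[1:2]) - 1L
  if (cap %% 2L == 0L) cap <- cap - 1L
  EBImage::gblur(x, sigma = sigma, radius = min(r, max(cap, 3L)),
                 boundary = "replicate")
}

# random curvilinear dark strokes standing in for submucosal vessels
#' @noRd
.draw_vessels <- function(h, w) {
  mask <- matrix(0, h, w)
  n_vessels <- sample(10:14, 1)
  for (v in seq_len(n_vessels)) {
    r <- runif(1, h * 0.1, h * 0.9)
    cc <- runif(1, w * 0.1, w * 0.9)
    ang <- runif(1, 0, 2 * pi)
    len <- round(runif(1, 0.4, 0.9) * w)
    thick <- sample(0:1, 1)
    for (s in seq_len(len)) {
      ang <- ang + rnorm(1, 0, 0.25)
      r <- r + sin(ang)
      cc <- cc + cos(ang)
      if (r < 1 || r > h || cc < 1 || cc > w) break
      rr <- max(1, round(r) - thick):min(h, round(r) + thick)
      ci <- max(1, round(cc) - thick):min(w, round(cc) + thick)
      mask[rr, ci] <- 1
    }
  }
  mask
}

# mucosa-like base texture: smooth band-limited background with dark
# curvilinear vessel strokes; luminance kept in mid exposure so that no
# pixel reaches the specular threshold on its own. The illumination band
# is class-conditional (see generate_frame): adequately exposed frames sit
# in a brighter, tighter band than frames captured during motion.
#' @noRd
.base_texture <- function(h, w, level_lo = 0.60, level_hi = 0.72,
                          vessel_strength = 0.25) {
  bg <- matrix(rnorm(h * w), h, w)
  bg <- .gblur_safe(bg, sigma = max(2, w / 16))
  rng <- range(bg)
  bg <- (bg - rng[1]) / max(rng[2] - rng[1], 1e-12)
  level <- runif(1, level_lo, level_hi)
  lum <- level + (bg - 0.5) * 0.18
  # smooth illumination mottling: per-frame low-frequency exposure field
  mot <- .gblur_safe(matrix(rnorm(h * w), h, w), sigma = max(4, w / 6))
  lum <- lum + 0.05 * mot / max(sd(mot), 1e-12)
  vess <- .gblur_safe(.draw_vessels(h, w), sigma = 0.8)
  lum <- lum * (1 - vessel_strength * pmin(1, pmax(0, vess)))
  lum <- lum * (level / mean(lum))   # pin global exposure to the drawn level
  img <- array(0, c(h, w, 3))
  img[, , 1] <- lum
  img[, , 2] <- lum * 0.72
  img[, , 3] <- lum * 0.70
  img
}

# paint random disks into a logical mask until it covers target_px pixels;
# overshoot is trimmed deterministically (lowest linear indices kept)
#' @noRd
.paint_disks <- function(h, w, target_px, r_lo, r_hi) {
  mask <- matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  iter <- 0
  while (sum(mask) < target_px && iter < 500) {
    iter <- iter + 1
    cy <- runif(1, 1, h)
    cx <- runif(1, 1, w)
    rad <- runif(1, r_lo, r_hi)
    mask <- mask | ((rows - cy)^2 + (cols - cx)^2 <= rad^2)
  }
  if (sum(mask) < target_px) {                # deterministic fill fallback
    need <- which(!mask)[seq_len(target_px - sum(mask))]
    mask[need] <- TRUE
  }
  extra <- sum(mask) - target_px
  if (extra > 0) {
    on <- which(mask)
    mask[on[seq_len(extra)]] <- FALSE
  }
  mask
}

#' Generate one synthetic frame
#'
#' Renders a frame obeying its category's measurable criterion: `B` is the
#' vessel texture convolved with a wide Gaussian blur; `I` is the sharp
#' texture at mid exposure with small bright reflections (at most 10% of
#' the area); `S` carries bright white or light-green blobs (maximum
#' channel >= 230) covering at least half of the pixels; `U` has at least
#' 90% of pixels with every channel below 40. Bit-identical output for the
#' same spec.
#'
#' @param spec a [frame_spec()].
#' @return an integer array `height x width x 3` with values in `[0, 255]`.
#' @export
generate_frame <- function(spec) {
  .assert(inherits(spec, "frame_spec"), "spec must be a frame_spec")
  h <- spec$height; w <- spec$width; npix <- h * w
  img <- withr::with_seed(spec$seed, {
    x <- if (spec$category == "B")
      .base_texture(h, w, level_lo = 0.40, level_hi = 0.44)
    else .base_texture(h, w, level_lo = 0.60, level_hi = 0.68)
    if (spec$category == "B") {
      for (ch in 1:3)
        x[, , ch] <- .gblur_safe(x[, , ch], sigma = max(spec$blur_sigma, 2))
      # motion integration also compresses contrast toward the local mean
      mu <- mean(x)
      x <- mu + (x - mu) * 0.6
    } else if (spec$category == "I") {
      if (spec$blur_sigma > 0)
        for (ch in 1:3)
          x[, , ch] <- .gblur_safe(x[, , ch], sigma = spec$blur_sigma)
      budget <- floor(spec$reflection_fraction * npix)
      if (budget > 0) {
        mask <- .paint_disks(h, w, budget, r_lo = 1.5, r_hi = max(2, w / 28))
        for (ch in 1:3) {
          plane <- x[, , ch]
          plane[mask] <- runif(sum(mask), 0.94, 1)
          x[, , ch] <- plane
        }
      }
    } else if (spec$category == "S") {
      # bright bubbles/blobs, each independently white or light green,
      # painted until the required area is covered
      target <- ceiling(spec$reflection_fraction * npix)
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      covered <- matrix(FALSE, h, w)
      iter <- 0
      while (sum(covered) < target && iter < 500) {
        iter <- iter + 1
        cy <- runif(1, 1, h); cx <- runif(1, 1, w)
        rad <- runif(1, w / 10, w / 4)
        disk <- (rows - cy)^2 + (cols - cx)^2 <= rad^2
        n_on <- sum(disk)
        light_green <- runif(1) < 0.5
        hi <- runif(n_on, 0.92, 1)
        lo <- runif(n_on, 0.76, 0.86)
        vals <- if (light_green) list(lo, hi, lo) else list(hi, hi, hi)
        for (ch in 1:3) {
          plane <- x[, , ch]
          plane[disk] <- vals[[ch]]
          x[, , ch] <- plane
        }
        covered <- covered | disk
      }
      if (sum(covered) < target) {               # deterministic fallback
        need <- which(!covered)[seq_len(target - sum(covered))]
        for (ch in 1:3) {
          plane <- x[, , ch]
          plane[need] <- 0.96
          x[, , ch] <- plane
        }
      }
    } else if (spec$category == "U") {
      x <- x * (0.14 / max(x))                 # everything below the dark cut
      budget <- floor((1 - spec$dark_fraction) * npix)
      if (budget > 0) {
        mask <- .paint_disks(h, w, budget, r_lo = 2, r_hi = max(3, w / 16))
        for (ch in 1:3) {
          plane <- x[, , ch]
          plane[mask] <- runif(sum(mask), 0.45, 0.7)
          x[, , ch] <- plane
        }
      }
    }
    x
  })
  out <- array(as.integer(pmin(255, pmax(0, round(img * 255)))), dim(img))
  out
}

#' Pixel statistics of a frame
#'
#' @param img an integer `H x W x 3` array with values in `[0, 255]`.
#' @return list with `bright_fraction` (max channel >= 230),
#'   `dark_fraction` (max channel < 40) and `laplacian_variance`
#'   (variance of a 3x3 Laplacian response on the grayscale image,
#'   a standard sharpness measure).
#' @export
frame_stats <- function(img) {
  .assert(length(dim(img)) == 3 && dim(img)[3] == 3,
          "img must be an H x W x 3 array")
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  gray <- (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- EBImage::filter2(gray, lap, boundary = "replicate")
  list(bright_fraction = mean(mx >= 230),
       dark_fraction = mean(mx < 40),
       laplacian_variance = var(as.vector(resp)))
}

#' Generate a labeled synthetic frame set
#'
#' Produces `n_per_class` frames for each of the four categories (720
#' frames at the dataset-scale default of 180 per class), shuffled
#' deterministically by `seed`.
#'
#' @param n_per_class frames per category (>= 1).
#' @param size square frame edge in pixels (default 128).
#' @param seed integer master seed.
#' @return an object of class `frame_set`: list with `images` (list of
#'   `size x size x 3` integer arrays), `labels` (factor with levels
#'   I, B, S, U) and `ids` (character frame identifiers).
#' @export
generate_frame_set <- function(n_per_class, size = 128, seed = 1) {
  .assert(is.numeric(n_per_class) && n_per_class >= 1,
          "n_per_class must be >= 1")
  n_per_class <- as.integer(n_per_class)
  cats <- rep(FRAME_CATEGORIES, each = n_per_class)
  n <- length(cats)
  ord_seeds <- withr::with_seed(seed, {
    list(seeds = sample.int(2147483000, n), ord = sample.int(n))
  })
  images <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- frame_spec(cats[i], size, size, seed = ord_seeds$seeds[i])
    images[[i]] <- generate_frame(sp)
  }
  ord <- ord_seeds$ord
  structure(list(images = images[ord],
                 labels = factor(cats[ord], levels = FRAME_CATEGORIES),
                 ids = sprintf("frame_%05d", seq_len(n))),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("frame_set:", length(x$images), "frames,", d[1], "x", d[2], "px\n")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Specification of Gaussian blob embeddings
#'
#' A fast stand-in for CNN feature embeddings: isotropic Gaussian clusters
#' with pairwise-equidistant centers, used to exercise the reduction,
#' clustering, labeling and tuning stages at scale.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param n_per_cluster points per cluster (>= 1).
#' @param dim feature dimensionality (>= `n_clusters` when
#'   `separation > 0`, so that centers can be placed pairwise equidistant).
#' @param separation pairwise distance between cluster centers (>= 0).
#' @param noise_sd within-cluster standard deviation (> 0).
#' @param seed integer seed.
#' @return an object of class `blob_spec`.
#' @export
blob_spec <- function(n_clusters, n_per_cluster, dim, separation = 10,
                      noise_sd = 1, seed = 1) {
  .assert(n_clusters >= 2, "n_clusters must be >= 2")
  .assert(n_per_cluster >= 1, "n_per_cluster must be >= 1")
  .assert(dim >= 1, "dim must be >= 1")
  .assert(separation >= 0, "separation must be >= 0")
  .assert(noise_sd > 0, "noise_sd must be > 0")
  if (separation > 0)
    .assert(dim >= n_clusters,
            "dim must be >= n_clusters for equidistant centers")
  structure(list(n_clusters = as.integer(n_clusters),
                 n_per_cluster = as.integer(n_per_cluster),
                 dim = as.integer(dim), separation = separation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "blob_spec")
}

#' Generate Gaussian blob embeddings with ground truth
#'
#' Cluster centers sit at scaled coordinate basis vectors, so every pair
#' of centers is exactly `separation` apart; rows are drawn from isotropic
#' Gaussians around them. Deterministic given the spec seed.
#'
#' @param spec a [blob_spec()].
#' @return list with `embedding` (a `frame_embedding`: values matrix
#'   `N x dim`, frame ids, backend tag) and `labels` (integer ground-truth
#'   cluster of each row, `1..n_clusters`).
#' @export
generate_blob_embeddings <- function(spec) {
  .assert(inherits(spec, "blob_spec"), "spec must be a blob_spec")
  k <- spec$n_clusters; m <- spec$n_per_cluster; d <- spec$dim
  centers <- matrix(0, k, d)
  if (spec$separation > 0)
    for (j in seq_len(k)) centers[j, j] <- spec$separation / sqrt(2)
  labels <- rep(seq_len(k), each = m)
  X <- withr::with_seed(spec$seed, {
    centers[labels, , drop = FALSE] +
      matrix(rnorm(k * m * d, sd = spec$noise_sd), k * m, d)
  })
  ids <- sprintf("blob_%05d", seq_len(nrow(X)))
  rownames(X) <- ids
  emb <- structure(list(values = X, frame_ids = ids,
                        backend_tag = sprintf("gaussian-blobs(seed=%d)",
                                              spec$seed)),
                   class = "frame_embedding")
  list(embedding = emb, labels = labels)
}
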