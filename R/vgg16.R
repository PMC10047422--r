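# Random-weight VGG16 feature extractor, forward pass only.
#
# The 13-layer convolutional stack of the VGG16 architecture (3x3 kernels,
# stride 1, pad 1, ReLU, 2x2 max pooling after each block) followed by the
# first 4096-unit fully connected layer. Weights are never trained: they are
# drawn once from a fan-in-scaled Gaussian (He initialization) under a fixed
# seed, which is enough to produce a usable 4096-d embedding for clustering.
# Convolutions are computed as im2col + GEMM so the heavy lifting happens in
# BLAS.

VGG16_BLOCKS <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                     c(512, 512, 512), c(512, 512, 512))
VGG16_INPUT <- 224L
VGG16_FEAT_DIM <- 4096L

# Generate the full weight set under `seed`. Conv weights are stored as
# (out_ch) x (9 * in_ch) matrices matching the im2col patch layout.
#' @noRd
.vgg16_weights <- function(seed) {
  withr::with_seed(seed, {
    convs <- list()
    in_ch <- 3L
    for (b in seq_along(VGG16_BLOCKS)) {
      for (out_ch in VGG16_BLOCKS[[b]]) {
        fan_in <- 9L * in_ch
        convs[[length(convs) + 1L]] <-
          list(W = matrix(rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
                          out_ch, fan_in),
               out_ch = out_ch)
        in_ch <- out_ch
      }
    }
    fc_in <- 7L * 7L * 512L
    fc <- matrix(rnorm(VGG16_FEAT_DIM * fc_in, sd = sqrt(2 / fc_in)),
                 VGG16_FEAT_DIM, fc_in)
    list(convs = convs, fc = fc)
  })
}

# 3x3/pad-1 convolution of an H x W x C array via im2col; returns H x W x O
#' @noRd
.conv3x3 <- function(x, W) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  pad <- array(0, c(h + 2L, w + 2L, cc))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, 9L * cc, h * w)
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      s <- pad[dy + seq_len(h), dx + seq_len(w), , drop = FALSE]
      dim(s) <- c(h * w, cc)
      cols[k * cc + seq_len(cc), ] <- t(s)
      k <- k + 1L
    }
  }
  out <- W %*% cols                      # O x (H*W)
  out[out < 0] <- 0                      # ReLU
  array(t(out), c(h, w, nrow(W)))
}

#' @noRd
.maxpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  o1 <- seq(1, h, by = 2); o2 <- seq(2, h, by = 2)
  p1 <- seq(1, w, by = 2); p2 <- seq(2, w, by = 2)
  pmax(x[o1, p1, , drop = FALSE], x[o2, p1, , drop = FALSE],
       x[o1, p2, , drop = FALSE], x[o2, p2, , drop = FALSE])
}

# forward pass: img is H x W x 3 in [0, 1], already resized to 224 x 224
#' @noRd
.vgg16_forward <- function(img, weights) {
  x <- img
  li <- 0L
  for (b in seq_along(VGG16_BLOCKS)) {
    for (j in seq_along(VGG16_BLOCKS[[b]])) {
      li <- li + 1L
      x <- .conv3x3(x, weights$convs[[li]]$W)
    }
    x <- .maxpool2(x)
  }
  v <- as.vector(x)                      # 7*7*512, column-major (H, W, C)
  out <- drop(weights$fc %*% v)
  out[out < 0] <- 0                      # first FC activation (post-ReLU)
  out
}
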