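#' Extract fixed-length feature embeddings from frames
#'
#' Converts every frame of a frame set into one feature vector. Two
#' backends are available:
#'
#' * `"cnn-vgg16-random"` (the pipeline default for real data): frames are
#'   bilinearly resized to the VGG16 input size (224 x 224), pixel values
#'   scaled to `[0, 1]`, and passed through a randomly initialized (seeded,
#'   untrained) VGG16-architecture network truncated after the first
#'   4096-unit fully connected activation, so `D = 4096`. The weight
#'   initialization is a fan-in-scaled Gaussian fixed by `seed`; the choice
#'   of the surviving fully connected layer is recorded in `backend_tag`.
#' * `"pixel-downsample"`: grayscale bilinear downsample to 32 x 32,
#'   flattened, so `D = 1024`. Orders of magnitude faster; used throughout
#'   the test suite and appropriate whenever frames differ in global
#'   exposure/texture rather than fine detail.
#'
#' Both backends are deterministic given `seed` and the input.
#'
#' @param frames a `frame_set` (see [generate_frame_set()], [read_frame_set()]).
#' @param backend `"pixel-downsample"` or `"cnn-vgg16-random"`.
#' @param seed integer seed controlling the CNN weight draw.
#' @return an object of class `frame_embedding`: list with `values`
#'   (`N x D` matrix, rows aligned with `frame_ids`), `frame_ids`, and
#'   `backend_tag`.
#' @export
extract_embeddings <- function(frames, backend = c("pixel-downsample",
                                                   "cnn-vgg16-random"),
                               seed = 42) {
  backend <- match.arg(backend)
  .assert(inherits(frames, "frame_set"), "frames must be a frame_set")
  n <- length(frames$images)
  .assert(n >= 1, "frame set is empty")
  dims <- vapply(frames$images, function(im) dim(im)[1:2], numeric(2))
  .assert(all(dims == dims[, 1]), "all frames must share the same shape")

  gray01 <- function(im)
    (0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3]) / 255

  if (backend == "pixel-downsample") {
    vals <- t(vapply(frames$images, function(im) {
      g <- EBImage::resize(gray01(im), w = 32, h = 32)
      as.vector(g)
    }, numeric(1024)))
    tag <- "pixel-downsample(32x32,gray)"
  } else {
    wts <- .vgg16_weights(seed)
    vals <- t(vapply(frames$images, function(im) {
      rs <- array(0, c(VGG16_INPUT, VGG16_INPUT, 3))
      for (ch in 1:3)
        rs[, , ch] <- EBImage::resize(im[, , ch] / 255,
                                      w = VGG16_INPUT, h = VGG16_INPUT)
      .vgg16_forward(rs, wts)
    }, numeric(VGG16_FEAT_DIM)))
    tag <- sprintf("cnn-vgg16-random(first-fc4096,seed=%d)", seed)
  }
  .assert(all(is.finite(vals)), "embedding produced non-finite values")
  rownames(vals) <- frames$ids
  structure(list(values = vals, frame_ids = frames$ids, backend_tag = tag),
            class = "frame_embedding")
}

#' @export
print.frame_embedding <- function(x, ...) {
  cat("frame_embedding:", nrow(x$values), "x", ncol(x$values),
      "| backend:", x$backend_tag, "\n")
  invisible(x)
}

# coerce a plain matrix to the embedding container
#' @noRd
as_embedding <- function(x, tag = "user-matrix") {
  if (inherits(x, "frame_embedding")) return(x)
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row_%05d", seq_len(nrow(x)))
  structure(list(values = x, frame_ids = ids, backend_tag = tag),
            class = "frame_embedding")
}
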