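#' Instance encoders
#'
#' An encoder maps each tile of a bag to a fixed-length feature vector. Three
#' kinds are supported through one contract:
#' \describe{
#'   \item{passthrough}{the bag already is a feature matrix (precomputed
#'     features); returned unchanged after a shape check.}
#'   \item{small-conv}{a compact convolutional embedder: three 3x3
#'     convolution + ReLU + 2x2 mean-pool blocks followed by global average
#'     pooling to `d = 64` features. Its weights are seeded random
#'     projections and stay frozen, so encoding is a deterministic, reusable
#'     featurization; random convolutional features of this kind are a
#'     standard lightweight baseline when no pretrained backbone is bundled.}
#'   \item{custom}{any user-supplied function `f(pixel_array) -> numeric(d)`,
#'     e.g. an adapter around an external pretrained embedder.}
#' }
#'
#' @param feature_dim expected feature dimension (passthrough; `NULL` skips
#'   the check).
#' @return an object of class `mil_encoder`.
#' @export
encoder_passthrough <- function(feature_dim = NULL) {
  structure(list(kind = "passthrough", d = feature_dim,
                 id = "passthrough"), class = "mil_encoder")
}

#' @rdname encoder_passthrough
#' @param d output feature dimension of the small-conv encoder.
#' @param channels channel widths of the three convolution blocks; the last
#'   equals `d`.
#' @param seed seed for the frozen random weights.
#' @export
encoder_smallconv <- function(d = 64L, channels = c(8L, 16L, d), seed = 42L) {
  stopifnot(length(channels) == 3L, channels[3] == d)
  set.seed(seed)
  c_in <- c(3L, channels[1:2])
  weights <- vector("list", 3L)
  for (b in 1:3) {
    # He-initialized 3x3 kernels, stored as one (9 * c_in) x c_out matrix
    weights[[b]] <- list(
      W = matrix(rnorm(9L * c_in[b] * channels[b], sd = sqrt(2 / (9 * c_in[b]))),
                 9L * c_in[b], channels[b]),
      b = rep(0, channels[b])
    )
  }
  structure(list(kind = "small-conv", d = as.integer(d),
                 channels = as.integer(channels), weights = weights,
                 id = sprintf("small-conv-d%d-seed%d", d, seed)),
            class = "mil_encoder")
}

#' @rdname encoder_passthrough
#' @param fun function mapping an H x W x 3 pixel array to a length-`d`
#'   numeric vector.
#' @param id identifier recorded as feature provenance.
#' @export
encoder_custom <- function(fun, d, id = "custom") {
  stopifnot(is.function(fun))
  structure(list(kind = "custom", d = as.integer(d), fun = fun, id = id),
            class = "mil_encoder")
}

# 3x3 same-padding convolution via 9 shifted matrix products
conv3x3 <- function(img, W, bias) {
  d <- dim(img); h <- d[1]; w <- d[2]; c_in <- d[3]
  c_out <- length(bias)
  pad <- array(0, c(h + 2L, w + 2L, c_in))
  pad[2:(h + 1L), 2:(w + 1L), ] <- img
  acc <- matrix(rep(bias, each = h * w), h * w, c_out)
  k <- 0L
  for (dx in 0:2) {
    for (dy in 0:2) {
      crop <- matrix(pad[dy + seq_len(h), dx + seq_len(w), ], h * w, c_in)
      acc <- acc + crop %*% W[k * c_in + seq_len(c_in), , drop = FALSE]
      k <- k + 1L
    }
  }
  array(acc, c(h, w, c_out))
}

pool2x2 <- function(img) {
  d <- dim(img)
  out <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- downsample_block_mean(img[, , c], 2L)
  out
}

smallconv_forward <- function(px, enc) {
  x <- px
  for (b in 1:3) {
    x <- conv3x3(x, enc$weights[[b]]$W, enc$weights[[b]]$b)
    x <- pmax(x, 0)
    x <- pool2x2(x)
  }
  apply(x, 3, mean)
}

#' Encode a bag of tiles into an instance-feature matrix
#'
#' @param bag either a numeric matrix of precomputed features (one row per
#'   instance; passthrough encoder) or a list of tiles from [tile_image()].
#' @param encoder a `mil_encoder`.
#' @return a numeric matrix `H` with one row per instance and
#'   `attr(H, "provenance")` naming the encoder. Encoding is deterministic.
#' @export
encode_bag <- function(bag, encoder) {
  stopifnot(inherits(encoder, "mil_encoder"))
  if (encoder$kind == "passthrough") {
    if (!is.matrix(bag)) stop("passthrough encoder expects a feature matrix")
    if (nrow(bag) == 0L) stop("empty bag: no instances to encode")
    if (!is.null(encoder$d) && ncol(bag) != encoder$d) {
      stop(sprintf("feature_dim mismatch: bag has %d columns, encoder expects %d",
                   ncol(bag), encoder$d))
    }
    H <- bag
  } else {
    if (!is.list(bag)) stop(encoder$kind, " encoder expects a list of tiles")
    if (length(bag) == 0L) stop("empty bag: no instances to encode")
    rows <- lapply(bag, function(t) {
      px <- if (is.list(t)) t$pixels else t
      if (encoder$kind == "small-conv") smallconv_forward(px, encoder)
      else encoder$fun(px)
    })
    H <- do.call(rbind, rows)
    if (ncol(H) != encoder$d) {
      stop(sprintf("encoder returned %d features, declared d = %d",
                   ncol(H), encoder$d))
    }
  }
  if (any(!is.finite(H))) stop("non-finite instance features")
  attr(H, "provenance") <- encoder$id
  H
}
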