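#' Configuration for synthetic feature-space MIL bags
#'
#' Describes a weakly labelled multiple-instance dataset in feature space:
#' every bag is a `bag_size` x `feature_dim` matrix of instance features,
#' background instances are i.i.d. Gaussian noise, and positive bags carry a
#' known subset of "signal" instances whose mean is shifted on a fixed block
#' of coordinates (the first `ceiling(feature_dim / 4)` dimensions). This is
#' the stand-in for encoder output when testing the bag classifier without
#' images.
#'
#' @param n_bags number of bags.
#' @param bag_size instances per bag.
#' @param feature_dim feature dimensionality d.
#' @param witness_rate fraction of signal instances within a positive bag,
#'   in (0, 1]; at least one signal instance is always planted.
#' @param signal_shift mean shift added to signal instances on the signal
#'   coordinates. `0` produces a null dataset with no class signal.
#' @param noise_sd standard deviation of the background features (> 0).
#' @param pos_fraction fraction of positive bags, in (0, 1).
#' @param seed RNG seed.
#' @return an object of class `bag_config`.
#' @export
bag_config <- function(n_bags, bag_size, feature_dim,
                       witness_rate = 0.1, signal_shift = 1,
                       noise_sd = 1, pos_fraction = 0.5, seed = 1L) {
  if (n_bags < 2) stop_config("n_bags", "must be >= 2")
  if (bag_size < 1) stop_config("bag_size", "must be >= 1")
  if (feature_dim < 1) stop_config("feature_dim", "must be >= 1")
  if (witness_rate <= 0 || witness_rate > 1)
    stop_config("witness_rate", "must lie in (0, 1]")
  if (signal_shift < 0) stop_config("signal_shift", "must be >= 0")
  if (noise_sd <= 0) stop_config("noise_sd", "must be > 0")
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop_config("pos_fraction", "must lie strictly in (0, 1)")
  structure(list(
    n_bags = as.integer(n_bags), bag_size = as.integer(bag_size),
    feature_dim = as.integer(feature_dim), witness_rate = witness_rate,
    signal_shift = signal_shift, noise_sd = noise_sd,
    pos_fraction = pos_fraction, seed = as.integer(seed)
  ), class = "bag_config")
}

#' Indices of the signal coordinates for a feature dimension
#' @param feature_dim feature dimensionality.
#' @return integer vector, the first `ceiling(feature_dim / 4)` dimensions.
#' @export
signal_dims <- function(feature_dim) seq_len(ceiling(feature_dim / 4))

#' Generate synthetic feature-space MIL bags with known ground truth
#'
#' The number of positive bags is `round(pos_fraction * n_bags)`; positive
#' labels are assigned to the first k bags and then shuffled under the seed,
#' so the count is deterministic. Background instances are
#' N(0, noise_sd^2) i.i.d.; each positive bag plants
#' `max(1, round(witness_rate * bag_size))` signal instances with
#' `signal_shift` added on the signal coordinates. A bag's label is positive
#' if and only if its instance mask contains at least one signal instance
#' (standard MIL semantics).
#'
#' @param config a [bag_config()].
#' @return a list with components
#'   \describe{
#'     \item{bags}{list of `bag_size` x `feature_dim` matrices.}
#'     \item{ground_truth}{list with `bag_labels` (0/1 integer vector),
#'       `instance_mask` (list of logical vectors marking planted signal
#'       instances), and `signal_dims`.}
#'   }
#' @export
gen_feature_bags <- function(config) {
  stopifnot(inherits(config, "bag_config"))
  set.seed(config$seed)
  n <- config$n_bags
  k <- round(config$pos_fraction * n)
  labels <- sample(rep(c(1L, 0L), c(k, n - k)))
  sdim <- signal_dims(config$feature_dim)
  n_sig <- max(1L, round(config$witness_rate * config$bag_size))
  bags <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    H <- matrix(rnorm(config$bag_size * config$feature_dim, sd = config$noise_sd),
                config$bag_size, config$feature_dim)
    mask <- rep(FALSE, config$bag_size)
    if (labels[i] == 1L) {
      idx <- sample(config$bag_size, n_sig)
      H[idx, sdim] <- H[idx, sdim] + config$signal_shift
      mask[idx] <- TRUE
    }
    bags[[i]] <- H
    masks[[i]] <- mask
  }
  list(bags = bags,
       ground_truth = list(bag_labels = labels, instance_mask = masks,
                           signal_dims = sdim))
}

#' Generate multi-scale feature bags sharing signal with independent noise
#'
#' Emulates three magnification levels of the same slides: every scale sees
#' the same clean signal component (same labels, same planted instances, same
#' shift) but an independent Gaussian noise draw, so per-scale predictions
#' carry partly independent errors that a mean-pooling ensemble can average
#' out.
#'
#' @param config a [bag_config()].
#' @param scales character vector of scale names.
#' @return list with `bags_by_scale` (named list of bag lists) and
#'   `ground_truth` as in [gen_feature_bags()].
#' @export
gen_multiscale_feature_bags <- function(config,
                                        scales = c("20x", "10x", "5x")) {
  stopifnot(inherits(config, "bag_config"), length(scales) >= 1)
  set.seed(config$seed)
  n <- config$n_bags
  k <- round(config$pos_fraction * n)
  labels <- sample(rep(c(1L, 0L), c(k, n - k)))
  sdim <- signal_dims(config$feature_dim)
  n_sig <- max(1L, round(config$witness_rate * config$bag_size))
  masks <- vector("list", n)
  clean <- vector("list", n)
  for (i in seq_len(n)) {
    S <- matrix(0, config$bag_size, config$feature_dim)
    mask <- rep(FALSE, config$bag_size)
    if (labels[i] == 1L) {
      idx <- sample(config$bag_size, n_sig)
      S[idx, sdim] <- config$signal_shift
      mask[idx] <- TRUE
    }
    clean[[i]] <- S
    masks[[i]] <- mask
  }
  bags_by_scale <- lapply(stats::setNames(scales, scales), function(sc) {
    lapply(clean, function(S) {
      S + matrix(rnorm(length(S), sd = config$noise_sd), nrow(S), ncol(S))
    })
  })
  list(bags_by_scale = bags_by_scale,
       ground_truth = list(bag_labels = labels, instance_mask = masks,
                           signal_dims = sdim))
}

#' Configuration for synthetic multi-scale slide images
#'
#' @param n_slides number of slides.
#' @param base_size pixels per side of the base (20x) image; must be a
#'   positive multiple of 4 so 10x and 5x block-mean downsamplings are
#'   integral.
#' @param lesion_fraction fraction of a positive slide's area covered by
#'   lesion texture, strictly in (0, 1).
#' @param background_kind `"tissue-texture"` (low-amplitude smooth noise that
#'   survives the entropy filter) or `"blank"` (near-constant intensity that
#'   the entropy filter removes).
#' @param pos_fraction fraction of positive slides, in (0, 1).
#' @param seed RNG seed.
#' @return an object of class `slide_config`.
#' @export
slide_config <- function(n_slides, base_size = 896, lesion_fraction = 0.25,
                         background_kind = c("tissue-texture", "blank"),
                         pos_fraction = 0.5, seed = 1L) {
  background_kind <- match.arg(background_kind)
  if (n_slides < 2) stop_config("n_slides", "must be >= 2")
  if (base_size < 4 || base_size %% 4 != 0)
    stop_config("base_size", "must be a positive multiple of 4")
  if (lesion_fraction <= 0 || lesion_fraction >= 1)
    stop_config("lesion_fraction", "must lie strictly in (0, 1)")
  if (pos_fraction <= 0 || pos_fraction >= 1)
    stop_config("pos_fraction", "must lie strictly in (0, 1)")
  structure(list(
    n_slides = as.integer(n_slides), base_size = as.integer(base_size),
    lesion_fraction = lesion_fraction, background_kind = background_kind,
    pos_fraction = pos_fraction, seed = as.integer(seed)
  ), class = "slide_config")
}

# smooth low-amplitude random field: coarse Gaussian grid upsampled bilinearly
smooth_field <- function(size, coarse = 16, amplitude = 1) {
  g <- matrix(rnorm(coarse * coarse), coarse, coarse)
  src <- seq(1, coarse, length.out = size)
  i0 <- clamp(floor(src), 1, coarse - 1)
  fr <- src - i0
  up_rows <- g[i0, , drop = FALSE] * (1 - fr) + g[i0 + 1, , drop = FALSE] * fr
  out <- up_rows[, i0, drop = FALSE] * rep(1 - fr, each = size) +
    up_rows[, i0 + 1, drop = FALSE] * rep(fr, each = size)
  out * amplitude
}

# per-region grayscale textures on the 0..255 scale
tissue_texture <- function(h, w) {
  200 + smooth_field(max(h, w), coarse = 14, amplitude = 18)[seq_len(h), seq_len(w)] +
    matrix(rnorm(h * w, sd = 12), h, w)
}

lesion_texture <- function(h, w) {
  speckle <- matrix(sample(c(-65, 65), h * w, replace = TRUE), h, w)
  125 + speckle + matrix(rnorm(h * w, sd = 12), h, w)
}

# tint a grayscale field into an H x W x 3 array, clamped to [0, 255]
tint <- function(g, mult) {
  out <- array(0, c(nrow(g), ncol(g), 3L))
  for (c in 1:3) out[, , c] <- clamp(g * mult[c], 0, 255)
  out
}

#' Block-mean downsample an image by an integer factor
#'
#' Lower magnifications are produced by block-mean averaging (how scanners
#' build pyramid levels), not by subsampling.
#'
#' @param img H x W x C array (or H x W matrix) with H, W divisible by
#'   `factor`.
#' @param factor integer downsampling factor.
#' @return downsampled array of the same number of channels.
#' @export
downsample_block_mean <- function(img, factor) {
  f <- as.integer(factor)
  one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    stopifnot(h %% f == 0, w %% f == 0)
    m1 <- matrix(colMeans(matrix(m, nrow = f)), h %/% f, w)
    t(matrix(colMeans(matrix(t(m1), nrow = f)), w %/% f, h %/% f))
  }
  if (length(dim(img)) == 2L) return(one(img))
  out <- array(0, c(dim(img)[1] %/% f, dim(img)[2] %/% f, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- one(img[, , c])
  out
}

#' Generate synthetic slide pyramids with planted lesions
#'
#' Positive slides contain one contiguous square lesion region of
#' high-contrast speckle texture occupying approximately `lesion_fraction`
#' of the area; negative slides contain background only. The 10x and 5x
#' images are 2x and 4x block-mean downsamplings of the 20x image. Pixel
#' intensities follow the 8-bit convention (0..255).
#'
#' @param config a [slide_config()].
#' @return list with components
#'   \describe{
#'     \item{slides}{list; each element has `slide_id`, `label`, and
#'       `images`, a named list of H x W x 3 arrays for `"20x"`, `"10x"`,
#'       `"5x"`.}
#'     \item{ground_truth}{list with `slide_labels` and `lesion_mask`
#'       (list of base-resolution 0/1 matrices).}
#'   }
#' @export
gen_slide_pyramids <- function(config) {
  stopifnot(inherits(config, "slide_config"))
  set.seed(config$seed)
  n <- config$n_slides
  k <- round(config$pos_fraction * n)
  labels <- sample(rep(c(1L, 0L), c(k, n - k)))
  b <- config$base_size
  side <- max(1L, round(sqrt(config$lesion_fraction) * b))
  slides <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    g <- if (config$background_kind == "blank") {
      matrix(235, b, b)
    } else {
      tissue_texture(b, b)
    }
    mask <- matrix(0L, b, b)
    if (labels[i] == 1L) {
      y0 <- sample.int(b - side + 1L, 1L)
      x0 <- sample.int(b - side + 1L, 1L)
      ry <- y0:(y0 + side - 1L); rx <- x0:(x0 + side - 1L)
      g[ry, rx] <- lesion_texture(side, side)
      mask[ry, rx] <- 1L
    }
    img20 <- tint(g, c(1.00, 0.90, 0.96))
    slides[[i]] <- list(
      slide_id = sprintf("slide_%03d", i),
      label = labels[i],
      images = list(
        "20x" = img20,
        "10x" = downsample_block_mean(img20, 2L),
        "5x"  = downsample_block_mean(img20, 4L)
      )
    )
    masks[[i]] <- mask
  }
  list(slides = slides,
       ground_truth = list(slide_labels = labels, lesion_mask = masks))
}
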