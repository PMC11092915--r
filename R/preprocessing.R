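#' Cut an image into non-overlapping 224x224 tiles
#'
#' Tiles are laid on a 0-based, half-open grid
#' `[x*ts, (x+1)*ts) x [y*ts, (y+1)*ts)`; partial tiles at the right/bottom
#' edges are discarded, so the tile count is
#' `floor(H/ts) * floor(W/ts)`.
#'
#' @param image H x W x 3 array (8-bit convention, values 0..255).
#' @param tile_size side length in pixels; the working default is 224.
#' @param magnification tag stored on each tile (`"20x"`, `"10x"`, `"5x"`).
#' @return list of tiles; each tile is a list with `pixels`
#'   (tile_size x tile_size x 3), `grid_x`, `grid_y` (0-based column/row
#'   indices), `magnification`, and `entropy_bits` (filled by
#'   [tile_entropy()], `NA` here).
#' @export
tile_image <- function(image, tile_size = 224L, magnification = NA_character_) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("image must be an H x W x 3 array")
  h <- d[1]; w <- d[2]; ts <- as.integer(tile_size)
  ny <- h %/% ts; nx <- w %/% ts
  if (ny < 1L || nx < 1L) {
    stop(sprintf("image (%d x %d) smaller than one %d x %d tile: no tiles produced",
                 h, w, ts, ts))
  }
  tiles <- vector("list", ny * nx)
  k <- 0L
  for (gy in 0:(ny - 1L)) {
    for (gx in 0:(nx - 1L)) {
      k <- k + 1L
      tiles[[k]] <- list(
        pixels = image[gy * ts + seq_len(ts), gx * ts + seq_len(ts), , drop = FALSE],
        grid_x = gx, grid_y = gy,
        magnification = magnification,
        entropy_bits = NA_real_
      )
    }
  }
  tiles
}

#' Shannon entropy of a tile's grayscale histogram, in bits
#'
#' The tile is converted to 8-bit luminance (0.299 R + 0.587 G + 0.114 B),
#' binned into the 256 integer gray levels, and the base-2 Shannon entropy of
#' the histogram is returned. Bounded in [0, 8]: a constant tile scores 0
#' bits, a tile using all 256 levels equally scores 8 bits. Tiles scoring
#' below 5 bits are treated as background by [filter_background()].
#'
#' @param tile a tile from [tile_image()] or a pixel array (H x W x 3 or an
#'   H x W grayscale matrix), values in [0, 255].
#' @return entropy in bits.
#' @export
tile_entropy <- function(tile) {
  px <- if (is.list(tile)) tile$pixels else tile
  lum <- if (length(dim(px)) == 3L) {
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  } else {
    px
  }
  if (min(lum) < 0 || max(lum) > 255) stop("tile pixels must lie in [0, 255]")
  bins <- pmin(floor(lum), 255) + 1L
  counts <- tabulate(bins, nbins = 256L)
  p <- counts[counts > 0] / length(lum)
  -sum(p * log2(p))
}

#' Remove background tiles by entropy threshold
#'
#' Retains exactly the tiles whose entropy is at or above the threshold;
#' tiles with entropy strictly less than the threshold are excluded as
#' likely background. Order is preserved. Entropies are computed on the fly
#' for tiles that do not carry one yet.
#'
#' @param tiles list of tiles.
#' @param threshold entropy cut in bits; default 5.
#' @return list of retained tiles, each with `entropy_bits` filled in.
#' @export
filter_background <- function(tiles, threshold = 5.0) {
  if (length(tiles) == 0L) return(list())
  tiles <- lapply(tiles, function(t) {
    if (is.na(t$entropy_bits)) t$entropy_bits <- tile_entropy(t)
    t
  })
  tiles[vapply(tiles, function(t) t$entropy_bits >= threshold, logical(1))]
}

#' Fit per-channel normalization statistics per magnification
#'
#' Computes the per-channel mean and (population) variance over all pixels
#' of all supplied tiles, separately for each magnification level. The
#' statistics should be fitted on the training split only, so that test
#' slides never influence them. Channels with zero variance get their sd
#' clamped to 1 with a warning.
#'
#' @param tiles list of tiles carrying `magnification` tags.
#' @return an object of class `normalization_stats`: named list per
#'   magnification of `list(mean, var, sd)` length-3 numeric vectors.
#' @export
fit_normalization <- function(tiles) {
  if (length(tiles) == 0L) stop("need at least one tile to fit normalization")
  mags <- vapply(tiles, function(t) t$magnification, character(1))
  out <- lapply(split(tiles, mags), function(tl) {
    mean_c <- numeric(3); var_c <- numeric(3)
    for (c in 1:3) {
      v <- unlist(lapply(tl, function(t) as.vector(t$pixels[, , c])))
      mean_c[c] <- mean(v)
      var_c[c] <- mean((v - mean_c[c])^2)
    }
    sd_c <- sqrt(var_c)
    if (any(var_c == 0)) {
      warning("zero-variance channel(s); sd clamped to 1")
      sd_c[var_c == 0] <- 1
    }
    list(mean = mean_c, var = var_c, sd = sd_c)
  })
  structure(out, class = "normalization_stats")
}

#' Apply fitted normalization to a tile
#'
#' @param tile a tile; its magnification selects the statistics entry.
#' @param stats a `normalization_stats` object from [fit_normalization()].
#' @return the tile with real-valued standardized pixels.
#' @export
apply_normalization <- function(tile, stats) {
  s <- stats[[tile$magnification]]
  if (is.null(s)) stop("no normalization statistics for magnification ",
                       tile$magnification)
  for (c in 1:3) tile$pixels[, , c] <- (tile$pixels[, , c] - s$mean[c]) / s$sd[c]
  tile
}

#' Augmentation parameters
#'
#' Each transform fires independently with its own probability. Defaults are
#' deliberately mild; magnitudes are on the 8-bit (0..255) intensity scale.
#'
#' @param p_flip_h,p_flip_v,p_rot,p_noise,p_jitter,p_crop per-transform
#'   probabilities.
#' @param noise_sd sd of additive Gaussian pixel noise.
#' @param jitter maximal relative brightness/contrast perturbation.
#' @param crop_scale range of the random crop's linear scale before resizing
#'   back to the original side length.
#' @return list of class `augment_params`.
#' @export
augment_params <- function(p_flip_h = 0.5, p_flip_v = 0.5, p_rot = 0.5,
                           p_noise = 0.5, p_jitter = 0.5, p_crop = 0.5,
                           noise_sd = 5, jitter = 0.10,
                           crop_scale = c(0.8, 1.0)) {
  structure(list(p_flip_h = p_flip_h, p_flip_v = p_flip_v, p_rot = p_rot,
                 p_noise = p_noise, p_jitter = p_jitter, p_crop = p_crop,
                 noise_sd = noise_sd, jitter = jitter, crop_scale = crop_scale),
            class = "augment_params")
}

# bilinear resize of an H x W x C array to out_h x out_w
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img); h <- d[1]; w <- d[2]
  sy <- if (out_h == 1L) (h + 1) / 2 else seq(1, h, length.out = out_h)
  sx <- if (out_w == 1L) (w + 1) / 2 else seq(1, w, length.out = out_w)
  y0 <- clamp(floor(sy), 1, h - 1); fy <- sy - y0
  x0 <- clamp(floor(sx), 1, w - 1); fx <- sx - x0
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    m <- img[, , c]
    top <- m[y0, x0] * (1 - fy) + m[y0 + 1, x0] * fy
    bot <- m[y0, x0 + 1] * (1 - fy) + m[y0 + 1, x0 + 1] * fy
    out[, , c] <- top * rep(1 - fx, each = out_h) + bot * rep(fx, each = out_h)
  }
  out
}

rotate90 <- function(img, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

#' Randomly augment a training tile
#'
#' Applies, each with its configured probability: horizontal/vertical flip,
#' rotation by a multiple of 90 degrees, additive Gaussian pixel noise,
#' brightness/contrast jitter, and random crop-and-resize back to the
#' original side length. Output shape is unchanged and values stay in
#' [0, 255]. Deterministic given the RNG state (set a seed before calling,
#' or pass `seed`).
#'
#' @param tile a tile with 8-bit-scale pixels.
#' @param params an [augment_params()].
#' @param seed optional seed fixing the RNG state for this call.
#' @return the augmented tile.
#' @export
augment <- function(tile, params = augment_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- tile$pixels
  d <- dim(px)
  if (runif(1) < params$p_flip_h) px <- px[, d[2]:1, , drop = FALSE]
  if (runif(1) < params$p_flip_v) px <- px[d[1]:1, , , drop = FALSE]
  if (runif(1) < params$p_rot) px <- rotate90(px, sample(1:3, 1))
  if (runif(1) < params$p_noise) {
    px <- px + array(rnorm(length(px), sd = params$noise_sd), dim(px))
  }
  if (runif(1) < params$p_jitter) {
    brightness <- runif(1, -params$jitter, params$jitter) * 255
    contrast <- 1 + runif(1, -params$jitter, params$jitter)
    px <- (px - 127.5) * contrast + 127.5 + brightness
  }
  if (runif(1) < params$p_crop) {
    s <- runif(1, params$crop_scale[1], params$crop_scale[2])
    ch <- max(2L, round(d[1] * s)); cw <- max(2L, round(d[2] * s))
    y0 <- sample.int(d[1] - ch + 1L, 1L); x0 <- sample.int(d[2] - cw + 1L, 1L)
    px <- bilinear_resize(px[y0 + seq_len(ch) - 1L, x0 + seq_len(cw) - 1L, ,
                             drop = FALSE], d[1], d[2])
  }
  tile$pixels <- clamp(px, 0, 255)
  tile
}

#' Stratified fold assignment for a set of labelled bags
#'
#' Cycles fold indices through the label-grouped, seed-shuffled bags so folds
#' are near-equal in size and class balance. Used when all bags belong to the
#' training split and only folds are needed (see [make_split()] for the full
#' train/test plan).
#'
#' @param labels 0/1 labels.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of 0-based fold indices.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  set.seed(seed)
  fold <- integer(length(labels))
  counter <- 0L
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      fold[i] <- counter %% n_folds
      counter <- counter + 1L
    }
  }
  fold
}

#' Stratified train/test split with cross-validation folds
#'
#' Assigns each slide to train or test at a test fraction of about 1/5,
#' stratified by label, then partitions the training slides into `n_folds`
#' near-equal folds (also stratified). Deterministic given the seed.
#'
#' @param slide_ids character or integer slide identifiers.
#' @param labels binary slide labels (0/1), same length.
#' @param seed RNG seed.
#' @param test_fraction held-out fraction; default 0.2 (a 4:1 split).
#' @param n_folds number of cross-validation folds; default 5.
#' @return an object of class `split_plan`: a data.frame with columns
#'   `slide_id`, `label`, `split` (`"train"`/`"test"`), `fold` (0-based,
#'   `NA` for test slides).
#' @export
make_split <- function(slide_ids, labels, seed = 1L,
                       test_fraction = 0.2, n_folds = 5L) {
  stopifnot(length(slide_ids) == length(labels))
  n <- length(slide_ids)
  if (n < 10L) stop("need at least 10 slides to build a split plan")
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < n_folds)) {
    stop(sprintf(
      "stratification error: class %s has %d slides, fewer than n_folds = %d",
      names(counts)[which(counts < n_folds)[1]],
      min(counts), n_folds))
  }
  set.seed(seed)
  split <- rep("train", n)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    split[sample(idx, n_test)] <- "test"
  }
  fold <- rep(NA_integer_, n)
  counter <- 0L
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl & split == "train")
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      fold[i] <- counter %% n_folds
      counter <- counter + 1L
    }
  }
  structure(
    data.frame(slide_id = slide_ids, label = labels, split = split,
               fold = fold, stringsAsFactors = FALSE),
    class = c("split_plan", "data.frame"),
    n_folds = as.integer(n_folds)
  )
}
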