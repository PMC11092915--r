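make_image <- function(h, w, value = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(value)) array(runif(h * w * 3, 0, 255), c(h, w, 3L))
  else array(value, c(h, w, 3L))
}

test_that("tiling counts follow floor arithmetic and edge tiles are dropped", {
  t1 <- tile_image(make_image(224, 224), 224)
  expect_length(t1, 1L)
  expect_identical(c(t1[[1]]$grid_x, t1[[1]]$grid_y), c(0L, 0L))
  expect_length(tile_image(make_image(448, 224), 224), 2L)
  t12 <- tile_image(make_image(1000, 800), 224)
  expect_length(t12, 12L)  # floor(1000/224) * floor(800/224) = 4 * 3
  coords <- t(vapply(t12, function(t) c(t$grid_x, t$grid_y), integer(2)))
  expect_identical(nrow(unique(coords)), 12L)
  expect_true(all(vapply(t12, function(t) all(dim(t$pixels)[1:2] == 224L),
                         logical(1))))
})

test_that("tiles reproduce the half-open grid content exactly", {
  img <- make_image(500, 300, seed = 4)
  tl <- tile_image(img, 224)
  t2 <- tl[[2]]  # grid (0, 1): rows 225..448 of column block 1..224
  expect_identical(c(t2$grid_x, t2$grid_y), c(0L, 1L))
  expect_identical(t2$pixels[, , 1], img[225:448, 1:224, 1])
})

test_that("too-small images raise an error naming the dimensions", {
  expect_error(tile_image(make_image(100, 300), 224), "100 x 300")
})

test_that("entropy hits its closed-form anchors", {
  expect_identical(tile_entropy(make_image(32, 32, value = 137)), 0)
  # all 256 gray levels equally frequent -> 8 bits (grayscale input)
  g <- matrix(rep(0:255, each = 4), 32, 32)
  expect_equal(tile_entropy(g), 8, tolerance = 1e-12)
  # half 0 / half 255 -> 1 bit
  h <- array(rep(c(0, 255), each = 512 * 3 / 2), c(16, 32, 3))
  h[] <- rep(c(0, 255), length.out = length(h))
  expect_equal(tile_entropy(h), 1, tolerance = 1e-12)
  expect_error(tile_entropy(make_image(8, 8, value = 300)), "0, 255")
})

test_that("entropy matches an independent histogram oracle on 100 tiles", {
  for (seed in 1:100) {
    t <- random_tile(seed, size = 32L)
    expect_equal(tile_entropy(t), oracle_entropy(t$pixels), tolerance = 1e-9)
  }
})

test_that("background filter excludes strictly-below-threshold tiles, keeping order", {
  tiles <- lapply(1:3, random_tile, size = 16L)
  tiles[[1]]$entropy_bits <- 4.9
  tiles[[2]]$entropy_bits <- 5.0
  tiles[[3]]$entropy_bits <- 7.2
  kept <- filter_background(tiles, threshold = 5.0)
  expect_identical(vapply(kept, `[[`, numeric(1), "entropy_bits"), c(5.0, 7.2))
  expect_identical(filter_background(list()), list())
  # all-blank slide -> zero retained tiles (empty bag, not an error)
  blank <- tile_image(make_image(448, 224, value = 200), 224)
  expect_length(filter_background(blank), 0L)
})

test_that("filtered count on random tiles matches the entropy oracle", {
  tiles <- lapply(101:110, random_tile, size = 16L)
  kept <- filter_background(tiles, threshold = 5.0)
  oracle_kept <- sum(vapply(tiles, function(t) oracle_entropy(t$pixels) >= 5,
                            logical(1)))
  expect_identical(length(kept), oracle_kept)
})

test_that("normalization statistics match hand arithmetic and a two-pass oracle", {
  const <- function(v) list(pixels = array(v, c(8, 8, 3L)), grid_x = 0L,
                            grid_y = 0L, magnification = "20x",
                            entropy_bits = NA_real_)
  expect_warning(s <- fit_normalization(list(const(3))), "zero-variance")
  expect_equal(s[["20x"]]$mean, rep(3, 3))
  expect_equal(s[["20x"]]$var, rep(0, 3))
  expect_equal(s[["20x"]]$sd, rep(1, 3))

  s2 <- fit_normalization(list(const(0), const(2)))
  expect_equal(s2[["20x"]]$mean, rep(1, 3))
  expect_equal(s2[["20x"]]$var, rep(1, 3))

  tiles <- lapply(1:4, random_tile, size = 16L)
  s3 <- fit_normalization(tiles)
  o <- oracle_mean_var(tiles)
  expect_equal(s3[["20x"]]$mean, o$mean, tolerance = 1e-9)
  expect_equal(s3[["20x"]]$var, o$var, tolerance = 1e-9)
})

test_that("standardized training tiles have mean 0 and variance 1 per channel", {
  tiles <- lapply(1:5, random_tile, size = 16L)
  s <- fit_normalization(tiles)
  norm <- lapply(tiles, apply_normalization, stats = s)
  for (c in 1:3) {
    v <- unlist(lapply(norm, function(t) as.vector(t$pixels[, , c])))
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-6)
  }
})

test_that("normalization is fitted per magnification and immune to test slides", {
  t20 <- lapply(1:3, random_tile, magnification = "20x", size = 16L)
  t10 <- lapply(4:6, random_tile, magnification = "10x", size = 16L)
  s <- fit_normalization(c(t20, t10))
  expect_setequal(names(s), c("20x", "10x"))
  expect_false(isTRUE(all.equal(s[["20x"]]$mean, s[["10x"]]$mean)))
  # leakage guard: adding test-slide tiles to the dataset does not change
  # statistics fitted on the training tiles
  s_train <- fit_normalization(t20)
  extra_test_tiles <- lapply(50:60, random_tile, size = 16L)
  s_train_again <- fit_normalization(t20)
  expect_identical(s_train, s_train_again)
})

test_that("augmentation is identity at zero probability and involutive for flips", {
  t <- random_tile(9, size = 32L)
  off <- augment_params(0, 0, 0, 0, 0, 0)
  expect_identical(augment(t, off, seed = 1)$pixels, t$pixels)
  flip <- augment_params(1, 0, 0, 0, 0, 0)
  twice <- augment(augment(t, flip, seed = 1), flip, seed = 2)
  expect_equal(twice$pixels, t$pixels, tolerance = 1e-12)
})

test_that("augmentation is deterministic given the seed and shape-preserving", {
  t <- random_tile(10, size = 48L)
  a1 <- augment(t, seed = 77)
  a2 <- augment(t, seed = 77)
  expect_identical(a1$pixels, a2$pixels)
  expect_identical(dim(a1$pixels), dim(t$pixels))
  expect_true(min(a1$pixels) >= 0 && max(a1$pixels) <= 255)
  a3 <- augment(t, seed = 78)
  expect_false(identical(a1$pixels, a3$pixels))
})

test_that("split plan reproduces the forced 10-slide partition", {
  ids <- sprintf("s%02d", 1:10)
  labels <- rep(c(0, 1), each = 5)
  plan <- make_split(ids, labels, seed = 3)
  expect_identical(sum(plan$split == "train"), 8L)
  expect_identical(sum(plan$split == "test"), 2L)
  # stratified test set: one per class
  expect_identical(sort(plan$label[plan$split == "test"]), c(0L, 1L))
  sizes <- sort(as.integer(table(plan$fold[plan$split == "train"])))
  expect_identical(sizes, c(1L, 1L, 2L, 2L, 2L))
})

test_that("folds partition the training slides and the plan is deterministic", {
  set.seed(1)
  ids <- sprintf("s%02d", 1:37)
  labels <- rbinom(37, 1, 0.4)
  if (min(table(labels)) < 5) labels[1:5] <- 1 - labels[1]
  plan <- make_split(ids, labels, seed = 12)
  train <- plan[plan$split == "train", ]
  expect_true(all(!is.na(train$fold)))
  expect_true(all(is.na(plan$fold[plan$split == "test"])))
  expect_true(all(train$fold %in% 0:4))
  expect_identical(make_split(ids, labels, seed = 12), plan)
  expect_false(identical(make_split(ids, labels, seed = 13)$split, plan$split))
})

test_that("split errors on too few slides or an unstratifiable class", {
  expect_error(make_split(1:8, rep(0:1, 4)), "at least 10")
  expect_error(make_split(1:12, c(rep(0, 9), rep(1, 3))), "stratification")
})
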