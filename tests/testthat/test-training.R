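small_dataset <- function(seed, n_bags = 60, signal_shift = 3, d = 8,
                          bag_size = 20) {
  gen_feature_bags(bag_config(n_bags, bag_size, d, witness_rate = 0.15,
                              signal_shift = signal_shift, seed = seed))
}

test_that("zero learning rate is a fixed point of training", {
  ds <- small_dataset(1)
  cfg <- train_config(learning_rate = 0, iterations = 20L, batch_bags = 8L,
                      attn_dim = 8L, hidden = 8L, seed = 5)
  fit <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, cfg)
  init <- init_abmil(8, attn_dim = 8L, hidden = 8L, seed = cfg$seed)
  expect_identical(param_vector(fit$params), param_vector(init))
})

test_that("training is deterministic given the configuration seed", {
  ds <- small_dataset(2)
  cfg <- train_config(iterations = 30L, batch_bags = 16L, attn_dim = 8L,
                      hidden = 8L, seed = 9)
  f1 <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, cfg)
  f2 <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, cfg)
  expect_identical(param_vector(f1$params), param_vector(f2$params))
  expect_identical(f1$loss_trace, f2$loss_trace)
  cfg2 <- cfg; cfg2$seed <- 10L
  f3 <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, cfg2)
  expect_false(identical(param_vector(f1$params), param_vector(f3$params)))
})

test_that("loss decreases on linearly separable bags over three seeds", {
  for (seed in 1:3) {
    ds <- small_dataset(seed, signal_shift = 3)
    fit <- train_single_scale(ds$bags, ds$ground_truth$bag_labels,
                              train_config(seed = seed, attn_dim = 32L,
                                           hidden = 32L))
    smoothed <- function(i) mean(fit$loss_trace[pmax(1, i - 9):i])
    expect_lt(smoothed(500), smoothed(10))
  }
})

test_that("degenerate training inputs raise training errors", {
  ds <- small_dataset(3)
  one_class <- which(ds$ground_truth$bag_labels == 1L)
  expect_error(train_single_scale(ds$bags[one_class],
                                  ds$ground_truth$bag_labels[one_class],
                                  train_config(iterations = 2L)),
               "both classes")
  bags <- ds$bags
  bags[[1]] <- matrix(numeric(0), 0, 8)
  expect_warning(
    train_single_scale(bags, ds$ground_truth$bag_labels,
                       train_config(iterations = 2L, batch_bags = 4L,
                                    attn_dim = 4L, hidden = 4L)),
    "empty bag")
})

test_that("cross-validation validates every bag exactly once and picks the max", {
  ds <- small_dataset(4, n_bags = 40)
  labels <- ds$ground_truth$bag_labels
  set.seed(11)
  folds <- integer(40)
  for (cl in 0:1) {
    idx <- sample(which(labels == cl))
    folds[idx] <- (seq_along(idx) - 1L) %% 5L
  }
  cfg <- train_config(iterations = 40L, batch_bags = 16L, attn_dim = 8L,
                      hidden = 8L, seed = 2)
  cv <- cross_validate(ds$bags, labels, folds, cfg)
  expect_identical(nrow(cv$fold_metrics), 5L)
  expect_identical(sum(cv$fold_metrics$n_val), 40L)
  expect_identical(cv$best_val_auc, max(cv$fold_metrics$val_auc, na.rm = TRUE))
  expect_s3_class(cv$best_params, "abmil_params")
})

test_that("a single-class validation fold is skipped with a warning", {
  ds <- small_dataset(5, n_bags = 30)
  labels <- ds$ground_truth$bag_labels
  folds <- rep(1:4, length.out = 30)
  folds[labels == 1L][1] <- 0L
  folds[folds == 0L & labels == 0L] <- 1L  # fold 0 now pure positive
  cfg <- train_config(iterations = 20L, batch_bags = 8L, attn_dim = 4L,
                      hidden = 4L, seed = 3)
  expect_warning(cv <- cross_validate(ds$bags, labels, folds, cfg),
                 "single class")
  expect_true(cv$fold_metrics$skipped[cv$fold_metrics$fold == 0])
  expect_true(is.na(cv$fold_metrics$val_auc[cv$fold_metrics$fold == 0]))
})

test_that("train_all_scales yields one model per magnification on shared folds", {
  ms <- gen_multiscale_feature_bags(bag_config(30, 10, 6, signal_shift = 2,
                                               seed = 6))
  labels <- ms$ground_truth$bag_labels
  folds <- rep(0:4, length.out = 30)
  cfg <- train_config(iterations = 25L, batch_bags = 8L, attn_dim = 4L,
                      hidden = 4L, seed = 4)
  cvs <- train_all_scales(ms$bags_by_scale, labels, folds, cfg)
  expect_named(cvs, c("20x", "10x", "5x"))
  for (cv in cvs) expect_s3_class(cv$best_params, "abmil_params")
  expect_error(train_all_scales(ms$bags_by_scale[c("20x", "5x")], labels,
                                folds, cfg),
               "missing magnification.*10x")
})

test_that("stronger weight decay shrinks the parameter norm (3 seeds)", {
  for (seed in 1:3) {
    ds <- small_dataset(seed + 20, n_bags = 40)
    base <- train_config(iterations = 150L, batch_bags = 16L, attn_dim = 8L,
                         hidden = 8L, seed = seed, weight_decay = 0,
                         learning_rate = 1e-3)
    heavy <- base; heavy$weight_decay <- 1e-2
    f0 <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, base)
    f1 <- train_single_scale(ds$bags, ds$ground_truth$bag_labels, heavy)
    expect_lt(sqrt(sum(param_vector(f1$params)^2)),
              sqrt(sum(param_vector(f0$params)^2)))
  }
})

test_that("best cross-validated model recovers a strong planted signal", {
  # n_bags = 200, bag_size = 30, d = 16, witness rate 0.1, shift >= 3
  for (seed in 1:3) {
    tr <- gen_feature_bags(bag_config(200, 30, 16, witness_rate = 0.1,
                                      signal_shift = 3, seed = seed))
    labels <- tr$ground_truth$bag_labels
    plan <- make_split(sprintf("b%03d", 1:200), labels, seed = seed,
                       test_fraction = 0.001)  # folds over (almost) all bags
    keep <- plan$split == "train"
    cv <- cross_validate(tr$bags[keep], labels[keep], plan$fold[keep],
                         train_config(seed = seed))
    expect_gte(cv$best_val_auc, 0.9)
  }
})
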