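#' Default pipeline configuration
#'
#' The composite pipeline runs simulate -> tile -> train -> predict ->
#' evaluate. A single global seed fans out to per-stage seeds (stage name
#' hashed) so every stage is independently reproducible. Either a synthetic
#' slide specification (`synthetic`), a synthetic feature-bag specification
#' (`feature_bags`), or an on-disk image manifest (`input_manifest`) names
#' the input.
#'
#' @param seed global run seed.
#' @param out_dir output directory for all artifacts.
#' @param synthetic list of [slide_config()] arguments (image mode), or
#'   `NULL`.
#' @param feature_bags list of [bag_config()] arguments (feature mode), or
#'   `NULL`.
#' @param input_manifest path to an existing slide manifest, or `NULL`.
#' @param tile_size tile side length.
#' @param entropy_threshold background filter cut in bits.
#' @param encoder list: `kind` (`"small-conv"` or `"passthrough"`), `d`.
#' @param train list of [train_config()] overrides.
#' @param threshold decision threshold on the ensemble probability.
#' @param bootstrap_B bootstrap replicates for the evaluation CIs.
#' @return a named configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("attmil-run-"),
                            synthetic = list(n_slides = 12L, base_size = 896L,
                                             lesion_fraction = 0.25,
                                             background_kind = "tissue-texture",
                                             pos_fraction = 0.5),
                            feature_bags = NULL, input_manifest = NULL,
                            tile_size = 224L, entropy_threshold = 5.0,
                            encoder = list(kind = "small-conv", d = 64L),
                            train = list(), threshold = 0.5,
                            bootstrap_B = 500L) {
  list(seed = as.integer(seed), out_dir = out_dir, synthetic = synthetic,
       feature_bags = feature_bags, input_manifest = input_manifest,
       tile_size = as.integer(tile_size),
       entropy_threshold = entropy_threshold, encoder = encoder,
       train = train, threshold = threshold,
       bootstrap_B = as.integer(bootstrap_B))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  # a YAML naming feature bags or a manifest replaces the synthetic default
  if (!("synthetic" %in% names(raw)) &&
      (!is.null(cfg$feature_bags) || !is.null(cfg$input_manifest))) {
    cfg$synthetic <- NULL
  }
  cfg
}

validate_config <- function(config) {
  for (f in c("seed", "out_dir")) {
    if (is.null(config[[f]])) {
      stop("configuration validation error: missing required field '", f, "'")
    }
  }
  n_inputs <- sum(!vapply(config[c("synthetic", "feature_bags",
                                   "input_manifest")], is.null, logical(1)))
  if (n_inputs != 1L) {
    stop("configuration validation error: exactly one of 'synthetic', ",
         "'feature_bags', 'input_manifest' must be set")
  }
  invisible(config)
}

log_stage <- function(stage, what, t0 = NULL) {
  dur <- if (is.null(t0)) "" else sprintf(" [%.1fs]",
                                          as.numeric(Sys.time()) - t0)
  message(sprintf("[attmil] %-9s %s%s", stage, what, dur))
}

# tile + filter + normalize + encode one image-mode dataset
featurize_slides <- function(slides, plan, config, enc) {
  scales <- c("20x", "10x", "5x")
  tiles_all <- lapply(slides, function(s) {
    lapply(stats::setNames(scales, scales), function(mag) {
      filter_background(
        tile_image(s$images[[mag]], config$tile_size, magnification = mag),
        config$entropy_threshold)
    })
  })
  manifest_rows <- list()
  for (i in seq_along(slides)) {
    for (mag in scales) {
      tl <- tiles_all[[i]][[mag]]
      if (length(tl) > 0L) {
        manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
          slide_id = slides[[i]]$slide_id, magnification = mag,
          grid_x = vapply(tl, `[[`, integer(1), "grid_x"),
          grid_y = vapply(tl, `[[`, integer(1), "grid_y"),
          entropy_bits = vapply(tl, `[[`, numeric(1), "entropy_bits"),
          retained = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  train_idx <- which(plan$split == "train")
  train_tiles <- unlist(lapply(train_idx, function(i) {
    unlist(tiles_all[[i]], recursive = FALSE)
  }), recursive = FALSE)
  if (length(train_tiles) == 0L) stop("no retained training tiles")
  stats <- fit_normalization(train_tiles)
  bags_by_scale <- lapply(stats::setNames(scales, scales), function(mag) {
    lapply(seq_along(slides), function(i) {
      tl <- tiles_all[[i]][[mag]]
      if (length(tl) == 0L) return(matrix(numeric(0), 0L, enc$d))
      tl <- lapply(tl, apply_normalization, stats = stats)
      encode_bag(tl, enc)
    })
  })
  list(bags_by_scale = bags_by_scale,
       tiles_manifest = do.call(rbind, manifest_rows),
       norm_stats = stats)
}

#' Run the full weakly supervised slide-classification pipeline
#'
#' Executes simulate -> tile -> train -> predict -> evaluate (feature-bag
#' mode skips tiling and encoding), writing every artifact under
#' `config$out_dir`: the slide/bag dataset, a tiles manifest, one checkpoint
#' per magnification, `predictions.csv`, `metrics.csv` and a JSON run
#' manifest. Re-running with the same seed reproduces the prediction CSV
#' byte for byte.
#'
#' @param config a [pipeline_config()] list or the path to a YAML file.
#' @return list with `plan`, `predictions` (data.frame), `report`
#'   (`eval_report`), `manifest` (run-manifest list), `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(out_dir = config$out_dir)
  scales <- c("20x", "10x", "5x")

  # --- simulate / load -------------------------------------------------
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$feature_bags)) {
    fb_cfg <- do.call(bag_config, c(config$feature_bags,
                                    list(seed = derive_seed(config$seed,
                                                            "simulate"))))
    sim <- gen_multiscale_feature_bags(fb_cfg)
    slide_ids <- sprintf("bag_%04d", seq_len(fb_cfg$n_bags))
    labels <- sim$ground_truth$bag_labels
    bags_by_scale <- sim$bags_by_scale
    paths$bags <- write_feature_bags(bags_by_scale[["20x"]], labels,
                                     file.path(config$out_dir, "bags"))
    log_stage("simulate", sprintf("%d feature bags (d = %d)", fb_cfg$n_bags,
                                  fb_cfg$feature_dim), t0)
  } else {
    if (!is.null(config$synthetic)) {
      sl_cfg <- do.call(slide_config, c(config$synthetic,
                                        list(seed = derive_seed(config$seed,
                                                                "simulate"))))
      pyr <- gen_slide_pyramids(sl_cfg)
      paths$slides <- write_slide_dataset(pyr, file.path(config$out_dir,
                                                         "slides"))
    } else {
      pyr <- read_slide_dataset(config$input_manifest)
      paths$slides <- config$input_manifest
    }
    slide_ids <- vapply(pyr$slides, `[[`, character(1), "slide_id")
    labels <- vapply(pyr$slides, function(s) as.integer(s$label), integer(1))
    log_stage("simulate", sprintf("%d slides", length(slide_ids)), t0)
  }

  # --- split ------------------------------------------------------------
  plan <- make_split(slide_ids, labels, seed = derive_seed(config$seed,
                                                           "split"))
  log_stage("split", sprintf("%d train / %d test slides",
                             sum(plan$split == "train"),
                             sum(plan$split == "test")))

  # --- tile + encode (image mode only) ----------------------------------
  if (is.null(config$feature_bags)) {
    t0 <- as.numeric(Sys.time())
    enc <- if (identical(config$encoder$kind, "passthrough")) {
      encoder_passthrough(config$encoder$d)
    } else {
      encoder_smallconv(d = config$encoder$d %||% 64L,
                        seed = derive_seed(config$seed, "encoder"))
    }
    feat <- featurize_slides(pyr$slides, plan, config, enc)
    bags_by_scale <- feat$bags_by_scale
    paths$tiles_manifest <- file.path(config$out_dir, "tiles_manifest.csv")
    utils::write.csv(feat$tiles_manifest, paths$tiles_manifest,
                     row.names = FALSE)
    log_stage("tile", sprintf("%d tiles retained",
                              nrow(feat$tiles_manifest)), t0)
    # drop slides that lost every tile at some magnification
    empty <- vapply(seq_along(slide_ids), function(i) {
      any(vapply(scales, function(sc) nrow(bags_by_scale[[sc]][[i]]) == 0L,
                 logical(1)))
    }, logical(1))
    if (any(empty)) {
      warning(sum(empty), " slide(s) with an empty bag excluded: ",
              paste(slide_ids[empty], collapse = ", "))
      keep <- !empty
      slide_ids <- slide_ids[keep]; labels <- labels[keep]
      plan <- plan[keep, ]
      bags_by_scale <- lapply(bags_by_scale, function(b) b[keep])
    }
  }

  # --- train ------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  tc <- do.call(train_config, c(config$train,
                                list(seed = derive_seed(config$seed,
                                                        "train"))))
  is_train <- plan$split == "train"
  train_bags <- lapply(bags_by_scale, function(b) b[is_train])
  cv <- train_all_scales(train_bags, labels[is_train], plan$fold[is_train],
                         tc)
  models <- lapply(cv, `[[`, "best_params")
  paths$checkpoints <- vapply(scales, function(sc) {
    save_checkpoint(models[[sc]],
                    file.path(config$out_dir, sprintf("model_%s.rds", sc)),
                    magnification = sc, seed = tc$seed)
  }, character(1))
  log_stage("train", sprintf("3 scales x 5-fold CV; best val AUC %s",
                             paste(sprintf("%s=%.3f", scales,
                                           vapply(cv, `[[`, numeric(1),
                                                  "best_val_auc")),
                                   collapse = " ")), t0)

  # --- predict ----------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  is_test <- plan$split == "test"
  test_bags <- lapply(bags_by_scale, function(b) b[is_test])
  predictions <- predict_slides(test_bags, models,
                                slide_ids = slide_ids[is_test],
                                labels = labels[is_test],
                                threshold = config$threshold)
  paths$predictions <- file.path(config$out_dir, "predictions.csv")
  utils::write.csv(format(predictions, digits = 15), paths$predictions,
                   row.names = FALSE, quote = FALSE)
  log_stage("predict", sprintf("%d test slides", nrow(predictions)), t0)

  # --- evaluate ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  report <- evaluate_predictions(predictions$p_ensemble,
                                 predictions$pred_label,
                                 predictions$label,
                                 B = config$bootstrap_B,
                                 seed = derive_seed(config$seed, "evaluate"))
  metrics <- data.frame(
    metric = c("auc", "accuracy", "fpr", "fnr"),
    point = vapply(c("auc", "accuracy", "fpr", "fnr"), function(m)
      report[[m]], numeric(1)),
    ci_lo = vapply(report$ci, `[[`, numeric(1), 1L),
    ci_hi = vapply(report$ci, `[[`, numeric(1), 2L))
  paths$metrics <- file.path(config$out_dir, "metrics.csv")
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  log_stage("evaluate", sprintf("AUC %.3f accuracy %.3f", report$auc,
                                report$accuracy), t0)

  # --- run manifest -----------------------------------------------------
  manifest <- list(
    run_id = sprintf("run-seed-%d", config$seed),
    version = as.character(utils::packageVersion("attmil")),
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(
      c("simulate", "split", "encoder", "train", "evaluate"),
      c("simulate", "split", "encoder", "train", "evaluate")),
      function(s) derive_seed(config$seed, s)),
    config = config[setdiff(names(config), "out_dir")],
    paths = paths)
  paths$manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(plan = plan, predictions = predictions, report = report,
       manifest = manifest, paths = paths, models = models, cv = cv)
}
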