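#' Write a synthetic slide dataset to disk
#'
#' One PNG per magnification per slide plus a plain-text manifest
#' (`manifest.csv`: slide_id, label, path_20x, path_10x, path_5x with paths
#' relative to the manifest).
#'
#' @param pyramids output of [gen_slide_pyramids()].
#' @param dir output directory (created if needed).
#' @return path to the manifest file.
#' @export
write_slide_dataset <- function(pyramids, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(pyramids$slides, function(s) {
    paths <- vapply(names(s$images), function(mag) {
      p <- sprintf("%s_%s.png", s$slide_id, mag)
      png::writePNG(s$images[[mag]] / 255, file.path(dir, p))
      p
    }, character(1))
    data.frame(slide_id = s$slide_id, label = s$label,
               path_20x = paths[["20x"]], path_10x = paths[["10x"]],
               path_5x = paths[["5x"]], stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

#' Read a slide dataset written by [write_slide_dataset()]
#'
#' @param manifest path to `manifest.csv`.
#' @return list as produced by [gen_slide_pyramids()] (without ground-truth
#'   lesion masks): `slides`, each with `slide_id`, `label`, `images` on the
#'   0..255 scale.
#' @export
read_slide_dataset <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  slides <- lapply(seq_len(nrow(tab)), function(i) {
    imgs <- lapply(c("20x" = "path_20x", "10x" = "path_10x", "5x" = "path_5x"),
                   function(col) png::readPNG(file.path(base, tab[[col]][i])) * 255)
    list(slide_id = tab$slide_id[i], label = tab$label[i], images = imgs)
  })
  list(slides = slides,
       ground_truth = list(slide_labels = tab$label, lesion_mask = NULL))
}

#' Write feature bags as one matrix file per bag plus a labels table
#'
#' @param bags list of instance-feature matrices.
#' @param labels 0/1 bag labels.
#' @param dir output directory.
#' @param encoder_id provenance string recorded in the metadata sidecar.
#' @return path to `labels.csv` (columns bag_id, label, path).
#' @export
write_feature_bags <- function(bags, labels, dir, encoder_id = "passthrough") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("bag_%04d", seq_along(bags))
  paths <- paste0(ids, ".csv")
  for (i in seq_along(bags)) {
    utils::write.csv(as.data.frame(bags[[i]]), file.path(dir, paths[i]),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(encoder = encoder_id, d = ncol(bags[[1]]), n_bags = length(bags)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(bag_id = ids, label = as.integer(labels), path = paths,
               stringsAsFactors = FALSE),
    labels_path, row.names = FALSE)
  labels_path
}

#' Read feature bags written by [write_feature_bags()]
#'
#' @param labels_path path to `labels.csv`.
#' @return list with `bags`, `labels`, `meta`.
#' @export
read_feature_bags <- function(labels_path) {
  tab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  base <- dirname(labels_path)
  bags <- lapply(tab$path, function(p) {
    as.matrix(utils::read.csv(file.path(base, p)))
  })
  meta_path <- file.path(base, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  list(bags = bags, labels = tab$label, meta = meta)
}

#' Save / load a model checkpoint with a plain-text sidecar
#'
#' The parameters are serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the shape metadata, magnification and seed so a
#' checkpoint is self-describing.
#'
#' @param params an `abmil_params`.
#' @param path checkpoint file path.
#' @param magnification magnification tag (optional).
#' @param seed training seed (optional).
#' @return `save_checkpoint`: the path, invisibly.
#' @export
save_checkpoint <- function(params, path, magnification = NA_character_,
                            seed = NA_integer_) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(params, path)
  jsonlite::write_json(
    list(d = params$d, attn_dim = params$attn_dim, hidden = params$hidden,
         magnification = magnification, seed = seed,
         version = as.character(utils::packageVersion("attmil"))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the `abmil_params`.
#' @export
load_checkpoint <- function(path) readRDS(path)
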