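#' Multi-scale ensemble prediction for one slide
#'
#' Runs the per-magnification models on the slide's bags in evaluation mode
#' and mean-pools the three positive-class probabilities into one slide-level
#' risk — the "consultation" strategy of combining magnifications the way a
#' pathologist zooms in and out. The ensemble probability is the arithmetic
#' mean, hence always within the range of the per-scale probabilities.
#'
#' @param bags_by_scale named list of instance-feature matrices for this
#'   slide, one per magnification.
#' @param models named list of trained `abmil_params`, one per magnification.
#' @param threshold decision threshold on the ensemble probability
#'   (default 0.5).
#' @param scales magnifications to ensemble.
#' @param missing_scale `"error"` (default) aborts if any magnification is
#'   absent; `"mean-available"` averages over the available ones and flags
#'   the slide.
#' @param slide_id optional identifier carried into the output.
#' @return list of class `slide_prediction`: `slide_id`, per-scale positive
#'   probabilities (`p_20x`, `p_10x`, `p_5x`; `NA` when absent and
#'   tolerated), `p_ensemble`, `pred_label`, `incomplete` flag.
#' @export
predict_slide <- function(bags_by_scale, models, threshold = 0.5,
                          scales = c("20x", "10x", "5x"),
                          missing_scale = c("error", "mean-available"),
                          slide_id = NA_character_) {
  missing_scale <- match.arg(missing_scale)
  have <- intersect(scales, intersect(names(bags_by_scale), names(models)))
  absent <- setdiff(scales, have)
  if (length(absent) > 0L && missing_scale == "error") {
    stop("missing magnification(s) for prediction: ",
         paste(absent, collapse = ", "))
  }
  if (length(have) == 0L) stop("no magnification available for prediction")
  p <- stats::setNames(rep(NA_real_, length(scales)), scales)
  for (sc in have) {
    p[sc] <- forward_bag(bags_by_scale[[sc]], models[[sc]], mode = "eval")$p[2]
  }
  p_ens <- mean(p[have])
  structure(list(
    slide_id = slide_id,
    p_20x = p[["20x"]], p_10x = p[["10x"]], p_5x = p[["5x"]],
    p_ensemble = p_ens,
    pred_label = as.integer(p_ens >= threshold),
    incomplete = length(absent) > 0L
  ), class = "slide_prediction")
}

#' Ensemble predictions for a set of slides
#'
#' @param bags_by_scale named list (per magnification) of bag lists, aligned
#'   across scales.
#' @param models named list of trained `abmil_params` per magnification.
#' @param slide_ids identifiers, one per slide.
#' @param labels optional true labels appended to the output.
#' @inheritParams predict_slide
#' @return data.frame with columns `slide_id`, `p_5x`, `p_10x`, `p_20x`,
#'   `p_ensemble`, `pred_label` (and `label` when given).
#' @export
predict_slides <- function(bags_by_scale, models, slide_ids = NULL,
                           labels = NULL, threshold = 0.5,
                           scales = c("20x", "10x", "5x"),
                           missing_scale = c("error", "mean-available")) {
  missing_scale <- match.arg(missing_scale)
  n <- length(bags_by_scale[[1]])
  if (is.null(slide_ids)) slide_ids <- sprintf("slide_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    one <- lapply(bags_by_scale, `[[`, i)
    pr <- predict_slide(one, models, threshold, scales, missing_scale,
                        slide_id = slide_ids[i])
    data.frame(slide_id = pr$slide_id, p_5x = pr$p_5x, p_10x = pr$p_10x,
               p_20x = pr$p_20x, p_ensemble = pr$p_ensemble,
               pred_label = pr$pred_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out$label <- as.integer(labels)
  out
}
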