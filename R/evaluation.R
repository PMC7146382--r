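# Pixelwise evaluation: confusion counts, Dice similarity coefficient,
# sensitivity, specificity, and corpus-level macro averages.

#' Pixelwise confusion counts between predicted and reference masks
#'
#' The positive class is "nest".
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_contract("confusion: mask shapes differ")
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  tibble(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
         tn = sum(!p & !t))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)`, identical to the set form
#' `2|X intersect Y| / (|X| + |Y|)`.  When both masks are empty (no nest
#' pixels anywhere) the coefficient is defined as 1.
#'
#' @param counts A [confusion()] row (or any list with `tp`, `fp`, `fn`).
#' @return DSC in `[0, 1]`.
#' @examples
#' dsc(list(tp = 2, fp = 1, fn = 1))  # 2*2 / (4 + 1 + 1)
#' @export
dsc <- function(counts) {
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) return(1.0)
  2 * counts$tp / denom
}

#' Sensitivity (true-positive rate over nest pixels)
#'
#' `SEN = TP / (TP + FN)`; defined as 1 (with a warning) when the
#' reference contains no positive pixels.
#'
#' @param counts A [confusion()] row.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    warn("no positive reference pixels; sensitivity defined as 1")
    return(1.0)
  }
  counts$tp / (counts$tp + counts$fn)
}

#' Specificity (true-negative rate over background pixels)
#'
#' `SPE = TN / (TN + FP)`; defined as 1 (with a warning) when the
#' reference contains no background pixels.
#'
#' @param counts A [confusion()] row.
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0) {
    warn("no negative reference pixels; specificity defined as 1")
    return(1.0)
  }
  counts$tn / (counts$tn + counts$fp)
}

#' Evaluate a segmentation model on labeled images
#'
#' Predicts a mask for every labeled image and computes pixelwise
#' confusion counts and DSC / sensitivity / specificity per image; the
#' summary is the unweighted per-image mean (macro average).  A pooled
#' (pixel-weighted) summary is available via `pooled = TRUE`.
#'
#' @param model A segmentation-variant `cae_model`.
#' @param images List of `slide_image`s; unlabeled ones are dropped.
#' @param stride,threshold Passed to [predict_mask()].
#' @param pooled Also attach metrics computed over pooled pixel counts.
#' @param predict_fn Predictor override, mainly for testing: a
#'   `function(image)` returning an HxW 0/1 mask.  Defaults to the model.
#' @return `seg_evaluation` tibble: one row per image (`image_id`, counts,
#'   metrics) with a `macro` attribute holding the averages.
#' @export
evaluate_corpus <- function(model, images, stride = 128L, threshold = 0.5,
                            pooled = FALSE, predict_fn = NULL) {
  labeled <- purrr::keep(images, function(s) isTRUE(s$labeled))
  if (length(labeled) == 0) stop_data("no labeled images to evaluate")
  predict_fn <- predict_fn %||%
    function(img) predict_mask(model, img, stride, threshold)$mask
  rows <- purrr::map(labeled, function(img) {
    cm <- confusion(predict_fn(img), img$mask)
    dplyr::mutate(cm, image_id = img$image_id, dsc = dsc(cm),
                  sensitivity = sensitivity(cm), specificity = specificity(cm),
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "image_id", "tp", "fp", "fn", "tn", "dsc",
                       "sensitivity", "specificity")
  macro <- tibble(
    n_images = nrow(out),
    dsc = mean(out$dsc),
    sensitivity = mean(out$sensitivity),
    specificity = mean(out$specificity)
  )
  if (pooled) {
    tot <- as.list(colSums(out[, c("tp", "fp", "fn", "tn")]))
    macro$dsc_pooled <- dsc(tot)
    macro$sensitivity_pooled <- sensitivity(tot)
    macro$specificity_pooled <- specificity(tot)
  }
  attr(out, "macro") <- macro
  class(out) <- c("seg_evaluation", class(out))
  out
}

#' Write an evaluation report CSV (per-image rows plus a summary row)
#'
#' @param evaluation A [evaluate_corpus()] result.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(evaluation, path) {
  macro <- attr(evaluation, "macro")
  summary_row <- tibble(image_id = "macro_average",
                        tp = NA_integer_, fp = NA_integer_,
                        fn = NA_integer_, tn = NA_integer_,
                        dsc = macro$dsc, sensitivity = macro$sensitivity,
                        specificity = macro$specificity)
  readr::write_csv(dplyr::bind_rows(tibble::as_tibble(evaluation), summary_row),
                   path)
  invisible(path)
}
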