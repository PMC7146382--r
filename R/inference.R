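# Whole-image inference: tile an arbitrary-size image into 128x128
# patches, predict per-patch probability maps, stitch them back (mean over
# overlaps) and binarize at the threshold.

#' Tile an image into 128x128 patches for inference
#'
#' Tiles are placed on a `stride` grid over a reflect-padded canvas so
#' every pixel is covered at least once.
#'
#' @param image A `slide_image` (or an HxWx3 array).
#' @param stride Tile stride in `[1, 128]`; 128 means non-overlapping.
#' @return Tibble with `row`, `col` (0-based origins on the padded canvas)
#'   and a `tile` list-column of 128x128x3 arrays; attributes
#'   `canvas_shape` and `image_shape`.
#' @export
tile_image <- function(image, stride = 128L) {
  rgb <- if (inherits(image, "slide_image")) image$rgb else image
  if (stride < 1 || stride > 128) stop_config("'stride' must be in [1, 128]")
  ps <- 128L
  H <- nrow(rgb); W <- ncol(rgb)
  Hp <- pad_for_grid(H, ps, stride)
  Wp <- pad_for_grid(W, ps, stride)
  padded <- reflect_pad_rgb(rgb, Hp, Wp)
  origins <- expand.grid(row = seq.int(0L, Hp - ps, by = stride),
                         col = seq.int(0L, Wp - ps, by = stride))
  tiles <- purrr::pmap(origins, function(row, col) {
    padded[(row + 1):(row + ps), (col + 1):(col + ps), , drop = FALSE]
  })
  out <- tibble(row = as.integer(origins$row), col = as.integer(origins$col),
                tile = tiles)
  attr(out, "canvas_shape") <- c(Hp, Wp)
  attr(out, "image_shape") <- c(H, W)
  out
}

#' Stitch probability tiles back into a full-image map
#'
#' Overlapping pixels receive the mean of all contributing tiles; the
#' padded margin is cropped away.  For a non-overlapping tiling this is an
#' exact reassembly.
#'
#' @param tiles Tibble with `row`, `col` and a list-column of 128x128
#'   probability matrices (column name `tile` or `prob`).
#' @param canvas_shape `c(Hp, Wp)` of the padded canvas (defaults to the
#'   tiles' attribute).
#' @param image_shape `c(H, W)` to crop to (defaults to the canvas).
#' @return `probability_map`: an HxW matrix in `[0, 1]` (attribute
#'   `source_id` if known).
#' @export
stitch <- function(tiles, canvas_shape = attr(tiles, "canvas_shape"),
                   image_shape = attr(tiles, "image_shape") %||% canvas_shape) {
  if (is.null(canvas_shape)) stop_contract("canvas_shape is required")
  vals <- tiles[["prob"]] %||% tiles[["tile"]]
  ps <- nrow(vals[[1]])
  acc <- matrix(0, canvas_shape[1], canvas_shape[2])
  cnt <- matrix(0L, canvas_shape[1], canvas_shape[2])
  for (i in seq_len(nrow(tiles))) {
    r <- tiles$row[i]; c <- tiles$col[i]
    rows <- (r + 1):(r + ps); cols <- (c + 1):(c + ps)
    acc[rows, cols] <- acc[rows, cols] + vals[[i]]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  if (any(cnt == 0)) stop_contract("tiling leaves uncovered pixels")
  out <- (acc / cnt)[seq_len(image_shape[1]), seq_len(image_shape[2]),
                     drop = FALSE]
  class(out) <- c("probability_map", class(out))
  out
}

#' Predict a whole-image nest mask
#'
#' Tiles the image, runs the segmentation model on every tile, stitches
#' the per-tile probability maps and thresholds them (`>=`, so a pixel at
#' exactly the threshold is positive).
#'
#' @param model A segmentation-variant `cae_model`.
#' @param image A `slide_image` or HxWx3 array.
#' @param stride Tile stride; 128 (non-overlapping) matches the training
#'   patch grid, smaller strides average overlapping predictions to soften
#'   patch-border artifacts.
#' @param threshold Probability threshold in (0, 1).
#' @param chunk Tiles per compute chunk.
#' @return List with `mask` (HxW 0/1 matrix, class `binary_mask`, with
#'   `threshold` attribute), `prob` (the `probability_map`) and
#'   `source_id`.
#' @export
predict_mask <- function(model, image, stride = 128L, threshold = 0.5,
                         chunk = 8L) {
  if (!inherits(model, "cae_model") ||
      model$architecture$variant != "segmentation") {
    stop_usage("predict_mask needs a segmentation-variant model")
  }
  if (threshold <= 0 || threshold >= 1) stop_config("'threshold' must be in (0, 1)")
  tiles <- tile_image(image, stride)
  n <- nrow(tiles)
  x <- array(unlist(tiles$tile, use.names = FALSE), c(128L, 128L, 3L, n))
  pr <- cae_forward(model, x, chunk = chunk)
  tiles$prob <- purrr::map(seq_len(n), function(i) pr[, , 1L, i])
  prob <- stitch(tiles)
  mask <- (unclass(prob) >= threshold) * 1L
  attr(mask, "threshold") <- threshold
  class(mask) <- c("binary_mask", class(mask))
  list(mask = mask,
       prob = prob,
       source_id = if (inherits(image, "slide_image")) image$image_id else NA_character_)
}

#' Write a prediction to disk
#'
#' The probability map is written as 32-bit single-channel TIFF and the
#' mask as a 0/255 PNG.
#'
#' @param prediction A [predict_mask()] result.
#' @param prob_path,mask_path Output paths (either may be `NULL`).
#' @export
write_prediction <- function(prediction, prob_path = NULL, mask_path = NULL) {
  if (!is.null(prob_path)) {
    tiff::writeTIFF(unclass(prediction$prob), prob_path,
                    bits.per.sample = 32L, reduce = TRUE)
  }
  if (!is.null(mask_path)) {
    png::writePNG(unclass(prediction$mask) * 1.0, mask_path)
  }
  invisible(prediction)
}
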