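# Image-level stratified splitting and 128x128 patch extraction with
# class-dependent stride.  Splitting always happens on whole images,
# before any patch is cut, so no tissue from a validation/test image can
# leak into the training patch set.

#' Patch-extraction configuration
#'
#' Background regions are scanned at `negative_stride` (no overlap by
#' default); wherever a window contains nest pixels the local 3x3 block of
#' grid cells is re-scanned at the finer `positive_stride`, producing
#' overlapping nest examples.  Nest patches are later rotated by
#' `augment_angles` to generate four more examples each, which together
#' with the overlap balances the two classes.
#'
#' @param patch_size Patch side in pixels.
#' @param negative_stride Grid stride for background regions.
#' @param positive_stride Finer stride used around nest-positive windows.
#' @param augment_angles Rotation angles (degrees, each in (0, 360)) used
#'   by [augment_patch()].
#' @param positive_rule Minimum number of mask-positive pixels for a patch
#'   to count as class "nest".
#' @return A `patch_config` object.
#' @export
patch_config <- function(patch_size = 128L,
                         negative_stride = 128L,
                         positive_stride = 64L,
                         augment_angles = c(45, 90, 135, 180),
                         positive_rule = 1L) {
  if (!(positive_stride >= 1 && positive_stride <= negative_stride &&
        negative_stride <= patch_size)) {
    stop_config("need 1 <= positive_stride <= negative_stride <= patch_size")
  }
  if (length(augment_angles) == 0 || any(augment_angles <= 0) ||
      any(augment_angles >= 360)) {
    stop_config("'augment_angles' must be nonempty, each angle in (0, 360)")
  }
  if (positive_rule < 1) stop_config("'positive_rule' must be >= 1")
  structure(
    list(patch_size = as.integer(patch_size),
         negative_stride = as.integer(negative_stride),
         positive_stride = as.integer(positive_stride),
         augment_angles = as.numeric(augment_angles),
         positive_rule = as.integer(positive_rule)),
    class = "patch_config"
  )
}

#' Stratified image-level train/validation/test split
#'
#' Images are assigned to splits by largest-remainder apportionment within
#' each stratum (labeled / unlabeled), so the labeled-to-unlabeled
#' proportion of every split matches the corpus proportion to within one
#' image.  The split is computed on images, never on patches.
#'
#' @param images List of `slide_image` objects.
#' @param fractions Numeric length-3 vector of train/validation/test
#'   proportions, summing to 1.
#' @param seed Integer seed for the within-stratum shuffle.
#' @return A `split_assignment` tibble with columns `image_id`, `labeled`,
#'   `split`.
#' @examples
#' \donttest{
#' corpus <- generate_corpus(10, 0.5, synth_params(image_height = 128,
#'   image_width = 128), seed = 1)
#' table(split_corpus(corpus, c(0.7, 0.15, 0.15), seed = 1)$split)
#' }
#' @export
split_corpus <- function(images, fractions = c(0.70, 0.143, 0.157), seed = 1L) {
  if (length(images) < 3L) stop_config("need at least 3 images to split")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_config("'fractions' must be 3 nonnegative proportions summing to 1")
  }
  n_nonzero <- sum(fractions > 0)
  if (length(images) < n_nonzero) {
    stop_config("fewer images (%d) than nonzero splits (%d)",
                length(images), n_nonzero)
  }
  ids <- purrr::map_chr(images, "image_id")
  if (anyDuplicated(ids)) stop_data("duplicate image_id in corpus")
  labeled <- purrr::map_lgl(images, "labeled")

  split_names <- c("train", "validation", "test")
  assign_stratum <- function(stratum_ids, shuffle_seed) {
    n <- length(stratum_ids)
    target <- n * fractions
    base <- floor(target)
    rem <- target - base
    extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
    counts <- base
    counts[extra] <- counts[extra] + 1
    shuffled <- withr::with_seed(shuffle_seed, sample(stratum_ids))
    setNames(rep(split_names, counts), shuffled)
  }
  lab_assign <- assign_stratum(ids[labeled], derive_seed(seed, "split-labeled"))
  unl_assign <- assign_stratum(ids[!labeled], derive_seed(seed, "split-unlabeled"))
  assignment <- c(lab_assign, unl_assign)[ids]

  out <- tibble(image_id = ids, labeled = labeled,
                split = factor(assignment, levels = split_names))
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_assignment", class(out))
  out
}

# reflect-pad an image (and mask) on the bottom/right so that a stride
# grid of patch-sized windows covers every pixel
pad_for_grid <- function(H, size, stride) {
  if (H < size) return(as.integer(size))
  as.integer(size + ceiling((H - size) / stride) * stride)
}

reflect_pad_br <- function(m, Hp, Wp) {
  H <- nrow(m); W <- ncol(m)
  if (Hp - H > H - 1 || Wp - W > W - 1) {
    stop_data("image %dx%d too small to reflect-pad to %dx%d", H, W, Hp, Wp)
  }
  ridx <- c(seq_len(H), seq.int(H - 1, by = -1, length.out = Hp - H))
  cidx <- c(seq_len(W), seq.int(W - 1, by = -1, length.out = Wp - W))
  m[ridx, cidx, drop = FALSE]
}

reflect_pad_rgb <- function(rgb, Hp, Wp) {
  out <- array(0, c(Hp, Wp, 3))
  for (c in 1:3) out[, , c] <- reflect_pad_br(rgb[, , c], Hp, Wp)
  out
}

#' Extract 128x128 patches from one slide with class-dependent stride
#'
#' The image is scanned on a `negative_stride` grid (reflect-padded on the
#' bottom/right so border tissue is kept).  Any grid window containing at
#' least `positive_rule` mask pixels triggers a re-scan of its 3x3
#' grid-cell neighborhood at `positive_stride`, producing overlapping nest
#' examples.  Unlabeled slides yield mask-less patches on the plain grid.
#'
#' @param image A `slide_image`.
#' @param config A [patch_config()].
#' @return Tibble with columns `source_id`, `row`, `col` (0-based origin),
#'   `positive`, `augmented`, and list-columns `rgb` (128x128x3 arrays)
#'   and `mask` (128x128 0/1 matrices or `NULL`).
#' @export
extract_patches <- function(image, config = patch_config()) {
  ps <- config$patch_size
  ns <- config$negative_stride
  H <- nrow(image$rgb); W <- ncol(image$rgb)
  Hp <- pad_for_grid(H, ps, ns)
  Wp <- pad_for_grid(W, ps, ns)
  rgb <- reflect_pad_rgb(image$rgb, Hp, Wp)
  mask <- NULL
  if (image$labeled) {
    if (!identical(dim(image$mask), c(H, W))) {
      stop_data("mask/rgb size mismatch for image '%s'", image$image_id)
    }
    mask <- reflect_pad_br(image$mask, Hp, Wp)
  }

  grid_rows <- seq.int(0L, Hp - ps, by = ns)
  grid_cols <- seq.int(0L, Wp - ps, by = ns)
  origins <- expand.grid(row = grid_rows, col = grid_cols)

  window_positive <- function(r, c) {
    sum(mask[(r + 1):(r + ps), (c + 1):(c + ps)]) >= config$positive_rule
  }

  if (!is.null(mask)) {
    pos_grid <- origins[mapply(window_positive, origins$row, origins$col), ,
                        drop = FALSE]
    if (nrow(pos_grid) > 0) {
      extras <- purrr::pmap(pos_grid, function(row, col) {
        rs <- seq.int(max(0L, row - ns), min(Hp - ps, row + ns),
                      by = config$positive_stride)
        cs <- seq.int(max(0L, col - ns), min(Wp - ps, col + ns),
                      by = config$positive_stride)
        expand.grid(row = rs, col = cs)
      })
      origins <- unique(rbind(origins, dplyr::bind_rows(extras)))
    }
  }
  origins <- origins[order(origins$row, origins$col), ]

  rows <- purrr::pmap(origins, function(row, col) {
    tile <- rgb[(row + 1):(row + ps), (col + 1):(col + ps), , drop = FALSE]
    mtile <- if (is.null(mask)) NULL else
      mask[(row + 1):(row + ps), (col + 1):(col + ps)]
    tibble(source_id = image$image_id, row = as.integer(row),
           col = as.integer(col),
           positive = !is.null(mtile) && sum(mtile) >= config$positive_rule,
           augmented = FALSE,
           rgb = list(tile), mask = list(mtile))
  })
  dplyr::bind_rows(rows)
}

# --- rotation ---------------------------------------------------------------

rot90_exact <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}

# bilinear (rgb) / nearest (mask) rotation about the patch center with
# reflected out-of-range sampling
rotate_free <- function(m, angle, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(rep(seq_len(H), W), H, W)
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  # source coordinates: rotate destination grid by -angle
  sy <- cy + cos(th) * (gy - cy) - sin(th) * (gx - cx)
  sx <- cx + sin(th) * (gy - cy) + cos(th) * (gx - cx)
  reflect_idx <- function(i, n) {
    i <- (i - 1) %% (2 * n - 2)
    ifelse(i >= n, 2 * n - 2 - i, i) + 1
  }
  if (nearest) {
    iy <- reflect_idx(round(sy), H)
    ix <- reflect_idx(round(sx), W)
    matrix(m[cbind(as.vector(iy), as.vector(ix))], H, W)
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    idx <- function(a, b) m[cbind(as.vector(reflect_idx(a, H)),
                                  as.vector(reflect_idx(b, W)))]
    v <- (1 - fy) * (1 - fx) * idx(y0, x0) +
         (1 - fy) * fx       * idx(y0, x0 + 1) +
         fy       * (1 - fx) * idx(y0 + 1, x0) +
         fy       * fx       * idx(y0 + 1, x0 + 1)
    matrix(v, H, W)
  }
}

rotate_patch_plane <- function(m, angle, nearest = FALSE) {
  a <- ((angle %% 360) + 360) %% 360
  if (a %% 90 == 0) rot90_exact(m, a %/% 90) else rotate_free(m, a, nearest)
}

#' Rotation augmentation of a nest patch
#'
#' Rotates a positive patch (image and mask) about its center by each
#' angle, yielding `length(angles)` additional examples (the default four).
#' Right-angle rotations are exact pixel permutations; other angles use
#' bilinear interpolation with reflected sampling for the image and
#' nearest-neighbor re-binarized at 0.5 for the mask.
#'
#' @param patch One row of an [extract_patches()] tibble (or an equivalent
#'   one-row tibble).
#' @param angles Rotation angles in degrees.
#' @param strict Error if the patch is not nest-positive (augmentation
#'   exists to balance the nest class).
#' @return Tibble of augmented patches, same columns as [extract_patches()].
#' @export
augment_patch <- function(patch, angles = c(45, 90, 135, 180), strict = TRUE) {
  p <- as.list(patch[1, ])
  if (strict && !isTRUE(p$positive)) {
    stop_usage("augmentation applies to nest-positive patches")
  }
  rows <- purrr::map(angles, function(a) {
    rgb <- p$rgb[[1]]
    rot <- array(0, dim(rgb))
    for (c in 1:3) rot[, , c] <- rotate_patch_plane(rgb[, , c], a)
    mt <- p$mask[[1]]
    if (!is.null(mt)) {
      mt <- (rotate_patch_plane(mt, a, nearest = TRUE) >= 0.5) * 1L
    }
    tibble(source_id = p$source_id, row = p$row, col = p$col,
           positive = p$positive, augmented = TRUE,
           rgb = list(clip01(rot)), mask = list(mt))
  })
  dplyr::bind_rows(rows)
}

#' Class balance of a patch set
#'
#' @param patches Patch tibble (possibly empty).
#' @return One-row tibble with `n_positive`, `n_negative` and their
#'   `ratio` (positive / negative).
#' @export
balance_report <- function(patches) {
  n_pos <- if (nrow(patches)) sum(patches$positive) else 0L
  n_neg <- if (nrow(patches)) sum(!patches$positive) else 0L
  tibble(n_positive = as.integer(n_pos), n_negative = as.integer(n_neg),
         ratio = n_pos / n_neg)
}

#' Extract (and augment) patches for a whole split corpus
#'
#' Applies [extract_patches()] to every image and joins the split
#' assignment; training-split nest patches additionally receive rotation
#' augmentation.
#'
#' @param corpus List of `slide_image` objects.
#' @param assignment A [split_corpus()] result.
#' @param config A [patch_config()].
#' @param augment Augment training-split positive patches?
#' @return Patch tibble with an extra `split` column.
#' @export
prepare_patches <- function(corpus, assignment, config = patch_config(),
                            augment = TRUE) {
  split_of <- setNames(as.character(assignment$split), assignment$image_id)
  all <- purrr::map(corpus, function(img) {
    patches <- extract_patches(img, config)
    patches$split <- split_of[[img$image_id]]
    patches
  })
  patches <- dplyr::bind_rows(all)
  if (augment) {
    pos_train <- dplyr::filter(patches, .data$split == "train", .data$positive)
    if (nrow(pos_train) > 0) {
      aug <- purrr::map(seq_len(nrow(pos_train)), function(i) {
        a <- augment_patch(pos_train[i, ], config$augment_angles)
        a$split <- "train"
        a
      })
      patches <- dplyr::bind_rows(patches, dplyr::bind_rows(aug))
    }
  }
  patches
}

#' Write a patch index CSV (origins and labels, not pixel data)
#'
#' @param patches Patch tibble from [prepare_patches()].
#' @param path Output CSV path.
#' @export
write_patch_index <- function(patches, path) {
  idx <- dplyr::select(patches, dplyr::any_of(
    c("source_id", "row", "col", "positive", "augmented", "split")))
  readr::write_csv(idx, path)
  invisible(idx)
}
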