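# Seeded generator of H&E-like images with nest-shaped cell clusters and
# exact binary ground-truth masks.  The generator emulates the *structure*
# the segmentation pipeline assumes -- eosin-pink textured stroma,
# hematoxylin-purple nuclei grouped into cohesive nests, variable image
# sizes, a mixed labeled/unlabeled corpus -- not the physical scale or
# optics of a real slide scanner.

#' Parameters of the synthetic H&E slide generator
#'
#' Defaults describe a small crop of an H&E-stained skin specimen: a pink
#' eosin background with low-frequency texture, and one to three nests,
#' each a cluster of dozens of purple nuclei whose union (after a
#' morphological closing that fills the small intercellular gaps) defines
#' the ground-truth mask.
#'
#' @param image_height,image_width Image dimensions in pixels (>= 128).
#' @param nest_count_range Integer range for the number of nests per image.
#' @param nest_radius_range Pixel range for the nest radius.
#' @param cells_per_nest_range Integer range for nuclei per nest.
#' @param cell_radius_range Pixel range for individual nucleus radii.
#' @param background_rgb_mean Mean eosin (stroma) color, components in `[0, 1]`.
#' @param nucleus_rgb_mean Mean hematoxylin (nucleus) color, components in `[0, 1]`.
#' @param color_jitter_sd Per-nucleus Gaussian color jitter (sd).
#' @param noise_sd I.i.d. Gaussian pixel noise (sd), clipped to `[0, 1]`.
#' @param labeled Should generated slides carry ground-truth masks?
#' @return A validated `synth_params` object.
#' @examples
#' p <- synth_params(image_height = 128, image_width = 128)
#' s <- generate_slide(p, seed = 1)
#' dim(s$rgb)
#' @export
synth_params <- function(image_height = 256,
                         image_width = 384,
                         nest_count_range = c(1, 3),
                         nest_radius_range = c(14, 26),
                         cells_per_nest_range = c(30, 80),
                         cell_radius_range = c(2, 4),
                         background_rgb_mean = c(0.91, 0.74, 0.82),
                         nucleus_rgb_mean = c(0.36, 0.25, 0.55),
                         color_jitter_sd = 0.04,
                         noise_sd = 0.02,
                         labeled = TRUE) {
  if (!is_scalar_number(image_height) || !is_scalar_number(image_width) ||
      image_height < 128 || image_width < 128) {
    stop_config("image dimensions must be numbers >= 128")
  }
  assert_range(nest_count_range, "nest_count_range", integer = TRUE)
  if (nest_count_range[1] < 0) stop_config("nest counts must be >= 0")
  assert_range(nest_radius_range, "nest_radius_range")
  assert_range(cells_per_nest_range, "cells_per_nest_range", integer = TRUE)
  assert_range(cell_radius_range, "cell_radius_range")
  for (nm in c("background_rgb_mean", "nucleus_rgb_mean")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(v < 0) || any(v > 1)) {
      stop_config("'%s' must be a 3-vector in [0, 1]", nm)
    }
  }
  if (!is_scalar_number(color_jitter_sd) || color_jitter_sd < 0 ||
      !is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_config("jitter and noise standard deviations must be >= 0")
  }
  structure(
    list(
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      nest_count_range = as.integer(nest_count_range),
      nest_radius_range = as.numeric(nest_radius_range),
      cells_per_nest_range = as.integer(cells_per_nest_range),
      cell_radius_range = as.numeric(cell_radius_range),
      background_rgb_mean = as.numeric(background_rgb_mean),
      nucleus_rgb_mean = as.numeric(nucleus_rgb_mean),
      color_jitter_sd = color_jitter_sd,
      noise_sd = noise_sd,
      labeled = isTRUE(labeled)
    ),
    class = "synth_params"
  )
}

# one slide-image container; mask is an integer 0/1 matrix or NULL
new_slide_image <- function(image_id, rgb, mask = NULL) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(rgb)[1:2])) {
      stop_data("mask dimensions %s do not match image %s",
                paste(dim(mask), collapse = "x"),
                paste(dim(rgb)[1:2], collapse = "x"))
    }
    if (!all(mask %in% c(0L, 1L))) stop_data("mask values must be 0/1")
  }
  structure(
    list(image_id = image_id, rgb = rgb, mask = mask,
         labeled = !is.null(mask)),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image '%s'> %dx%d, %s\n", x$image_id,
              nrow(x$rgb), ncol(x$rgb),
              if (x$labeled) {
                sprintf("labeled (%.1f%% nest pixels)", 100 * mean(x$mask))
              } else "unlabeled"))
  invisible(x)
}

# sample nest geometry: centers by rejection (centers may not approach
# closer than 80% of the sum of radii), cells as truncated-Gaussian spray
sample_nest_geometry <- function(params, H, W) {
  n_nests <- sample_range(params$nest_count_range, 1L, integer = TRUE)
  nests <- list()
  if (n_nests == 0) return(nests)
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  for (i in seq_len(n_nests)) {
    r <- sample_range(params$nest_radius_range)
    placed <- FALSE
    for (try in seq_len(200L)) {
      cy <- runif(1, r + 2, H - r - 1)
      cx <- runif(1, r + 2, W - r - 1)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >=
              0.8 * (radii + r))) {
        placed <- TRUE
        break
      }
    }
    if (!placed) next  # overcrowded image: keep fewer nests
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
    n_cells <- sample_range(params$cells_per_nest_range, 1L, integer = TRUE)
    # truncated gaussian spray keeps the cluster cohesive
    ang <- runif(n_cells, 0, 2 * pi)
    rad <- pmin(abs(rnorm(n_cells, 0, r / 2)), r - 1)
    nests[[length(nests) + 1L]] <- list(
      center = c(cy, cx), radius = r,
      cell_y = cy + rad * sin(ang),
      cell_x = cx + rad * cos(ang),
      cell_r = sample_range(params$cell_radius_range, n_cells)
    )
  }
  nests
}

# raster union of a nest's cell disks on the full canvas (0/1 matrix)
rasterize_cells <- function(nest, H, W) {
  m <- matrix(0L, H, W)
  for (i in seq_along(nest$cell_y)) {
    cy <- nest$cell_y[i]; cx <- nest$cell_x[i]; r <- nest$cell_r[i]
    ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
    xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    m[ys, xs] <- pmax(m[ys, xs], (d2 <= r^2) * 1L)
  }
  m
}

# ground-truth footprint: morphological closing of the cell-disk union,
# filling intercellular gaps; brush diameter tied to the cell scale
nest_footprint <- function(cells, params) {
  brush_size <- 2L * as.integer(ceiling(mean(params$cell_radius_range))) + 1L
  closed <- EBImage::closing(cells, EBImage::makeBrush(brush_size, "disc"))
  (closed > 0) * 1L
}

#' Generate one synthetic H&E-like slide image
#'
#' Renders nests of purple nuclei on a textured pink background.  The
#' ground-truth mask is exactly the union of the per-nest footprints (the
#' morphological closing of each nest's cell disks).  Identical
#' `(params, seed)` give bit-identical output.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer seed.
#' @param image_id Identifier stored with the slide.
#' @return A `slide_image`: list with `image_id`, `rgb` (HxWx3 array in
#'   `[0, 1]`), `mask` (HxW 0/1 matrix, labeled slides only), `labeled`.
#' @export
generate_slide <- function(params, seed,
                           image_id = sprintf("slide_%d", seed)) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  H <- params$image_height
  W <- params$image_width
  withr::with_seed(as.integer(seed), {
    nests <- sample_nest_geometry(params, H, W)

    # background: low-frequency multiplicative texture over the eosin mean
    tex <- matrix(rnorm(H * W), H, W)
    tex <- as.matrix(EBImage::gblur(tex, sigma = 8))
    tex <- 1 + 0.06 * tex / max(stats::sd(tex), 1e-8)
    rgb <- array(0, c(H, W, 3))
    for (c in 1:3) rgb[, , c] <- params$background_rgb_mean[c] * tex

    mask <- matrix(0L, H, W)
    for (nest in nests) {
      cells <- rasterize_cells(nest, H, W)
      fp <- nest_footprint(cells, params)
      mask <- pmax(mask, fp)
      # faint basophilic tint over the whole footprint (cytoplasm between
      # nuclei inside a nest is not plain stroma)
      tint <- c(0.62, 0.45, 0.65)
      for (c in 1:3) {
        ch <- rgb[, , c]
        ch[fp == 1] <- 0.7 * ch[fp == 1] + 0.3 * tint[c]
        rgb[, , c] <- ch
      }
      # individual nuclei with per-cell color jitter
      for (i in seq_along(nest$cell_y)) {
        col <- clip01(params$nucleus_rgb_mean + rnorm(3, 0, params$color_jitter_sd))
        cy <- nest$cell_y[i]; cx <- nest$cell_x[i]; r <- nest$cell_r[i]
        ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
        xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
        inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
        for (c in 1:3) {
          ch <- rgb[ys, xs, c]
          ch[inside] <- col[c]
          rgb[ys, xs, c] <- ch
        }
      }
    }

    rgb <- clip01(rgb + array(rnorm(length(rgb), 0, params$noise_sd), dim(rgb)))
    mask <- matrix(as.integer(mask), H, W)
    slide <- new_slide_image(image_id, rgb, if (params$labeled) mask else NULL)
    # sampled geometry kept alongside so masks can be re-rasterized
    attr(slide, "geometry") <- nests
    slide
  })
}

#' Generate a corpus of synthetic slides with a labeled subset
#'
#' Exactly `round(n_images * labeled_fraction)` slides carry ground-truth
#' masks; which ones is decided by a seeded shuffle.  Optionally the image
#' sizes vary around the configured dimensions.
#'
#' @param n_images Number of slides (> 0).
#' @param labeled_fraction Proportion of labeled slides in `[0, 1]`.
#' @param params A [synth_params()] object (its `labeled` field is ignored).
#' @param seed Integer seed.
#' @param size_jitter Relative size variation; each slide's height and
#'   width are drawn uniformly from `dim * (1 +/- size_jitter)` (rounded,
#'   min 128).  `0` keeps all sizes fixed.
#' @return List of `slide_image` objects.
#' @export
generate_corpus <- function(n_images, labeled_fraction, params, seed,
                            size_jitter = 0) {
  if (!is_scalar_number(n_images) || n_images <= 0) {
    stop_config("'n_images' must be a positive number")
  }
  if (!is_scalar_number(labeled_fraction) || labeled_fraction < 0 ||
      labeled_fraction > 1) {
    stop_config("'labeled_fraction' must be in [0, 1]")
  }
  n_images <- as.integer(n_images)
  n_labeled <- as.integer(round(n_images * labeled_fraction))
  labeled <- rep(FALSE, n_images)
  withr::with_seed(derive_seed(seed, "corpus-labels"), {
    labeled[sample.int(n_images, n_labeled)] <- TRUE
  })
  sizes <- matrix(rep(c(params$image_height, params$image_width),
                      each = n_images), ncol = 2)
  if (size_jitter > 0) {
    withr::with_seed(derive_seed(seed, "corpus-sizes"), {
      jit <- matrix(runif(2 * n_images, 1 - size_jitter, 1 + size_jitter),
                    ncol = 2)
      sizes <- matrix(pmax(128L, as.integer(round(sizes * jit))), ncol = 2)
    })
  }
  purrr::map(seq_len(n_images), function(i) {
    p <- params
    p$image_height <- sizes[i, 1]
    p$image_width <- sizes[i, 2]
    p$labeled <- labeled[i]
    generate_slide(p, derive_seed(seed, paste0("slide-", i)),
                   image_id = sprintf("img_%03d", i))
  })
}

#' Write a corpus to disk with a manifest
#'
#' Images are written as 8-bit RGB PNG (or TIFF), masks as single-channel
#' PNG with values 0/255, and a manifest CSV describing the corpus.
#'
#' @param corpus List of `slide_image` objects.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"` for the RGB images.
#' @return The manifest as a tibble (invisibly written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
write_corpus <- function(corpus, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(corpus, function(s) {
    img_path <- file.path(dir, paste0(s$image_id, ".", format))
    if (format == "png") {
      png::writePNG(s$rgb, img_path)
    } else {
      tiff::writeTIFF(s$rgb, img_path, bits.per.sample = 8L)
    }
    mask_path <- ""
    if (s$labeled) {
      mask_path <- file.path(dir, paste0(s$image_id, "_mask.png"))
      png::writePNG(s$mask * 1.0, mask_path)
    }
    tibble(image_id = s$image_id, path = img_path, mask_path = mask_path,
           labeled = s$labeled, height = nrow(s$rgb), width = ncol(s$rgb))
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read a corpus previously written by [write_corpus()]
#'
#' @param manifest Path to a manifest CSV, or a directory containing
#'   `manifest.csv`.
#' @return List of `slide_image` objects.
#' @export
read_corpus <- function(manifest) {
  path <- if (dir.exists(manifest)) file.path(manifest, "manifest.csv") else manifest
  if (!file.exists(path)) stop_io("manifest not found: %s", path)
  man <- readr::read_csv(path, show_col_types = FALSE)
  purrr::pmap(man, function(image_id, path, mask_path, labeled, ...) {
    rgb <- read_rgb(path)
    mask <- NULL
    if (isTRUE(labeled)) {
      if (is.na(mask_path) || !nzchar(mask_path)) {
        stop_data("labeled image '%s' has no mask path", image_id)
      }
      mask <- read_mask(mask_path)
    }
    new_slide_image(image_id, rgb, mask)
  })
}

# raster readers normalised to [0,1] HxWx3 / 0-1 HxW
read_rgb <- function(path) {
  if (!file.exists(path)) stop_io("image not found: %s", path)
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

read_mask <- function(path) {
  m <- read_rgb(path)[, , 1]
  (m >= 0.5) * 1L
}
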