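# Shared fixtures and independent oracles used across the suite.

# small, fast generator settings for unit tests
tiny_params <- function(...) {
  defaults <- list(image_height = 128, image_width = 128,
                   nest_count_range = c(1, 2),
                   nest_radius_range = c(10, 14),
                   cells_per_nest_range = c(20, 40),
                   cell_radius_range = c(2, 3))
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

tiny_corpus <- function(n = 8, labeled_fraction = 0.5, seed = 11, ...) {
  generate_corpus(n, labeled_fraction, tiny_params(...), seed)
}

# lightweight slide stubs for split tests (splitting never looks at pixels)
stub_corpus <- function(n, n_labeled) {
  purrr::map(seq_len(n), function(i) {
    structure(list(image_id = sprintf("stub_%03d", i), labeled = i <= n_labeled),
              class = "slide_image")
  })
}

# a labeled patch fixture with an off-center mask square
fixture_patch <- function(seed = 1, positive = TRUE) {
  set.seed(seed)
  mask <- matrix(0L, 128, 128)
  if (positive) mask[20:50, 70:110] <- 1L
  tibble::tibble(
    source_id = "fixture", row = 0L, col = 0L,
    positive = positive, augmented = FALSE,
    rgb = list(array(runif(128 * 128 * 3), c(128, 128, 3))),
    mask = list(mask)
  )
}

# build a patch tibble straight from a corpus split (training split)
fixture_patches <- function(corpus, split = NULL, config = patch_config()) {
  tbl <- dplyr::bind_rows(purrr::map(corpus, extract_patches, config = config))
  tbl
}

# expected per-layer reference: name, output shape, parameter count
listing_reference <- function() {
  tibble::tribble(
    ~name,             ~h,  ~w,  ~c,   ~params,
    "conv2d",          128, 128, 32,   896,
    "conv2d_1",        128, 128, 64,   18496,
    "max_pooling2d",   64,  64,  64,   0,
    "conv2d_2",        64,  64,  64,   36928,
    "conv2d_3",        64,  64,  128,  73856,
    "max_pooling2d_1", 32,  32,  128,  0,
    "conv2d_4",        32,  32,  128,  147584,
    "conv2d_5",        32,  32,  64,   73792,
    "max_pooling2d_2", 16,  16,  64,   0,
    "conv2d_6",        16,  16,  64,   36928,
    "conv2d_7",        16,  16,  32,   18464,
    "conv2d_8",        16,  16,  32,   9248,
    "conv2d_9",        16,  16,  64,   18496,
    "up_sampling2d",   32,  32,  64,   0,
    "conv2d_10",       32,  32,  64,   36928,
    "conv2d_11",       32,  32,  128,  73856,
    "up_sampling2d_1", 64,  64,  128,  0,
    "conv2d_12",       64,  64,  128,  147584,
    "conv2d_13",       64,  64,  64,   73792,
    "up_sampling2d_2", 128, 128, 64,   0,
    "conv2d_14",       128, 128, 64,   36928,
    "conv2d_15",       128, 128, 32,   18464,
    "conv2d_16",       128, 128, 1,    289
  )
}

# per-pixel loop oracle for confusion counts (independent of confusion())
loop_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# independent enumeration of patch origins under the stride rules:
# plain grid at negative stride; for every nest-positive grid window, its
# 3x3 grid-cell neighborhood re-scanned at the positive stride
oracle_origins <- function(mask, ps = 128L, ns = 128L, pstr = 64L, rule = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  padto <- function(n) if (n <= ps) ps else
    ps + as.integer(ceiling((n - ps) / ns)) * ns
  Hp <- padto(H); Wp <- padto(W)
  ridx <- c(seq_len(H), seq.int(H - 1, by = -1, length.out = Hp - H))
  cidx <- c(seq_len(W), seq.int(W - 1, by = -1, length.out = Wp - W))
  mp <- mask[ridx, cidx]
  pos <- function(r, c) sum(mp[(r + 1):(r + ps), (c + 1):(c + ps)]) >= rule
  base_r <- seq.int(0L, Hp - ps, by = ns)
  base_c <- seq.int(0L, Wp - ps, by = ns)
  keys <- character(0)
  for (r in base_r) for (c in base_c) keys <- c(keys, paste(r, c))
  for (r in base_r) {
    for (c in base_c) {
      if (!pos(r, c)) next
      rr <- seq.int(max(0L, r - ns), min(Hp - ps, r + ns), by = pstr)
      cc <- seq.int(max(0L, c - ns), min(Wp - ps, c + ns), by = pstr)
      for (r2 in rr) for (c2 in cc) keys <- c(keys, paste(r2, c2))
    }
  }
  keys <- unique(keys)
  parts <- strsplit(keys, " ")
  out <- data.frame(row = as.integer(purrr::map_chr(parts, 1)),
                    col = as.integer(purrr::map_chr(parts, 2)))
  out$positive <- mapply(pos, out$row, out$col)
  out[order(out$row, out$col), ]
}
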