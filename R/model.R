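# The convolutional autoencoder: 16 hidden 3x3 conv layers with
# size-preserving padding, three 2x2 max-pools in the encoder, three 2x2
# upsamplings in the decoder, and a final conv head that is either a
# 3-channel ReLU reconstruction layer or a 1-channel sigmoid segmentation
# layer.  A 128x128x3 input is compressed to a 16x16x64 latent code at the
# third max-pool; that boundary is the encoder/decoder split used for
# weight transfer and freezing.

# hidden conv channel progression around the bottleneck
CAE_CHANNELS <- c(32L, 64L, 64L, 128L, 128L, 64L, 64L, 32L,
                  32L, 64L, 64L, 128L, 128L, 64L, 64L, 32L)

#' Build the convolutional-autoencoder architecture
#'
#' The two variants share every layer except the final convolution:
#' 3 channels with ReLU for reconstruction, 1 channel with sigmoid for
#' segmentation.
#'
#' @param variant `"segmentation"` or `"reconstruction"`.
#' @return A `cae_architecture`: a list with a `layers` tibble (name, kind,
#'   channels, activation, output shape, parameter count), the `variant`,
#'   `encoder_end_index` (the third max-pool, whose 16x16x64 output is the
#'   latent code), and `input_shape`.
#' @examples
#' arch <- build_architecture("segmentation")
#' count_parameters(arch)
#' @export
build_architecture <- function(variant = c("segmentation", "reconstruction")) {
  variant <- match.arg(variant)
  layers <- list()
  add <- function(kind, out_channels = NA_integer_, activation = "none") {
    layers[[length(layers) + 1L]] <<- list(kind = kind,
                                           out_channels = out_channels,
                                           activation = activation)
  }
  ch <- CAE_CHANNELS
  add("conv", ch[1], "relu"); add("conv", ch[2], "relu"); add("maxpool")
  add("conv", ch[3], "relu"); add("conv", ch[4], "relu"); add("maxpool")
  add("conv", ch[5], "relu"); add("conv", ch[6], "relu"); add("maxpool")
  add("conv", ch[7], "relu"); add("conv", ch[8], "relu")
  add("conv", ch[9], "relu"); add("conv", ch[10], "relu"); add("upsample")
  add("conv", ch[11], "relu"); add("conv", ch[12], "relu"); add("upsample")
  add("conv", ch[13], "relu"); add("conv", ch[14], "relu"); add("upsample")
  add("conv", ch[15], "relu"); add("conv", ch[16], "relu")
  if (variant == "segmentation") add("conv", 1L, "sigmoid")
  else add("conv", 3L, "relu")

  h <- 128L; w <- 128L; cin <- 3L
  n_conv <- 0L; n_pool <- 0L; n_up <- 0L
  rows <- purrr::map(layers, function(l) {
    name <- switch(l$kind,
      conv = if (n_conv == 0L) "conv2d" else sprintf("conv2d_%d", n_conv),
      maxpool = if (n_pool == 0L) "max_pooling2d" else
        sprintf("max_pooling2d_%d", n_pool),
      upsample = if (n_up == 0L) "up_sampling2d" else
        sprintf("up_sampling2d_%d", n_up))
    in_channels <- cin
    if (l$kind == "conv") {
      n_conv <<- n_conv + 1L
      cin <<- l$out_channels
      params <- as.integer((9L * in_channels + 1L) * l$out_channels)
    } else if (l$kind == "maxpool") {
      n_pool <<- n_pool + 1L
      h <<- h %/% 2L; w <<- w %/% 2L
      params <- 0L
    } else {
      n_up <<- n_up + 1L
      h <<- h * 2L; w <<- w * 2L
      params <- 0L
    }
    tibble(name = name, kind = l$kind,
           in_channels = as.integer(in_channels),
           out_channels = as.integer(if (l$kind == "conv") l$out_channels
                                     else in_channels),
           kernel = if (l$kind == "conv") 3L else 2L,
           activation = l$activation,
           out_height = h, out_width = w, params = params)
  })
  layer_tbl <- dplyr::bind_rows(rows)
  structure(
    list(layers = layer_tbl, variant = variant,
         encoder_end_index = max(which(layer_tbl$kind == "maxpool")),
         input_shape = c(128L, 128L, 3L)),
    class = "cae_architecture"
  )
}

#' Count trainable parameters of an architecture
#'
#' Each 3x3 convolution with `c_in` input and `c_out` output channels has
#' `(9 c_in + 1) c_out` weights and biases; pooling and upsampling layers
#' have none.
#'
#' @param arch A [build_architecture()] result (or a `cae_model`).
#' @param scope `"all"`, `"encoder"`, `"decoder"`, or `"per_layer"`.
#' @return An integer count, or for `"per_layer"` a tibble of layer names
#'   and counts.
#' @export
count_parameters <- function(arch, scope = c("all", "encoder", "decoder",
                                             "per_layer")) {
  scope <- match.arg(scope)
  if (inherits(arch, "cae_model")) arch <- arch$architecture
  tbl <- arch$layers
  enc <- seq_len(arch$encoder_end_index)
  switch(scope,
    all = sum(tbl$params),
    encoder = sum(tbl$params[enc]),
    decoder = sum(tbl$params[-enc]),
    per_layer = dplyr::select(tbl, "name", "params")
  )
}

#' @export
format.cae_architecture <- function(x, ...) {
  tbl <- x$layers
  type_of <- c(conv = "Conv2D", maxpool = "MaxPooling2D",
               upsample = "UpSampling2D")
  lines <- c(
    sprintf("Model: convolutional autoencoder (%s variant)", x$variant),
    sprintf("%-34s%-26s%s", "Layer (Type)", "Output Shape", "Nb. of Param."),
    sprintf("%-34s%-26s%d", "input_1 (InputLayer)",
            "[(None, 128, 128, 3)]", 0L),
    sprintf("%-34s%-26s%s",
            sprintf("%s (%s)", tbl$name, type_of[tbl$kind]),
            sprintf("(None, %d, %d, %d)", tbl$out_height, tbl$out_width,
                    tbl$out_channels),
            format(tbl$params, big.mark = ",", trim = TRUE)),
    sprintf("Total params: %s", format(sum(tbl$params), big.mark = ",")),
    sprintf("Trainable params: %s", format(sum(tbl$params), big.mark = ",")),
    "Non-trainable params: 0"
  )
  lines
}

#' @export
print.cae_architecture <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

# integer codes shared with the C++ core
layer_codes <- function(arch) {
  tbl <- arch$layers
  list(
    kind = c(conv = 1L, maxpool = 2L, upsample = 3L)[tbl$kind],
    cout = ifelse(tbl$kind == "conv", tbl$out_channels, 0L),
    act = c(none = 0L, relu = 1L, sigmoid = 2L)[tbl$activation]
  )
}

#' Create a convolutional-autoencoder model
#'
#' @param variant Head variant, or an existing [build_architecture()] object.
#' @param seed Optional seed; when given the weights are initialized
#'   immediately (see [initialize_weights()]).
#' @return A `cae_model`: architecture, per-layer weights (`W` arrays of
#'   dim 3x3xc_in x c_out and bias vectors `b`), and per-layer frozen flags.
#' @export
cae_model <- function(variant = "segmentation", seed = NULL) {
  arch <- if (inherits(variant, "cae_architecture")) variant
          else build_architecture(variant)
  model <- structure(
    list(architecture = arch,
         weights = vector("list", nrow(arch$layers)),
         frozen = rep(FALSE, nrow(arch$layers))),
    class = "cae_model"
  )
  if (!is.null(seed)) model <- initialize_weights(model, seed)
  model
}

#' Glorot-uniform weight initialization
#'
#' Convolution weights are drawn from
#' `U(-sqrt(6 / (fan_in + fan_out)), +sqrt(6 / (fan_in + fan_out)))` with
#' `fan = 9 * channels`; biases start at zero.  Deterministic under `seed`.
#'
#' @param model A `cae_model`.
#' @param seed Integer seed.
#' @param layers Indices of layers to (re)initialize; defaults to all.
#' @return The model with weights filled in.
#' @export
initialize_weights <- function(model, seed, layers = NULL) {
  tbl <- model$architecture$layers
  layers <- layers %||% seq_len(nrow(tbl))
  withr::with_seed(as.integer(seed), {
    for (l in layers) {
      if (tbl$kind[l] != "conv") next
      cin <- tbl$in_channels[l]; cout <- tbl$out_channels[l]
      limit <- sqrt(6 / (9 * cin + 9 * cout))
      model$weights[[l]] <- list(
        W = array(runif(9 * cin * cout, -limit, limit), c(3, 3, cin, cout)),
        b = numeric(cout)
      )
    }
  })
  model
}

encoder_layer_indices <- function(model) {
  seq_len(model$architecture$encoder_end_index)
}

decoder_layer_indices <- function(model) {
  setdiff(seq_len(nrow(model$architecture$layers)),
          encoder_layer_indices(model))
}

#' Transfer a trained encoder into a fresh model
#'
#' Copies the encoder weights (through the third max-pool, i.e. the layers
#' producing the 16x16x64 code) bit-for-bit into a new model of the target
#' variant and freshly re-initializes the decoder -- the weight-transfer
#' step between the reconstruction and segmentation stages.
#'
#' @param source A trained `cae_model`.
#' @param target_variant Head variant of the new model.
#' @param seed Seed for the decoder re-initialization.
#' @return A new `cae_model`.
#' @export
transfer_encoder <- function(source, target_variant = "segmentation", seed) {
  if (!inherits(source, "cae_model")) stop_contract("'source' must be a cae_model")
  enc_conv <- intersect(encoder_layer_indices(source),
                        which(source$architecture$layers$kind == "conv"))
  if (any(purrr::map_lgl(source$weights[enc_conv], is.null))) {
    stop_contract("source encoder weights are not initialized")
  }
  target <- cae_model(target_variant)
  enc <- encoder_layer_indices(target)
  if (!identical(source$architecture$layers$out_channels[enc],
                 target$architecture$layers$out_channels[enc])) {
    stop_contract("encoder architectures do not match")
  }
  target <- initialize_weights(target, seed, layers = decoder_layer_indices(target))
  target$weights[enc] <- source$weights[enc]
  target
}

#' Freeze or unfreeze the encoder
#'
#' Frozen layers are treated as a fixed feature extractor: the trainer
#' never updates them, so their weights stay bitwise identical through any
#' number of steps.
#'
#' @param model A `cae_model`.
#' @param frozen Logical.
#' @return The model with `frozen` flags set on exactly the encoder layers.
#' @export
set_encoder_frozen <- function(model, frozen = TRUE) {
  model$frozen[] <- FALSE
  model$frozen[encoder_layer_indices(model)] <- isTRUE(frozen)
  model
}

#' Forward pass through the autoencoder
#'
#' @param model An initialized `cae_model`.
#' @param x Input batch: `128 x 128 x 3 x N` array (a single `128x128x3`
#'   array is promoted to a batch of one) with values in `[0, 1]`.
#' @param upto Run only layers `1..upto` (e.g. the encoder); default all.
#' @param from Feed `x` in at layer `from` (e.g. a latent code into the
#'   decoder); default 1.
#' @param chunk Samples processed per internal chunk.
#' @return Output array `H x W x C x N`; C is 3 (reconstruction) or 1
#'   (segmentation probabilities in (0, 1)).
#' @export
cae_forward <- function(model, x, upto = NULL, from = 1L, chunk = 8L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop_contract("input must be HxWxCxN")
  if (from == 1L && !identical(as.integer(dim(x)[1:3]),
                               model$architecture$input_shape)) {
    stop_contract("input shape %s does not match the %s network input",
                  paste(dim(x)[1:3], collapse = "x"),
                  paste(model$architecture$input_shape, collapse = "x"))
  }
  if (any(purrr::map_lgl(model$weights[model$architecture$layers$kind == "conv"],
                         is.null))) {
    stop_contract("model weights are not initialized")
  }
  codes <- layer_codes(model$architecture)
  L <- length(codes$kind)
  upto <- upto %||% L
  nc_forward(model$weights, codes$kind, codes$cout, codes$act, x,
             as.integer(from - 1L), as.integer(upto - 1L), as.integer(chunk))
}

#' @export
predict.cae_model <- function(object, x, ...) cae_forward(object, x, ...)

#' @export
print.cae_model <- function(x, ...) {
  init <- !any(purrr::map_lgl(
    x$weights[x$architecture$layers$kind == "conv"], is.null))
  cat(sprintf("<cae_model: %s variant, %s params, %s%s>\n",
              x$architecture$variant,
              format(count_parameters(x$architecture), big.mark = ","),
              if (init) "initialized" else "uninitialized",
              if (any(x$frozen)) ", encoder frozen" else ""))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the architecture table, every weight tensor and
#' the frozen flags; the round-trip is bit-exact.
#'
#' @param model A `cae_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the restored `cae_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: %s", path)
  model <- readRDS(path)
  if (!inherits(model, "cae_model")) stop_io("not a cae_model checkpoint: %s", path)
  model
}
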