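# Three-phase semi-supervised training:
#   1. reconstruction with MSE on patches from all images (no masks needed),
#   2. segmentation with BCE on labeled patches, encoder frozen, decoder
#      freshly re-initialized,
#   3. fine-tuning of the whole network at a halved learning-rate base.
# Each phase checkpoints at the smallest validation loss.

#' Training configuration
#'
#' @param batch_size Mini-batch size.
#' @param base_lr_main Learning-rate base for the reconstruction and
#'   segmentation phases.
#' @param base_lr_finetune Learning-rate base for fine-tuning.
#' @param epochs_per_phase Integer vector of three epoch counts.
#' @param lr_floor Lower bound of the decayed learning rate.
#' @param seed Master seed driving initialization and shuffling.
#' @param threshold Probability threshold for mask binarization.
#' @param chunk Samples per internal compute chunk.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 64L,
                         base_lr_main = 0.001,
                         base_lr_finetune = 0.0005,
                         epochs_per_phase = c(50L, 40L, 20L),
                         lr_floor = 1e-6,
                         seed = 1L,
                         threshold = 0.5,
                         chunk = 8L) {
  if (batch_size < 1) stop_config("'batch_size' must be >= 1")
  if (length(epochs_per_phase) != 3L || any(epochs_per_phase < 1)) {
    stop_config("'epochs_per_phase' must be 3 integers >= 1")
  }
  if (threshold <= 0 || threshold >= 1) stop_config("'threshold' must be in (0, 1)")
  if (base_lr_main <= 0 || base_lr_finetune <= 0 || lr_floor <= 0) {
    stop_config("learning rates must be positive")
  }
  structure(
    list(batch_size = as.integer(batch_size),
         base_lr_main = base_lr_main,
         base_lr_finetune = base_lr_finetune,
         epochs_per_phase = as.integer(epochs_per_phase),
         lr_floor = lr_floor,
         seed = as.integer(seed),
         threshold = threshold,
         chunk = as.integer(chunk)),
    class = "train_config"
  )
}

#' Logarithmic learning-rate decay
#'
#' `lr(epoch) = max(floor, -log10(0.01 * epoch + 0.1) * base)`: the rate
#' starts at `base` (epoch 0), decays to the floor by epoch 90, and is
#' nonincreasing throughout.
#'
#' @param epoch Epoch index (0-based); vectorized.
#' @param base Learning-rate base (`0.001` main, `0.0005` fine-tuning).
#' @param floor Lower bound.
#' @return Learning rate(s).
#' @examples
#' lr_schedule(0, 0.001)    # 0.001
#' lr_schedule(90, 0.001)   # floor
#' @export
lr_schedule <- function(epoch, base, floor = 1e-6) {
  if (any(epoch < 0)) stop_config("'epoch' must be >= 0")
  if (base <= 0) stop_config("'base' must be positive")
  pmax(floor, -log10(0.01 * epoch + 0.1) * base)
}

#' Mean squared error between two equally shaped arrays
#'
#' @param x,x_hat Numeric arrays of identical shape.
#' @return Mean of squared elementwise differences.
#' @export
mse_loss <- function(x, x_hat) {
  if (!identical(dim(x) %||% length(x), dim(x_hat) %||% length(x_hat))) {
    stop_contract("mse_loss: shape mismatch")
  }
  mean((x - x_hat)^2)
}

#' Binary cross-entropy between 0/1 targets and probabilities
#'
#' Probabilities are clipped to `[eps, 1 - eps]` for numerical safety.
#'
#' @param y Binary targets.
#' @param p Predicted probabilities.
#' @param eps Clipping bound.
#' @return Mean of `-(y log p + (1 - y) log(1 - p))`.
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (!identical(dim(y) %||% length(y), dim(p) %||% length(p))) {
    stop_contract("bce_loss: shape mismatch")
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# --- patch tensors ----------------------------------------------------------

patches_to_x <- function(patches) {
  n <- nrow(patches)
  if (n == 0) stop_data("empty patch set")
  ps <- dim(patches$rgb[[1]])[1]
  array(unlist(patches$rgb, use.names = FALSE), c(ps, ps, 3L, n))
}

patches_to_y <- function(patches) {
  n <- nrow(patches)
  if (n == 0 || is.null(patches$mask[[1]])) stop_data("patches carry no masks")
  ps <- dim(patches$mask[[1]])[1]
  array(as.double(unlist(patches$mask, use.names = FALSE)), c(ps, ps, 1L, n))
}

labeled_patches <- function(patches) {
  keep <- !purrr::map_lgl(patches$mask, is.null)
  patches[keep, ]
}

# --- optimizer --------------------------------------------------------------

adam_init <- function(model, layers) {
  st <- list(t = 0L, m = vector("list", length(model$weights)),
             v = vector("list", length(model$weights)))
  for (l in layers) {
    w <- model$weights[[l]]
    if (is.null(w)) next
    st$m[[l]] <- list(W = array(0, dim(w$W)), b = numeric(length(w$b)))
    st$v[[l]] <- st$m[[l]]
  }
  st
}

adam_step <- function(model, grads, state, layers, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in layers) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (part in c("W", "b")) {
      state$m[[l]][[part]] <- beta1 * state$m[[l]][[part]] + (1 - beta1) * g[[part]]
      state$v[[l]][[part]] <- beta2 * state$v[[l]][[part]] + (1 - beta2) * g[[part]]^2
      model$weights[[l]][[part]] <- model$weights[[l]][[part]] -
        lr * (state$m[[l]][[part]] / c1) /
          (sqrt(state$v[[l]][[part]] / c2) + eps)
    }
  }
  list(model = model, state = state)
}

# --- generic phase loop -----------------------------------------------------

# x, y: HxWxCxN arrays (x may be latent codes when from > 1); trains layers
# [from, L] that are not frozen, checkpoints at the smallest validation loss
run_phase <- function(model, x, y, val_x, val_y, loss, base_lr, epochs,
                      config, phase, from = 1L) {
  codes <- layer_codes(model$architecture)
  L <- length(codes$kind)
  loss_code <- c(mse = 1L, bce = 2L)[[loss]]
  n <- dim(x)[4]
  trainable <- setdiff(seq.int(from, L), which(model$frozen))
  trainable <- trainable[model$architecture$layers$kind[trainable] == "conv"]
  state <- adam_init(model, trainable)

  train_hist <- val_hist <- lr_hist <- numeric(epochs)
  best_val <- Inf
  best_epoch <- NA_integer_
  best_weights <- NULL
  val_loss_fun <- function(m) {
    out <- cae_forward(m, val_x, from = from, chunk = config$chunk)
    if (loss == "mse") mse_loss(val_y, out) else bce_loss(val_y, out)
  }

  for (e in seq_len(epochs)) {
    lr <- lr_schedule(e - 1L, base_lr, config$lr_floor)
    lr_hist[e] <- lr
    ord <- withr::with_seed(
      derive_seed(config$seed, sprintf("%s-epoch-%d", phase, e)),
      sample.int(n)
    )
    batch_starts <- seq.int(1L, n, by = config$batch_size)
    losses <- sizes <- numeric(length(batch_starts))
    for (bi in seq_along(batch_starts)) {
      ids <- ord[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
      gb <- nc_grad(model$weights, codes$kind, codes$cout, codes$act,
                    x[, , , ids, drop = FALSE], y[, , , ids, drop = FALSE],
                    loss_code, as.integer(from - 1L), config$chunk)
      losses[bi] <- gb$loss
      sizes[bi] <- length(ids)
      upd <- adam_step(model, gb$grads, state, trainable, lr)
      model <- upd$model
      state <- upd$state
    }
    train_hist[e] <- sum(losses * sizes) / sum(sizes)
    val_hist[e] <- val_loss_fun(model)
    if (isTRUE(getOption("nestcae.verbose"))) {
      message(sprintf("%s phase=%s epoch=%d lr=%.3e train_loss=%.6f val_loss=%.6f",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), phase, e, lr,
                      train_hist[e], val_hist[e]))
    }
    if (val_hist[e] < best_val) {  # strict: ties keep the earliest epoch
      best_val <- val_hist[e]
      best_epoch <- e
      best_weights <- model$weights
    }
  }
  model$weights <- best_weights
  structure(
    list(phase = phase,
         train_loss_history = train_hist,
         val_loss_history = val_hist,
         lr_history = lr_hist,
         best_epoch = best_epoch,
         checkpoint = model),
    class = "phase_result"
  )
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result '%s'> %d epochs, best epoch %d (val loss %.5g)\n",
              x$phase, length(x$val_loss_history), x$best_epoch,
              x$val_loss_history[x$best_epoch]))
  invisible(x)
}

#' Phase 1: unsupervised reconstruction pre-training
#'
#' Trains the reconstruction-variant autoencoder to reproduce its input
#' patches (MSE loss); every patch, labeled or not, participates since the
#' input is its own target.
#'
#' @param model A reconstruction-variant `cae_model` (initialized; if not,
#'   it is initialized from the config seed).
#' @param train_patches,val_patches Patch tibbles from [extract_patches()]
#'   / [prepare_patches()].
#' @param config A [train_config()].
#' @return A `phase_result` with loss histories and the best-validation
#'   checkpoint.
#' @export
train_phase1_reconstruction <- function(model, train_patches, val_patches,
                                        config = train_config()) {
  if (model$architecture$variant != "reconstruction") {
    stop_contract("phase 1 needs the reconstruction variant")
  }
  if (nrow(train_patches) == 0) stop_data("empty training patch set")
  if (is.null(model$weights[[1]])) {
    model <- initialize_weights(model, derive_seed(config$seed, "phase1-init"))
  }
  x <- patches_to_x(train_patches)
  vx <- patches_to_x(val_patches)
  run_phase(model, x, x, vx, vx, "mse", config$base_lr_main,
            config$epochs_per_phase[1], config, "reconstruction")
}

#' Phase 2: segmentation training with a frozen encoder
#'
#' Transfers the phase-1 encoder into a segmentation-variant model,
#' re-initializes the decoder, freezes the encoder and trains with binary
#' cross-entropy on labeled patches only.  Because the encoder is fixed,
#' the latent codes of all patches are computed once up front and training
#' runs on the decoder alone; the returned encoder weights are bitwise
#' those of the phase-1 checkpoint.
#'
#' @param pretrained The phase-1 checkpoint (`cae_model`, reconstruction
#'   variant).
#' @param train_patches,val_patches Labeled patch tibbles (rows without
#'   masks are dropped).
#' @param config A [train_config()].
#' @return A `phase_result`.
#' @export
train_phase2_segmentation <- function(pretrained, train_patches, val_patches,
                                      config = train_config()) {
  train_patches <- labeled_patches(train_patches)
  val_patches <- labeled_patches(val_patches)
  if (nrow(train_patches) == 0) stop_data("no labeled training patches")
  if (nrow(val_patches) == 0) stop_data("no labeled validation patches")

  model <- transfer_encoder(pretrained, "segmentation",
                            derive_seed(config$seed, "phase2-init"))
  model <- set_encoder_frozen(model, TRUE)
  enc_end <- model$architecture$encoder_end_index

  x <- patches_to_x(train_patches)
  vx <- patches_to_x(val_patches)
  code_tr <- cae_forward(model, x, upto = enc_end, chunk = config$chunk)
  code_va <- cae_forward(model, vx, upto = enc_end, chunk = config$chunk)
  y <- patches_to_y(train_patches)
  vy <- patches_to_y(val_patches)
  run_phase(model, code_tr, y, code_va, vy, "bce", config$base_lr_main,
            config$epochs_per_phase[2], config, "segmentation",
            from = enc_end + 1L)
}

#' Phase 3: whole-network fine-tuning
#'
#' Unfreezes the encoder and continues segmentation training end-to-end at
#' the fine-tuning learning-rate base (half the main base).
#'
#' @param model The phase-2 checkpoint (segmentation variant).
#' @param train_patches,val_patches Labeled patch tibbles.
#' @param config A [train_config()].
#' @return A `phase_result`.
#' @export
train_phase3_finetune <- function(model, train_patches, val_patches,
                                  config = train_config()) {
  if (model$architecture$variant != "segmentation") {
    stop_contract("phase 3 needs the segmentation variant")
  }
  train_patches <- labeled_patches(train_patches)
  val_patches <- labeled_patches(val_patches)
  if (nrow(train_patches) == 0) stop_data("no labeled training patches")
  model <- set_encoder_frozen(model, FALSE)
  x <- patches_to_x(train_patches)
  vx <- patches_to_x(val_patches)
  y <- patches_to_y(train_patches)
  vy <- patches_to_y(val_patches)
  run_phase(model, x, y, vx, vy, "bce", config$base_lr_finetune,
            config$epochs_per_phase[3], config, "finetune")
}

#' Run the full three-phase semi-supervised pipeline
#'
#' Splits the corpus at the image level, extracts patches, then runs
#' reconstruction pre-training on patches from all training images,
#' segmentation training on the labeled subset with the encoder frozen,
#' and fine-tuning.  Rotation augmentation is applied to training-split
#' nest patches and used in the segmentation phases (it exists to balance
#' the nest class; reconstruction trains on the unaugmented patches).
#'
#' @param corpus List of `slide_image` objects.
#' @param assignment Optional [split_corpus()] result; computed from
#'   `fractions` and the config seed when omitted.
#' @param fractions Train/validation/test proportions.
#' @param patch_cfg A [patch_config()].
#' @param config A [train_config()].
#' @return A `cae_fit`: list with the final `model` (phase-3 best
#'   checkpoint), the three `phases`, the `assignment` and the `patches`
#'   index (origins only).
#' @export
run_semi_supervised <- function(corpus, assignment = NULL,
                                fractions = c(0.70, 0.143, 0.157),
                                patch_cfg = patch_config(),
                                config = train_config()) {
  assignment <- assignment %||%
    split_corpus(corpus, fractions, derive_seed(config$seed, "split"))
  patches <- prepare_patches(corpus, assignment, patch_cfg)
  tr <- patches[patches$split == "train", ]
  va <- patches[patches$split == "validation", ]
  if (nrow(va) == 0) stop_data("validation split has no patches")

  recon <- cae_model("reconstruction",
                     seed = derive_seed(config$seed, "phase1-init"))
  p1 <- train_phase1_reconstruction(recon, tr[!tr$augmented, ],
                                    va[!va$augmented, ], config)
  p2 <- train_phase2_segmentation(p1$checkpoint, tr, va[!va$augmented, ],
                                  config)
  p3 <- train_phase3_finetune(p2$checkpoint, tr, va[!va$augmented, ], config)

  structure(
    list(model = p3$checkpoint,
         phases = list(reconstruction = p1, segmentation = p2, finetune = p3),
         assignment = assignment,
         patch_index = dplyr::select(patches, "source_id", "row", "col",
                                     "positive", "augmented", "split")),
    class = "cae_fit"
  )
}

#' @export
print.cae_fit <- function(x, ...) {
  cat("<cae_fit> three-phase semi-supervised autoencoder\n")
  for (p in x$phases) print(p)
  invisible(x)
}

#' Write per-phase loss histories to a CSV
#'
#' @param fit A `cae_fit` or single `phase_result`.
#' @param path Output path.
#' @export
write_history_csv <- function(fit, path) {
  readr::write_csv(tidy(fit), path)
  invisible(path)
}
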