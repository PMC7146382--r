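# broom-style tidiers for fitted objects

#' Tidy a training-phase result into per-epoch rows
#'
#' @param x A `phase_result`.
#' @param ... Unused.
#' @return Tibble with `phase`, `epoch`, `lr`, `train_loss`, `val_loss`.
#' @export
tidy.phase_result <- function(x, ...) {
  tibble(phase = x$phase,
         epoch = seq_along(x$train_loss_history),
         lr = x$lr_history,
         train_loss = x$train_loss_history,
         val_loss = x$val_loss_history)
}

#' @rdname tidy.phase_result
#' @export
tidy.cae_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$phases, tidy))
}

#' One-row summary of a training phase
#'
#' @param x A `phase_result`.
#' @param ... Unused.
#' @return Tibble with the phase, epoch count, best epoch and losses.
#' @export
glance.phase_result <- function(x, ...) {
  tibble(phase = x$phase,
         epochs = length(x$val_loss_history),
         best_epoch = x$best_epoch,
         best_val_loss = x$val_loss_history[x$best_epoch],
         final_train_loss = x$train_loss_history[length(x$train_loss_history)])
}

#' @rdname glance.phase_result
#' @export
glance.cae_fit <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$phases, glance))
}

#' @export
tidy.seg_evaluation <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.seg_evaluation <- function(x, ...) attr(x, "macro")
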