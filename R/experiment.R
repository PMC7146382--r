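# Desk-scale end-to-end experiment on synthetic slides: generate a mixed
# labeled/unlabeled corpus, run the three-phase protocol, and measure
# held-out segmentation quality.

#' Run the desk-scale synthetic end-to-end experiment
#'
#' Generates `n_images` synthetic H&E-like slides (half labeled by
#' default), runs the full three-phase semi-supervised pipeline with
#' shortened epoch budgets, and evaluates the final model on the labeled
#' images of the held-out test split.  Everything is deterministic under
#' `seed`.
#'
#' @param seed Master seed.
#' @param n_images Corpus size.
#' @param image_size `c(height, width)` of the synthetic slides.
#' @param labeled_fraction Fraction of slides with ground truth.
#' @param epochs Three epoch counts for the phases.
#' @param params Generator parameters ([synth_params()]); the image size
#'   above overrides its dimensions.
#' @param fractions Train/validation/test split proportions.
#' @return List with the `fit` (a `cae_fit`), the held-out `evaluation`
#'   (a `seg_evaluation`), and `mean_dsc` (macro-average test DSC).
#' @export
desk_scale_experiment <- function(seed,
                                  n_images = 40L,
                                  image_size = c(256L, 256L),
                                  labeled_fraction = 0.5,
                                  epochs = c(5L, 5L, 3L),
                                  params = synth_params(),
                                  fractions = c(0.70, 0.143, 0.157)) {
  params$image_height <- as.integer(image_size[1])
  params$image_width <- as.integer(image_size[2])
  corpus <- generate_corpus(n_images, labeled_fraction, params,
                            derive_seed(seed, "experiment-corpus"))
  cfg <- train_config(epochs_per_phase = epochs, seed = as.integer(seed))
  fit <- run_semi_supervised(corpus, fractions = fractions, config = cfg)
  test_ids <- fit$assignment$image_id[fit$assignment$split == "test"]
  test_images <- purrr::keep(corpus, function(s) s$image_id %in% test_ids)
  evaluation <- evaluate_corpus(fit$model, test_images,
                                threshold = cfg$threshold)
  list(fit = fit, evaluation = evaluation,
       mean_dsc = attr(evaluation, "macro")$dsc)
}

#' Train a supervised-from-scratch baseline on the same patches
#'
#' The comparison arm for the semi-supervised protocol: an identically
#' budgeted segmentation model (same epochs as phases 2+3 combined, same
#' batch size and schedules) trained from random initialization on the
#' labeled patches only, with no reconstruction pre-training.
#'
#' @param corpus,assignment,patch_cfg,config As in [run_semi_supervised()].
#' @return A `phase_result` whose checkpoint is the baseline model.
#' @export
train_supervised_baseline <- function(corpus, assignment,
                                      patch_cfg = patch_config(),
                                      config = train_config()) {
  patches <- prepare_patches(corpus, assignment, patch_cfg)
  tr <- labeled_patches(patches[patches$split == "train", ])
  va <- labeled_patches(patches[patches$split == "validation" &
                                  !patches$augmented, ])
  if (nrow(tr) == 0) stop_data("no labeled training patches")
  model <- cae_model("segmentation",
                     seed = derive_seed(config$seed, "baseline-init"))
  x <- patches_to_x(tr); y <- patches_to_y(tr)
  vx <- patches_to_x(va); vy <- patches_to_y(va)
  run_phase(model, x, y, vx, vy, "bce", config$base_lr_main,
            config$epochs_per_phase[2] + config$epochs_per_phase[3],
            config, "supervised_baseline")
}
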