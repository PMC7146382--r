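test_that("the learning-rate decay follows its closed form", {
  expect_equal(lr_schedule(0, 0.001), 0.001)
  expect_equal(lr_schedule(0, 0.0005), 0.0005)
  epochs <- 0:120
  lr <- lr_schedule(epochs, 0.001)
  expect_equal(lr, pmax(1e-6, -log10(0.01 * epochs + 0.1) * 0.001))
  expect_true(all(diff(lr) <= 0))
  expect_equal(lr_schedule(90, 0.001), 1e-6)   # -log10(1.0) clamps to floor
  expect_equal(lr_schedule(120, 0.001), 1e-6)
  expect_error(lr_schedule(-1, 0.001), class = "nestcae_config_error")
  expect_error(lr_schedule(1, 0), class = "nestcae_config_error")
})

test_that("loss functions match scalar loop oracles", {
  expect_identical(mse_loss(1:10 / 10, 1:10 / 10), 0)
  expect_identical(mse_loss(rep(0, 4), rep(1, 4)), 1)
  set.seed(1)
  y <- runif(10); yh <- runif(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (y[i] - yh[i])^2
  expect_equal(mse_loss(y, yh), acc / 10, tolerance = 1e-12)

  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  yb <- rbinom(16, 1, 0.5); p <- runif(16, 0.01, 0.99)
  acc <- 0
  for (i in 1:16) acc <- acc - (yb[i] * log(p[i]) + (1 - yb[i]) * log(1 - p[i]))
  expect_equal(bce_loss(yb, p), acc / 16, tolerance = 1e-12)
  expect_true(is.finite(bce_loss(c(0, 1), c(0, 1))))  # clipping
  expect_error(mse_loss(1:3, 1:4), class = "nestcae_contract_error")
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0.5, 2, 3)),
               class = "nestcae_contract_error")
})

test_that("training configuration is validated", {
  expect_error(train_config(batch_size = 0), class = "nestcae_config_error")
  expect_error(train_config(threshold = 1), class = "nestcae_config_error")
  expect_error(train_config(epochs_per_phase = c(1, 1)),
               class = "nestcae_config_error")
})

# a small labeled patch set shared by the phase tests
phase_fixture <- function() {
  corpus <- tiny_corpus(6, 1, seed = 31)
  asn <- split_corpus(corpus, c(2, 1, 0) / 3, seed = 1)
  patches <- prepare_patches(corpus, asn, augment = FALSE)
  list(train = patches[patches$split == "train", ],
       val = patches[patches$split == "validation", ])
}

test_that("phase 1 bookkeeping: reported loss is the epoch-mean MSE", {
  fx <- phase_fixture()
  # vanishing learning rate: the model is effectively static, so the
  # reported first-epoch training loss equals the dataset MSE of the
  # initial model
  cfg <- train_config(batch_size = 4, epochs_per_phase = c(1, 1, 1),
                      base_lr_main = 1e-12, lr_floor = 1e-15, seed = 9)
  model <- cae_model("reconstruction", seed = 99)
  res <- train_phase1_reconstruction(model, fx$train, fx$val, cfg)
  x <- nestcae:::patches_to_x(fx$train)
  direct <- mse_loss(x, cae_forward(model, x))
  expect_equal(res$train_loss_history[1], direct, tolerance = 1e-5)
  expect_identical(res$best_epoch, which.min(res$val_loss_history))
})

test_that("phase 1 is deterministic and selects the best validation epoch", {
  fx <- phase_fixture()
  cfg <- train_config(batch_size = 8, epochs_per_phase = c(3, 2, 1), seed = 5)
  m <- cae_model("reconstruction")
  r1 <- train_phase1_reconstruction(m, fx$train, fx$val, cfg)
  r2 <- train_phase1_reconstruction(m, fx$train, fx$val, cfg)
  expect_identical(r1$train_loss_history, r2$train_loss_history)
  expect_identical(r1$val_loss_history, r2$val_loss_history)
  expect_identical(r1$checkpoint$weights, r2$checkpoint$weights)
  expect_lte(r1$val_loss_history[r1$best_epoch], r1$val_loss_history[1])
  expect_identical(r1$lr_history, lr_schedule(0:2, 0.001))
  expect_true(all(is.finite(r1$train_loss_history)))
  expect_error(train_phase1_reconstruction(cae_model("segmentation", seed = 1),
                                           fx$train, fx$val, cfg),
               class = "nestcae_contract_error")
})

test_that("phase 2 freezes the encoder bitwise and trains the decoder", {
  fx <- phase_fixture()
  cfg <- train_config(batch_size = 8, epochs_per_phase = c(2, 3, 1), seed = 6)
  p1 <- train_phase1_reconstruction(cae_model("reconstruction"),
                                    fx$train, fx$val, cfg)
  p2 <- train_phase2_segmentation(p1$checkpoint, fx$train, fx$val, cfg)
  enc <- seq_len(p2$checkpoint$architecture$encoder_end_index)
  expect_identical(p2$checkpoint$weights[enc], p1$checkpoint$weights[enc])
  expect_identical(p2$checkpoint$architecture$variant, "segmentation")
  expect_true(all(p2$checkpoint$frozen[enc]))
  # the decoder was reset, not copied
  dec_conv <- setdiff(which(p2$checkpoint$architecture$layers$kind == "conv"),
                      enc)
  for (l in head(dec_conv, -1)) {
    expect_false(identical(p2$checkpoint$weights[[l]]$W,
                           p1$checkpoint$weights[[l]]$W))
  }
  # training moved the decoder
  init <- transfer_encoder(p1$checkpoint, "segmentation",
                           nestcae::derive_seed(cfg$seed, "phase2-init"))
  expect_false(identical(p2$checkpoint$weights[[dec_conv[1]]]$W,
                         init$weights[[dec_conv[1]]]$W))
  expect_true(all(is.finite(p2$val_loss_history)))
  expect_error(train_phase2_segmentation(p1$checkpoint, fx$train[0, ],
                                         fx$val, cfg),
               class = "nestcae_data_error")
})

test_that("phase 3 unfreezes the encoder and uses the fine-tuning base rate", {
  fx <- phase_fixture()
  cfg <- train_config(batch_size = 8, epochs_per_phase = c(1, 1, 2), seed = 7)
  p1 <- train_phase1_reconstruction(cae_model("reconstruction"),
                                    fx$train, fx$val, cfg)
  p2 <- train_phase2_segmentation(p1$checkpoint, fx$train, fx$val, cfg)
  p3 <- train_phase3_finetune(p2$checkpoint, fx$train, fx$val, cfg)
  enc <- seq_len(p3$checkpoint$architecture$encoder_end_index)
  conv_enc <- intersect(enc, which(p3$checkpoint$architecture$layers$kind == "conv"))
  expect_false(identical(p3$checkpoint$weights[conv_enc],
                         p2$checkpoint$weights[conv_enc]))
  expect_false(any(p3$checkpoint$frozen))
  expect_identical(p3$lr_history[1], 0.0005)
  # fine-tuning does not catastrophically degrade the phase-2 solution
  expect_lte(min(p3$val_loss_history),
             p2$val_loss_history[p2$best_epoch] + 0.05)
})

test_that("a frozen encoder stays bitwise fixed through generic training", {
  fx <- phase_fixture()
  cfg <- train_config(batch_size = 8, epochs_per_phase = c(1, 1, 1), seed = 8)
  m <- set_encoder_frozen(cae_model("segmentation", seed = 3), TRUE)
  x <- nestcae:::patches_to_x(fx$train)
  y <- nestcae:::patches_to_y(fx$train)
  res <- nestcae:::run_phase(m, x, y, x, y, "bce", 0.001, 1L, cfg, "probe")
  enc <- seq_len(m$architecture$encoder_end_index)
  expect_identical(res$checkpoint$weights[enc], m$weights[enc])
  dec1 <- setdiff(which(m$architecture$layers$kind == "conv"), enc)[1]
  expect_false(identical(res$checkpoint$weights[[dec1]]$W, m$weights[[dec1]]$W))
  # unfrozen: one epoch changes encoder weights too
  m2 <- set_encoder_frozen(m, FALSE)
  res2 <- nestcae:::run_phase(m2, x, y, x, y, "bce", 0.001, 1L, cfg, "probe")
  expect_false(identical(res2$checkpoint$weights[[1]]$W, m2$weights[[1]]$W))
})

test_that("tidiers expose per-epoch rows and per-phase summaries", {
  fx <- phase_fixture()
  cfg <- train_config(batch_size = 8, epochs_per_phase = c(2, 1, 1), seed = 2)
  p1 <- train_phase1_reconstruction(cae_model("reconstruction"),
                                    fx$train, fx$val, cfg)
  td <- tidy(p1)
  expect_identical(nrow(td), 2L)
  expect_named(td, c("phase", "epoch", "lr", "train_loss", "val_loss"))
  gl <- glance(p1)
  expect_identical(gl$best_epoch, p1$best_epoch)
  expect_identical(gl$phase, "reconstruction")
})
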