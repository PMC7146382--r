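test_that("the segmentation architecture matches the reference row for row", {
  arch <- build_architecture("segmentation")
  ref <- listing_reference()
  expect_identical(nrow(arch$layers), nrow(ref))
  expect_identical(arch$layers$name, ref$name)
  expect_identical(arch$layers$out_height, as.integer(ref$h))
  expect_identical(arch$layers$out_width, as.integer(ref$w))
  expect_identical(arch$layers$out_channels, as.integer(ref$c))
  expect_identical(arch$layers$params, as.integer(ref$params))
  expect_identical(sum(arch$layers$params), 822529L)
  # the code: 16x16x64 after the third max-pool
  enc <- arch$encoder_end_index
  expect_identical(arch$layers$name[enc], "max_pooling2d_2")
  expect_identical(unlist(arch$layers[enc, c("out_height", "out_width",
                                             "out_channels")], use.names = FALSE),
                   c(16L, 16L, 64L))
})

test_that("the two head variants differ only in the final conv layer", {
  seg <- build_architecture("segmentation")
  rec <- build_architecture("reconstruction")
  n <- nrow(seg$layers)
  expect_identical(seg$layers[-n, ], rec$layers[-n, ])
  expect_identical(rec$layers$out_channels[n], 3L)
  expect_identical(rec$layers$activation[n], "relu")
  expect_identical(seg$layers$out_channels[n], 1L)
  expect_identical(seg$layers$activation[n], "sigmoid")
  expect_identical(rec$layers$params[n], 867L)
  expect_identical(count_parameters(rec), 823107L)
})

test_that("parameter accounting is consistent across scopes", {
  arch <- build_architecture("segmentation")
  expect_identical(count_parameters(arch, "encoder"), 351552L)
  expect_identical(count_parameters(arch, "encoder") +
                     count_parameters(arch, "decoder"),
                   count_parameters(arch, "all"))
  per <- count_parameters(arch, "per_layer")
  expect_identical(sum(per$params), 822529L)
  expect_identical(per$params[per$name == "conv2d"], 896L)
})

test_that("the architecture summary prints the reference table", {
  txt <- format(build_architecture("segmentation"))
  expect_true(any(grepl("input_1 (InputLayer)", txt, fixed = TRUE)))
  expect_true(any(grepl("conv2d (Conv2D)", txt, fixed = TRUE) &
                    grepl("(None, 128, 128, 32)", txt, fixed = TRUE) &
                    grepl("896", txt)))
  expect_true(any(grepl("max_pooling2d_2 (MaxPooling2D)", txt, fixed = TRUE) &
                    grepl("(None, 16, 16, 64)", txt, fixed = TRUE)))
  expect_true(any(grepl("Total params: 822,529", txt, fixed = TRUE)))
  expect_true(any(grepl("Trainable params: 822,529", txt, fixed = TRUE)))
})

test_that("Glorot initialization is seeded, bounded and zero-biased", {
  m1 <- cae_model("segmentation", seed = 42)
  m2 <- cae_model("segmentation", seed = 42)
  m3 <- cae_model("segmentation", seed = 43)
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))
  tbl <- m1$architecture$layers
  for (l in which(tbl$kind == "conv")) {
    lim <- sqrt(6 / (9 * tbl$in_channels[l] + 9 * tbl$out_channels[l]))
    expect_true(all(abs(m1$weights[[l]]$W) <= lim))
    expect_identical(m1$weights[[l]]$b, numeric(tbl$out_channels[l]))
    expect_identical(dim(m1$weights[[l]]$W),
                     c(3L, 3L, tbl$in_channels[l], tbl$out_channels[l]))
  }
})

test_that("forward passes have the contracted shapes and ranges", {
  seg <- cae_model("segmentation", seed = 1)
  x <- array(runif(128 * 128 * 3 * 2), c(128, 128, 3, 2))
  out <- cae_forward(seg, x)
  expect_identical(dim(out), c(128L, 128L, 1L, 2L))
  expect_true(all(out > 0 & out < 1))

  rec <- cae_model("reconstruction", seed = 1)
  ro <- cae_forward(rec, array(0, c(128, 128, 3, 1)))
  expect_identical(dim(ro), c(128L, 128L, 3L, 1L))
  expect_true(all(is.finite(ro)))
  expect_true(all(ro >= 0))

  code <- cae_forward(seg, x, upto = seg$architecture$encoder_end_index)
  expect_identical(dim(code), c(16L, 16L, 64L, 2L))
  resumed <- cae_forward(seg, code,
                         from = seg$architecture$encoder_end_index + 1L)
  expect_equal(resumed, out, tolerance = 1e-6)

  expect_error(cae_forward(seg, array(0, c(64, 64, 3, 1))))
  expect_error(cae_forward(cae_model("segmentation"), x),
               class = "nestcae_contract_error")
})

test_that("encoder transfer copies weights bitwise and resets the decoder", {
  src <- cae_model("reconstruction", seed = 7)
  tgt <- transfer_encoder(src, "segmentation", seed = 8)
  enc <- seq_len(tgt$architecture$encoder_end_index)
  expect_identical(tgt$weights[enc], src$weights[enc])
  dec_conv <- setdiff(which(tgt$architecture$layers$kind == "conv"),
                      enc)
  for (l in head(dec_conv, -1)) {
    expect_false(identical(tgt$weights[[l]]$W, src$weights[[l]]$W))
  }
  expect_identical(count_parameters(tgt), 822529L)
  expect_error(transfer_encoder(cae_model("reconstruction"), "segmentation", 1),
               class = "nestcae_contract_error")
})

test_that("freezing flags exactly the encoder and unfreezing clears it", {
  m <- cae_model("segmentation", seed = 1)
  f <- set_encoder_frozen(m, TRUE)
  enc <- seq_len(m$architecture$encoder_end_index)
  expect_true(all(f$frozen[enc]))
  expect_false(any(f$frozen[-enc]))
  expect_false(any(set_encoder_frozen(f, FALSE)$frozen))
})

test_that("checkpoints round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".rds")
  m <- set_encoder_frozen(cae_model("segmentation", seed = 3), TRUE)
  save_checkpoint(m, path)
  expect_identical(load_checkpoint(path), m)
  expect_error(load_checkpoint("/nonexistent/ckpt.rds"),
               class = "nestcae_io_error")
})
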