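test_that("stratified split reproduces the 70-image study proportions", {
  corpus <- stub_corpus(70, 39)
  asn <- split_corpus(corpus, c(0.70, 0.143, 0.157), seed = 4)
  expect_identical(as.vector(table(asn$split)), c(49L, 10L, 11L))
  lab <- asn[asn$labeled, ]
  expect_identical(as.vector(table(lab$split)), c(27L, 6L, 6L))
  unl <- asn[!asn$labeled, ]
  expect_identical(as.vector(table(unl$split)), c(22L, 4L, 5L))
})

test_that("splits are deterministic, exhaustive and stratified within one image", {
  corpus <- stub_corpus(23, 9)
  a <- split_corpus(corpus, c(0.6, 0.2, 0.2), seed = 1)
  b <- split_corpus(corpus, c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(a, b)
  c <- split_corpus(corpus, c(0.6, 0.2, 0.2), seed = 2)
  expect_false(identical(a$split, c$split))
  expect_setequal(a$image_id, purrr::map_chr(corpus, "image_id"))
  expect_identical(anyDuplicated(a$image_id), 0L)
  # labeled share of each split within one image of the corpus share
  for (s in levels(a$split)) {
    sub <- a[a$split == s, ]
    expected <- nrow(sub) * 9 / 23
    expect_lte(abs(sum(sub$labeled) - expected), 1)
  }
  # three images, one per split
  tri <- split_corpus(stub_corpus(3, 3), c(1, 1, 1) / 3, seed = 5)
  expect_identical(as.vector(table(tri$split)), c(1L, 1L, 1L))
})

test_that("split rejects bad inputs", {
  expect_error(split_corpus(stub_corpus(2, 1)), class = "nestcae_config_error")
  expect_error(split_corpus(stub_corpus(5, 2), c(0.5, 0.3, 0.1)),
               class = "nestcae_config_error")
})

test_that("grid extraction matches the stride arithmetic", {
  p <- synth_params(image_height = 256, image_width = 256, labeled = FALSE)
  img <- generate_slide(p, seed = 2)
  pats <- extract_patches(img)
  expect_identical(nrow(pats), 4L)
  expect_identical(pats$row, c(0L, 0L, 128L, 128L))
  expect_identical(pats$col, c(0L, 128L, 0L, 128L))
  expect_false(any(pats$positive))
  expect_true(all(purrr::map_lgl(pats$mask, is.null)))

  one <- extract_patches(generate_slide(tiny_params(labeled = FALSE), seed = 2))
  expect_identical(nrow(one), 1L)
  expect_identical(dim(one$rgb[[1]]), c(128L, 128L, 3L))
})

test_that("extraction agrees with the exhaustive origin-enumeration oracle", {
  # synthetic mask: a 40x40 square centered at (128,128) on a 256x256 slide
  rgb <- array(runif(256 * 256 * 3), c(256, 256, 3))
  mask <- matrix(0L, 256, 256)
  mask[109:148, 109:148] <- 1L
  img <- structure(list(image_id = "sq", rgb = rgb, mask = mask,
                        labeled = TRUE), class = "slide_image")
  got <- extract_patches(img)
  want <- oracle_origins(mask)
  expect_identical(got$row, want$row)
  expect_identical(got$col, want$col)
  expect_identical(got$positive, unname(want$positive))

  # and on generated slides up to 512x512, including non-multiple sizes
  for (spec in list(c(256, 384), c(200, 200), c(512, 320))) {
    p <- synth_params(image_height = spec[1], image_width = spec[2],
                      nest_count_range = c(1, 3))
    s <- generate_slide(p, seed = spec[1] + spec[2])
    got <- extract_patches(s)
    want <- oracle_origins(s$mask)
    expect_identical(got$row, want$row)
    expect_identical(got$col, want$col)
    expect_identical(got$positive, unname(want$positive))
    expect_identical(anyDuplicated(got[, c("row", "col")]), 0L)
    expect_true(all(purrr::map_lgl(got$rgb, function(t)
      identical(dim(t), c(128L, 128L, 3L)))))
  }
})

test_that("finer positive stride never loses positive patches", {
  p <- synth_params(image_height = 256, image_width = 320)
  s <- generate_slide(p, seed = 9)
  n64 <- sum(extract_patches(s, patch_config(positive_stride = 64))$positive)
  n32 <- sum(extract_patches(s, patch_config(positive_stride = 32))$positive)
  n16 <- sum(extract_patches(s, patch_config(positive_stride = 16))$positive)
  expect_gte(n32, n64)
  expect_gte(n16, n32)
})

test_that("rotation augmentation emits four exact-count examples", {
  patch <- fixture_patch()
  aug <- augment_patch(patch)
  expect_identical(nrow(aug), 4L)
  expect_true(all(aug$augmented))

  # 180-degree rotation is an involution
  once <- augment_patch(patch, angles = 180)
  twice <- augment_patch(dplyr::mutate(once, augmented = FALSE), angles = 180)
  expect_identical(twice$rgb[[1]], patch$rgb[[1]])
  expect_identical(twice$mask[[1]], patch$mask[[1]])

  # right-angle rotation permutes pixels: mask pixel count preserved
  r90 <- augment_patch(patch, angles = 90)
  expect_identical(sum(r90$mask[[1]]), sum(patch$mask[[1]]))
  expect_identical(sort(as.vector(r90$rgb[[1]])), sort(as.vector(patch$rgb[[1]])))

  # free-angle rotation keeps shape and binarized mask
  r45 <- augment_patch(patch, angles = 45)
  expect_identical(dim(r45$rgb[[1]]), c(128L, 128L, 3L))
  expect_true(all(r45$mask[[1]] %in% c(0L, 1L)))
  expect_gt(sum(r45$mask[[1]]), 0)

  expect_error(augment_patch(fixture_patch(positive = FALSE)),
               class = "nestcae_usage_error")
})

test_that("balance report counts classes and augmentation evens them out", {
  empty <- fixture_patch()[0, ]
  expect_identical(balance_report(empty)$n_positive, 0L)
  expect_identical(balance_report(empty)$n_negative, 0L)
  both <- dplyr::bind_rows(fixture_patch(), fixture_patch(positive = FALSE))
  expect_identical(balance_report(both)$ratio, 1)

  # on large slides the plain grid is dominated by background windows;
  # overlap re-scanning plus rotation augmentation pulls the class ratio
  # toward 1
  p <- synth_params(image_height = 512, image_width = 512,
                    nest_count_range = c(1, 1),
                    nest_radius_range = c(10, 14))
  corpus <- generate_corpus(4, 1, p, seed = 21)
  asn <- split_corpus(corpus, c(1, 0, 0), seed = 1)
  plain <- patch_config(positive_stride = 128)  # disables overlap
  before <- balance_report(prepare_patches(corpus, asn, plain,
                                           augment = FALSE))
  after <- balance_report(prepare_patches(corpus, asn, patch_config(),
                                          augment = TRUE))
  expect_lte(abs(log(after$ratio)), abs(log(before$ratio)))
})

test_that("no patch from a held-out image reaches the training set", {
  corpus <- tiny_corpus(6, 0.5, seed = 13)
  asn <- split_corpus(corpus, c(0.5, 0.25, 0.25), seed = 2)
  patches <- prepare_patches(corpus, asn)
  for (s in c("validation", "test")) {
    held <- asn$image_id[asn$split == s]
    expect_false(any(patches$source_id[patches$split == "train"] %in% held))
  }
  expect_setequal(unique(patches$source_id), asn$image_id)
})
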