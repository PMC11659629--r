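test_that("fusion model construction validates crop geometry", {
  b <- build_fusion_model()
  expect_s3_class(b, "model_bundle")
  expect_equal(dim(b$params$w_mask), c(36, 8))
  expect_equal(b$spec$crop_px, 64L)
  expect_error(build_fusion_model(crop_px = 63), "incompatible crop size")
  expect_error(build_fusion_model(crop_px = 46), "incompatible crop size")
})

test_that("zero mask reproduces the RGB-only network exactly", {
  b <- build_fusion_model(seed = 1)
  set.seed(2)
  crops <- lapply(1:6, function(i) {
    structure(list(rgb = array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3)),
                   mask = matrix(FALSE, 64, 64)), class = "object_crop")
  })
  p_zero_mask <- predict_scores(b, crops)
  b_rgb_only <- b
  b_rgb_only$params$w_mask[] <- 0
  expect_equal(p_zero_mask$probability_mf,
               predict_scores(b_rgb_only, crops)$probability_mf,
               tolerance = 1e-14)

  # zeroed mask encoder: predictions independent of any mask
  crops_m <- lapply(crops, function(cr) {
    cr$mask <- matrix(runif(64 * 64) > 0.5, 64, 64); cr
  })
  expect_equal(predict_scores(b_rgb_only, crops_m)$probability_mf,
               predict_scores(b_rgb_only, crops)$probability_mf,
               tolerance = 1e-14)
  # ... while the fused model does respond to the mask
  expect_false(isTRUE(all.equal(predict_scores(b, crops_m)$probability_mf,
                                p_zero_mask$probability_mf)))
})

test_that("probabilities are a softmax and duplicates score identically", {
  b <- build_fusion_model(seed = 3)
  dset <- generate_labelled_crops(3, scene_config(seed = 30))
  crops <- c(dset$crops[1:4], dset$crops[1])  # duplicate of the first
  fw <- mitodetect:::.fusion_forward(b, stack_crops(crops))
  expect_equal(rowSums(fw$probs), rep(1, 5))
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_equal(fw$probs[5, ], fw$probs[1, ])
})

test_that("train/validation split is stratified, exhaustive and reproducible", {
  labels <- rep(c(TRUE, FALSE), c(100, 900))
  sp <- split_train_val(labels, 0.10, seed = 1)
  expect_length(sp$val, 100)
  expect_length(sp$train, 900)
  expect_setequal(c(sp$train, sp$val), 1:1000)
  # class ratio preserved within one item
  expect_equal(sum(labels[sp$val]), 10)
  sp2 <- split_train_val(labels, 0.10, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_val(labels, 0.10, seed = 2)))
  expect_warning(split_train_val(c(TRUE, rep(FALSE, 10)), 0.2, 1), "fewer than 2")
})

test_that("training is deterministic and rejects invalid configurations", {
  dset <- generate_labelled_crops(25, scene_config(seed = 31))
  d <- stack_crops(dset$crops)
  b1 <- train_classifier(d, dset$is_mf, train_config(epochs = 2), seed = 7)
  b2 <- train_classifier(d, dset$is_mf, train_config(epochs = 2), seed = 7)
  expect_identical(b1$history, b2$history)
  expect_identical(b1$params, b2$params)
  expect_error(train_config(epochs = 0))
  expect_error(train_classifier(matrix(numeric(0), 16384, 0), logical(0)),
               "empty")
})

test_that("raising the decision threshold never increases MF calls", {
  b <- desk_models(1)[[1]]
  ho <- holdout_crops()
  d <- stack_crops(ho$crops)
  counts <- vapply(seq(0, 1, by = 0.1), function(t) {
    sum(predict_scores(b, d, decision_threshold = t)$label == "MF")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("desk-scale training separates mitotic figures from mimics", {
  b <- desk_models(1)[[1]]
  expect_gte(tail(b$history$val_acc, 1), 0.95)
  ho <- holdout_crops()
  p <- predict_scores(b, ho$crops)
  tp <- sum(p$label == "MF" & ho$is_mf)
  fp <- sum(p$label == "MF" & !ho$is_mf)
  fn <- sum(p$label != "MF" & ho$is_mf)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)
})

test_that("majority voting follows the tie-to-negative rule", {
  mk <- function(labels) data.frame(
    crop_id = seq_along(labels), probability_mf = as.numeric(labels == "MF"),
    label = factor(labels, levels = c("non-MF", "MF")))
  v <- ensemble_vote(list(mk(c("MF", "non-MF")), mk(c("MF", "non-MF")),
                          mk(c("non-MF", "non-MF")), mk(c("MF", "MF")),
                          mk(c("non-MF", "MF"))))
  expect_equal(as.character(v$label), c("MF", "non-MF"))  # 3/5 and 2/5
  single <- ensemble_vote(list(mk(c("MF", "non-MF"))))
  expect_equal(as.character(single$label), c("MF", "non-MF"))
  tie <- ensemble_vote(list(mk(c("MF")), mk(c("non-MF"))))
  expect_equal(as.character(tie$label), "non-MF")
  bad <- mk(c("MF", "non-MF")); bad$crop_id <- c(5, 6)
  expect_error(ensemble_vote(list(mk(c("MF", "non-MF")), bad)), "misaligned")
})

test_that("model bundles survive a text serialisation round trip", {
  b <- desk_models(1)[[1]]
  dir <- file.path(tempdir(), "bundle-roundtrip")
  save_model_bundle(b, dir)
  b2 <- load_model_bundle(dir)
  ho <- holdout_crops()
  d <- stack_crops(ho$crops)
  expect_equal(predict_scores(b2, d)$probability_mf,
               predict_scores(b, d)$probability_mf, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
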