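test_that("chromogen-positive mask extraction follows the threshold rule", {
  white <- array(255, c(64, 64, 3))
  expect_false(any(extract_positive_mask(white)$mask))

  # brown disc (150, 90, 60) on a pink background (240, 180, 200)
  img <- array(0, c(64, 64, 3))
  img[, , 1] <- 240; img[, , 2] <- 180; img[, , 3] <- 200
  disc <- (row(img[, , 1]) - 32)^2 + (col(img[, , 1]) - 32)^2 <= 10^2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- c(150, 90, 60)[ch]
    img[, , ch] <- plane
  }
  th <- list(r = c(120, 255), g = c(0, 110), b = c(0, 100))
  out <- extract_positive_mask(img, th)
  expect_identical(out$mask, disc)
  expect_equal(nrow(out$components), 1)
  expect_equal(out$components$x_px, mean(which(disc, arr.ind = TRUE)[, 2] - 1))

  # second tiny blob below the minimum area is discarded
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[2:3, 2:3] <- c(150, 90, 60)[ch]
    img[, , ch] <- plane
  }
  out2 <- extract_positive_mask(img, th, min_area_px = 16)
  expect_equal(nrow(out2$components), 1)
})

test_that("affine estimation is exact on noiseless correspondences", {
  true_tf <- rbind(c(1.02, -0.05, 12), c(0.04, 0.98, -7))
  set.seed(50)
  src <- cbind(runif(40, 0, 500), runif(40, 0, 500))
  dst <- mitodetect:::.apply_affine(true_tf, src)
  fit <- estimate_affine_ransac(src, dst, registration_config(seed = 1))
  expect_true(fit$ok)
  expect_lt(max(abs(fit$transform - true_tf)), 1e-6)
  expect_length(fit$inliers, 40)
  expect_error(estimate_affine_ransac(src[1:2, ], dst[1:2, ]), "at least 3")
})

test_that("RANSAC recovers the transform under 30% gross outliers", {
  true_tf <- rbind(c(0.99, 0.03, 25), c(-0.02, 1.01, -14))
  set.seed(0)
  n <- 100
  src <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  dst <- mitodetect:::.apply_affine(true_tf, src) +
    matrix(rnorm(2 * n, 0, 0.5), n, 2)
  out_idx <- 1:30
  dst[out_idx, ] <- dst[out_idx, ] + matrix(runif(60, 50, 300), 30, 2)
  fit <- estimate_affine_ransac(src, dst, registration_config(seed = 0))
  expect_true(fit$ok)
  expect_lt(max(abs(fit$transform[, 1:2] - true_tf[, 1:2])), 0.01)
  expect_true(all(setdiff(1:n, out_idx) %in% fit$inliers))
  expect_false(any(out_idx %in% fit$inliers))
})

test_that("annotation transfer maps centroids exactly and flags bounds", {
  meta <- image_meta(200, 200)
  ann <- data.frame(x_px = c(10, 150), y_px = c(20, 198), class = "mf")
  ident <- rbind(c(1, 0, 0), c(0, 1, 0))
  same <- transfer_annotations(ann, ident, meta)
  expect_equal(same$x_px, ann$x_px)
  expect_false(any(same$out_of_bounds))

  shift <- rbind(c(1, 0, 10), c(0, 1, 5))
  moved <- transfer_annotations(ann, shift, meta)
  expect_equal(moved$x_px, ann$x_px + 10)
  expect_equal(moved$y_px, ann$y_px + 5)
  expect_equal(moved$out_of_bounds, c(FALSE, TRUE))
  expect_error(transfer_annotations(ann, rbind(c(1, 1, 0), c(1, 1, 0)), meta),
               "singular")
})

test_that("mask transfer under a near-rigid transform conserves area", {
  meta <- image_meta(128, 128)
  m <- matrix(FALSE, 128, 128)
  m[(row(m) - 60)^2 + (col(m) - 50)^2 <= 12^2] <- TRUE
  rot <- 3 * pi / 180
  tf <- rbind(c(cos(rot), -sin(rot), 8), c(sin(rot), cos(rot), 3))
  ann <- data.frame(x_px = 49, y_px = 59)
  out <- transfer_annotations(ann, tf, meta, masks = list(m))
  tm <- attr(out, "masks")[[1]]
  expect_lt(abs(sum(tm) - sum(m)) / sum(m), 0.05)
  # composition with the inverse returns the centroid within a pixel
  back <- transfer_annotations(out, affine_invert(tf), meta)
  expect_lt(abs(back$x_px - ann$x_px), 1)
  expect_lt(abs(back$y_px - ann$y_px), 1)
})
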