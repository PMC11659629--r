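test_that("point grid is cell-centred with the documented cardinality", {
  g <- generate_point_grid(1024, 64)
  expect_equal(nrow(g), 4096)
  expect_equal(g[1, ], c(x = 8, y = 8))
  expect_equal(unique(diff(sort(unique(g[, "x"])))), 16)
  expect_equal(generate_point_grid(64, 1), cbind(x = 32, y = 32))
  expect_error(generate_point_grid(0, 64), "positive")
})

test_that("box prompts preserve order and reject degenerate boxes", {
  boxes <- rbind(c(0, 0, 10, 10), c(5, 5, 9, 30), c(2, 2, 4, 4))
  pr <- prompts_from_boxes(boxes)
  expect_length(pr, 3)
  expect_equal(pr[[2]][["x1"]], 9)
  expect_error(prompts_from_boxes(rbind(c(10, 10, 10, 40))), "index 1")
  expect_equal(prompts_from_boxes(matrix(numeric(0), 0, 4)), list())
})

test_that("stability score matches a per-pixel enumeration oracle", {
  expect_equal(compute_stability_score(matrix(10, 4, 4), 1), 1)
  expect_equal(compute_stability_score(matrix(c(2, 0.5, -0.5, -2), 2, 2), 1),
               1 / 3)
  expect_equal(compute_stability_score(matrix(-10, 4, 4), 1), 0)

  oracle <- function(logits, offset) {
    inter <- 0; uni <- 0
    for (v in as.vector(logits)) {
      hi <- v >= offset; lo <- v >= -offset
      inter <- inter + (hi && lo); uni <- uni + (hi || lo)
    }
    if (uni == 0) 0 else inter / uni
  }
  set.seed(10)
  for (i in 1:25) {
    lg <- matrix(rnorm(16, 0, 2), 4, 4)
    off <- runif(1, 0.2, 2)
    expect_equal(compute_stability_score(lg, off), oracle(lg, off))
  }
  # monotone non-increasing in the offset
  lg <- matrix(rnorm(64, 0, 2), 8, 8)
  vals <- vapply(seq(0.1, 3, by = 0.1), compute_stability_score,
                 numeric(1), logits = lg)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("candidate filtering applies strict score and inclusive area rules", {
  cands <- list(
    disc_candidate(64, 20, 20, 3, quality = 0.9, stability = 0.9),    # ~1.8 um2, too small
    disc_candidate(128, 64, 64, 35, quality = 0.9, stability = 0.9),  # ~240 um2, too large
    disc_candidate(64, 20, 44, 3.5, quality = 0.79, stability = 0.95),
    disc_candidate(64, 44, 20, 3.5, quality = 0.95, stability = 0.8),
    disc_candidate(64, 32, 32, 5.6, quality = 0.9, stability = 0.9))  # ~6 um2, kept
  # area bounds inclusive in um2; strict > applied to quality and stability
  expect_lt(cands[[1]]$area_um2, 2.25)
  expect_gt(cands[[2]]$area_um2, 225)
  kept <- filter_candidates(cands, proposer_config())
  expect_length(kept, 1)
  expect_equal(kept[[1]]$centroid_x, cands[[5]]$centroid_x)
  expect_equal(kept[[1]]$area_um2, kept[[1]]$area_px * 0.0625)
  # idempotence and subset
  expect_identical(filter_candidates(kept, proposer_config()), kept)
  qs <- vapply(kept, `[[`, numeric(1), "quality")
  expect_true(all(qs %in% vapply(cands, `[[`, numeric(1), "quality")))
})

test_that("NMS keeps the highest-quality of overlapping candidates", {
  a <- disc_candidate(64, 30, 30, 8, quality = 0.95)
  b <- disc_candidate(64, 30, 30, 8, quality = 0.90)
  kept <- nms_dedupe(list(b, a), nms_iou = 0.7)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$quality, 0.95)

  disjoint <- nms_dedupe(list(disc_candidate(64, 15, 15, 6, 0.9),
                              disc_candidate(64, 48, 48, 6, 0.8)), 0.7)
  expect_length(disjoint, 2)

  # overlapping pair straddling the threshold
  p <- disc_candidate(64, 30, 30, 8, 0.95)
  q <- disc_candidate(64, 32, 30, 8, 0.90)
  iou <- mitodetect:::.box_iou(p$bbox, q$bbox)
  expect_gt(iou, 0.7)
  expect_length(nms_dedupe(list(p, q), nms_iou = 0.7), 1)
  expect_length(nms_dedupe(list(p, q), nms_iou = iou + 0.01), 2)
})

test_that("NMS is idempotent and output passes a brute-force pairwise audit", {
  set.seed(11)
  for (trial in 1:5) {
    cands <- lapply(1:20, function(i) {
      disc_candidate(128, runif(1, 10, 117), runif(1, 10, 117),
                     runif(1, 3, 10), quality = runif(1, 0.81, 1))
    })
    kept <- nms_dedupe(cands, nms_iou = 0.5)
    expect_identical(nms_dedupe(kept, 0.5), kept)
    if (length(kept) > 1) {
      for (i in 1:(length(kept) - 1)) for (j in (i + 1):length(kept)) {
        expect_lte(mitodetect:::.box_iou(kept[[i]]$bbox, kept[[j]]$bbox), 0.5)
      }
    }
  }
})

test_that("proposal stage recovers planted nuclei on synthetic scenes", {
  sc <- generate_scene(scene_config(
    scene_px = 512, counts = c(ordinary = 8, mf = 4, mlf = 4, clutter = 5),
    seed = 21))
  cands <- propose_objects(sc$rgb, reference_backend(), proposer_config(),
                           image_meta(512, 512))
  expect_gt(length(cands), 0)
  # every planted stained nucleus within the admissible area band must be
  # recovered (faint clutter debris sits near the segmentation threshold by
  # design and is not a nucleus)
  admissible <- sc$records[sc$records$area_um2 >= 2.25 &
                           sc$records$area_um2 <= 225 &
                           sc$records$class %in% c("ordinary", "mf", "mlf"), ]
  found <- vapply(seq_len(nrow(admissible)), function(i) {
    d <- sqrt((vapply(cands, `[[`, numeric(1), "centroid_x") - admissible$x_px[i])^2 +
              (vapply(cands, `[[`, numeric(1), "centroid_y") - admissible$y_px[i])^2)
    any(d < 8)
  }, logical(1))
  expect_gte(mean(found), 0.95)

  blank <- array(255, c(256, 256, 3))
  expect_length(propose_objects(blank, reference_backend(), proposer_config(),
                                image_meta(256, 256)), 0)
  tight <- proposer_config(area_max_um2 = 2.5)
  expect_length(propose_objects(sc$rgb, reference_backend(), tight,
                                image_meta(512, 512)), 0)
})

test_that("object crops are centred, padded and mask-conserving", {
  sc <- generate_scene(scene_config(scene_px = 256,
                                    counts = c(ordinary = 2, mf = 1, mlf = 1,
                                               clutter = 0),
                                    seed = 22))
  cands <- propose_objects(sc$rgb, reference_backend(), proposer_config(),
                           image_meta(256, 256))
  for (cm in cands) {
    crop <- extract_object_crop(sc$rgb, cm, 64)
    expect_equal(dim(crop$rgb), c(64, 64, 3))
    expect_equal(dim(crop$mask), c(64, 64))
    expect_lte(sum(crop$mask), cm$area_px)  # clipping can only remove
  }
  # centroid near an edge: still full-size via reflect padding
  edge <- disc_candidate(256, 5, 128, 4, 0.9)
  crop <- extract_object_crop(sc$rgb, edge, 64)
  expect_equal(dim(crop$rgb), c(64, 64, 3))
  expect_lte(sum(crop$mask), edge$area_px)
  expect_error(extract_object_crop(sc$rgb[1:32, 1:32, , drop = FALSE],
                                   edge, 64), "larger than tile")
})
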