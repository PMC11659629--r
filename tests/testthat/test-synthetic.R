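test_that("scene generation honours counts, classes and determinism", {
  cfg <- scene_config(scene_px = 256,
                      counts = c(ordinary = 4, mf = 2, mlf = 2, clutter = 3),
                      seed = 60)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$records), 11)
  expect_equal(as.integer(table(sc$records$class)[c("ordinary", "mf", "mlf", "clutter")]),
               c(4L, 2L, 2L, 3L))
  expect_length(sc$masks, 11)
  sc2 <- generate_scene(cfg)
  expect_identical(sc$rgb, sc2$rgb)
  expect_identical(sc$records, sc2$records)

  empty <- generate_scene(scene_config(scene_px = 128,
                                       counts = c(ordinary = 0, mf = 0,
                                                  mlf = 0, clutter = 0),
                                       seed = 1))
  expect_equal(nrow(empty$records), 0)

  expect_error(generate_scene(scene_config(scene_px = 128, seed = 2)),
               "infeasible packing")
})

test_that("re-rendering from records reproduces the raster bit for bit", {
  sc <- generate_scene(scene_config(scene_px = 256,
                                    counts = c(ordinary = 3, mf = 2, mlf = 1,
                                               clutter = 1),
                                    seed = 61))
  expect_identical(render_scene(sc), sc$rgb)
})

test_that("planted areas respect class ranges and the admissible band", {
  cfg <- scene_config(scene_px = 512, seed = 62)
  sc <- generate_scene(cfg)
  for (cl in unique(sc$records$class)) {
    a <- sc$records$area_um2[sc$records$class == cl]
    rng <- cfg$area_um2[[cl]]
    # rasterisation quantises the sampled area; allow one pixel ring of slack
    expect_true(all(a >= rng[1] * 0.7 & a <= rng[2] * 1.3))
  }
  mfa <- sc$records$area_um2[sc$records$class == "mf"]
  expect_true(all(mfa >= 2.25 & mfa <= 225))
  # spacing policy respected
  d <- as.matrix(dist(sc$records[, c("x_px", "y_px")]))
  diag(d) <- Inf
  expect_gte(min(d) * cfg$pixel_size_um, cfg$min_spacing_um * 0.5)
})

test_that("labelled crops carry exact masks and a separable signal", {
  dset <- generate_labelled_crops(50, scene_config(seed = 63))
  expect_length(dset$crops, 200)
  expect_equal(sum(dset$is_mf), 50)
  expect_equal(sum(!dset$is_mf), 150)
  expect_true(all(vapply(dset$crops, function(cr) sum(cr$mask) > 0, logical(1))))
  mean_od <- vapply(dset$crops, function(cr) {
    od <- od_transform(cr$rgb, "forward")
    mean(od[, , 1][cr$mask])
  }, numeric(1))
  expect_gt(mean(mean_od[dset$class == "mf"]),
            mean(mean_od[dset$class == "ordinary"]))
})

test_that("mosaic generation conserves ground truth and drops blank tiles", {
  mos <- desk_mosaic()
  per_tile <- vapply(mos$scenes, function(s) if (is.null(s)) 0L else nrow(s$records),
                     integer(1))
  expect_equal(nrow(mos$truth), sum(per_tile))
  expect_null(mos$scenes[[4]])  # the blank glass tile has no scene

  plan <- plan_tiles(mos$meta, downsample_gray(mos$rgb, 4),
                     tile_config(tile_px = 512, downsample_factor = 4))
  # the blank tile's centre region is not covered by any retained tile
  blank_cx <- mos$origins$origin_x_px[4] + 256
  blank_cy <- mos$origins$origin_y_px[4] + 256
  covered <- any(plan$origin_x_px <= blank_cx & blank_cx < plan$origin_x_px + 512 &
                 plan$origin_y_px <= blank_cy & blank_cy < plan$origin_y_px + 512 &
                 plan$tissue_fraction > 0.5)
  expect_false(covered)
  expect_lt(nrow(plan), ceiling(dim(mos$rgb)[1] / 512)^2)

  cfg <- scene_config(scene_px = 256,
                      counts = c(ordinary = 2, mf = 1, mlf = 1, clutter = 1),
                      seed = 64)
  m1 <- generate_wsi_like(2, cfg, n_blank = 1)
  m2 <- generate_wsi_like(2, cfg, n_blank = 1)
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$rgb, m2$rgb)
})
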