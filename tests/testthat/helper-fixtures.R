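# Shared fixtures, built in code and memoised for the session so the
# expensive ones (trained models) are paid for once across test files.

.fixture_cache <- new.env(parent = emptyenv())

# standard desk-scale training set: 500 crops per class (2000 total)
desk_crops <- function() {
  if (is.null(.fixture_cache$crops)) {
    .fixture_cache$crops <- generate_labelled_crops(500, scene_config(seed = 42))
  }
  .fixture_cache$crops
}

# k models from the five-seed protocol, 10 desk epochs on the desk crops
desk_models <- function(k = 1L) {
  if (is.null(.fixture_cache$models)) .fixture_cache$models <- list()
  seeds <- 0:4
  for (i in seq_len(k)) {
    key <- as.character(seeds[i])
    if (is.null(.fixture_cache$models[[key]])) {
      ds <- desk_crops()
      .fixture_cache$models[[key]] <- train_classifier(
        ds$crops, ds$is_mf, train_config(epochs = 10), seed = seeds[i])
    }
  }
  lapply(as.character(seeds[seq_len(k)]), function(key) .fixture_cache$models[[key]])
}

# small held-out crop set from an independent seed
holdout_crops <- function() {
  if (is.null(.fixture_cache$holdout)) {
    .fixture_cache$holdout <- generate_labelled_crops(100, scene_config(seed = 99))
  }
  .fixture_cache$holdout
}

# 2x2 mosaic (one blank tile) used by pipeline and acceptance tests
desk_mosaic <- function() {
  if (is.null(.fixture_cache$mosaic)) {
    .fixture_cache$mosaic <- generate_wsi_like(
      4, scene_config(scene_px = 512,
                      counts = c(ordinary = 8, mf = 4, mlf = 4, clutter = 5),
                      seed = 11),
      n_blank = 1)
  }
  .fixture_cache$mosaic
}

mosaic_run_config <- function() {
  run_config(tiling = tile_config(tile_px = 512, downsample_factor = 4),
             training = train_config(epochs = 10))
}

# build a candidate from a disc mask placed on an npx-square tile
disc_candidate <- function(npx, cx, cy, r, quality = 0.9, stability = 0.9,
                           pixel_size_um = 0.25) {
  xs <- matrix(rep(0:(npx - 1L), each = npx), npx, npx)
  ys <- matrix(rep(0:(npx - 1L), times = npx), npx, npx)
  candidate_mask((xs - cx)^2 + (ys - cy)^2 <= r^2, quality, stability,
                 pixel_size_um)
}
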