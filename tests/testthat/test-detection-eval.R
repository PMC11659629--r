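test_that("distance matching applies the radius rule one-to-one", {
  cfg <- match_config(radius_um = 7.5)
  gt <- data.frame(x_um = 50, y_um = 50)
  hit <- match_detections(data.frame(x_um = 50, y_um = 50), gt, cfg)
  expect_equal(c(hit$n_tp, hit$n_fp, hit$n_fn), c(1, 0, 0))

  miss <- match_detections(data.frame(x_um = 58, y_um = 50), gt, cfg)
  expect_equal(c(miss$n_tp, miss$n_fp, miss$n_fn), c(0, 1, 1))

  two <- match_detections(data.frame(x_um = c(52, 55), y_um = c(50, 50)), gt, cfg)
  expect_equal(c(two$n_tp, two$n_fp, two$n_fn), c(1, 1, 0))
  expect_equal(as.integer(two$pairs[1, 1]), 1L)  # the nearer one is matched

  expect_error(match_detections(data.frame(x = 1, y = 2), gt, cfg), "x_um")
})

test_that("matching is order invariant and monotone in the radius", {
  set.seed(40)
  det <- data.frame(x_um = runif(15, 0, 100), y_um = runif(15, 0, 100))
  gt <- data.frame(x_um = runif(12, 0, 100), y_um = runif(12, 0, 100))
  m1 <- match_detections(det, gt, match_config(10))
  perm <- sample(nrow(det))
  m2 <- match_detections(det[perm, ], gt, match_config(10))
  expect_equal(m1$n_tp, m2$n_tp)
  tps <- vapply(c(1, 2, 5, 7.5, 10, 20, 50), function(r) {
    match_detections(det, gt, match_config(r))$n_tp
  }, numeric(1))
  expect_true(all(diff(tps) >= 0))
})

test_that("greedy matching is within one pair of the exhaustive optimum", {
  set.seed(41)
  for (trial in 1:20) {
    nd <- sample(1:6, 1); ng <- sample(1:6, 1)
    det <- data.frame(x_um = runif(nd, 0, 30), y_um = runif(nd, 0, 30))
    gt <- data.frame(x_um = runif(ng, 0, 30), y_um = runif(ng, 0, 30))
    cfg <- match_config(radius_um = 10)
    g <- match_detections(det, gt, cfg, method = "greedy")
    o <- match_detections(det, gt, cfg, method = "optimal")
    expect_lte(g$n_tp, o$n_tp)
    expect_gte(g$n_tp, o$n_tp - 1)
  }
})

test_that("metrics follow the precision/recall/F1 identities", {
  m <- compute_metrics(list(n_tp = 82, n_fp = 18, n_fn = 12))
  expect_equal(m$precision, 0.82)
  expect_equal(round(m$f1, 2), 0.85)
  perfect <- compute_metrics(list(n_tp = 5, n_fp = 0, n_fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  none <- compute_metrics(list(n_tp = 0, n_fp = 0, n_fn = 0))
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  expect_true(none$degenerate)
  expect_error(compute_metrics(list(n_tp = -1, n_fp = 0, n_fn = 0)), "negative")
  # harmonic mean identity
  expect_equal(f1_score(0.82, 0.88), 2 * 0.82 * 0.88 / (0.82 + 0.88))
  expect_equal(f1_score(0, 0), 0)
})

test_that("run summaries report mean, sample sd and ensemble rows", {
  mk <- function(p, r) compute_metrics(list(
    n_tp = round(100 * r), n_fp = round(100 * r * (1 - p) / p),
    n_fn = round(100 * (1 - r))))
  runs <- list(mk(0.8, 0.9), mk(0.82, 0.88), mk(0.84, 0.86),
               mk(0.81, 0.89), mk(0.83, 0.87))
  rep1 <- summarize_runs(runs, ensemble = mk(0.85, 0.9))
  expect_equal(rep1$n_runs, 5)
  expect_equal(rep1$f1_mean, mean(vapply(runs, `[[`, numeric(1), "f1")))
  expect_equal(rep1$f1_sd, sd(vapply(runs, `[[`, numeric(1), "f1")))
  expect_false(rep1$single_run)
  expect_false(is.na(rep1$f1_ensemble))

  rep2 <- summarize_runs(runs[1])
  expect_equal(rep2$f1_sd, 0)
  expect_true(rep2$single_run)

  rep3 <- summarize_runs(c(runs[1:2], runs[3:4]),
                         group = c("breast", "breast", "melanoma", "melanoma"))
  expect_equal(nrow(rep3), 2)
  expect_setequal(rep3$group, c("breast", "melanoma"))
  lines <- capture.output(format_report(rep3))
  expect_length(lines, 3)
  expect_match(lines[1], "Precision")
})
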