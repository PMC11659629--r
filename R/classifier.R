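#' Training configuration for the mask-fusion classifier
#'
#' Defaults mirror the detection protocol: learning rate 0.001, 30 epochs,
#' AdamW with decoupled weight decay, cosine-annealing learning-rate
#' schedule, a stratified 90/10 train/validation split, five random seeds
#' and a 0.5 decision threshold. The reference batch size in the protocol is
#' 8000, a GPU-scale setting; this package trains on CPU at desk scale, so
#' the default here is 64 — small enough that the cosine schedule sees a
#' useful number of optimiser steps on datasets of a few thousand crops —
#' with otherwise identical semantics.
#'
#' @param learning_rate Initial learning rate.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled weight-decay coefficient (applied to
#'   weights, not biases).
#' @param val_fraction Validation fraction of the data.
#' @param seeds Integer seeds; one model is trained per seed.
#' @param decision_threshold Mitotic-figure probability threshold.
#' @param class_weights Optional length-2 numeric (non-MF, MF) loss weights;
#'   \code{NULL} (default) trains unweighted.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 0.001,
                         epochs = 30L,
                         batch_size = 64L,
                         weight_decay = 1e-4,
                         val_fraction = 0.10,
                         seeds = 0:4,
                         decision_threshold = 0.5,
                         class_weights = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            val_fraction > 0, val_fraction < 1,
            decision_threshold >= 0, decision_threshold <= 1,
            weight_decay >= 0, length(seeds) >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, val_fraction = val_fraction,
                 seeds = as.integer(seeds),
                 decision_threshold = decision_threshold,
                 class_weights = class_weights),
            class = "train_config")
}

# im2col index table for one channel of a crop_px image:
# rows = output positions (oy fastest), cols = kernel taps (dy fastest).
.im2col_index <- function(crop_px, kernel_px, stride) {
  out_px <- (crop_px - kernel_px) %/% stride + 1L
  oy <- rep(0:(out_px - 1L), times = out_px)
  ox <- rep(0:(out_px - 1L), each = out_px)
  dy <- rep(0:(kernel_px - 1L), times = kernel_px)
  dx <- rep(0:(kernel_px - 1L), each = kernel_px)
  idx <- outer(oy * stride + 1L, dy, `+`) + outer(ox * stride, dx, `+`) * crop_px
  storage.mode(idx) <- "integer"
  list(idx = idx, out_px = out_px)
}

#' Build a mask-fusion classifier
#'
#' Constructs a compact convolutional network over 4-channel object crops
#' (RGB + binary mask). The RGB channels pass through the first convolution
#' (with bias); the mask channel is encoded by a separate stride-matched
#' convolution \emph{without bias} whose output is summed into the first
#' convolution's output before the activation. An all-zero mask therefore
#' reproduces the RGB-only network output exactly. The fused activation is
#' average-pooled and classified by a 2-logit softmax head.
#'
#' @param crop_px Crop edge length (default 64). Must satisfy
#'   \code{(crop_px - kernel_px)} divisible by \code{stride} with the
#'   convolution output divisible by \code{pool_px}.
#' @param n_filters First-layer filter count.
#' @param kernel_px Convolution kernel size.
#' @param stride Convolution stride.
#' @param pool_px Average-pooling window (non-overlapping).
#' @param seed Seed for weight initialisation.
#' @return An object of class \code{model_bundle} holding the weights, the
#'   architecture/preprocessing spec and provenance fields.
#' @export
build_fusion_model <- function(crop_px = 64L, n_filters = 8L, kernel_px = 6L,
                               stride = 2L, pool_px = 5L, seed = 0L) {
  if ((crop_px - kernel_px) %% stride != 0L) {
    stop("incompatible crop size: (crop_px - kernel_px) must be divisible by stride")
  }
  out_px <- (crop_px - kernel_px) %/% stride + 1L
  if (out_px %% pool_px != 0L) {
    stop("incompatible crop size: convolution output ", out_px,
         " not divisible by pool_px ", pool_px)
  }
  set.seed(seed)
  k2 <- kernel_px^2
  n_feat <- (out_px %/% pool_px)^2 * n_filters
  params <- list(
    w_rgb = matrix(stats::rnorm(3L * k2 * n_filters, 0, sqrt(2 / (3 * k2))),
                   3L * k2, n_filters),
    b_rgb = numeric(n_filters),
    w_mask = matrix(stats::rnorm(k2 * n_filters, 0, sqrt(2 / k2)),
                    k2, n_filters),
    w_fc = matrix(stats::rnorm(n_feat * 2L, 0, sqrt(2 / n_feat)), n_feat, 2L),
    b_fc = numeric(2L))
  structure(list(
    params = params,
    spec = list(crop_px = as.integer(crop_px), n_filters = as.integer(n_filters),
                kernel_px = as.integer(kernel_px), stride = as.integer(stride),
                pool_px = as.integer(pool_px), out_px = out_px,
                n_feat = n_feat, rgb_scale = 255, rgb_offset = 0.5),
    seed = as.integer(seed), history = NULL, train_config = NULL,
    data_hash = NULL),
    class = "model_bundle")
}

#' Stack object crops into the classifier's input matrix
#'
#' Flattens each crop into a column: the three RGB planes scaled and
#' centred to \code{[-0.5, 0.5]} (\code{x / rgb_scale - rgb_offset})
#' followed by the binary mask plane. Centring keeps the first-layer
#' gradients well conditioned; the constants live in the model's
#' preprocessing spec.
#'
#' @param crops List of \code{object_crop}s (\code{rgb} in \code{[0,255]},
#'   logical \code{mask}).
#' @param spec A model spec (for the crop size and RGB scale); defaults to
#'   the standard 64 px / 255 layout.
#' @return Numeric matrix, \code{4 * crop_px^2} rows by \code{length(crops)}
#'   columns.
#' @export
stack_crops <- function(crops, spec = list(crop_px = 64L, rgb_scale = 255,
                                      rgb_offset = 0.5)) {
  n <- length(crops)
  px2 <- spec$crop_px^2
  off <- spec$rgb_offset %||% 0.5
  d <- matrix(0, 4L * px2, n)
  for (i in seq_len(n)) {
    cr <- crops[[i]]
    if (nrow(cr$mask) != spec$crop_px) {
      stop("crop ", i, " has size ", nrow(cr$mask), ", expected ", spec$crop_px)
    }
    d[, i] <- c(as.vector(cr$rgb) / spec$rgb_scale - off, as.numeric(cr$mask))
  }
  d
}

# Forward pass over stacked crops (columns of d). Returns probabilities and,
# when want_cache, the intermediates needed for the backward pass.
.fusion_forward <- function(bundle, d, want_cache = FALSE) {
  sp <- bundle$spec
  p <- bundle$params
  n <- ncol(d)
  px2 <- sp$crop_px^2
  ic <- .im2col_index(sp$crop_px, sp$kernel_px, sp$stride)
  npos <- nrow(ic$idx)
  ktaps <- ncol(ic$idx)
  idx_rgb <- cbind(ic$idx, ic$idx + px2, ic$idx + 2L * px2)
  idx_mask <- ic$idx + 3L * px2
  p_rgb <- matrix(0, n * npos, 3L * ktaps)
  p_mask <- matrix(0, n * npos, ktaps)
  for (i in seq_len(n)) {
    col <- d[, i]
    rows <- ((i - 1L) * npos + 1L):(i * npos)
    p_rgb[rows, ] <- col[idx_rgb]
    p_mask[rows, ] <- col[idx_mask]
  }
  z <- p_rgb %*% p$w_rgb + p_mask %*% p$w_mask
  z <- sweep(z, 2L, p$b_rgb, `+`)
  a <- pmax(z, 0)
  # non-overlapping average pooling via rowsum over (image, pool-cell) groups
  grid <- sp$out_px %/% sp$pool_px
  oy <- rep(0:(sp$out_px - 1L), times = sp$out_px)
  ox <- rep(0:(sp$out_px - 1L), each = sp$out_px)
  cell <- (oy %/% sp$pool_px) + (ox %/% sp$pool_px) * grid  # 0-based
  ncell <- grid^2
  grp <- rep((0:(n - 1L)) * ncell, each = npos) + rep(cell, times = n)
  pooled <- rowsum(a, grp, reorder = TRUE) / sp$pool_px^2  # (n*ncell) x F
  arr <- array(pooled, dim = c(ncell, n, sp$n_filters))
  feats <- matrix(aperm(arr, c(2L, 1L, 3L)), n, sp$n_feat)
  logits <- sweep(feats %*% p$w_fc, 2L, p$b_fc, `+`)
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  out <- list(probs = probs)
  if (want_cache) {
    out$cache <- list(p_rgb = p_rgb, p_mask = p_mask, z = z, feats = feats,
                      grp = grp, cell = cell, npos = npos, ncell = ncell, n = n)
  }
  out
}

# Backward pass: gradient of mean (weighted) cross-entropy w.r.t. parameters.
.fusion_backward <- function(bundle, fw, y_onehot, weights = NULL) {
  sp <- bundle$spec
  p <- bundle$params
  ca <- fw$cache
  n <- ca$n
  w <- if (is.null(weights)) rep(1, n) else weights
  dlogits <- (fw$probs - y_onehot) * (w / sum(w))
  d_wfc <- crossprod(ca$feats, dlogits)
  d_bfc <- colSums(dlogits)
  dfeat <- dlogits %*% t(p$w_fc)
  darr <- array(dfeat, dim = c(n, ca$ncell, sp$n_filters))
  dpool <- matrix(aperm(darr, c(2L, 1L, 3L)), n * ca$ncell, sp$n_filters)
  rowmap <- rep((0:(n - 1L)) * ca$ncell, each = ca$npos) + rep(ca$cell, times = n) + 1L
  da <- dpool[rowmap, , drop = FALSE] / sp$pool_px^2
  dz <- da * (ca$z > 0)
  list(w_rgb = crossprod(ca$p_rgb, dz),
       b_rgb = colSums(dz),
       w_mask = crossprod(ca$p_mask, dz),
       w_fc = d_wfc, b_fc = d_bfc)
}

#' Stratified train/validation split
#'
#' Splits sample indices into disjoint, exhaustive train and validation
#' sets, stratified by class so the class ratio is preserved in both parts
#' (within one item per class). Reproducible for a fixed seed.
#'
#' @param labels Class label per sample (factor, character or logical).
#' @param val_fraction Validation fraction in (0, 1); default 0.10.
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{val}.
#' @export
split_train_val <- function(labels, val_fraction = 0.10, seed = 0L) {
  n <- length(labels)
  if (n == 0L) stop("empty dataset")
  stopifnot(val_fraction > 0, val_fraction < 1)
  set.seed(seed)
  labels <- as.factor(labels)
  val <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      warning("class '", cl, "' has fewer than 2 members; degenerate stratification")
      next
    }
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Train the mask-fusion classifier
#'
#' Minimises (optionally class-weighted) cross-entropy with AdamW
#' (decoupled weight decay on the weight matrices, none on biases) under a
#' cosine-annealing learning-rate schedule. Training is deterministic for a
#' fixed seed: the split, weight initialisation and batch shuffling all draw
#' from the seeded R generator.
#'
#' @param crops List of \code{object_crop}s, or a pre-stacked matrix from
#'   [stack_crops()].
#' @param is_mf Logical vector: is each crop a mitotic figure?
#' @param config A [train_config()].
#' @param seed Seed for this run (defaults to the first of
#'   \code{config$seeds}).
#' @param crop_px Crop size forwarded to [build_fusion_model()].
#' @return A \code{model_bundle} with a \code{history} data.frame (epoch,
#'   learning rate, training loss, validation loss and accuracy) and split
#'   provenance attached.
#' @export
train_classifier <- function(crops, is_mf, config = train_config(),
                             seed = config$seeds[1], crop_px = 64L) {
  stopifnot(inherits(config, "train_config"))
  d <- if (is.matrix(crops)) crops else
    stack_crops(crops, list(crop_px = crop_px, rgb_scale = 255, rgb_offset = 0.5))
  n <- ncol(d)
  if (n == 0L) stop("empty training set")
  if (length(is_mf) != n) stop("is_mf length must match the number of crops")
  split <- split_train_val(is_mf, config$val_fraction, seed)
  bundle <- build_fusion_model(crop_px = crop_px, seed = seed)
  bundle$train_config <- config
  bundle$seed <- as.integer(seed)
  bundle$data_hash <- sprintf("n%d-s%.6f", n, sum(d) / n)
  bundle$split <- split

  y <- cbind(1 - as.numeric(is_mf), as.numeric(is_mf))
  wts <- NULL
  if (!is.null(config$class_weights)) {
    wts <- ifelse(is_mf, config$class_weights[2], config$class_weights[1])
  }
  opt <- lapply(bundle$params, function(p) list(m = p * 0, v = p * 0))
  step <- 0L
  decay_mask <- c(w_rgb = TRUE, b_rgb = FALSE, w_mask = TRUE,
                  w_fc = TRUE, b_fc = FALSE)
  hist <- vector("list", config$epochs)
  tr <- split$train
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- sample(tr)
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      fw <- .fusion_forward(bundle, d[, bi, drop = FALSE], want_cache = TRUE)
      wb <- if (is.null(wts)) NULL else wts[bi]
      wnorm <- if (is.null(wb)) rep(1, length(bi)) else wb
      losses <- c(losses, sum(-log(pmax(rowSums(fw$probs * y[bi, , drop = FALSE]),
                                        1e-12)) * wnorm) / sum(wnorm))
      grads <- .fusion_backward(bundle, fw, y[bi, , drop = FALSE], wb)
      step <- step + 1L
      for (nm in names(bundle$params)) {
        g <- grads[[nm]]
        opt[[nm]]$m <- 0.9 * opt[[nm]]$m + 0.1 * g
        opt[[nm]]$v <- 0.999 * opt[[nm]]$v + 0.001 * g^2
        mhat <- opt[[nm]]$m / (1 - 0.9^step)
        vhat <- opt[[nm]]$v / (1 - 0.999^step)
        upd <- mhat / (sqrt(vhat) + 1e-8)
        if (decay_mask[[nm]]) upd <- upd + config$weight_decay * bundle$params[[nm]]
        bundle$params[[nm]] <- bundle$params[[nm]] - lr * upd
      }
    }
    vi <- split$val
    vf <- .fusion_forward(bundle, d[, vi, drop = FALSE])
    val_loss <- mean(-log(pmax(rowSums(vf$probs * y[vi, , drop = FALSE]), 1e-12)))
    val_acc <- mean((vf$probs[, 2] >= config$decision_threshold) == is_mf[vi])
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = mean(losses),
                                val_loss = val_loss, val_acc = val_acc)
  }
  bundle$history <- do.call(rbind, hist)
  bundle
}

#' Score object crops with a trained model
#'
#' @param bundle A \code{model_bundle}.
#' @param crops List of \code{object_crop}s or a pre-stacked matrix.
#' @param decision_threshold Mitotic-figure probability threshold; a crop is
#'   labelled \code{"MF"} iff its probability is >= the threshold.
#' @param crop_id Optional identifiers (default sequential).
#' @return data.frame with \code{crop_id}, \code{probability_mf},
#'   \code{label} (factor MF / non-MF).
#' @export
predict_scores <- function(bundle, crops, decision_threshold = 0.5,
                           crop_id = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  d <- if (is.matrix(crops)) crops else stack_crops(crops, bundle$spec)
  if (nrow(d) != 4L * bundle$spec$crop_px^2) {
    stop("crop shape does not match the model's preprocessing spec")
  }
  fw <- .fusion_forward(bundle, d)
  n <- ncol(d)
  if (is.null(crop_id)) crop_id <- seq_len(n)
  data.frame(crop_id = crop_id,
             probability_mf = fw$probs[, 2],
             label = factor(ifelse(fw$probs[, 2] >= decision_threshold,
                                   "MF", "non-MF"),
                            levels = c("non-MF", "MF")))
}

#' Majority-vote ensembling of prediction records
#'
#' Combines the labels of k models on the same crops by majority vote; an
#' exact tie (even k) resolves conservatively to non-MF.
#'
#' @param records List of prediction data.frames from [predict_scores()],
#'   one per model, with aligned \code{crop_id}s.
#' @return data.frame with \code{crop_id}, \code{votes_mf}, \code{k},
#'   \code{probability_mf} (mean across models) and the ensemble
#'   \code{label}.
#' @export
ensemble_vote <- function(records) {
  stopifnot(length(records) >= 1)
  ids <- records[[1]]$crop_id
  for (r in records[-1]) {
    if (length(r$crop_id) != length(ids) || any(r$crop_id != ids)) {
      stop("prediction records have misaligned crop ids")
    }
  }
  k <- length(records)
  votes <- Reduce(`+`, lapply(records, function(r) as.integer(r$label == "MF")))
  prob <- Reduce(`+`, lapply(records, function(r) r$probability_mf)) / k
  data.frame(crop_id = ids, votes_mf = votes, k = k, probability_mf = prob,
             label = factor(ifelse(votes * 2L > k, "MF", "non-MF"),
                            levels = c("non-MF", "MF")))
}

#' Serialise / load a model bundle as plain text
#'
#' Writes the weights and the architecture/preprocessing spec to a directory
#' as JSON (weights included), so bundles survive text-only storage.
#'
#' @param bundle A \code{model_bundle}.
#' @param dir Target directory (created if missing).
#' @return \code{save_model_bundle}: the directory, invisibly;
#'   \code{load_model_bundle}: the restored \code{model_bundle}.
#' @export
save_model_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(spec = bundle$spec, seed = bundle$seed,
              data_hash = bundle$data_hash,
              params = lapply(bundle$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), x = as.vector(p))
                else list(dim = NULL, x = as.vector(p))
              }))
  jsonlite::write_json(out, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  params <- lapply(raw$params, function(p) {
    if (length(p$dim) == 2) matrix(as.numeric(p$x), p$dim[[1]], p$dim[[2]])
    else as.numeric(p$x)
  })
  structure(list(params = params, spec = as.list(raw$spec),
                 seed = raw$seed, data_hash = raw$data_hash,
                 history = NULL, train_config = NULL),
            class = "model_bundle")
}
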