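#' Detection-matching configuration
#'
#' @param radius_um Maximum centroid distance for a detection to match a
#'   ground-truth object (default 7.5 um, i.e. 30 px at 0.25 um/px — the
#'   mitosis-benchmark community convention; the matching criterion is a
#'   convention, so results depend on it and it is configurable).
#' @param pixel_size_um Pixel size used when converting pixel coordinates.
#' @return An object of class \code{match_config}.
#' @export
match_config <- function(radius_um = 7.5, pixel_size_um = 0.25) {
  stopifnot(radius_um > 0, pixel_size_um > 0)
  structure(list(radius_um = radius_um, pixel_size_um = pixel_size_um),
            class = "match_config")
}

# enumerate all one-to-one assignments maximising matched pairs, then pick
# the one with the smallest total distance; only for small oracle instances
.match_optimal <- function(dmat, radius) {
  nd <- nrow(dmat)
  ng <- ncol(dmat)
  if (nd == 0L || ng == 0L) return(matrix(integer(0), ncol = 2))
  if (nd > 8L || ng > 8L) stop("optimal matching is an oracle for small instances (<= 8)")
  best <- list(n = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, cost) {
    if (i > nd) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, used, pairs, cost)  # leave detection i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && dmat[i, j] <= radius) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)), cost + dmat[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), matrix(integer(0), ncol = 2), 0)
  best$pairs
}

#' Match detections to ground truth
#'
#' One-to-one matching of detection and ground-truth centroids in a common
#' micrometre frame. The default policy is greedy nearest-first: candidate
#' pairs within \code{radius_um} are sorted by ascending distance and
#' accepted while both endpoints are free (deterministic and order
#' independent). Unmatched detections are false positives; unmatched truths
#' are false negatives. An exhaustive optimal matcher is available for small
#' oracle instances.
#'
#' @param detections data.frame with \code{x_um}, \code{y_um}.
#' @param truth data.frame with \code{x_um}, \code{y_um}.
#' @param config A [match_config()].
#' @param method \code{"greedy"} (default) or \code{"optimal"}.
#' @return A \code{match_result}: list with \code{n_tp}, \code{n_fp},
#'   \code{n_fn} and \code{pairs} (two-column matrix of detection/truth row
#'   indices).
#' @export
match_detections <- function(detections, truth, config = match_config(),
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  for (df in list(detections, truth)) {
    if (nrow(df) > 0 && (is.null(df$x_um) || is.null(df$y_um))) {
      stop("coordinates must be provided in micrometre columns x_um / y_um")
    }
  }
  nd <- nrow(detections)
  ng <- nrow(truth)
  pairs <- matrix(integer(0), ncol = 2)
  if (nd > 0L && ng > 0L) {
    dmat <- sqrt(outer(detections$x_um, truth$x_um, `-`)^2 +
                 outer(detections$y_um, truth$y_um, `-`)^2)
    if (method == "optimal") {
      pairs <- .match_optimal(dmat, config$radius_um)
    } else {
      cand <- which(dmat <= config$radius_um, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(dmat[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        det_free <- rep(TRUE, nd)
        tru_free <- rep(TRUE, ng)
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]
          j <- cand[r, 2]
          if (det_free[i] && tru_free[j]) {
            pairs <- rbind(pairs, c(i, j))
            det_free[i] <- FALSE
            tru_free[j] <- FALSE
          }
        }
      }
    }
  }
  n_tp <- nrow(pairs)
  structure(list(n_tp = n_tp, n_fp = nd - n_tp, n_fn = ng - n_tp,
                 pairs = pairs),
            class = "match_result")
}

#' Precision, recall and F1 from matched counts
#'
#' \code{Precision = N_TP / (N_TP + N_FP)}, \code{Recall = N_TP /
#' (N_TP + N_FN)}, \code{F1 = 2 P R / (P + R)}. Zero denominators yield 0
#' with a \code{degenerate} flag so aggregate reports never hold undefined
#' entries.
#'
#' @param match A \code{match_result} from [match_detections()], or a list
#'   with \code{n_tp}, \code{n_fp}, \code{n_fn}.
#' @return A \code{metrics} object: list with \code{precision},
#'   \code{recall}, \code{f1}, \code{degenerate}.
#' @export
compute_metrics <- function(match) {
  n_tp <- match$n_tp
  n_fp <- match$n_fp
  n_fn <- match$n_fn
  if (any(c(n_tp, n_fp, n_fn) < 0)) stop("negative counts")
  degenerate <- FALSE
  precision <- if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else { degenerate <- TRUE; 0 }
  recall <- if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else { degenerate <- TRUE; 0 }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "metrics")
}

#' F1 score as the harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors.
#' @return \code{2 P R / (P + R)}, 0 where both are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Summarise detection metrics across runs
#'
#' Aggregates per-run (per-seed) metrics into a benchmark-style report row:
#' per-metric mean and sample standard deviation (n-1 denominator; reported
#' as 0 and flagged when n = 1), plus the ensemble F1 when ensemble metrics
#' are supplied. With a grouping vector (e.g. tumour type), one row is
#' produced per group.
#'
#' @param metrics_list List of \code{metrics} objects (or a list of lists
#'   when grouped).
#' @param ensemble Optional \code{metrics} object for the ensemble run (or a
#'   list per group).
#' @param group Optional character vector naming the group of each element
#'   of \code{metrics_list}.
#' @return data.frame with columns \code{group}, \code{n_runs},
#'   \code{precision_mean}, \code{precision_sd}, \code{recall_mean},
#'   \code{recall_sd}, \code{f1_mean}, \code{f1_sd}, \code{f1_ensemble},
#'   \code{single_run}.
#' @export
summarize_runs <- function(metrics_list, ensemble = NULL, group = NULL) {
  stopifnot(length(metrics_list) >= 1)
  if (is.null(group)) group <- rep("all", length(metrics_list))
  rows <- lapply(unique(group), function(g) {
    ms <- metrics_list[group == g]
    p <- vapply(ms, `[[`, numeric(1), "precision")
    r <- vapply(ms, `[[`, numeric(1), "recall")
    f <- vapply(ms, `[[`, numeric(1), "f1")
    n <- length(ms)
    sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    ens <- NA_real_
    if (!is.null(ensemble)) {
      e <- if (inherits(ensemble, "metrics")) ensemble else ensemble[[g]]
      if (!is.null(e)) ens <- e$f1
    }
    data.frame(group = g, n_runs = n,
               precision_mean = mean(p), precision_sd = sd0(p),
               recall_mean = mean(r), recall_sd = sd0(r),
               f1_mean = mean(f), f1_sd = sd0(f),
               f1_ensemble = ens, single_run = n == 1L)
  })
  do.call(rbind, rows)
}

#' Format a summary report as a text table
#'
#' @param report data.frame from [summarize_runs()].
#' @return Character vector of formatted lines (also printed).
#' @export
format_report <- function(report) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  lines <- c(sprintf("%-22s %-13s %-13s %-13s %-11s", "Group", "Precision",
                     "Recall", "F1", "Ensemble F1"))
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf(
      "%-22s %-13s %-13s %-13s %-11s",
      report$group[i],
      fmt(report$precision_mean[i], report$precision_sd[i]),
      fmt(report$recall_mean[i], report$recall_sd[i]),
      fmt(report$f1_mean[i], report$f1_sd[i]),
      ifelse(is.na(report$f1_ensemble[i]), "-",
             sprintf("%.2f", report$f1_ensemble[i]))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
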