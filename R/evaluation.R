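#' Pair ground-truth events with detections by greedy vicinity matching
#'
#' Candidate pairs within `radius_um` are taken globally closest first, each
#' ground-truth event and each detection used at most once. Leftover ground
#' truth is missed; leftover detections are spurious.
#'
#' @param gt data.frame with `x_um`, `y_um` of ground-truth events.
#' @param detections data.frame with `x_um`, `y_um` of detected events.
#' @param radius_um pairing radius; default the merged-event scale (3/4
#'   wavelength, 385 um) beyond which two echoes are distinct events.
#' @return list: `pairs` (data.frame `gt`, `det`, `deviation_um` -- row
#'   indices into the inputs), `missed` (gt row indices), `spurious`
#'   (detection row indices).
#' @export
pair_events <- function(gt, detections, radius_um = merge_threshold_um()) {
  ng <- nrow(gt); nd <- nrow(detections)
  if (ng == 0 || nd == 0) {
    return(list(pairs = data.frame(gt = integer(0), det = integer(0),
                                   deviation_um = numeric(0)),
                missed = seq_len(ng), spurious = seq_len(nd)))
  }
  d <- sqrt(outer(gt$x_um, detections$x_um, "-")^2 +
            outer(gt$y_um, detections$y_um, "-")^2)
  cand <- which(d <= radius_um, arr.ind = TRUE)
  used_g <- logical(ng); used_d <- logical(nd)
  pairs <- matrix(0L, 0, 2)
  devs <- numeric(0)
  if (nrow(cand) > 0) {
    ord <- order(d[cand])
    cand <- cand[ord, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (used_g[a] || used_d[b]) next
      used_g[a] <- TRUE; used_d[b] <- TRUE
      pairs <- rbind(pairs, c(a, b))
      devs <- c(devs, d[a, b])
    }
  }
  list(pairs = data.frame(gt = pairs[, 1], det = pairs[, 2],
                          deviation_um = devs),
       missed = which(!used_g), spurious = which(!used_d))
}

#' Root-mean-square localization error of paired events
#'
#' @param pairs a `pairs` data.frame from [pair_events()], or a numeric
#'   vector of deviations in micrometers.
#' @return `sqrt(mean(deviation^2))` in micrometers; NA with zero pairs.
#' @export
compute_rmse <- function(pairs) {
  e <- if (is.data.frame(pairs)) pairs$deviation_um else pairs
  if (length(e) == 0) return(NA_real_)
  sqrt(mean(e^2))
}

#' Ground-truth event table for evaluation
#'
#' Collapses per-particle ground truth into the events the detector is scored
#' against. In `merged` mode each merged-label cluster becomes one event at
#' the intensity-weighted mean of its constituent particle centers (weights:
#' rendered peak intensities, matching what the localizer estimates). In
#' `single` mode only well-separated particles (clusters of one) are kept.
#'
#' @param gt `ground_truth` data.frame (needs `merged_label`; uses
#'   `peak_intensity` weights when present).
#' @param mode `"merged"` or `"single"`.
#' @return data.frame `frame`, `x_um`, `y_um`, `n_particles`.
#' @export
gt_event_table <- function(gt, mode = c("merged", "single")) {
  mode <- match.arg(mode)
  w <- if ("peak_intensity" %in% names(gt)) gt$peak_intensity else rep(1, nrow(gt))
  key <- interaction(gt$frame, gt$merged_label, drop = TRUE)
  n <- tapply(w, key, length)
  ev <- data.frame(frame = as.integer(tapply(gt$frame, key, `[`, 1)),
                   x_um = as.numeric(tapply(w * gt$x_um, key, sum) /
                                     tapply(w, key, sum)),
                   y_um = as.numeric(tapply(w * gt$y_um, key, sum) /
                                     tapply(w, key, sum)),
                   n_particles = as.integer(n))
  if (mode == "single") ev <- ev[ev$n_particles == 1, ]
  ev <- ev[order(ev$frame), ]
  rownames(ev) <- NULL
  ev
}

#' Score a detection run against simulator ground truth
#'
#' Pairs detections with ground-truth events frame by frame and aggregates
#' the five accuracy statistics: RMSE, missed and spurious percentages, and
#' the minimum and maximum paired deviation.
#'
#' @param gt `ground_truth` data.frame from the simulator.
#' @param events detection events data.frame.
#' @param mode ground-truth collapsing mode, see [gt_event_table()].
#' @param radius_um pairing radius.
#' @param gradient_events optional second detection run (the gradient-relief
#'   baseline); when given, its report is attached for comparison.
#' @return an `evaluation_report`: counts, `rmse_um`, `missed_pct`,
#'   `spurious_pct`, `min_dev_um`, `max_dev_um` and the per-pair table.
#' @export
evaluate_run <- function(gt, events, mode = c("merged", "single"),
                         radius_um = merge_threshold_um(),
                         gradient_events = NULL) {
  mode <- match.arg(mode)
  gte <- gt_event_table(gt, mode)
  frames <- sort(unique(c(gte$frame, events$frame)))
  devs <- numeric(0)
  pair_rows <- list()
  n_missed <- 0L; n_spur <- 0L
  for (fr in frames) {
    g <- gte[gte$frame == fr, ]
    e <- events[events$frame == fr, ]
    pr <- pair_events(g, e, radius_um)
    n_missed <- n_missed + length(pr$missed)
    n_spur <- n_spur + length(pr$spurious)
    if (nrow(pr$pairs) > 0) {
      devs <- c(devs, pr$pairs$deviation_um)
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(frame = fr, gt_x_um = g$x_um[pr$pairs$gt],
                   gt_y_um = g$y_um[pr$pairs$gt],
                   det_x_um = e$x_um[pr$pairs$det],
                   det_y_um = e$y_um[pr$pairs$det],
                   deviation_um = pr$pairs$deviation_um)
    }
  }
  n_gt <- nrow(gte); n_det <- nrow(events); n_pairs <- length(devs)
  rep <- structure(list(
    mode = mode, radius_um = radius_um,
    n_ground_truth = n_gt, n_detected = n_det, n_pairs = n_pairs,
    rmse_um = compute_rmse(devs),
    missed_pct = if (n_gt > 0) 100 * n_missed / n_gt else NA_real_,
    spurious_pct = if (n_det > 0) 100 * n_spur / n_det else NA_real_,
    min_dev_um = if (n_pairs > 0) min(devs) else NA_real_,
    max_dev_um = if (n_pairs > 0) max(devs) else NA_real_,
    pair_table = if (length(pair_rows) > 0) do.call(rbind, pair_rows)
                 else data.frame()), class = "evaluation_report")
  if (!is.null(gradient_events)) {
    rep$gradient <- evaluate_run(gt, gradient_events, mode, radius_um)
    rep$gradient$pair_table <- NULL
  }
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$mode, " mode, radius ", x$radius_um, " um)\n",
      sep = "")
  cat(sprintf("  ground truth %d | detected %d | paired %d\n",
              x$n_ground_truth, x$n_detected, x$n_pairs))
  cat(sprintf("  RMSE %.1f um | missed %.2f%% | spurious %.2f%% | dev [%.1f, %.1f] um\n",
              x$rmse_um, x$missed_pct, x$spurious_pct,
              x$min_dev_um, x$max_dev_um))
  if (!is.null(x$gradient))
    cat(sprintf("  gradient baseline: RMSE %.1f um | missed %.2f%%\n",
                x$gradient$rmse_um, x$gradient$missed_pct))
  invisible(x)
}
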