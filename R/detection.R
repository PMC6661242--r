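#' Detection parameters
#'
#' The manual inputs of the detector: expected echo intensity, the admissible
#' echo size range, the multiscale blob-kernel sizes, the smoothing and
#' local-maxima widths used for seeding, and the probability-image region
#' threshold. `mean_echo_intensity` and `noise_threshold` default to the
#' sequence's estimated noise level at run time (NULL here).
#'
#' @param mean_echo_intensity minimum admissible mean region intensity
#'   (grayscale); NULL = the sequence noise level.
#' @param min_echo_area minimum echo area in pixels.
#' @param max_echo_area maximum echo area in pixels; set large (Inf) to keep
#'   merged events, ~20 px to keep single events only.
#' @param haar_scales center half-widths (px) of the blob kernels; defaults
#'   match the 8/12/20 px echo-area scales.
#' @param gaussian_sigma smoothing sigma (px) shared by seed detection and the
#'   watershed relief; default 1 px, matched to the ~1 px echo core.
#' @param local_maxima_width local-maxima neighborhood width (px); larger
#'   values merge nearby peaks into a single detection. The default 3 px
#'   (~400 um at the reference pitch) matches the merged-event scale.
#' @param region_threshold region threshold as a fraction of the maximum
#'   particle probability (1/e).
#' @param noise_threshold significance threshold in grayscale units; NULL =
#'   the sequence's average noise level.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(mean_echo_intensity = NULL, min_echo_area = 5,
                             max_echo_area = Inf, haar_scales = c(1, 2, 3),
                             gaussian_sigma = 1, local_maxima_width = 3,
                             region_threshold = exp(-1),
                             noise_threshold = NULL) {
  stopifnot(min_echo_area >= 1, max_echo_area > min_echo_area,
            region_threshold > 0, region_threshold < 1,
            length(haar_scales) >= 1, all(haar_scales >= 1))
  structure(list(mean_echo_intensity = mean_echo_intensity,
                 min_echo_area = min_echo_area, max_echo_area = max_echo_area,
                 haar_scales = haar_scales, gaussian_sigma = gaussian_sigma,
                 local_maxima_width = local_maxima_width,
                 region_threshold = region_threshold,
                 noise_threshold = noise_threshold),
            class = "detection_params")
}

# box sums over (2h+1)^2 windows via an integral image; edge windows are
# truncated and `count` carries the actual number of covered pixels
box_sum <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - h, 1); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1); c1 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r1 + 1, c1 + 1] - S[r0, c1 + 1] - S[r1 + 1, c0] + S[r0, c0]
  counts <- outer(r1 - r0 + 1, c1 - c0 + 1)
  list(sum = sums, count = counts)
}

#' Multiscale Haar-like blob feature image
#'
#' For each scale `h` a center-surround kernel is applied: the mean over the
#' (2h+1)^2 core minus the mean over the surrounding ring out to three core
#' widths. Kernels have zero mean and unit positive mass, so responses are in
#' intensity units. The feature image is the per-pixel maximum response across
#' scales, normalized to [0, 1].
#'
#' @param frame grayscale matrix.
#' @param haar_scales integer core half-widths in pixels.
#' @return normalized feature matrix with attributes `max_response` (the
#'   normalization constant, intensity units) and `kernel_l2` (per-scale
#'   kernel L2 norms, for noise calibration).
#' @export
haar_feature_image <- function(frame, haar_scales = c(1, 2, 3)) {
  stopifnot(length(haar_scales) >= 1)
  H_out <- 3 * (2 * max(haar_scales) + 1) %/% 2
  if (2 * H_out + 1 > min(dim(frame)))
    stop("configuration error: haar scale larger than the frame")
  resp <- NULL
  l2 <- numeric(length(haar_scales))
  for (k in seq_along(haar_scales)) {
    h <- haar_scales[k]
    H <- (3 * (2 * h + 1)) %/% 2 # outer half-width: ring spans 3 core widths
    core <- box_sum(frame, h)
    outer_ <- box_sum(frame, H)
    ring_sum <- outer_$sum - core$sum
    ring_cnt <- outer_$count - core$count
    r <- core$sum / core$count - ring_sum / pmax(ring_cnt, 1)
    n_core <- (2 * h + 1)^2
    n_ring <- (2 * H + 1)^2 - n_core
    l2[k] <- sqrt(1 / n_core + 1 / n_ring)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  mx <- max(resp)
  # a flat frame gives responses at rounding-error scale; treat as zero
  if (mx <= max(abs(frame)) * 1e-10) mx <- 0
  out <- if (mx > 0) pmax(resp, 0) / mx else matrix(0, nrow(frame), ncol(frame))
  attr(out, "max_response") <- mx
  attr(out, "kernel_l2") <- l2
  out
}

# Bonferroni bound on the per-pixel false-positive rate of thresholding the
# max-over-scales response at `threshold` (intensity units) under N(0, sigma)
# pixel noise.
haar_nominal_tail <- function(threshold, noise_sigma, kernel_l2) {
  sum(stats::pnorm(threshold / (noise_sigma * kernel_l2), lower.tail = FALSE))
}

#' Particle probability image
#'
#' Thresholds the normalized feature image at the noise level to get a binary
#' significance image, identifies its 8-connected components, and inside each
#' component sets every pixel to the fraction of significant pixels within a
#' local window matched to the component's bounding-box scale. Values are in
#' [0, 1] and zero wherever the significance image is zero.
#'
#' @param frame grayscale matrix (same shape as the feature image).
#' @param feature_image output of [haar_feature_image()].
#' @param noise_threshold significance threshold. In grayscale units when the
#'   feature image carries its `max_response` attribute (the usual case:
#'   pass the sequence's noise level), otherwise in normalized units.
#' @param mask optional `artifact_mask`; masked pixels are never significant.
#' @return matrix of class `ppi` with attribute `components` (labeled
#'   significance components).
#' @export
particle_probability_image <- function(frame, feature_image, noise_threshold,
                                       mask = NULL) {
  stopifnot(all(dim(frame) == dim(feature_image)))
  mx <- attr(feature_image, "max_response")
  thr <- if (!is.null(mx) && mx > 0) noise_threshold / mx else noise_threshold
  sig <- feature_image > thr
  if (!is.null(mask)) sig[mask] <- FALSE
  comp <- cpp_label8(sig)
  ppi <- matrix(0, nrow(frame), ncol(frame))
  labs <- setdiff(unique(as.integer(comp)), 0L)
  if (length(labs) > 0) {
    idx <- which(comp > 0)
    rows <- (idx - 1) %% nrow(comp) + 1
    cols <- (idx - 1) %/% nrow(comp) + 1
    lab <- comp[idx]
    # window side = mean bounding-box side (robust to elongation)
    side <- vapply(split(seq_along(idx), lab), function(ii) {
      (diff(range(rows[ii])) + diff(range(cols[ii]))) / 2 + 1
    }, numeric(1))
    win <- pmax(as.integer(side), 3L)
    halves <- (win - 1L) %/% 2L
    for (h in unique(halves)) {
      bs <- box_sum(sig + 0, h)
      frac <- bs$sum / bs$count
      sel <- lab %in% as.integer(names(side))[halves == h]
      ppi[idx[sel]] <- frac[idx[sel]]
    }
  }
  attr(ppi, "components") <- comp
  class(ppi) <- c("ppi", class(ppi))
  ppi
}

#' Watershed seed points and initial regions
#'
#' Initial regions are the 8-connected components of the particle probability
#' image above `region_threshold` times its maximum. Candidate seeds are the
#' local maxima of the Gaussian-smoothed frame within a
#' `local_maxima_width`-sized neighborhood; only maxima inside an initial
#' region (where the probability is above threshold) survive. A region whose
#' maxima were all smoothed away still contributes one seed at its brightest
#' smoothed pixel, so no region is left unseeded.
#'
#' @param frame grayscale matrix.
#' @param ppi a [particle_probability_image()].
#' @param params a [detection_params()].
#' @return list with `seeds` (data.frame row, col, region), `regions`
#'   (labeled matrix of initial regions) and `smoothed` (the smoothed frame).
#' @export
detect_seeds <- function(frame, ppi, params = detection_params()) {
  mx <- max(ppi)
  regions <- matrix(0L, nrow(frame), ncol(frame))
  smoothed <- smooth_frame(frame, params$gaussian_sigma)
  if (mx <= 0) {
    return(list(seeds = data.frame(row = integer(0), col = integer(0),
                                   region = integer(0)),
                regions = regions, smoothed = smoothed))
  }
  inregion <- ppi >= params$region_threshold * mx
  regions <- cpp_label8(inregion)
  h <- max(1L, as.integer(params$local_maxima_width) %/% 2L)
  maxima <- cpp_local_maxima(smoothed, h)
  keep <- which(maxima & regions > 0)
  seeds <- data.frame(row = (keep - 1) %% nrow(frame) + 1,
                      col = (keep - 1) %/% nrow(frame) + 1,
                      region = regions[keep])
  # guarantee one seed per region
  missing <- setdiff(setdiff(unique(as.integer(regions)), 0L), seeds$region)
  if (length(missing) > 0) {
    extra <- lapply(missing, function(lb) {
      ii <- which(regions == lb)
      best <- ii[which.max(smoothed[ii])]
      data.frame(row = (best - 1) %% nrow(frame) + 1,
                 col = (best - 1) %/% nrow(frame) + 1, region = lb)
    })
    seeds <- rbind(seeds, do.call(rbind, extra))
  }
  seeds <- seeds[order(seeds$region, seeds$row, seeds$col), ]
  rownames(seeds) <- NULL
  list(seeds = seeds, regions = regions, smoothed = smoothed)
}
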