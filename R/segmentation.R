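# Gaussian smoothing (EBImage) returned as a plain matrix
smooth_frame <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  m <- EBImage::imageData(EBImage::gblur(frame, sigma = sigma))
  matrix(as.numeric(m), nrow(frame), ncol(frame))
}

#' Marker-controlled watershed segmentation of seeded regions
#'
#' Segments each seeded region by flooding a relief image from the seed
#' markers, with every pixel outside the initial regions acting as a
#' background marker. The relief is either the inverted Gaussian-smoothed
#' frame (`max - smoothed`: bright echoes become basins, so the flood
#' recovers the full above-floor echo footprint) or, as the comparison
#' baseline, the gradient magnitude of the smoothed frame (whose ridge at the
#' echo's steepest slope cedes the outer annulus to the background, shrinking
#' the segmented area).
#'
#' @param frame grayscale matrix.
#' @param seeds seed data.frame (`row`, `col`) from [detect_seeds()].
#' @param regions labeled initial-region matrix from [detect_seeds()].
#' @param relief `"inverted_gaussian"` (the operative choice) or
#'   `"gradient"` (baseline).
#' @param gaussian_sigma smoothing sigma in pixels.
#' @param smoothed optional precomputed smoothed frame.
#' @param floor optional noise floor (grayscale). When given, the flood
#'   domain is the set of pixels whose smoothed intensity exceeds the floor
#'   (plus the seeds themselves): segmented regions then extend to the echo's
#'   above-floor footprint -- which is how the inverted-Gaussian relief
#'   recovers the echo area that the feature-domain significance footprint
#'   under-covers -- while staying clear of background noise. NULL confines
#'   the flood strictly to the initial regions.
#' @return integer label matrix: pixel value k belongs to seed k (row order
#'   of `seeds`), 0 is background.
#' @export
watershed_segment <- function(frame, seeds, regions,
                              relief = c("inverted_gaussian", "gradient"),
                              gaussian_sigma = 1, smoothed = NULL,
                              floor = NULL) {
  relief <- match.arg(relief)
  stopifnot(nrow(seeds) >= 1)
  if (any(seeds$row < 1 | seeds$row > nrow(frame) |
          seeds$col < 1 | seeds$col > ncol(frame)))
    stop("contract violation: seed outside the frame")
  sm <- smoothed %||% smooth_frame(frame, gaussian_sigma)
  rel <- if (relief == "inverted_gaussian") {
    max(sm) - sm
  } else {
    gx <- cbind(sm[, 2] - sm[, 1],
                (sm[, -(1:2), drop = FALSE] - sm[, 1:(ncol(sm) - 2), drop = FALSE]) / 2,
                sm[, ncol(sm)] - sm[, ncol(sm) - 1])
    gy <- rbind(sm[2, ] - sm[1, ],
                (sm[-(1:2), , drop = FALSE] - sm[1:(nrow(sm) - 2), , drop = FALSE]) / 2,
                sm[nrow(sm), ] - sm[nrow(sm) - 1, ])
    sqrt(gx^2 + gy^2)
  }
  domain <- if (is.null(floor)) regions > 0 else sm > floor
  domain[cbind(seeds$row, seeds$col)] <- TRUE
  markers <- matrix(0L, nrow(frame), ncol(frame))
  markers[!domain] <- -1L # background floods inward from outside the domain
  markers[cbind(seeds$row, seeds$col)] <- seq_len(nrow(seeds))
  mask <- matrix(TRUE, nrow(frame), ncol(frame))
  cpp_marker_watershed(rel, markers, mask)
}

#' Filter segmented regions into detection events
#'
#' Applies the paper-style size/intensity refinement: regions smaller than
#' `min_echo_area`, dimmer on average than `mean_echo_intensity`, or larger
#' than `max_echo_area` are eliminated (the residual noise classifier).
#' Surviving regions are localized by intensity-weighted centroid and flagged
#' `single` or `merged` by comparing their area with the single-event upper
#' quartile.
#'
#' @param labels label matrix from [watershed_segment()].
#' @param frame the original frame (intensity source).
#' @param params a [detection_params()]; `mean_echo_intensity` must be set.
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @param frame_index frame index recorded in the events.
#' @param single_q3_px area above which an event is flagged merged.
#' @return data.frame of detection events: `frame`, `x_um`, `y_um`,
#'   `area_px`, `mean_intensity`, `peak_intensity`, `kind`, `region`.
#' @export
filter_regions <- function(labels, frame, params, pixel_pitch_um = 132,
                           frame_index = 1L, single_q3_px = 20) {
  idx <- which(labels > 0)
  empty <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0),
                      peak_intensity = numeric(0), kind = character(0),
                      region = integer(0))
  if (length(idx) == 0) return(empty)
  lab <- labels[idx]
  inten <- frame[idx]
  rows <- (idx - 1) %% nrow(frame) + 1
  cols <- (idx - 1) %/% nrow(frame) + 1
  area <- tapply(inten, lab, length)
  tot <- tapply(inten, lab, sum)
  pk <- tapply(inten, lab, max)
  sx <- tapply(inten * px_center_x(cols, pixel_pitch_um), lab, sum)
  sy <- tapply(inten * px_center_y(rows, pixel_pitch_um), lab, sum)
  mean_int <- tot / area
  keep <- area >= params$min_echo_area & area <= params$max_echo_area &
    mean_int >= (params$mean_echo_intensity %||% 0) & tot > 0
  if (!any(keep)) return(empty)
  data.frame(frame = frame_index,
             x_um = (sx / tot)[keep], y_um = (sy / tot)[keep],
             area_px = as.integer(area[keep]),
             mean_intensity = as.numeric(mean_int[keep]),
             peak_intensity = as.numeric(pk[keep]),
             kind = ifelse(area[keep] > single_q3_px, "merged", "single"),
             region = as.integer(names(area))[keep],
             row.names = NULL)
}

#' Intensity-weighted center of mass of an event
#'
#' @param pixels data.frame with `row`, `col` of the event's pixel set.
#' @param intensities intensity at each pixel (positive total).
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @return c(x_um, y_um): the centroid in physical coordinates.
#' @export
localize <- function(pixels, intensities, pixel_pitch_um = 132) {
  stopifnot(nrow(pixels) >= 1, length(intensities) == nrow(pixels))
  tot <- sum(intensities)
  if (tot <= 0) stop("degenerate event: zero total intensity")
  c(x_um = sum(intensities * px_center_x(pixels$col, pixel_pitch_um)) / tot,
    y_um = sum(intensities * px_center_y(pixels$row, pixel_pitch_um)) / tot)
}

#' Detect, segment and localize microbubble events in one frame
#'
#' The per-frame pipeline: multiscale Haar features, particle probability
#' image, seed detection, marker-controlled watershed, size/intensity
#' filtering and centroid localization.
#'
#' @param frame grayscale matrix.
#' @param params a [detection_params()].
#' @param noise_sigma the sequence's noise level (grayscale units); fills the
#'   params' NULL thresholds.
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @param frame_index frame index stamped on the events.
#' @param relief watershed relief, see [watershed_segment()].
#' @param mask optional `artifact_mask`.
#' @param nlm apply the adaptive nonlocal-means pre-filter ([nlm_filter()])
#'   before the Haar stage; off by default (synthetic noise is already
#'   white, the filter is denoising support for real loops).
#' @return events data.frame as in [filter_regions()].
#' @export
detect_events <- function(frame, params = detection_params(), noise_sigma,
                          pixel_pitch_um = 132, frame_index = 1L,
                          relief = "inverted_gaussian", mask = NULL,
                          nlm = FALSE) {
  params$noise_threshold <- params$noise_threshold %||% noise_sigma
  params$mean_echo_intensity <- params$mean_echo_intensity %||% noise_sigma
  if (isTRUE(nlm)) frame <- nlm_filter(frame, noise_sigma)
  feat <- haar_feature_image(frame, params$haar_scales)
  ppi <- particle_probability_image(frame, feat, params$noise_threshold, mask)
  sd <- detect_seeds(frame, ppi, params)
  if (nrow(sd$seeds) == 0) {
    return(filter_regions(matrix(0L, nrow(frame), ncol(frame)), frame, params,
                          pixel_pitch_um, frame_index))
  }
  labels <- watershed_segment(frame, sd$seeds, sd$regions, relief,
                              params$gaussian_sigma, smoothed = sd$smoothed,
                              floor = params$noise_threshold)
  filter_regions(labels, frame, params, pixel_pitch_um, frame_index)
}

#' Run detection over a whole sequence
#'
#' @param x a `frame_sequence`.
#' @param params a [detection_params()].
#' @param mode `"merged"` keeps single and overlapping events
#'   (`max_echo_area` set large); `"single"` keeps only single-sized events
#'   (`max_echo_area` 20 px unless set explicitly).
#' @param relief watershed relief.
#' @param mask optional `artifact_mask`.
#' @param noise_sigma noise level; estimated from the sequence when NULL.
#' @param nlm apply the nonlocal-means pre-filter per frame (off by default).
#' @return events data.frame across frames, with attributes `noise_sigma` and
#'   `mode`.
#' @export
run_detection <- function(x, params = detection_params(),
                          mode = c("merged", "single"),
                          relief = "inverted_gaussian", mask = NULL,
                          noise_sigma = NULL, nlm = FALSE) {
  stopifnot(inherits(x, "frame_sequence"))
  mode <- match.arg(mode)
  noise_sigma <- noise_sigma %||% estimate_noise_sigma(x)
  if (is.infinite(params$max_echo_area) && mode == "single")
    params$max_echo_area <- 20
  out <- vector("list", length(x$frames))
  for (fr in seq_along(x$frames)) {
    out[[fr]] <- detect_events(x$frames[[fr]], params, noise_sigma,
                               x$pixel_pitch_um, fr, relief, mask, nlm)
  }
  ev <- do.call(rbind, out)
  attr(ev, "noise_sigma") <- noise_sigma
  attr(ev, "mode") <- mode
  ev
}
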