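#' Target size distribution of microbubble echoes
#'
#' Pixel-area distribution (at the reference 132 um pitch) that sampled echo
#' appearances must reproduce when rendered and thresholded at half maximum:
#' hard minimum 5 px, quartiles 8 and 20 px, median 12 px. Modeled as
#' `min_px` plus a log-normal fitted to the shifted quartiles, which pins the
#' minimum and both quartiles exactly and puts the median at 11.7 px.
#'
#' @param min_px hard minimum area (px).
#' @param q1_px,median_px,q3_px target quartiles (px).
#' @param pixel_pitch_um pixel pitch the areas refer to.
#' @return an object of class `echo_size_model`.
#' @export
echo_size_model <- function(min_px = 5, q1_px = 8, median_px = 12, q3_px = 20,
                            pixel_pitch_um = 132) {
  if (min_px > median_px || q1_px <= min_px || q3_px <= q1_px)
    stop("configuration error: infeasible size model (need min < Q1 < Q3)")
  z75 <- qnorm(0.75)
  meanlog <- (log(q1_px - min_px) + log(q3_px - min_px)) / 2
  sdlog <- (log(q3_px - min_px) - log(q1_px - min_px)) / (2 * z75)
  structure(list(min_px = min_px, q1_px = q1_px, median_px = median_px,
                 q3_px = q3_px, pixel_pitch_um = pixel_pitch_um,
                 meanlog = meanlog, sdlog = sdlog),
            class = "echo_size_model")
}

#' Sample microbubble echo appearances
#'
#' Each microbubble images as an anisotropic 2D Gaussian (the empirical
#' point-spread model: elliptical, variably oriented). The size distribution
#' the paper reports is that of *detected* echo areas, i.e. footprints above
#' the detection floor (the sequence noise level), so appearances are drawn
#' such that the area above `floor` -- `2 log(peak / floor) * pi * sigma_major
#' * sigma_minor / pitch^2` -- follows `size_model`. Aspect ratio is uniform
#' in `aspect_range`, orientation uniform, peak intensity uniform in
#' `intensity_range` (arbitrary grayscale units).
#'
#' @param n number of appearances to draw.
#' @param size_model an [echo_size_model()].
#' @param aspect_range range of sigma_major / sigma_minor.
#' @param intensity_range range of peak intensity (grayscale units).
#' @param floor detection floor (grayscale units) the size model refers to;
#'   defaults to the reference noise level, a third of the faintest peak.
#' @param seed optional RNG seed.
#' @return data.frame with `sigma_major_um`, `sigma_minor_um`, `orientation`
#'   (radians), `peak_intensity` and the drawn `area_px`.
#' @export
sample_echo_appearance <- function(n, size_model = echo_size_model(),
                                   aspect_range = c(1, 2.5),
                                   intensity_range = c(0.3, 1),
                                   floor = intensity_range[1] / 3,
                                   seed = NULL) {
  stopifnot(inherits(size_model, "echo_size_model"), n >= 0,
            floor > 0, floor < 0.95 * intensity_range[1])
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    area_px <- size_model$min_px +
      rlnorm(n, size_model$meanlog, size_model$sdlog)
    ratio <- runif(n, aspect_range[1], aspect_range[2])
    theta <- runif(n, 0, pi)
    peak <- runif(n, intensity_range[1], intensity_range[2])
    area_um2 <- area_px * size_model$pixel_pitch_um^2
    prod_sigma <- area_um2 / (2 * log(peak / floor) * pi)
    sigma_minor <- sqrt(prod_sigma / ratio)
    sigma_major <- ratio * sigma_minor
    data.frame(sigma_major_um = sigma_major, sigma_minor_um = sigma_minor,
               orientation = theta, peak_intensity = peak, area_px = area_px)
  }
  app <- draw(n)
  # enforce the hard 5 px minimum on the *rendered* footprint: elongated
  # near-minimum draws can pixelate below it; redraw those few
  for (pass in 1:20) {
    small <- which(app$area_px < size_model$min_px + 2.5)
    if (length(small) == 0) break
    bad <- small[rendered_area_px(app[small, , drop = FALSE],
                                  size_model$pixel_pitch_um,
                                  floor = floor) < size_model$min_px]
    if (length(bad) == 0) break
    app[bad, ] <- draw(length(bad))
  }
  attr(app, "floor") <- floor
  app
}

#' Analytic above-floor footprint area of an appearance, in pixels
#'
#' Area of the ellipse where the rendered Gaussian exceeds `floor`
#' (`2 log(peak / floor) pi sigma_major sigma_minor / pitch^2`); with
#' `floor = NULL`, the half-maximum footprint.
#'
#' @param appearance one or more rows of [sample_echo_appearance()] output.
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @param floor absolute detection floor; NULL = half the peak.
#' @return footprint area in pixels (continuous value).
#' @export
footprint_area_px <- function(appearance, pixel_pitch_um = 132, floor = NULL) {
  lr <- if (is.null(floor)) log(2) else log(appearance$peak_intensity / floor)
  2 * lr * pi * appearance$sigma_major_um * appearance$sigma_minor_um /
    pixel_pitch_um^2
}

#' Rendered pixel area of an appearance above the detection floor
#'
#' Renders one appearance noiselessly on a sufficient canvas and counts pixels
#' strictly above the floor -- the discrete counterpart of
#' [footprint_area_px()].
#'
#' @inheritParams footprint_area_px
#' @param floor absolute detection floor; NULL = half the peak.
#' @param offset_px sub-pixel placement offset (x, y) in pixels.
#' @return integer pixel count per appearance row.
#' @export
rendered_area_px <- function(appearance, pixel_pitch_um = 132,
                             floor = NULL, offset_px = c(0, 0)) {
  vapply(seq_len(nrow(appearance)), function(i) {
    app <- appearance[i, ]
    thr <- if (is.null(floor)) app$peak_intensity / 2 else floor
    half <- ceiling(app$sigma_major_um *
                      sqrt(2 * max(log(app$peak_intensity / thr), 0.1)) /
                      pixel_pitch_um) + 3
    n <- 2 * half + 1
    cx <- (half + 0.5 + offset_px[1]) * pixel_pitch_um
    cy <- (half + 0.5 + offset_px[2]) * pixel_pitch_um
    img <- render_frame(data.frame(x_um = cx, y_um = cy), app,
                        shape = c(n, n), pixel_pitch_um = pixel_pitch_um,
                        noise_sigma = 0)
    sum(img > thr)
  }, numeric(1))
}
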