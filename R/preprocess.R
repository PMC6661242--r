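#' Mask static bright artifacts from pre-injection frames
#'
#' Pixels that sit above the given intensity quantile in every pre-injection
#' frame are flagged as artifacts (transducer reverberations, bright static
#' echoes) and excluded from all downstream detection.
#'
#' @param pre_frames list of pre-injection frames (matrices), or a
#'   `frame_sequence`.
#' @param intensity_quantile per-frame brightness quantile above which a pixel
#'   is considered bright.
#' @return logical matrix (TRUE = masked) of class `artifact_mask`.
#' @export
build_artifact_mask <- function(pre_frames, intensity_quantile = 0.995) {
  if (inherits(pre_frames, "frame_sequence")) pre_frames <- pre_frames$frames
  stopifnot(length(pre_frames) >= 1, intensity_quantile > 0,
            intensity_quantile < 1)
  bright <- lapply(pre_frames, function(f) {
    thr <- quantile(f, intensity_quantile)
    f > thr
  })
  mask <- Reduce(`&`, bright)
  structure(mask, class = c("artifact_mask", class(mask)))
}

#' Estimate the background noise level of a sequence
#'
#' Robust scale estimate assuming more than half of the pixels are background:
#' `(Q75 - median) / qnorm(0.75)` over the pooled pixels. For zero-clipped
#' additive Gaussian noise (median 0) this recovers the pre-clipping sigma;
#' sparse bright echoes do not move the 75th percentile appreciably.
#'
#' @param x a `frame_sequence`, list of frames, or matrix. Pre-injection
#'   frames, when available, give the cleanest estimate.
#' @param max_frames number of frames pooled (evenly spaced).
#' @return estimated noise standard deviation in grayscale units.
#' @export
estimate_noise_sigma <- function(x, max_frames = 20) {
  frames <- if (inherits(x, "frame_sequence")) x$frames
            else if (is.matrix(x)) list(x) else x
  idx <- unique(round(seq(1, length(frames), length.out = min(max_frames,
                                                              length(frames)))))
  v <- unlist(lapply(frames[idx], as.numeric))
  as.numeric((quantile(v, 0.75) - median(v)) / qnorm(0.75))
}

#' Rigid (translation-only) registration against a reference frame
#'
#' Phase correlation estimates the in-plane translation of every frame
#' relative to the reference (breathing motion is in-plane by experimental
#' design); each frame is shifted back by the rounded shift with zero fill.
#' Sub-pixel shift estimates (parabolic peak interpolation) are reported.
#'
#' @param x a `frame_sequence` with at least 2 frames.
#' @param reference_index frame used as the reference.
#' @return list with `sequence` (registered) and `shifts` (n x 2 matrix of
#'   (dy, dx) estimated displacements of each frame relative to the
#'   reference, in pixels).
#' @export
rigid_register <- function(x, reference_index = 1L) {
  stopifnot(inherits(x, "frame_sequence"), length(x$frames) >= 2,
            reference_index >= 1, reference_index <= length(x$frames))
  ref <- x$frames[[reference_index]]
  Fr <- fft(ref)
  shifts <- matrix(0, length(x$frames), 2,
                   dimnames = list(NULL, c("dy", "dx")))
  out <- x$frames
  for (i in seq_along(x$frames)) {
    if (i == reference_index) next
    f <- x$frames[[i]]
    if (stats::sd(f) == 0 || stats::sd(ref) == 0) {
      warning("flat frame: zero shift assumed for frame ", i)
      next
    }
    cp <- Fr * Conj(fft(f))
    cp <- cp / pmax(Mod(cp), 1e-12)
    r <- Re(fft(cp, inverse = TRUE))
    pk <- arrayInd(which.max(r), dim(r))
    dy <- pk[1] - 1L; dx <- pk[2] - 1L
    if (dy > nrow(r) / 2) dy <- dy - nrow(r)
    if (dx > ncol(r) / 2) dx <- dx - ncol(r)
    # parabolic sub-pixel refinement around the correlation peak
    sub <- function(v0, v1, v2) {
      den <- v0 - 2 * v1 + v2
      if (abs(den) < 1e-12) 0 else 0.5 * (v0 - v2) / den
    }
    wrap <- function(k, n) ((k - 1) %% n) + 1
    # the correlation peak gives the correction; report its negative as the
    # frame's displacement relative to the reference
    corr <- c(
      dy + sub(r[wrap(pk[1] - 1, nrow(r)), pk[2]], r[pk[1], pk[2]],
               r[wrap(pk[1] + 1, nrow(r)), pk[2]]),
      dx + sub(r[pk[1], wrap(pk[2] - 1, ncol(r))], r[pk[1], pk[2]],
               r[pk[1], wrap(pk[2] + 1, ncol(r))]))
    shifts[i, ] <- -corr
    out[[i]] <- shift_frame(f, round(corr[1]), round(corr[2]))
  }
  list(sequence = frame_sequence(out, x$pixel_pitch_um, x$frame_rate_hz),
       shifts = shifts)
}

# integer translation with zero fill; (dy, dx) is the displacement of the
# frame content relative to the reference, so we shift content back by it
shift_frame <- function(f, dy, dx) {
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- f[src_r[ok_r], src_c[ok_c]]
  out
}
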