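#' Adaptive nonlocal-means pre-filter
#'
#' Patch-based denoising applied (optionally) before the Haar detection
#' stage: each pixel is replaced by a weighted mean of pixels in a search
#' window, weighted by the similarity of their surrounding patches,
#' `w = exp(-max(d2 - 2 sigma^2, 0) / h^2)` with `d2` the mean squared patch
#' difference. Smooths background noise while preserving echo structure
#' (similar patches recur along an echo, not across its edge). The bandwidth
#' adapts to the sequence noise level (`h = noise_sigma` by default).
#'
#' @param frame grayscale matrix.
#' @param noise_sigma background noise level (grayscale units).
#' @param patch_half patch half-width in pixels (patch side `2*patch_half+1`).
#' @param search_half search-window half-width in pixels.
#' @param h similarity bandwidth; defaults to `noise_sigma`.
#' @return the filtered frame (same shape).
#' @export
nlm_filter <- function(frame, noise_sigma, patch_half = 1, search_half = 3,
                       h = noise_sigma) {
  stopifnot(noise_sigma >= 0, h > 0, patch_half >= 1, search_half >= 1)
  nr <- nrow(frame); nc <- ncol(frame)
  wsum <- matrix(0, nr, nc)
  acc <- matrix(0, nr, nc)
  shift2d <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[which(okr), which(okc)] <- m[rs[okr], cs[okc]]
    out
  }
  for (dr in -search_half:search_half) {
    for (dc in -search_half:search_half) {
      sh <- shift2d(frame, dr, dc)
      d2 <- box_sum((frame - sh)^2, patch_half)
      d2 <- d2$sum / d2$count
      # subtract the noise-only expectation so identical patches weigh 1
      w <- exp(-pmax(d2 - 2 * noise_sigma^2, 0) / h^2)
      acc <- acc + w * sh
      wsum <- wsum + w
    }
  }
  acc / wsum
}
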