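#' Write a frame sequence as multi-page TIFF with a JSON sidecar
#'
#' Frames are scaled by `scale_max` and quantized to 16 bit; the sidecar
#' records `pixel_pitch_um`, `frame_rate_hz`, the intensity scale, and any
#' extra provenance passed in `metadata` (e.g. the full generator config).
#'
#' @param x a [frame_sequence()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param scale_max intensity mapped to the 16-bit ceiling; defaults to the
#'   sequence maximum.
#' @param metadata optional list merged into the sidecar.
#' @return (invisibly) the quantized `frame_sequence` exactly as stored --
#'   reloading with [load_sequence()] reproduces it bit for bit.
#' @export
write_sequence <- function(x, path, scale_max = NULL, metadata = list()) {
  stopifnot(inherits(x, "frame_sequence"))
  scale_max <- scale_max %||% max(1e-12, max(vapply(x$frames, max, numeric(1))))
  q <- lapply(x$frames, function(f) {
    k <- round(pmin(pmax(f / scale_max, 0), 1) * 65535)
    k / 65535
  })
  tiff::writeTIFF(q, path, bits.per.sample = 16L)
  # scale kept as a %.17g string: doubles survive the JSON round trip exactly
  sidecar <- c(list(pixel_pitch_um = x$pixel_pitch_um,
                    frame_rate_hz = x$frame_rate_hz,
                    scale_max = sprintf("%.17g", scale_max),
                    n_frames = length(q)),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(frame_sequence(lapply(q, function(f) f * scale_max),
                           x$pixel_pitch_um, x$frame_rate_hz))
}

#' Load a grayscale contrast loop
#'
#' Reads a multiframe grayscale loop. Pixel pitch and frame rate are taken
#' from the JSON sidecar written by [write_sequence()] when present, else from
#' the explicit arguments (an error if neither is available). Pixel values are
#' rescaled by the sidecar's `scale_max` so that a written sequence round
#' trips exactly.
#'
#' @param path input file path.
#' @param format "tiff" (multi-page). "dicom" is part of the interface but not
#'   supported by this build; convert DICOM loops to TIFF first.
#' @param crop optional integer rectangle c(row, col, height, width), 1-based.
#' @param pixel_pitch_um,frame_rate_hz metadata overrides.
#' @return a [frame_sequence()].
#' @export
load_sequence <- function(path, format = c("tiff", "dicom"), crop = NULL,
                          pixel_pitch_um = NULL, frame_rate_hz = NULL) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("format error: DICOM reading is not supported; convert to TIFF")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) {
      ch <- lapply(seq_len(dim(f)[3]), function(k) f[, , k])
      same <- all(vapply(ch[-1], function(m) identical(m, ch[[1]]), logical(1)))
      if (!same)
        stop("format error: color content without a grayscale conversion rule")
      ch[[1]]
    } else f
  })
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) jsonlite::read_json(sidecar_path) else list()
  pitch <- pixel_pitch_um %||% meta$pixel_pitch_um
  rate <- frame_rate_hz %||% meta$frame_rate_hz
  if (is.null(pitch) || is.null(rate))
    stop("metadata error: pixel pitch and frame rate not in sidecar; ",
         "pass pixel_pitch_um and frame_rate_hz explicitly")
  if (!is.null(meta$scale_max))
    frames <- lapply(frames, function(f) f * as.numeric(meta$scale_max))
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4, all(crop >= 1))
    r <- crop[1]:(crop[1] + crop[3] - 1)
    cc <- crop[2]:(crop[2] + crop[4] - 1)
    stopifnot(max(r) <= nrow(frames[[1]]), max(cc) <= ncol(frames[[1]]))
    frames <- lapply(frames, function(f) f[r, cc, drop = FALSE])
  }
  frame_sequence(frames, as.numeric(pitch), as.numeric(rate))
}

#' Write / read ground truth as CSV
#'
#' Columns `frame, particle_id, x_um, y_um, merged_label` (plus
#' `peak_intensity` when present).
#'
#' @param gt a `ground_truth` data.frame.
#' @param path CSV path.
#' @return `write_ground_truth` the path invisibly; `read_ground_truth`
#'   the data.frame.
#' @export
write_ground_truth <- function(gt, path) {
  keep <- intersect(c("frame", "particle_id", "x_um", "y_um", "merged_label",
                      "peak_intensity"), names(gt))
  write.csv(gt[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- read.csv(path)
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Write detection events / tracks as CSV
#' @param events events data.frame from [run_detection()].
#' @param tracks tracks data.frame from [link_tracks()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_events <- function(events, path) {
  keep <- intersect(c("frame", "x_um", "y_um", "area_px", "mean_intensity",
                      "peak_intensity", "kind"), names(events))
  write.csv(events[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_tracks <- function(tracks, path) {
  keep <- intersect(c("track_id", "frame", "x_um", "y_um", "speed_um_s"),
                    names(tracks))
  write.csv(tracks[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Write a super-resolution map as 32-bit TIFF
#' @param map an `sr_map` from [render_density_map()] or [render_velocity_map()].
#' @param path TIFF path.
#' @return the path, invisibly.
#' @export
write_sr_map <- function(map, path) {
  stopifnot(inherits(map, "sr_map"))
  v <- map$values
  mx <- max(v, 1e-12)
  tiff::writeTIFF(v / mx, path, bits.per.sample = 32L)
  jsonlite::write_json(list(kind = map$kind, pixel_pitch_um = map$pixel_pitch_um,
                            scale_max = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
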