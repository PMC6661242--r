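#' Link per-frame events into tracks by mutual nearest neighbors
#'
#' For each consecutive frame pair, an event in frame t and an event in frame
#' t+1 are linked when each is the other's nearest neighbor and their
#' distance is within the gate (ties broken by earlier event index).
#' Unlinked new events start tracks (birth); unlinked old events end tracks
#' (death). A death next to a merged-flagged event, or a birth emerging from
#' one, is recorded as a parent/child annotation (merge/split) without
#' changing track identities.
#'
#' @param events events data.frame (`frame`, `x_um`, `y_um`, optionally
#'   `kind`).
#' @param frame_rate_hz frame rate, for per-step speeds.
#' @param max_link_distance_um association gate; default covers 20 mm/s at
#'   the given frame rate.
#' @return list of class `ulm_tracks`: `tracks` (data.frame `track_id`,
#'   `frame`, `x_um`, `y_um`, `speed_um_s` -- the step speed into each point,
#'   NA at births) and `links` (merge/split annotations: `parent_track`,
#'   `child_track`, `frame`, `type`).
#' @export
link_tracks <- function(events, frame_rate_hz,
                        max_link_distance_um = 20000 / frame_rate_hz) {
  stopifnot(max_link_distance_um > 0, frame_rate_hz > 0)
  n <- nrow(events)
  track_id <- integer(n)
  speed <- rep(NA_real_, n)
  if (n == 0) {
    return(structure(list(tracks = data.frame(track_id = integer(0),
                                              frame = integer(0),
                                              x_um = numeric(0),
                                              y_um = numeric(0),
                                              speed_um_s = numeric(0)),
                          links = data.frame(parent_track = integer(0),
                                             child_track = integer(0),
                                             frame = integer(0),
                                             type = character(0))),
                     class = "ulm_tracks"))
  }
  ord <- order(events$frame, seq_len(n))
  ev <- events[ord, ]
  by_frame <- split(seq_len(n), ev$frame)
  frames <- as.integer(names(by_frame))
  next_track <- 0L
  links <- list()
  kind <- if ("kind" %in% names(ev)) ev$kind else rep("single", n)

  for (i in by_frame[[1]]) {
    next_track <- next_track + 1L
    track_id[i] <- next_track
  }
  for (fi in seq_along(frames)[-1]) {
    prev <- if (frames[fi] - frames[fi - 1] == 1) by_frame[[fi - 1]] else integer(0)
    cur <- by_frame[[fi]]
    matched_cur <- rep(FALSE, length(cur))
    matched_prev <- rep(FALSE, length(prev))
    if (length(prev) > 0) {
      d <- sqrt(outer(ev$x_um[prev], ev$x_um[cur], "-")^2 +
                outer(ev$y_um[prev], ev$y_um[cur], "-")^2)
      nn_of_prev <- apply(d, 1, which.min)
      nn_of_cur <- apply(d, 2, which.min)
      for (a in seq_along(prev)) {
        b <- nn_of_prev[a]
        if (nn_of_cur[b] == a && d[a, b] <= max_link_distance_um) {
          track_id[cur[b]] <- track_id[prev[a]]
          speed[cur[b]] <- d[a, b] * frame_rate_hz
          matched_cur[b] <- TRUE
          matched_prev[a] <- TRUE
        }
      }
    }
    for (bi in which(!matched_cur)) {
      next_track <- next_track + 1L
      track_id[cur[bi]] <- next_track
    }
    # merge/split annotations around merged-flagged events
    if (length(prev) > 0) {
      for (a in which(!matched_prev)) {
        j <- which(matched_cur & kind[cur] == "merged" &
                   d[a, ] <= max_link_distance_um)
        if (length(j) > 0) {
          j <- j[which.min(d[a, j])]
          links[[length(links) + 1L]] <-
            data.frame(parent_track = track_id[prev[a]],
                       child_track = track_id[cur[j]],
                       frame = frames[fi], type = "merge")
        }
      }
      for (bi in which(!matched_cur)) {
        j <- which(matched_prev & kind[prev] == "merged" &
                   d[, bi] <= max_link_distance_um)
        if (length(j) > 0) {
          j <- j[which.min(d[j, bi])]
          links[[length(links) + 1L]] <-
            data.frame(parent_track = track_id[prev[j]],
                       child_track = track_id[cur[bi]],
                       frame = frames[fi], type = "split")
        }
      }
    }
  }
  tracks <- data.frame(track_id = track_id, frame = ev$frame,
                       x_um = ev$x_um, y_um = ev$y_um, speed_um_s = speed)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  links <- if (length(links) > 0) do.call(rbind, links)
           else data.frame(parent_track = integer(0), child_track = integer(0),
                           frame = integer(0), type = character(0))
  structure(list(tracks = tracks, links = links), class = "ulm_tracks")
}

#' @export
print.ulm_tracks <- function(x, ...) {
  nt <- length(unique(x$tracks$track_id))
  cat("ulm_tracks:", nt, "tracks over", nrow(x$tracks), "events;",
      nrow(x$links), "merge/split link(s)\n")
  invisible(x)
}

# subpixel cells (cell = pitch / subdivision) traversed by one polyline;
# returns unique cell indices (row, col) on the subdivided grid
traverse_cells <- function(xs, ys, cell_um, nr_sub, nc_sub, speeds = NULL) {
  cells <- list()
  spd <- list()
  for (k in seq_len(length(xs) - 1)) {
    len <- sqrt((xs[k + 1] - xs[k])^2 + (ys[k + 1] - ys[k])^2)
    nstep <- max(2L, ceiling(len / (cell_um / 4)) + 1L)
    t <- seq(0, 1, length.out = nstep)
    cx <- ceiling((xs[k] + t * (xs[k + 1] - xs[k])) / cell_um)
    cy <- ceiling((ys[k] + t * (ys[k + 1] - ys[k])) / cell_um)
    cx <- pmin(pmax(cx, 1L), nc_sub)
    cy <- pmin(pmax(cy, 1L), nr_sub)
    cells[[k]] <- cy + (cx - 1) * nr_sub
    if (!is.null(speeds)) spd[[k]] <- rep(speeds[k], nstep)
  }
  idx <- unlist(cells)
  if (is.null(speeds)) return(unique(idx))
  s <- unlist(spd)
  agg <- tapply(s, idx, mean) # per-cell mean of this track's local speeds
  list(idx = as.integer(names(agg)), speed = as.numeric(agg))
}

#' Render the super-resolved track density map
#'
#' Each track's polyline (consecutive centroids joined by straight segments)
#' is rasterized onto a grid subdivided `subdivision` times per original
#' pixel; a subpixel's value is the number of distinct tracks whose polyline
#' crosses it (a track counts at most once per subpixel). Tracks need at
#' least 2 points to contribute.
#'
#' @param tracks an `ulm_tracks` or its `tracks` data.frame.
#' @param shape_px original canvas shape c(rows, cols) in pixels.
#' @param pixel_pitch_um original pixel pitch in micrometers.
#' @param subdivision subpixels per pixel side (3 by default: 44 um at the
#'   reference 132 um pitch, on the scale of the localization RMSE).
#' @return an `sr_map` (list: `values`, `pixel_pitch_um` of the subpixel,
#'   `kind`).
#' @export
render_density_map <- function(tracks, shape_px, pixel_pitch_um = 132,
                               subdivision = 3) {
  tr <- if (inherits(tracks, "ulm_tracks")) tracks$tracks else tracks
  cell <- pixel_pitch_um / subdivision
  nr <- shape_px[1] * subdivision
  nc <- shape_px[2] * subdivision
  vals <- matrix(0, nr, nc)
  for (id in unique(tr$track_id)) {
    p <- tr[tr$track_id == id, ]
    if (nrow(p) < 2) next
    idx <- traverse_cells(p$x_um, p$y_um, cell, nr, nc)
    vals[idx] <- vals[idx] + 1
  }
  structure(list(values = vals, pixel_pitch_um = cell, kind = "density",
                 subdivision = subdivision), class = "sr_map")
}

#' Render the super-resolved mean-velocity map
#'
#' Same rasterization as [render_density_map()], but each subpixel holds the
#' mean, over the tracks crossing it, of the track's local step speed on the
#' crossing segment. Subpixels with no track are zero (undefined).
#'
#' @inheritParams render_density_map
#' @return an `sr_map` with `kind = "velocity"` (um/s).
#' @export
render_velocity_map <- function(tracks, shape_px, pixel_pitch_um = 132,
                                subdivision = 3) {
  tr <- if (inherits(tracks, "ulm_tracks")) tracks$tracks else tracks
  cell <- pixel_pitch_um / subdivision
  nr <- shape_px[1] * subdivision
  nc <- shape_px[2] * subdivision
  ssum <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (id in unique(tr$track_id)) {
    p <- tr[tr$track_id == id, ]
    if (nrow(p) < 2) next
    seg_speed <- p$speed_um_s[-1] # speed of step k -> k+1 stored at point k+1
    res <- traverse_cells(p$x_um, p$y_um, cell, nr, nc, speeds = seg_speed)
    ssum[res$idx] <- ssum[res$idx] + res$speed
    cnt[res$idx] <- cnt[res$idx] + 1
  }
  vals <- ifelse(cnt > 0, ssum / cnt, 0)
  structure(list(values = vals, pixel_pitch_um = cell, kind = "velocity",
                 subdivision = subdivision), class = "sr_map")
}

#' @export
print.sr_map <- function(x, ...) {
  cat("sr_map (", x$kind, "): ", nrow(x$values), " x ", ncol(x$values),
      " subpixels of ", round(x$pixel_pitch_um, 1), " um\n", sep = "")
  invisible(x)
}

#' Measure the full width at half maximum across a map profile
#'
#' Samples the map along the line from `p0` to `p1` (micrometer coordinates,
#' bilinear interpolation at sub-subpixel steps), finds the global profile
#' peak and returns the distance between the two half-maximum crossings
#' (linear interpolation).
#'
#' @param map an `sr_map`.
#' @param p0,p1 profile endpoints, c(x_um, y_um).
#' @param step_um sampling step; default a tenth of a subpixel.
#' @return width in micrometers.
#' @export
measure_fwhm <- function(map, p0, p1, step_um = map$pixel_pitch_um / 10) {
  stopifnot(inherits(map, "sr_map"))
  len <- sqrt(sum((p1 - p0)^2))
  t <- seq(0, 1, by = step_um / len)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  prof <- bilinear_at(map$values, xs / map$pixel_pitch_um - 0.5,
                      ys / map$pixel_pitch_um - 0.5)
  if (all(prof <= 0)) stop("measurement error: profile is entirely zero")
  pk <- which.max(prof)
  half <- prof[pk] / 2
  cross <- function(side) {
    ii <- if (side < 0) seq(pk, 1) else seq(pk, length(prof))
    below <- which(prof[ii] < half)
    if (length(below) == 0) return(t[ii[length(ii)]] * len)
    j <- below[1]
    a <- ii[j - 1]; b <- ii[j]
    frac <- (prof[a] - half) / (prof[a] - prof[b])
    (t[a] + frac * (t[b] - t[a])) * len
  }
  abs(cross(+1) - cross(-1))
}

# bilinear interpolation on a matrix; (gx, gy) are fractional 0-based grid
# coordinates of cell centers (cell i center at gx = i - 1)
bilinear_at <- function(m, gx, gy) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  x0 <- pmin(floor(gx), nc - 2); y0 <- pmin(floor(gy), nr - 2)
  fx <- gx - x0; fy <- gy - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}
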