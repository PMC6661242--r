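#' Label merged events by single-linkage chaining
#'
#' Two particles belong to the same rendered event if they are connected by a
#' chain of center-to-center distances below `threshold_um` (three quarters of
#' the wavelength by default: closer echoes coalesce into one image event).
#'
#' @param x_um,y_um particle coordinates in micrometers.
#' @param threshold_um chaining distance (strictly below).
#' @return integer event labels, one per particle.
#' @export
merge_labels <- function(x_um, y_um, threshold_um = ulm2d::merge_threshold_um()) {
  n <- length(x_um)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(cbind(x_um, y_um)))
  adj <- d < threshold_um
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Advect particles through a solved vessel network
#'
#' Particles ride the solved Poiseuille flow: within a segment they advance by
#' the segment mean velocity times the frame interval; at junctions they pick
#' an outgoing segment with probability proportional to its outgoing flow.
#' Each particle keeps a fixed random radial offset (at most the radius) per
#' segment, so every reported position lies within the lumen. Particles that
#' exit an outlet leave the field; a replacement enters at an inlet (picked
#' proportionally to inlet inflow) under a fresh identity, keeping the imaged
#' population at `n_particles`. The initial population is seeded along the
#' network with probability proportional to segment volume (the steady state
#' of inlet injection at uniform concentration).
#'
#' @param network a solved `vessel_network`.
#' @param n_particles particles in the field per frame.
#' @param duration_s loop duration in seconds.
#' @param frame_rate_hz frame rate in Hz.
#' @param seed RNG seed.
#' @param merge_threshold_um chaining distance for merged-event labels.
#' @return a data.frame (class `ground_truth`) with one row per particle per
#'   frame: `frame`, `particle_id`, `x_um`, `y_um`, `segment`,
#'   `speed_um_s`, `merged_label` (event label within the frame).
#' @export
advect_particles <- function(network, n_particles, duration_s, frame_rate_hz,
                             seed = 1L,
                             merge_threshold_um = ulm2d::merge_threshold_um()) {
  if (!isTRUE(network$solved))
    stop("state error: solve_flow() must be run before advection")
  stopifnot(n_particles > 0, frame_rate_hz > 0, duration_s >= 0)
  n_frames <- round(duration_s * frame_rate_hz)
  empty <- data.frame(frame = integer(0), particle_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      segment = integer(0), speed_um_s = numeric(0),
                      merged_label = integer(0))
  class(empty) <- c("ground_truth", "data.frame")
  if (n_frames == 0) return(empty)

  set.seed(seed)
  seg <- network$segments
  nodes <- network$nodes
  nseg <- nrow(seg)
  vol <- pi * seg$radius_um^2 * seg$length_um

  # per-segment travel frame: upstream node, unit axis, unit normal
  up <- ifelse(seg$flow_um3_s >= 0, seg$node_a, seg$node_b)
  dn <- ifelse(seg$flow_um3_s >= 0, seg$node_b, seg$node_a)
  ax <- (nodes$x_um[dn] - nodes$x_um[up]) / seg$length_um
  ay <- (nodes$y_um[dn] - nodes$y_um[up]) / seg$length_um
  speed <- abs(seg$velocity_um_s)

  # outgoing segments per node (flow leaving the node)
  out_segs <- lapply(seq_len(nrow(nodes)), function(nd) which(up == nd))
  inlet_flow <- vapply(network$inlets, function(nd) {
    sum(abs(seg$flow_um3_s[out_segs[[nd]]]))
  }, numeric(1))

  draw_inlet_segment <- function() {
    if (all(inlet_flow == 0)) {
      nd <- sample(length(network$inlets), 1)
    } else {
      nd <- sample.int(length(network$inlets), 1, prob = inlet_flow)
    }
    cand <- out_segs[[network$inlets[nd]]]
    if (length(cand) == 0) return(NA_integer_)
    w <- abs(seg$flow_um3_s[cand])
    if (sum(w) == 0) cand[sample.int(length(cand), 1)]
    else cand[sample.int(length(cand), 1, prob = w)]
  }

  p_seg <- sample.int(nseg, n_particles, replace = TRUE, prob = vol)
  p_s <- runif(n_particles) * seg$length_um[p_seg]
  p_off <- runif(n_particles, -1, 1)
  p_id <- seq_len(n_particles)
  next_id <- n_particles + 1L

  dt_frame <- 1 / frame_rate_hz
  rec <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    xs <- nodes$x_um[up[p_seg]] + ax[p_seg] * p_s -
      ay[p_seg] * p_off * seg$radius_um[p_seg]
    ys <- nodes$y_um[up[p_seg]] + ay[p_seg] * p_s +
      ax[p_seg] * p_off * seg$radius_um[p_seg]
    lab <- merge_labels(xs, ys, merge_threshold_um)
    rec[[fr]] <- data.frame(frame = fr, particle_id = p_id,
                            x_um = xs, y_um = ys, segment = p_seg,
                            speed_um_s = speed[p_seg], merged_label = lab)
    if (fr == n_frames) break
    for (i in seq_len(n_particles)) {
      dt <- dt_frame
      for (hop in 1:100) { # bounded segment hops per frame step
        v <- speed[p_seg[i]]
        if (v <= 0) break
        len <- seg$length_um[p_seg[i]]
        adv <- v * dt
        if (p_s[i] + adv <= len) {
          p_s[i] <- p_s[i] + adv
          break
        }
        dt <- dt - (len - p_s[i]) / v
        node <- dn[p_seg[i]]
        cand <- out_segs[[node]]
        if (length(cand) == 0 || node %in% network$outlets) {
          # left the field: replacement particle at an inlet
          p_seg[i] <- draw_inlet_segment()
          p_s[i] <- 0
          p_off[i] <- runif(1, -1, 1)
          p_id[i] <- next_id
          next_id <- next_id + 1L
          if (is.na(p_seg[i])) break
        } else {
          w <- abs(seg$flow_um3_s[cand])
          p_seg[i] <- if (sum(w) == 0) cand[sample.int(length(cand), 1)]
                      else cand[sample.int(length(cand), 1, prob = w)]
          p_s[i] <- 0
          p_off[i] <- runif(1, -1, 1)
        }
      }
    }
  }
  gt <- do.call(rbind, rec)
  class(gt) <- c("ground_truth", "data.frame")
  attr(gt, "n_frames") <- n_frames
  attr(gt, "merge_threshold_um") <- merge_threshold_um
  gt
}

#' Distance from ground-truth positions to their vessel axis
#'
#' Perpendicular distance of each reported position to the axis of the segment
#' it rides, for checking lumen containment.
#'
#' @param gt a `ground_truth` data.frame from [advect_particles()].
#' @param network the solved network it was generated on.
#' @return data.frame with `dist_um` and the segment `radius_um`.
#' @export
lumen_distance <- function(gt, network) {
  seg <- network$segments
  nodes <- network$nodes
  a <- seg$node_a[gt$segment]; b <- seg$node_b[gt$segment]
  axx <- nodes$x_um[b] - nodes$x_um[a]
  axy <- nodes$y_um[b] - nodes$y_um[a]
  len <- seg$length_um[gt$segment]
  dx <- gt$x_um - nodes$x_um[a]
  dy <- gt$y_um - nodes$y_um[a]
  d_perp <- abs(axx * dy - axy * dx) / len
  data.frame(dist_um = d_perp, radius_um = seg$radius_um[gt$segment])
}
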