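# shared fixtures and independent oracles for the test suite

# one reference simulation per session (the benchmark study conditions)
reference_sim_cached <- local({
  env <- new.env()
  function(seed = 1L) {
    key <- paste0("sim", seed)
    if (is.null(env[[key]])) env[[key]] <- generate_sequence(reference_config(seed))
    env[[key]]
  }
})

# a symmetric Y bifurcation: inlet tube splitting into two identical daughters
y_bifurcation_network <- function(r_parent = 60, r_daughter = 40, len = 1000) {
  nodes <- data.frame(id = 1:4,
                      x_um = c(0, len, 2 * len, 2 * len),
                      y_um = c(0, 0, len * 0.6, -len * 0.6))
  lend <- sqrt(len^2 + (0.6 * len)^2)
  segments <- data.frame(id = 1:3, node_a = c(1L, 2L, 2L),
                         node_b = c(2L, 3L, 4L),
                         radius_um = c(r_parent, r_daughter, r_daughter),
                         length_um = c(len, lend, lend))
  net <- straight_tube_network() # template for the class structure
  net$nodes <- nodes
  net$segments <- segments
  net$inlets <- 1L
  net$outlets <- c(3L, 4L)
  net
}

# dense conductance-system oracle: independently assembled nodal solve
dense_flow_oracle <- function(network, dp, mu) {
  seg <- network$segments
  n <- nrow(network$nodes)
  g <- pi * seg$radius_um^4 / (8 * mu * seg$length_um)
  A <- matrix(0, n, n)
  b <- rep(0, n)
  for (k in seq_len(nrow(seg))) {
    i <- seg$node_a[k]; j <- seg$node_b[k]
    A[i, i] <- A[i, i] + g[k]; A[j, j] <- A[j, j] + g[k]
    A[i, j] <- A[i, j] - g[k]; A[j, i] <- A[j, i] - g[k]
  }
  for (nd in network$inlets) { A[nd, ] <- 0; A[nd, nd] <- 1; b[nd] <- dp }
  for (nd in network$outlets) { A[nd, ] <- 0; A[nd, nd] <- 1; b[nd] <- 0 }
  solve(A, b)
}

# brute-force transitive closure at a distance threshold (merge-label oracle)
closure_labels_oracle <- function(x, y, thr) {
  n <- length(x)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < thr &&
          lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# exhaustive minimum-total-distance one-to-one assignment (n <= 8)
optimal_assignment_oracle <- function(gt, det, radius) {
  ng <- nrow(gt); nd <- nrow(det)
  d <- sqrt(outer(gt$x_um, det$x_um, "-")^2 + outer(gt$y_um, det$y_um, "-")^2)
  d[d > radius] <- NA
  k <- min(ng, nd)
  best <- NULL; best_cost <- Inf; best_npairs <- -1L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  gsub_sets <- utils::combn(ng, k, simplify = FALSE)
  dsub_sets <- utils::combn(nd, k, simplify = FALSE)
  for (gs in gsub_sets) for (ds in dsub_sets) for (p in perms(ds)) {
    dd <- d[cbind(gs, p)]
    ok <- !is.na(dd)
    npairs <- sum(ok)
    cost <- sum(dd[ok])
    if (npairs > best_npairs || (npairs == best_npairs && cost < best_cost)) {
      best_npairs <- npairs; best_cost <- cost
      best <- data.frame(gt = gs[ok], det = p[ok], deviation_um = dd[ok])
    }
  }
  list(pairs = best, n_pairs = best_npairs, cost = best_cost)
}

# render a frame of isolated echoes on a tile grid (one echo per tile)
tile_frame <- function(n_tiles_x, n_tiles_y, tile_px, appearances,
                       noise_sigma = 0, jitter_px = 5, pitch = 132,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_tiles_x * n_tiles_y
  stopifnot(nrow(appearances) == n)
  tiles <- expand.grid(tx = seq_len(n_tiles_x) - 1, ty = seq_len(n_tiles_y) - 1)
  pos <- data.frame(
    x_um = (tiles$tx * tile_px + tile_px / 2 + runif(n, -jitter_px, jitter_px)) * pitch,
    y_um = (tiles$ty * tile_px + tile_px / 2 + runif(n, -jitter_px, jitter_px)) * pitch)
  frame <- render_frame(pos, appearances,
                        shape = c(n_tiles_y * tile_px, n_tiles_x * tile_px),
                        pixel_pitch_um = pitch, noise_sigma = noise_sigma)
  list(frame = frame, positions = pos)
}

# a single-echo appearance with a prescribed above-floor area
fixed_appearance <- function(area_px, peak = 0.6, floor = 0.1, ratio = 1.3,
                             theta = 0.4, pitch = 132) {
  prod_sigma <- area_px * pitch^2 / (2 * log(peak / floor) * pi)
  sb <- sqrt(prod_sigma / ratio)
  data.frame(sigma_major_um = ratio * sb, sigma_minor_um = sb,
             orientation = theta, peak_intensity = peak, area_px = area_px)
}
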