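#' Specification of a lattice vessel network
#'
#' Describes a rectangular grid of interconnecting vessels spanning a field of
#' `extent_um[1]` (x) by `extent_um[2]` (y), with nodes every `spacing_um`,
#' node positions jittered by up to `jitter_um`, a fraction `prune_frac` of
#' segments removed at random (connectivity preserved), and per-segment
#' diameters drawn log-uniformly from `diameter_range_um`.
#'
#' @param extent_um field extent (x, y) in micrometers; default 2.2 x 1.1 cm.
#' @param spacing_um lattice node spacing in micrometers.
#' @param jitter_um maximum node position jitter in micrometers.
#' @param prune_frac fraction of lattice segments to prune.
#' @param diameter_range_um vessel diameter range in micrometers.
#' @param seed RNG seed for jitter, pruning and diameter assignment.
#' @return an object of class `vessel_grid_spec`.
#' @export
vessel_grid_spec <- function(extent_um = c(22000, 11000), spacing_um = 1000,
                             jitter_um = 200, prune_frac = 0.25,
                             diameter_range_um = c(10, 500), seed = 1L) {
  stopifnot(length(extent_um) == 2, all(extent_um > 0), spacing_um > 0,
            jitter_um >= 0, prune_frac >= 0, prune_frac < 1)
  if (diameter_range_um[1] < 10 || diameter_range_um[2] > 500 ||
      diameter_range_um[1] > diameter_range_um[2])
    stop("configuration error: diameter range must lie within [10, 500] um")
  structure(list(extent_um = extent_um, spacing_um = spacing_um,
                 jitter_um = jitter_um, prune_frac = prune_frac,
                 diameter_range_um = diameter_range_um, seed = seed),
            class = "vessel_grid_spec")
}

new_vessel_network <- function(nodes, segments, inlets, outlets) {
  stopifnot(nrow(segments) >= 1)
  dx <- nodes$x_um[segments$node_b] - nodes$x_um[segments$node_a]
  dy <- nodes$y_um[segments$node_b] - nodes$y_um[segments$node_a]
  len <- sqrt(dx^2 + dy^2)
  if (any(abs(len - segments$length_um) > 1e-6 * pmax(len, 1)))
    stop("segment lengths inconsistent with node geometry")
  if (any(segments$radius_um < 5 - 1e-9 | segments$radius_um > 250 + 1e-9))
    stop("configuration error: radii must lie in [5, 250] um")
  if (any(segments$length_um < 25 - 1e-9 | segments$length_um > 2000 + 1e-9))
    stop("configuration error: segment lengths must lie in [25, 2000] um")
  structure(list(nodes = nodes, segments = segments,
                 inlets = inlets, outlets = outlets,
                 solved = FALSE), class = "vessel_network")
}

#' Build an interconnecting vessel network on a jittered lattice
#'
#' @param spec a [vessel_grid_spec()].
#' @return a `vessel_network`: node table (`id`, `x_um`, `y_um`), segment table
#'   (`id`, `node_a`, `node_b`, `radius_um`, `length_um`), inlet nodes (left
#'   edge) and outlet nodes (right edge). Flows are unset until [solve_flow()].
#' @export
build_vessel_network <- function(spec = vessel_grid_spec()) {
  stopifnot(inherits(spec, "vessel_grid_spec"))
  set.seed(spec$seed)
  nx <- max(2L, round(spec$extent_um[1] / spec$spacing_um) + 1L)
  ny <- max(2L, round(spec$extent_um[2] / spec$spacing_um) + 1L)
  gx <- seq(0, spec$extent_um[1], length.out = nx)
  gy <- seq(0, spec$extent_um[2], length.out = ny)
  nodes <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  nodes$x_um <- gx[nodes$ix] + runif(nrow(nodes), -spec$jitter_um, spec$jitter_um)
  nodes$y_um <- gy[nodes$iy] + runif(nrow(nodes), -spec$jitter_um, spec$jitter_um)
  # keep inlet/outlet columns on the field boundary
  nodes$x_um[nodes$ix == 1] <- 0
  nodes$x_um[nodes$ix == nx] <- spec$extent_um[1]
  nodes$id <- seq_len(nrow(nodes))
  nid <- function(ix, iy) (iy - 1L) * nx + ix
  eh <- cbind(nid(seq_len(nx - 1L), rep(seq_len(ny), each = nx - 1L)),
              nid(seq_len(nx - 1L) + 1L, rep(seq_len(ny), each = nx - 1L)))
  ev <- cbind(nid(rep(seq_len(nx), ny - 1L), rep(seq_len(ny - 1L), each = nx)),
              nid(rep(seq_len(nx), ny - 1L), rep(seq_len(ny - 1L), each = nx) + 1L))
  edges <- rbind(eh, ev)
  inlets <- nodes$id[nodes$ix == 1]
  outlets <- nodes$id[nodes$ix == nx]

  # prune random segments while keeping the graph connected
  n_drop <- floor(spec$prune_frac * nrow(edges))
  cand <- sample(nrow(edges))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  dropped <- logical(nrow(edges))
  for (e in cand) {
    if (sum(!dropped) <= 1 || sum(dropped) >= n_drop) break
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, edges[e, ]))
    if (igraph::is_connected(g2)) {
      g <- g2
      dropped[e] <- TRUE
    }
  }
  edges <- edges[!dropped, , drop = FALSE]
  if (nrow(edges) == 0) stop("configuration error: network has zero segments")

  d <- exp(runif(nrow(edges), log(spec$diameter_range_um[1]),
                 log(spec$diameter_range_um[2])))
  segments <- data.frame(
    id = seq_len(nrow(edges)),
    node_a = edges[, 1], node_b = edges[, 2],
    radius_um = d / 2,
    length_um = sqrt((nodes$x_um[edges[, 1]] - nodes$x_um[edges[, 2]])^2 +
                     (nodes$y_um[edges[, 1]] - nodes$y_um[edges[, 2]])^2))
  net <- new_vessel_network(nodes[, c("id", "x_um", "y_um")], segments,
                            inlets, outlets)
  net$spec <- spec
  net
}

#' Minimal network: one straight tube
#'
#' @param radius_um tube radius in micrometers.
#' @param length_um tube length in micrometers.
#' @return a `vessel_network` with 2 nodes and 1 segment (node 1 inlet,
#'   node 2 outlet), oriented along x.
#' @export
straight_tube_network <- function(radius_um = 50, length_um = 1000) {
  nodes <- data.frame(id = 1:2, x_um = c(0, length_um), y_um = c(0, 0))
  segments <- data.frame(id = 1L, node_a = 1L, node_b = 2L,
                         radius_um = radius_um, length_um = length_um)
  new_vessel_network(nodes, segments, inlets = 1L, outlets = 2L)
}

#' Solve Poiseuille flow on a vessel network
#'
#' Each segment carries laminar flow `Q = pi r^4 dP / (8 mu L)`. A fixed
#' pressure (`pressure_drop_pa` at inlets, 0 at outlets) is imposed and nodal
#' pressures follow from mass conservation (zero net flow at interior nodes).
#'
#' @param network a `vessel_network`.
#' @param pressure_drop_pa inlet-to-outlet pressure drop (Pa). Only the
#'   relative flow pattern matters for particle advection; the absolute scale
#'   sets the velocity scale.
#' @param viscosity_pa_s dynamic viscosity (Pa s); 3.5 mPa s is blood-like.
#' @return the network with `pressures` (Pa per node) and per-segment
#'   `flow_um3_s` (signed, node_a -> node_b positive) and `velocity_um_s`.
#' @export
solve_flow <- function(network, pressure_drop_pa = 5000, viscosity_pa_s = 3.5e-3) {
  stopifnot(inherits(network, "vessel_network"),
            length(network$inlets) >= 1, length(network$outlets) >= 1)
  seg <- network$segments
  n <- nrow(network$nodes)
  g <- pi * seg$radius_um^4 / (8 * viscosity_pa_s * seg$length_um)

  fixed <- rep(NA_real_, n)
  fixed[network$inlets] <- pressure_drop_pa
  fixed[network$outlets] <- 0
  free <- which(is.na(fixed))

  # every connected component must touch a boundary node
  gr <- igraph::graph_from_edgelist(cbind(seg$node_a, seg$node_b), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  bad <- setdiff(unique(comp), unique(comp[!is.na(fixed)]))
  if (length(bad) > 0)
    stop("solver error: nodes with no path to a boundary node: ",
         paste(which(comp %in% bad), collapse = ", "))

  p <- fixed
  if (length(free) > 0) {
    # weighted graph Laplacian, reduced to the free nodes
    L <- matrix(0, n, n)
    ia <- seg$node_a; ib <- seg$node_b
    for (k in seq_along(g)) {
      L[ia[k], ia[k]] <- L[ia[k], ia[k]] + g[k]
      L[ib[k], ib[k]] <- L[ib[k], ib[k]] + g[k]
      L[ia[k], ib[k]] <- L[ia[k], ib[k]] - g[k]
      L[ib[k], ia[k]] <- L[ib[k], ia[k]] - g[k]
    }
    A <- L[free, free, drop = FALSE]
    b <- -L[free, -free, drop = FALSE] %*% fixed[-free]
    p[free] <- as.numeric(solve(A, b))
  }

  seg$flow_um3_s <- g * (p[seg$node_a] - p[seg$node_b])
  seg$velocity_um_s <- seg$flow_um3_s / (pi * seg$radius_um^2)
  network$segments <- seg
  network$pressures <- p
  network$pressure_drop_pa <- pressure_drop_pa
  network$viscosity_pa_s <- viscosity_pa_s
  network$solved <- TRUE
  network
}

#' Mass-conservation residual of a solved network
#'
#' @param network a solved `vessel_network`.
#' @return max over interior nodes of |net signed flow| relative to the
#'   largest flow magnitude in the network.
#' @export
flow_residual <- function(network) {
  stopifnot(isTRUE(network$solved))
  seg <- network$segments
  net_at <- rep(0, nrow(network$nodes))
  for (k in seq_len(nrow(seg))) {
    net_at[seg$node_a[k]] <- net_at[seg$node_a[k]] - seg$flow_um3_s[k]
    net_at[seg$node_b[k]] <- net_at[seg$node_b[k]] + seg$flow_um3_s[k]
  }
  interior <- setdiff(network$nodes$id, c(network$inlets, network$outlets))
  if (length(interior) == 0) return(0)
  mx <- max(abs(seg$flow_um3_s))
  if (mx == 0) return(0)
  max(abs(net_at[interior])) / mx
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("vessel_network:", nrow(x$nodes), "nodes,", nrow(x$segments), "segments\n")
  cat("  diameters", round(min(2 * x$segments$radius_um), 1), "-",
      round(max(2 * x$segments$radius_um), 1), "um;",
      length(x$inlets), "inlet(s),", length(x$outlets), "outlet(s)\n")
  if (isTRUE(x$solved))
    cat("  solved: dP =", x$pressure_drop_pa, "Pa, max |v| =",
        signif(max(abs(x$segments$velocity_um_s)), 3), "um/s\n")
  invisible(x)
}
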