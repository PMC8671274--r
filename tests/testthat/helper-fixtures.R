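## Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fix_geo <- function() {
  if (is.null(.fix$geo)) .fix$geo <- generate_ideal_biv(geometry_params())
  .fix$geo
}
fix_cfg <- function() baseline_config()
fix_layer <- function() {
  if (is.null(.fix$layer)) {
    g <- fix_geo()
    .fix$layer <- select_se_layer(g$frame, fix_cfg()$eas, g$mesh)
  }
  .fix$layer
}
## one baseline Purkinje HPS (master seed 1), reused where the exact seed
## does not matter
fix_net <- function() {
  if (is.null(.fix$net)) {
    g <- fix_geo()
    .fix$net <- suppressWarnings(
      build_purkinje_hps(g$mesh, g$frame, fix_cfg()$eas, fix_cfg()$purkinje,
                         seed = 1L, layer = fix_layer()))
  }
  .fix$net
}

## flat-sheet surrogate of the sub-endocardial surface: a rectangular grid
## in the z = 0 plane with uniform UVC bands, used to study pure growth
flat_sheet <- function(nx = 81, ny = 81, spacing = 1) {
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  nodes <- cbind(nodes, 0)
  idx <- function(i, j) (j - 1) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    tris[[length(tris) + 1L]] <- rbind(
      c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
      c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  tri <- do.call(rbind, tris)
  n <- nrow(nodes)
  ## phi spreads nodes out so the exact centre maps uniquely
  uvc <- cbind(z = rep(0.5, n), rho = 0,
               phi = (nodes[, 1] / max(abs(xs))) * 3,
               nu = -1)
  frame <- structure(list(nodes = nodes, uvc = uvc, d_endo = rep(0, n),
                          edge_length = spacing * 2,
                          arc_lv = nx * spacing, arc_rv = nx * spacing),
                     class = "uvc_frame")
  layer <- structure(list(nodes = seq_len(n), fast_cv = rep(TRUE, n),
                          elements = integer(0), surface = tri,
                          surface_tag = rep("LV_ENDO", nrow(tri)),
                          s_z_min = 0, s_z_max = 1, s_rho = 1),
                     class = "se_layer")
  list(frame = frame, layer = layer,
       root = c(0.5, 0, 0, -1))
}

## arbitrary directed weighted graph wrapped as a propagation_graph, for
## solver tests against brute-force oracles
make_prop_graph <- function(n, from, to, w, n_tissue = n) {
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  structure(list(graph = g, n_tissue = n_tissue, n_net = n - n_tissue,
                 mode = "fixture", sim = NULL, pvj = NULL,
                 n_edges = length(w)),
            class = "propagation_graph")
}

## brute-force shortest arrival times by exhaustive simple-path enumeration
oracle_all_paths <- function(n, from, to, w, sources, times) {
  best <- rep(Inf, n)
  adj <- lapply(seq_len(n), function(v) which(from == v))
  recurse <- function(v, t, visited) {
    if (t >= best[v]) { } else best[v] <<- t
    for (e in adj[[v]]) {
      u <- to[e]
      if (!visited[u]) {
        visited[u] <- TRUE
        recurse(u, t + w[e], visited)
        visited[u] <- FALSE
      }
    }
  }
  for (s in seq_along(sources)) {
    visited <- logical(n)
    visited[sources[s]] <- TRUE
    recurse(sources[s], times[s], visited)
  }
  best
}

## Bellman-Ford single-source distances (independent of igraph)
oracle_bellman_ford <- function(n, from, to, w, source) {
  d <- rep(Inf, n)
  d[source] <- 0
  for (it in seq_len(n)) {
    changed <- FALSE
    for (e in seq_along(from)) {
      if (is.finite(d[from[e]]) && d[from[e]] + w[e] < d[to[e]]) {
        d[to[e]] <- d[from[e]] + w[e]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

## straight cable network of n_seg equal segments along +x
chain_network <- function(n_seg = 100, seg_len = 1) {
  nodes <- cbind(seq(0, by = seg_len, length.out = n_seg + 1), 0, 0)
  hpstwin:::new_purkinje_network(
    nodes = nodes,
    role = rep("BRANCH", n_seg + 1),
    fascicle = rep("lv_sf", n_seg + 1),
    segments = data.frame(from = seq_len(n_seg), to = seq_len(n_seg) + 1L,
                          length = rep(seg_len, n_seg),
                          fascicle = "lv_sf", stringsAsFactors = FALSE),
    root_nodes = c(lv_sf = 1L),
    territory = c(lv_sf = "LV_ENDO"))
}
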