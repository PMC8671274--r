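#' Assemble the coupled propagation graph
#'
#' Builds the directed weighted graph on which first-arrival activation
#' times are computed. Tissue vertices are the mesh nodes; edges are the
#' tetrahedral element edges augmented with 2-ring diagonals
#' (node pairs two hops apart, connected straight-line) to reduce the
#' metrication error of the graph eikonal solve. Edge weight is Euclidean
#' length divided by the myocardial conduction velocity. Exactly one HPS
#' mode is selected:
#' \itemize{
#'   \item fascicle mode (`layer` given): edges with both endpoints in the
#'     fast sub-endocardial layer conduct at `cv_purk`;
#'   \item Purkinje mode (`net` given): network vertices and cable edges
#'     (bidirectional, at `cv_purk`) are appended, with asymmetric PVJ
#'     coupling edges network to tissue weighted `delay_antero` and tissue
#'     to network weighted `delay_retro`; the sub-endocardial tissue keeps
#'     `cv_myo` since activation stems from the network itself.
#' }
#'
#' @param mesh a `biv_mesh`.
#' @param layer an `se_layer` or `NULL`.
#' @param net a `purkinje_network` or `NULL`.
#' @param sim a `simulation_config`.
#' @return object of class `propagation_graph`.
#' @export
assemble_graph <- function(mesh, layer = NULL, net = NULL, sim) {
  if (!is.null(layer) && !is.null(net))
    stop("assemble_graph: select exactly one of fascicle layer / network mode")
  n_tissue <- nrow(mesh$nodes)

  ## tissue 1-ring (tet edges)
  el <- mesh$elems
  e1 <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
              el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  swap <- e1[, 1] > e1[, 2]
  e1[swap, ] <- e1[swap, c(2, 1)]
  e1 <- unique(e1)

  ## 2-ring diagonals via sparse adjacency square
  A <- Matrix::sparseMatrix(i = e1[, 1], j = e1[, 2], x = 1,
                            dims = c(n_tissue, n_tissue), symmetric = TRUE)
  A2 <- A %*% A
  A2 <- methods::as(methods::as(A2, "generalMatrix"), "TsparseMatrix")
  keep <- A2@i < A2@j
  pairs2 <- cbind(A2@i[keep] + 1L, A2@j[keep] + 1L)
  ## exclude pairs already directly connected
  key1 <- e1[, 1] * (n_tissue + 1) + e1[, 2]
  key2 <- pairs2[, 1] * (n_tissue + 1) + pairs2[, 2]
  pairs2 <- pairs2[!(key2 %in% key1), , drop = FALSE]
  te <- rbind(e1, pairs2)
  tlen <- row_norms(mesh$nodes[te[, 1], , drop = FALSE] -
                      mesh$nodes[te[, 2], , drop = FALSE])
  cv <- rep(sim$cv_myo, nrow(te))
  if (!is.null(layer)) {
    inset <- logical(n_tissue)
    inset[layer$nodes] <- TRUE
    fast <- inset[te[, 1]] & inset[te[, 2]]
    ## a 2-ring diagonal between two sub-endocardial nodes may tunnel
    ## through the wall (e.g. across the septum, whose two faces are both
    ## endocardial); fast conduction additionally requires a shared
    ## sub-endocardial neighbour, keeping the fast subgraph on the surface
    n1 <- nrow(e1)
    is2 <- seq_len(nrow(te)) > n1
    chk <- which(fast & is2)
    if (length(chk)) {
      A_se <- A[, layer$nodes, drop = FALSE]
      common <- Matrix::tcrossprod(A_se)
      ok <- common[cbind(te[chk, 1], te[chk, 2])] > 0
      fast[chk[!ok]] <- FALSE
    }
    cv[fast] <- sim$cv_purk
  }
  tw <- tlen / cv   # mm / (m/s) == mm / (mm/ms) -> ms

  from <- c(te[, 1], te[, 2])
  to <- c(te[, 2], te[, 1])
  w <- c(tw, tw)

  n_net <- 0L
  pvj <- NULL
  if (!is.null(net)) {
    n_net <- nrow(net$nodes)
    sf <- net$segments$from + n_tissue
    st <- net$segments$to + n_tissue
    swt <- net$segments$length / sim$cv_purk
    from <- c(from, sf, st)
    to <- c(to, st, sf)
    w <- c(w, swt, swt)
    pvj <- net$pvj
    if (nrow(pvj)) {
      from <- c(from, pvj$pvj + n_tissue, pvj$tissue)
      to <- c(to, pvj$tissue, pvj$pvj + n_tissue)
      w <- c(w, rep(sim$delay_antero, nrow(pvj)),
             rep(sim$delay_retro, nrow(pvj)))
    }
  }
  if (any(w < 0)) stop("assemble_graph: negative edge weight")

  g <- igraph::make_empty_graph(n = n_tissue + n_net, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w

  comp <- igraph::components(
    igraph::subgraph(g, seq_len(n_tissue)), mode = "weak")
  if (comp$no != 1) stop("assemble_graph: tissue graph is disconnected")

  structure(list(graph = g, n_tissue = n_tissue, n_net = n_net,
                 mode = if (is.null(net)) "fascicle" else "purkinje",
                 sim = sim, pvj = pvj,
                 n_edges = length(w)),
            class = "propagation_graph")
}

#' @export
print.propagation_graph <- function(x, ...) {
  cat("propagation_graph (", x$mode, " mode): ", x$n_tissue,
      " tissue + ", x$n_net, " network vertices, ", x$n_edges,
      " directed edges\n", sep = "")
  invisible(x)
}

#' Pacing protocol
#'
#' @param scenario `"sinus"` or `"rv_apical"`.
#' @param vertices graph vertex indices of the sources (network vertices
#'   offset by the tissue node count).
#' @param times source activation offsets (ms), recycled to the vertices.
#' @return object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(scenario, vertices, times) {
  stopifnot(scenario %in% c("sinus", "rv_apical"), length(vertices) >= 1)
  times <- rep_len(times, length(vertices))
  if (any(times < 0)) stop("pacing_protocol: source times must be >= 0")
  structure(list(scenario = scenario, vertices = as.integer(vertices),
                 times = as.numeric(times)),
            class = "pacing_protocol")
}

#' Solve first-arrival activation times
#'
#' Multi-source Dijkstra over the directed weighted propagation graph with
#' per-source time offsets; returns the earliest arrival per vertex.
#' Unreached vertices are flagged (`Inf`), never defaulted to zero.
#'
#' @param g a `propagation_graph`.
#' @param protocol a `pacing_protocol`.
#' @return object of class `activation_map`: numeric vector of activation
#'   times (ms) over tissue then network vertices, with attributes
#'   `n_tissue`, `sources`, `scenario`.
#' @export
solve_activation <- function(g, protocol) {
  stopifnot(inherits(g, "propagation_graph"),
            inherits(protocol, "pacing_protocol"))
  nv <- g$n_tissue + g$n_net
  if (any(protocol$vertices < 1 | protocol$vertices > nv))
    stop("solve_activation: source vertex outside graph")
  if (any(igraph::E(g$graph)$weight < 0))
    stop("solve_activation: negative edge weight")
  d <- igraph::distances(g$graph, v = protocol$vertices, mode = "out",
                         weights = igraph::E(g$graph)$weight,
                         algorithm = "dijkstra")
  act <- do.call(pmin, c(lapply(seq_len(nrow(d)), function(i)
    d[i, ] + protocol$times[i]), na.rm = FALSE))
  act <- as.numeric(act)
  structure(act, n_tissue = g$n_tissue, sources = protocol$vertices,
            scenario = protocol$scenario, class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- is.finite(x)
  cat("activation_map: ", length(x), " vertices (",
      attr(x, "n_tissue"), " tissue); ", sum(!fin), " unreached; range [",
      round(min(x[fin]), 2), ", ", round(max(x[fin]), 2), "] ms\n", sep = "")
  invisible(x)
}

#' Run a pacing scenario for either HPS representation
#'
#' Builds the propagation graph and protocol for the requested scenario and
#' representation, solves the activation map, and reports activation times
#' at the five mapped fascicular root nodes (the Purkinje-model analogue of
#' the configured `t_his`).
#'
#' Scenarios: under `sinus`, the fascicle model fires its discs at the
#' configured `t_his` while the Purkinje model is activated from the His
#' root `b_h0` at time zero; under `rv_apical`, pacing starts at the
#' mapped coordinate `pace_uvc` at time zero and the fascicle model keeps
#' its fast sub-endocardial layer conductive but fires no timed sources
#' (replicating retrograde activation of the HPS surrogate).
#'
#' @param mesh a `biv_mesh`; @param frame a `uvc_frame`.
#' @param hps a `fascicle_hps` or `purkinje_network`.
#' @param sim a `simulation_config`.
#' @param scenario `"sinus"` or `"rv_apical"`.
#' @param eas an `eas_config` (root locations for the report).
#' @param pace_uvc pacing coordinate for `rv_apical`
#'   (default `(0.3, 0, 0, +1)`, apical RV endocardium).
#' @param graph optional prebuilt `propagation_graph` (reused across
#'   scenarios).
#' @return list with `act` (`activation_map`), `report` (named numeric,
#'   root activation times in ms), `graph`, `protocol`.
#' @export
run_scenario <- function(mesh, frame, hps, sim,
                         scenario = c("sinus", "rv_apical"),
                         eas = baseline_config()$eas,
                         pace_uvc = c(0.3, 0, 0, +1),
                         graph = NULL) {
  scenario <- match.arg(scenario)
  is_fasc <- inherits(hps, "fascicle_hps")
  if (!is_fasc && !inherits(hps, "purkinje_network"))
    stop("run_scenario: hps must be a fascicle_hps or purkinje_network")
  if (is.null(graph)) {
    graph <- if (is_fasc)
      assemble_graph(mesh, layer = hps$layer, net = NULL, sim = sim)
    else
      assemble_graph(mesh, layer = NULL, net = hps, sim = sim)
  }

  if (scenario == "sinus") {
    if (is_fasc) {
      verts <- unlist(hps$discs, use.names = FALSE)
      times <- rep(hps$times, times = vapply(hps$discs, length, 1L))
      protocol <- pacing_protocol("sinus", verts, times)
    } else {
      protocol <- pacing_protocol("sinus", hps$his_root + graph$n_tissue, 0)
    }
  } else {
    pace_node <- uvc_to_cartesian(frame, pace_uvc)$index
    protocol <- pacing_protocol("rv_apical", pace_node, 0)
  }

  act <- solve_activation(graph, protocol)
  if (scenario == "rv_apical" && !is.finite(act[protocol$vertices[1]]))
    stop("run_scenario: pacing vertex unreachable")

  report <- if (is_fasc) {
    stats::setNames(act[hps$roots], names(hps$roots))
  } else {
    stats::setNames(act[hps$root_nodes + graph$n_tissue],
                    names(hps$root_nodes))
  }
  list(act = act, report = report, graph = graph, protocol = protocol)
}
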