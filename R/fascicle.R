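#' Select the fast-conducting sub-endocardial (SE) layer
#'
#' The SE layer is the set of mesh nodes with apicobasal coordinate
#' `z` in `[s_z_min, s_z_max]` and normalized endocardial depth
#' `d_endo <= s_rho`, on both endocardia including the RV-facing septal
#' face. With the baseline `s_rho = 0.1` this is approximately a
#' one-element-deep endocardial shell. Member elements are those with at
#' least three of their four nodes in the member set (boundary-adjacent
#' rule).
#'
#' @param frame a `uvc_frame`.
#' @param eas an `eas_config` (SE bounds `s_z_min`, `s_z_max`, `s_rho`).
#' @param mesh optional `biv_mesh`; when given, member elements and the SE
#'   surface triangulation are attached.
#' @return object of class `se_layer`: `nodes` (member node indices),
#'   `fast_cv` (per-member flag), `elements` (member element indices, if
#'   `mesh` given), `surface` (SE-restricted endocardial triangles), plus
#'   the bounds used.
#' @export
select_se_layer <- function(frame, eas, mesh = NULL) {
  stopifnot(inherits(frame, "uvc_frame"))
  z <- frame$uvc[, "z"]
  sel <- z >= eas$s_z_min & z <= eas$s_z_max & frame$d_endo <= eas$s_rho
  if (!any(sel))
    stop("select_se_layer: bounds exclude the entire mesh (empty selection)")
  nodes <- which(sel)
  elements <- integer(0)
  se_tri <- NULL
  se_tri_tag <- NULL
  if (!is.null(mesh)) {
    inset <- logical(nrow(frame$uvc))
    inset[nodes] <- TRUE
    cnt <- inset[mesh$elems[, 1]] + inset[mesh$elems[, 2]] +
      inset[mesh$elems[, 3]] + inset[mesh$elems[, 4]]
    elements <- which(cnt >= 3)
    tri <- mesh$surface$tri
    endo <- mesh$surface$tag %in% c("LV_ENDO", "RV_ENDO")
    keep <- endo & inset[tri[, 1]] & inset[tri[, 2]] & inset[tri[, 3]]
    se_tri <- tri[keep, , drop = FALSE]
    se_tri_tag <- as.character(mesh$surface$tag[keep])
  }
  structure(list(nodes = nodes,
                 fast_cv = rep(TRUE, length(nodes)),
                 elements = elements,
                 surface = se_tri,
                 surface_tag = se_tri_tag,
                 s_z_min = eas$s_z_min, s_z_max = eas$s_z_max,
                 s_rho = eas$s_rho),
            class = "se_layer")
}

#' @export
print.se_layer <- function(x, ...) {
  cat("se_layer:", length(x$nodes), "nodes, z in [", x$s_z_min, ",",
      x$s_z_max, "], d_endo <=", x$s_rho, "\n")
  invisible(x)
}

## Undirected SE surface graph (edges of the SE endocardial triangulation,
## weighted by Euclidean length) for geodesic disc construction.
se_surface_graph <- function(frame, layer) {
  if (is.null(layer$surface) || nrow(layer$surface) == 0)
    stop("se layer has no surface triangulation; pass `mesh` to select_se_layer")
  tri <- layer$surface
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  ed <- t(apply(ed, 1, sort))
  ed <- unique(ed)
  w <- row_norms(frame$nodes[ed[, 1], , drop = FALSE] -
                   frame$nodes[ed[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(
    matrix(as.character(ed), ncol = 2), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Build the phenomenological fascicle-based HPS
#'
#' Each of the five fascicular root locations is mapped into the SE layer
#' and dilated into a disc: all SE-layer surface nodes within geodesic
#' (surface-graph) distance `delta_rad * L_ab` of the root, where `L_ab` is
#' the apicobasal endocardial arc length of the root's ventricle. Discs are
#' fired at the configured `t_his` timings.
#'
#' @param frame a `uvc_frame`.
#' @param layer an `se_layer` built with a mesh (surface attached).
#' @param eas an `eas_config`.
#' @param fasc a `fascicle_config`.
#' @return object of class `fascicle_hps`: per-fascicle `discs` (node index
#'   vectors), `times` (ms), `roots` (mapped root node indices), and the
#'   `layer`.
#' @export
build_fascicle_hps <- function(frame, layer, eas, fasc) {
  stopifnot(inherits(layer, "se_layer"))
  g <- se_surface_graph(frame, layer)
  vnames <- igraph::V(g)$name
  discs <- list()
  roots <- integer(0)
  for (fn in fascicle_names) {
    b <- eas[[paste0("b_", fn)]]
    root <- uvc_to_cartesian(frame, b)$index
    if (!root %in% layer$nodes)
      stop("build_fascicle_hps: root ", fn, " maps outside the SE layer")
    arc <- if (startsWith(fn, "lv")) frame$arc_lv else frame$arc_rv
    radius <- fasc$delta_rad * arc
    if (radius <= 0 || !as.character(root) %in% vnames) {
      disc <- root
    } else {
      d <- igraph::distances(g, v = as.character(root))[1, ]
      disc <- sort(unique(c(root, as.integer(vnames[d <= radius]))))
    }
    discs[[fn]] <- disc
    roots[fn] <- root
  }
  structure(list(discs = discs,
                 times = fasc$t_his[fascicle_names],
                 roots = roots,
                 layer = layer),
            class = "fascicle_hps")
}

#' @export
print.fascicle_hps <- function(x, ...) {
  cat("fascicle_hps: 5 discs, sizes",
      paste(vapply(x$discs, length, 1L), collapse = "/"),
      "nodes; t_his =", paste(x$times, collapse = ", "), "ms\n")
  invisible(x)
}
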