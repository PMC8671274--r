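## ---- purkinje_network container --------------------------------------------

new_purkinje_network <- function(nodes, role, fascicle, segments,
                                 root_nodes = integer(0), his_root = NA_integer_,
                                 territory = character(0),
                                 pvj = data.frame(pvj = integer(0),
                                                  tissue = integer(0))) {
  structure(list(nodes = nodes, role = role, fascicle = fascicle,
                 segments = segments, root_nodes = root_nodes,
                 his_root = his_root, territory = territory, pvj = pvj,
                 dropped_pvjs = 0L),
            class = "purkinje_network")
}

#' @export
print.purkinje_network <- function(x, ...) {
  cat("purkinje_network:", nrow(x$nodes), "nodes,", nrow(x$segments),
      "segments,", nrow(x$pvj), "PVJ couplings\n")
  print(table(x$role))
  invisible(x)
}

#' Parent/offspring counts per network node
#'
#' @param net a `purkinje_network`.
#' @return data.frame with `parents` and `children` per node.
#' @export
network_degrees <- function(net) {
  n <- nrow(net$nodes)
  data.frame(
    parents = tabulate(net$segments$to, nbins = n),
    children = tabulate(net$segments$from, nbins = n))
}

## subdivide the straight segment a -> b into pieces of length <= res (mm);
## returns matrix of interior points (possibly 0 rows)
subdivide_points <- function(a, b, res) {
  len <- sqrt(sum((b - a)^2))
  n <- ceiling(len / res - 1e-9)
  if (n <= 1) return(matrix(numeric(0), 0, 3))
  tt <- seq_len(n - 1) / n
  outer(1 - tt, a) + outer(tt, b)
}

## ---- His bundle -------------------------------------------------------------

#' Construct the His bundle from UVC bifurcation points
#'
#' Lays out the bundle as polyline paths between the mapped bifurcation
#' coordinates: `b_h0 -> b_h1`, `b_h1 -> b_h_lv -> {lv_sf, lv_af, lv_pf}`
#' and `b_h1 -> b_h_rv -> b_h_rv_mid -> {rv_sf, rv_mod}`. Each leg is a
#' straight Cartesian segment between mapped endpoints, walked at the cable
#' resolution; intermediate points are snapped to the nearest sub-endocardial
#' surface node when one lies within two edge lengths (the basal trunk
#' between `b_h0` and the bifurcation runs intramurally, where no
#' sub-endocardial node is nearby, and is left on the straight path). The
#' polyline is then discretized at `segment_resolution`. `b_h0` is the
#' unique network root (exit of the atrio-ventricular node).
#'
#' @param frame a `uvc_frame`.
#' @param purk a `purkinje_config`.
#' @param eas an `eas_config`.
#' @param layer an `se_layer` built with a mesh (snap targets).
#' @return a `purkinje_network` holding only HIS segments, with
#'   `root_nodes` marking the five fascicular leaf endpoints and `his_root`
#'   the `b_h0` node.
#' @export
build_his_bundle <- function(frame, purk, eas, layer) {
  res <- purk$segment_resolution / 1000
  snap_ids <- unique(as.vector(layer$surface))
  snap_pts <- frame$nodes[snap_ids, , drop = FALSE]
  tol <- 2 * frame$edge_length

  map_pt <- function(b, nm) {
    r <- uvc_to_cartesian(frame, b)
    if (!is.finite(r$dist))
      stop("build_his_bundle: bifurcation point ", nm, " maps outside the mesh")
    r$point
  }
  way <- list(h0 = map_pt(purk$b_h0, "b_h0"),
              h1 = map_pt(purk$b_h1, "b_h1"),
              h_lv = map_pt(purk$b_h_lv, "b_h_lv"),
              h_rv = map_pt(purk$b_h_rv, "b_h_rv"),
              h_rv_mid = map_pt(purk$b_h_rv_mid, "b_h_rv_mid"))
  roots <- lapply(fascicle_names, function(fn)
    map_pt(eas[[paste0("b_", fn)]], paste0("b_", fn)))
  names(roots) <- fascicle_names

  ## snap a straight leg's interior points onto the SE surface where possible
  leg_polyline <- function(a, b) {
    len <- sqrt(sum((b - a)^2))
    n <- max(1, ceiling(len / res))
    tt <- seq(0, 1, length.out = n + 1)
    pts <- outer(1 - tt, a) + outer(tt, b)
    out <- list(pts[1, ])
    for (i in seq(2, n)) {
      p <- pts[i, ]
      nn <- cpp_nn1(p, snap_pts, logical(0))
      q <- if (sqrt(nn$dist2) <= tol) snap_pts[nn$index, ] else p
      prev <- out[[length(out)]]
      if (sum((q - prev)^2) > 1e-12) out[[length(out) + 1L]] <- q
    }
    if (sum((pts[n + 1, ] - out[[length(out)]])^2) > 1e-12)
      out[[length(out) + 1L]] <- pts[n + 1, ]
    do.call(rbind, out)
  }

  nodes <- matrix(numeric(0), 0, 3)
  segs_from <- integer(0); segs_to <- integer(0)
  child_ct <- integer(0)
  new_node <- function(p) {
    nodes <<- rbind(nodes, p)
    child_ct <<- c(child_ct, 0L)
    nrow(nodes)
  }
  ## each leg is its own node chain starting at `start_id`; when the start
  ## node already feeds two offspring the attachment cascades one node down
  ## its first child chain (trifurcations become staggered bifurcations)
  first_child <- function(id) {
    k <- which(segs_from == id)
    if (length(k)) segs_to[k[1]] else NA_integer_
  }
  add_leg <- function(start_id, b) {
    while (child_ct[start_id] >= 2L) {
      nxt <- first_child(start_id)
      if (is.na(nxt)) break
      start_id <- nxt
    }
    poly <- leg_polyline(nodes[start_id, ], b)
    prev <- start_id
    for (i in seq(2, nrow(poly))) {
      inter <- subdivide_points(poly[i - 1, ], poly[i, ], res)
      pts <- rbind(inter, poly[i, , drop = FALSE])
      for (r2 in seq_len(nrow(pts))) {
        cur <- new_node(pts[r2, ])
        segs_from <<- c(segs_from, prev); segs_to <<- c(segs_to, cur)
        child_ct[prev] <<- child_ct[prev] + 1L
        prev <- cur
      }
    }
    prev
  }

  h0_id <- new_node(way$h0)
  h1_id <- add_leg(h0_id, way$h1)
  h_lv_id <- add_leg(h1_id, way$h_lv)
  h_rv_id <- add_leg(h1_id, way$h_rv)
  h_rv_mid_id <- add_leg(h_rv_id, way$h_rv_mid)
  leaf <- integer(0)
  for (fn in c("lv_sf", "lv_af", "lv_pf"))
    leaf[fn] <- add_leg(h_lv_id, roots[[fn]])
  for (fn in c("rv_sf", "rv_mod"))
    leaf[fn] <- add_leg(h_rv_mid_id, roots[[fn]])

  lens <- row_norms(nodes[segs_to, , drop = FALSE] -
                      nodes[segs_from, , drop = FALSE])
  segments <- data.frame(from = segs_from, to = segs_to, length = lens,
                         fascicle = "his", stringsAsFactors = FALSE)
  new_purkinje_network(
    nodes = nodes,
    role = rep("HIS", nrow(nodes)),
    fascicle = rep("his", nrow(nodes)),
    segments = segments,
    root_nodes = leaf,
    his_root = h0_id)
}

## ---- fractal growth ---------------------------------------------------------

## Rodrigues rotation of v about unit axis k by angle a
rotate_about <- function(v, k, a) {
  v * cos(a) + cross3(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

## per-node outward-ish normals on a triangulated surface (area weighted)
surface_node_normals <- function(pts_all, tri) {
  e1 <- pts_all[tri[, 2], , drop = FALSE] - pts_all[tri[, 1], , drop = FALSE]
  e2 <- pts_all[tri[, 3], , drop = FALSE] - pts_all[tri[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ids <- unique(as.vector(tri))
  nrm <- matrix(0, length(ids), 3)
  pos <- match(as.vector(tri), ids)
  for (c3 in 1:3) {
    col_ids <- pos[((c3 - 1) * nrow(tri) + 1):(c3 * nrow(tri))]
    for (d in 1:3) {
      acc <- tapply(fn[, d], col_ids, sum)
      nrm[as.integer(names(acc)), d] <- nrm[as.integer(names(acc)), d] + acc
    }
  }
  n <- row_norms(nrm)
  list(ids = ids, normals = nrm / pmax(n, .Machine$double.eps))
}

#' Grow one recombinant fractal Purkinje fascicle network
#'
#' Grows a branching network on the sub-endocardial surface from a root
#' location. The first generation is a single branch; afterwards every
#' active tip spawns up to two branches deflected by +/- `psi` degrees about
#' the local surface normal. Branch lengths are drawn from
#' `Normal(mu, sigma * mu)` truncated to `[0.25 mu, 4 mu]`. Branches are
#' walked in sub-steps of `segment_resolution`; each sub-step direction is
#' `normalize((1 - r) * d_rot + r * d_rep)` where `d_rep` points away from
#' the nearest non-ancestor network node, and each sub-step is re-projected
#' onto the sub-endocardial surface. A sub-step passing within
#' `0.5 * segment_resolution` of an existing node of the same fascicle
#' collides: the branch connects to that node (if its parent count permits)
#' and terminates, producing a recombinant mesh topology. Tips leaving the
#' sub-endocardial band are truncated at its boundary. Growth stops once
#' the estimated coverage (fraction of the ventricle's sub-endocardial
#' surface nodes within distance `mu` of the network) reaches `delta_cov`,
#' or at the generation cap.
#'
#' @param frame a `uvc_frame`.
#' @param layer an `se_layer` with surface triangulation.
#' @param root UVC coordinate of the fascicle root (earliest activation
#'   site).
#' @param purk a `purkinje_config`.
#' @param seed integer seed for this fascicle's RNG stream.
#' @param fascicle label stored on nodes/segments.
#' @param collide logical; disable to study pure fractal growth (no
#'   recombination).
#' @return a `purkinje_network` for this fascicle (root node is node 1),
#'   with attribute fields `coverage` and `generations` recorded.
#' @export
grow_fascicle_network <- function(frame, layer, root, purk, seed,
                                  fascicle = "lv_sf", collide = TRUE) {
  res <- purk$segment_resolution / 1000
  mu <- purk$mu / 1000
  psi <- purk$psi * pi / 180
  rfac <- purk$r

  rootm <- uvc_to_cartesian(frame, root)
  root_id_mesh <- rootm$index
  if (!root_id_mesh %in% layer$nodes)
    stop("grow_fascicle_network: root ", fascicle, " lies outside the SE layer")

  ## territory: the endocardial surface tag the root sits on
  tri_all <- layer$surface
  tags <- layer$surface_tag
  on_tag <- vapply(seq_len(nrow(tri_all)), function(i)
    root_id_mesh %in% tri_all[i, ], logical(1))
  territory_tag <- if (any(on_tag)) tags[which(on_tag)[1]] else
    (if (as_uvc(root)[4] > 0 || as_uvc(root)[2] > 0.5) "RV_ENDO" else "LV_ENDO")
  keep_tri <- tags == territory_tag
  tri <- tri_all[keep_tri, , drop = FALSE]
  sn <- surface_node_normals(frame$nodes, tri)
  surf_ids <- sn$ids
  surf_pts <- frame$nodes[surf_ids, , drop = FALSE]
  surf_nrm <- sn$normals

  surf_info <- function(p) {
    nn <- cpp_nn1(p, surf_pts, logical(0))
    list(q = surf_pts[nn$index, ], n = surf_nrm[nn$index, ],
         dist = sqrt(nn$dist2))
  }
  project <- function(p, info) {
    d <- p - info$q
    p - sum(d * info$n) * info$n
  }

  ## growth state
  cap <- 4096L
  nodes <- matrix(NA_real_, cap, 3)
  n_nodes <- 0L
  parent_ct <- integer(cap); child_ct <- integer(cap)
  segs <- vector("list", 4096L); n_segs <- 0L
  add_node <- function(p) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > nrow(nodes)) {
      nodes <<- rbind(nodes, matrix(NA_real_, nrow(nodes), 3))
      parent_ct <<- c(parent_ct, integer(nrow(nodes) / 2))
      child_ct <<- c(child_ct, integer(nrow(nodes) / 2))
    }
    nodes[n_nodes, ] <<- p
    n_nodes
  }
  add_seg <- function(a, b) {
    n_segs <<- n_segs + 1L
    if (n_segs > length(segs)) segs <<- c(segs, vector("list", length(segs)))
    segs[[n_segs]] <<- c(a, b)
    child_ct[a] <<- child_ct[a] + 1L
    parent_ct[b] <<- parent_ct[b] + 1L
  }

  covered <- logical(nrow(surf_pts))
  mark_cover <- function(p) cpp_cover_update(p, surf_pts, mu, covered)
  coverage <- function() mean(covered)

  root_pos <- rootm$point
  rid <- add_node(root_pos)
  mark_cover(root_pos)
  ## reserve one parent slot on the root for the incoming His segment, so
  ## collisions into the root cannot push it past two parents after welding
  parent_ct[rid] <- 1L
  grid <- cpp_grid_new(mu)   # spatial hash for repulsion/collision queries
  cpp_grid_insert(grid, rid, root_pos)

  if (purk$delta_cov <= 0) {
    net <- new_purkinje_network(
      nodes = nodes[1, , drop = FALSE],
      role = "BRANCH",
      fascicle = fascicle,
      segments = data.frame(from = integer(0), to = integer(0),
                            length = numeric(0), fascicle = character(0),
                            stringsAsFactors = FALSE),
      root_nodes = stats::setNames(1L, fascicle),
      territory = stats::setNames(territory_tag, fascicle))
    net$coverage <- coverage(); net$generations <- 0L
    return(net)
  }

  set.seed(seed)
  info0 <- surf_info(root_pos)
  t0 <- unit(cross3(info0$n, if (abs(info0$n[1]) < 0.9) c(1, 0, 0)
                    else c(0, 1, 0)))
  d0 <- rotate_about(t0, info0$n, runif(1, 0, 2 * pi))

  draw_len <- function() {
    if (purk$sigma == 0) return(mu)
    min(max(rnorm(1, mu, purk$sigma * mu), 0.25 * mu), 4 * mu)
  }

  ## walk one branch (C++ inner loop); returns new tip (id, dir) or NULL
  walk_branch <- function(start_id, d_rot) {
    len <- draw_len()
    n_sub <- max(1L, round(len / res))
    ## ensure node capacity
    while (n_nodes + n_sub > nrow(nodes)) {
      nodes <<- rbind(nodes, matrix(NA_real_, nrow(nodes), 3))
      parent_ct <<- c(parent_ct, integer(length(parent_ct)))
      child_ct <<- c(child_ct, integer(length(child_ct)))
    }
    w <- cpp_walk_branch(start_id, nodes[start_id, ], d_rot, n_sub, res,
                         rfac, collide, surf_pts, surf_nrm, nodes, n_nodes,
                         parent_ct, child_ct[start_id], frame$edge_length,
                         mu, covered, grid)
    if (w$added > 0) {
      for (i in seq_along(w$seg_from)) {
        a <- w$seg_from[i]; b <- w$seg_to[i]
        n_segs <<- n_segs + 1L
        if (n_segs > length(segs)) segs <<- c(segs, vector("list", length(segs)))
        segs[[n_segs]] <<- c(a, b)
        child_ct[a] <<- child_ct[a] + 1L
        parent_ct[b] <<- parent_ct[b] + 1L
      }
      n_nodes <<- n_nodes + w$added
    }
    if (w$term == 2L && parent_ct[w$merge_target] < 2L &&
        child_ct[w$tip_id] < 2L) add_seg(w$tip_id, w$merge_target)
    if (w$term != 0L) return(NULL)
    list(id = w$tip_id, dir = w$tip_dir)
  }

  tips <- list(list(id = rid, dir = d0))
  gen <- 0L
  first <- TRUE
  while (length(tips) && coverage() < purk$delta_cov &&
         gen < purk$generation_cap) {
    gen <- gen + 1L
    new_tips <- list()
    for (tip in tips) {
      info <- surf_info(nodes[tip$id, ])
      n_branches <- if (first) 1L else 2L
      signs <- if (first) 0 else c(+1, -1)
      for (b in seq_len(n_branches)) {
        if (child_ct[tip$id] >= 2L) break
        dd <- rotate_about(tip$dir, info$n, signs[b] * psi)
        nt <- walk_branch(tip$id, dd)
        if (!is.null(nt)) new_tips[[length(new_tips) + 1L]] <- nt
        if (coverage() >= purk$delta_cov) break
      }
      if (coverage() >= purk$delta_cov) break
    }
    tips <- new_tips
    first <- FALSE
  }

  seg_m <- do.call(rbind, segs[seq_len(n_segs)])
  if (is.null(seg_m)) seg_m <- matrix(integer(0), 0, 2)
  nd <- nodes[seq_len(n_nodes), , drop = FALSE]
  lens <- if (nrow(seg_m)) row_norms(nd[seg_m[, 2], , drop = FALSE] -
                                       nd[seg_m[, 1], , drop = FALSE])
  else numeric(0)
  net <- new_purkinje_network(
    nodes = nd,
    role = rep("BRANCH", n_nodes),
    fascicle = rep(fascicle, n_nodes),
    segments = data.frame(from = seg_m[, 1], to = seg_m[, 2], length = lens,
                          fascicle = rep(fascicle, nrow(seg_m)),
                          stringsAsFactors = FALSE),
    root_nodes = stats::setNames(1L, fascicle),
    territory = stats::setNames(territory_tag, fascicle))
  net$coverage <- coverage()
  net$generations <- gen
  net
}

## ---- combination ------------------------------------------------------------

#' Merge the His bundle with the five fascicle networks
#'
#' Fascicle network roots are welded onto the matching His-bundle leaf
#' endpoints, so the union is connected to the `b_h0` root while networks
#' of different fascicles stay node-disjoint.
#'
#' @param his `purkinje_network` from [build_his_bundle()].
#' @param nets named list of per-fascicle networks from
#'   [grow_fascicle_network()].
#' @return combined `purkinje_network`.
#' @export
combine_networks <- function(his, nets) {
  nodes <- his$nodes; role <- his$role; fasc <- his$fascicle
  segments <- his$segments
  root_nodes <- integer(0)
  territory <- character(0)
  for (fn in names(nets)) {
    net <- nets[[fn]]
    leaf <- his$root_nodes[[fn]]
    offset <- nrow(nodes)
    ## network node 1 (its root) is identified with the His leaf
    remap <- c(leaf, offset + seq_len(nrow(net$nodes) - 1L))
    if (nrow(net$nodes) > 1) {
      nodes <- rbind(nodes, net$nodes[-1, , drop = FALSE])
      role <- c(role, net$role[-1])
      fasc <- c(fasc, net$fascicle[-1])
    }
    role[leaf] <- "BRANCH"
    fasc[leaf] <- fn
    if (nrow(net$segments)) {
      segments <- rbind(segments, data.frame(
        from = remap[net$segments$from],
        to = remap[net$segments$to],
        length = net$segments$length,
        fascicle = net$segments$fascicle,
        stringsAsFactors = FALSE))
    }
    root_nodes[fn] <- leaf
    territory[fn] <- net$territory[[fn]]
  }
  out <- new_purkinje_network(nodes, role, fasc, segments,
                              root_nodes = root_nodes,
                              his_root = his$his_root,
                              territory = territory)
  out
}

## ---- PVJ placement ----------------------------------------------------------

#' Stochastic placement of Purkinje-ventricular junctions
#'
#' Computes the linear PVJ density `lambda = delta_cov / mu` (junctions per
#' unit cable length) and traverses each fascicle network depth-first from
#' its root, accumulating the arc distance `d` since the last junction on
#' the current path. At each node a junction is accepted with probability
#' `min(1, lambda * d)` (a linear hazard whose mean spacing is
#' `1 / lambda`), resetting `d`. An accepted junction is realised as a stem
#' attached at the midpoint of the segment on which acceptance occurred:
#' the host segment is split at its midpoint and a transmurally oriented
#' stem of initial length `segment_resolution` is added there, ending in a
#' `PVJ` node. His segments never receive junctions.
#'
#' @param net combined `purkinje_network`.
#' @param purk a `purkinje_config`.
#' @param seed RNG seed.
#' @param mesh optional `biv_mesh`; when given, stems are oriented along
#'   the inward endocardial normal at the attachment point (otherwise a
#'   placeholder normal is used until [extend_transmural()]).
#' @return the network with stem/PVJ nodes and split host segments added.
#' @export
place_pvjs <- function(net, purk, seed, mesh = NULL) {
  non_his <- net$segments$fascicle != "his"
  if (!any(non_his)) stop("place_pvjs: network has no fascicle segments")
  mu <- purk$mu / 1000
  res <- purk$segment_resolution / 1000
  lambda <- purk$delta_cov / mu     # PVJs per mm of cable
  if (lambda <= 0) return(net)

  set.seed(seed)
  segments <- net$segments
  acc_edge <- integer(0)     # host segment rows that accepted a PVJ
  acc_fasc <- character(0)

  n_all <- nrow(net$nodes)
  seg_to <- segments$to
  seg_len <- segments$length
  acc_list <- list()
  for (fn in names(net$root_nodes)) {
    segf <- which(segments$fascicle == fn)
    if (!length(segf)) next
    ## CSR-style adjacency over this fascicle's segments
    ord <- segf[order(segments$from[segf])]
    from_s <- segments$from[ord]
    first <- integer(n_all + 1L)
    cnt <- tabulate(from_s, nbins = n_all)
    first <- c(0L, cumsum(cnt))   # edges for node v: ord[(first[v]+1):first[v+1]]
    ## iterative DFS from the fascicle root; visit each node once (first
    ## arrival), carrying the arc distance since the last accepted PVJ
    visited <- logical(n_all)
    root <- net$root_nodes[[fn]]
    visited[root] <- TRUE
    stack_node <- integer(2048L); stack_d <- numeric(2048L)
    stack_node[1L] <- root; stack_d[1L] <- 0
    n_stack <- 1L
    acc_e <- integer(0)
    while (n_stack > 0L) {
      node <- stack_node[n_stack]; dcur <- stack_d[n_stack]
      n_stack <- n_stack - 1L
      lo <- first[node] + 1L; hi <- first[node + 1L]
      if (lo > hi) next
      for (e in ord[lo:hi]) {
        to <- seg_to[e]
        if (visited[to]) next
        visited[to] <- TRUE
        d_here <- dcur + seg_len[e]
        if (runif(1) < min(1, lambda * d_here)) {
          acc_e <- c(acc_e, e)
          d_here <- 0
        }
        n_stack <- n_stack + 1L
        if (n_stack > length(stack_node)) {
          stack_node <- c(stack_node, integer(length(stack_node)))
          stack_d <- c(stack_d, numeric(length(stack_d)))
        }
        stack_node[n_stack] <- to
        stack_d[n_stack] <- d_here
      }
    }
    acc_list[[fn]] <- acc_e
  }
  acc_edge <- unlist(acc_list, use.names = FALSE) %||% integer(0)
  acc_fasc <- rep(names(acc_list), times = vapply(acc_list, length, 1L))

  n_acc <- length(acc_edge)
  if (n_acc == 0) {
    net$pvj <- data.frame(pvj = integer(0), tissue = integer(0),
                          stem_base = integer(0), fascicle = character(0))
    return(net)
  }

  ## batch realisation: split each host segment at its midpoint and hang a
  ## transmural stem of length `res` there
  a <- segments$from[acc_edge]; b <- segments$to[acc_edge]
  mids <- (net$nodes[a, , drop = FALSE] + net$nodes[b, , drop = FALSE]) / 2
  nrm <- matrix(rep(c(0, 0, -1), each = n_acc), ncol = 3)
  if (!is.null(mesh)) {
    for (tag in unique(unlist(net$territory))) {
      rows <- which(vapply(acc_fasc, function(f)
        (net$territory[[f]] %||% "LV_ENDO") == tag, logical(1)))
      if (!length(rows)) next
      tri <- mesh$surface$tri[mesh$surface$tag == tag, , drop = FALSE]
      sn <- surface_node_normals(mesh$nodes, tri)
      pts <- mesh$nodes[sn$ids, , drop = FALSE]
      ni <- cpp_nn_batch(mids[rows, , drop = FALSE], pts)
      nrm[rows, ] <- -sn$normals[ni, , drop = FALSE]
    }
  }
  n0 <- nrow(net$nodes)
  mid_ids <- n0 + seq_len(n_acc)
  pvj_ids <- n0 + n_acc + seq_len(n_acc)
  net$nodes <- rbind(net$nodes, mids, mids + res * nrm)
  net$role <- c(net$role, rep("PVJ_STEM", n_acc), rep("PVJ", n_acc))
  net$fascicle <- c(net$fascicle, acc_fasc, acc_fasc)
  half <- segments$length[acc_edge] / 2
  old_to <- segments$to[acc_edge]
  segments$to[acc_edge] <- mid_ids
  segments$length[acc_edge] <- half
  segments <- rbind(
    segments,
    data.frame(from = mid_ids, to = old_to, length = half,
               fascicle = acc_fasc, stringsAsFactors = FALSE),
    data.frame(from = mid_ids, to = pvj_ids, length = res,
               fascicle = acc_fasc, stringsAsFactors = FALSE))
  rownames(segments) <- NULL
  net$segments <- segments
  net$pvj <- data.frame(pvj = pvj_ids, tissue = NA_integer_,
                        stem_base = mid_ids, fascicle = acc_fasc,
                        stringsAsFactors = FALSE)
  net
}

## ---- transmural extension ---------------------------------------------------

#' Ray-traced transmural extension of PVJ stems
#'
#' For every junction, a paired intersection point on the next geometric
#' surface is found by casting a ray along the inward endocardial normal
#' from the stem attachment point ([surface_ray_pair()]). The paired
#' distance `D` is scaled by the transmural extent `s_rho`, randomized by a
#' Gaussian factor `g ~ Normal(1, sigma)`, and the stem is extended along
#' the ray to length `clamp(s_rho * D * max(0.25, g), 0, 0.95 * D)`; the
#' junction node moves to the extended tip and is re-discretized at the
#' cable resolution. Couplings to the nearest tissue node are recorded.
#' Junctions whose ray finds no paired surface are dropped with a warning.
#'
#' @param net `purkinje_network` after [place_pvjs()].
#' @param mesh a `biv_mesh`.
#' @param eas an `eas_config` (`s_rho`).
#' @param purk a `purkinje_config` (`sigma`, `segment_resolution`).
#' @param seed RNG seed.
#' @return the network with extended stems and `pvj` couplings filled in.
#' @export
extend_transmural <- function(net, mesh, eas, purk, seed) {
  if (!nrow(net$pvj)) return(net)
  res <- purk$segment_resolution / 1000
  set.seed(seed)
  n_pvj <- nrow(net$pvj)

  ## precompute, per originating surface tag: snap nodes + averaged inward
  ## normals, and the triangle soup of all OTHER boundary surfaces
  tri <- mesh$surface$tri
  tags_all <- as.character(mesh$surface$tag)
  surf_cache <- list()
  for (tag in unique(unlist(net$territory))) {
    own <- tags_all == tag
    sn <- surface_node_normals(mesh$nodes, tri[own, , drop = FALSE])
    other <- which(!own)
    surf_cache[[tag]] <- list(
      ids = sn$ids,
      pts = mesh$nodes[sn$ids, , drop = FALSE],
      inward = -sn$normals,
      v0 = mesh$nodes[tri[other, 1], , drop = FALSE],
      v1 = mesh$nodes[tri[other, 2], , drop = FALSE],
      v2 = mesh$nodes[tri[other, 3], , drop = FALSE])
  }

  keep <- rep(TRUE, n_pvj)
  tissue <- integer(n_pvj)
  tip_mat <- matrix(NA_real_, n_pvj, 3)
  gfac <- if (purk$sigma > 0) rnorm(n_pvj, 1, purk$sigma) else rep(1, n_pvj)
  pvj_tag <- vapply(net$pvj$fascicle, function(f)
    net$territory[[f]] %||% "LV_ENDO", character(1))
  base_pts <- net$nodes[net$pvj$stem_base, , drop = FALSE]
  dir_mat <- matrix(NA_real_, n_pvj, 3)
  D_all <- rep(Inf, n_pvj)
  for (tag in names(surf_cache)) {
    rows <- which(pvj_tag == tag)
    if (!length(rows)) next
    sc <- surf_cache[[tag]]
    ni <- cpp_nn_batch(base_pts[rows, , drop = FALSE], sc$pts)
    dir_mat[rows, ] <- sc$inward[ni, , drop = FALSE]
    D_all[rows] <- cpp_ray_first(base_pts[rows, , drop = FALSE],
                                 dir_mat[rows, , drop = FALSE],
                                 sc$v0, sc$v1, sc$v2, 1e-6)
  }
  for (i in seq_len(n_pvj)) {
    if (!is.finite(D_all[i])) { keep[i] <- FALSE; next }
    ell <- min(max(eas$s_rho * D_all[i] * max(0.25, gfac[i]), 0),
               0.95 * D_all[i])
    tip_mat[i, ] <- base_pts[i, ] + ell * dir_mat[i, ]
  }

  dropped <- sum(!keep)
  ## relocate PVJ nodes to the extended tips, re-discretize stems
  stem_rows <- match(paste(net$pvj$stem_base, net$pvj$pvj),
                     paste(net$segments$from, net$segments$to))
  drop_seg <- stem_rows[!keep]
  new_nodes <- list(); new_role <- list(); new_fasc <- list()
  new_segs <- list()
  n_next <- nrow(net$nodes)
  for (i in which(keep)) {
    base_id <- net$pvj$stem_base[i]
    pvj_id <- net$pvj$pvj[i]
    base_pt <- net$nodes[base_id, ]
    tip <- tip_mat[i, ]
    net$nodes[pvj_id, ] <- tip
    inter <- subdivide_points(base_pt, tip, res)
    if (nrow(inter)) {
      ids <- n_next + seq_len(nrow(inter))
      n_next <- n_next + nrow(inter)
      new_nodes[[length(new_nodes) + 1L]] <- inter
      new_role[[length(new_role) + 1L]] <- rep("PVJ_STEM", nrow(inter))
      new_fasc[[length(new_fasc) + 1L]] <- rep(net$pvj$fascicle[i],
                                               nrow(inter))
      chain <- c(base_id, ids, pvj_id)
      pts <- rbind(base_pt, inter, tip)
      lens <- row_norms(pts[-1, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])
      drop_seg <- c(drop_seg, stem_rows[i])
      new_segs[[length(new_segs) + 1L]] <- data.frame(
        from = chain[-length(chain)], to = chain[-1], length = lens,
        fascicle = net$pvj$fascicle[i], stringsAsFactors = FALSE)
    } else {
      net$segments$length[stem_rows[i]] <- sqrt(sum((tip - base_pt)^2))
    }
  }
  if (length(new_nodes)) {
    net$nodes <- rbind(net$nodes, do.call(rbind, new_nodes))
    net$role <- c(net$role, unlist(new_role))
    net$fascicle <- c(net$fascicle, unlist(new_fasc))
  }
  if (length(drop_seg)) net$segments <- net$segments[-drop_seg, ]
  if (length(new_segs))
    net$segments <- rbind(net$segments, do.call(rbind, new_segs))
  tips_kept <- tip_mat[keep, , drop = FALSE]
  if (nrow(tips_kept))
    tissue[keep] <- cpp_nn_batch(tips_kept, mesh$nodes)
  net$pvj$tissue <- tissue
  net$pvj <- net$pvj[keep, , drop = FALSE]
  if (dropped) {
    warning("extend_transmural: dropped ", dropped,
            " PVJ(s) with no paired surface")
    net$dropped_pvjs <- dropped
    net <- compact_network(net)
  }
  rownames(net$segments) <- NULL
  net
}

## drop nodes referenced by no segment (orphans left by dropped PVJs) and
## renumber everything contiguously
compact_network <- function(net) {
  used <- sort(unique(c(net$segments$from, net$segments$to,
                        net$root_nodes, net$his_root)))
  remap <- integer(nrow(net$nodes))
  remap[used] <- seq_along(used)
  net$nodes <- net$nodes[used, , drop = FALSE]
  net$role <- net$role[used]
  net$fascicle <- net$fascicle[used]
  net$segments$from <- remap[net$segments$from]
  net$segments$to <- remap[net$segments$to]
  net$root_nodes <- stats::setNames(remap[net$root_nodes],
                                    names(net$root_nodes))
  if (!is.na(net$his_root)) net$his_root <- remap[net$his_root]
  if (nrow(net$pvj)) {
    net$pvj$pvj <- remap[net$pvj$pvj]
    net$pvj$stem_base <- remap[net$pvj$stem_base]
  }
  net
}

#' Build the complete Purkinje-based HPS
#'
#' Orchestrates [build_his_bundle()], [grow_fascicle_network()] for the
#' five fascicles (each on its own named RNG substream derived from the
#' master seed), [combine_networks()], [place_pvjs()] and
#' [extend_transmural()].
#'
#' @param mesh a `biv_mesh`; @param frame a `uvc_frame`.
#' @param eas,fasc,purk configuration objects; @param seed master seed.
#' @param layer optional precomputed `se_layer`.
#' @return a `purkinje_network` ready for activation simulation.
#' @export
build_purkinje_hps <- function(mesh, frame, eas, purk, seed = 1L,
                               layer = NULL) {
  if (is.null(layer)) layer <- select_se_layer(frame, eas, mesh)
  his <- build_his_bundle(frame, purk, eas, layer)
  nets <- list()
  for (fn in fascicle_names) {
    nets[[fn]] <- grow_fascicle_network(
      frame, layer, eas[[paste0("b_", fn)]], purk,
      seed = sub_seed(seed, paste0("grow_", fn)), fascicle = fn)
  }
  net <- combine_networks(his, nets)
  if (any(net$segments$fascicle != "his")) {
    net <- place_pvjs(net, purk, seed = sub_seed(seed, "pvj"), mesh = mesh)
    net <- extend_transmural(net, mesh, eas, purk,
                             seed = sub_seed(seed, "transmural"))
  }
  net
}
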