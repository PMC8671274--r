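test_that("His bundle reaches the five fascicular roots as leaves", {
  g <- fix_geo()
  cfg <- fix_cfg()
  his <- build_his_bundle(g$frame, cfg$purkinje, cfg$eas, fix_layer())
  expect_length(his$root_nodes, 5)
  expect_setequal(names(his$root_nodes),
                  c("lv_sf", "lv_af", "lv_pf", "rv_sf", "rv_mod"))
  ## each leaf sits at the mapped root position
  for (fn in names(his$root_nodes)) {
    want <- uvc_to_cartesian(g$frame, cfg$eas[[paste0("b_", fn)]])$point
    expect_equal(unname(his$nodes[his$root_nodes[fn], ]), unname(want))
  }
  ## resolution bound on every HIS segment
  res <- cfg$purkinje$segment_resolution / 1000
  expect_lte(max(his$segments$length), res + 1e-9)
  ## degree caps hold
  deg <- network_degrees(his)
  expect_lte(max(deg$parents), 2)
  expect_lte(max(deg$children), 2)
})

test_that("RV paths run through the mid-septal waypoint, LV paths do not", {
  g <- fix_geo()
  cfg <- fix_cfg()
  his <- build_his_bundle(g$frame, cfg$purkinje, cfg$eas, fix_layer())
  mid_pt <- uvc_to_cartesian(g$frame, cfg$purkinje$b_h_rv_mid)$point
  mid_id <- which(apply(his$nodes, 1, function(p)
    sum((p - mid_pt)^2) < 1e-12))
  expect_length(mid_id, 1)
  ## walk upstream from each leaf to the His root; record passage
  parents <- split(his$segments$from, his$segments$to)
  ancestors <- function(leaf) {
    seen <- integer(0)
    frontier <- leaf
    while (length(frontier)) {
      seen <- c(seen, frontier)
      frontier <- unique(unlist(parents[as.character(frontier)]))
      frontier <- setdiff(frontier, seen)
    }
    seen
  }
  for (fn in c("rv_sf", "rv_mod"))
    expect_true(mid_id %in% ancestors(his$root_nodes[fn]))
  for (fn in c("lv_sf", "lv_af", "lv_pf"))
    expect_false(mid_id %in% ancestors(his$root_nodes[fn]))
})

test_that("zero coverage yields the root node only", {
  g <- fix_geo()
  cfg <- fix_cfg()
  purk <- cfg$purkinje
  purk$delta_cov <- 0
  net <- grow_fascicle_network(g$frame, fix_layer(), cfg$eas$b_lv_sf, purk,
                               seed = 3, fascicle = "lv_sf")
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$segments), 0L)
})

test_that("deterministic growth without collisions matches the binary-tree count", {
  sheet <- flat_sheet()
  cfg <- fix_cfg()
  purk <- cfg$purkinje
  purk$psi <- 0; purk$r <- 0; purk$sigma <- 0
  purk$delta_cov <- 1          # unreachable on the big sheet
  G <- 4
  purk$generation_cap <- G
  net <- grow_fascicle_network(sheet$frame, sheet$layer, sheet$root, purk,
                               seed = 5, fascicle = "lv_sf",
                               collide = FALSE)
  ## closed form: generation 1 grows a single branch, each later tip two;
  ## every branch contributes round(mu / resolution) nodes
  n_sub <- round(purk$mu / purk$segment_resolution)
  n_branches <- 2^G - 1
  expect_equal(nrow(net$nodes), 1 + n_branches * n_sub)
  expect_equal(nrow(net$segments), n_branches * n_sub)
})

test_that("degree caps and SE bounds hold across seeds", {
  g <- fix_geo()
  cfg <- fix_cfg()
  lay <- fix_layer()
  for (seed in c(2, 17, 91)) {
    net <- grow_fascicle_network(g$frame, lay, cfg$eas$b_rv_mod,
                                 cfg$purkinje, seed = seed,
                                 fascicle = "rv_mod")
    deg <- network_degrees(net)
    expect_lte(max(deg$parents), 2)
    expect_lte(max(deg$children), 2)
    ## all nodes within one edge length of the SE band
    se_pts <- g$frame$nodes[lay$nodes, , drop = FALSE]
    nn <- hpstwin:::cpp_nn_batch(net$nodes, se_pts)
    d <- sqrt(rowSums((net$nodes - se_pts[nn, , drop = FALSE])^2))
    expect_lte(max(d), g$frame$edge_length)
  }
})

test_that("fixed seed reproduces the network bit-for-bit", {
  g <- fix_geo()
  cfg <- fix_cfg()
  a <- grow_fascicle_network(g$frame, fix_layer(), cfg$eas$b_rv_mod,
                             cfg$purkinje, seed = 21, fascicle = "rv_mod")
  b <- grow_fascicle_network(g$frame, fix_layer(), cfg$eas$b_rv_mod,
                             cfg$purkinje, seed = 21, fascicle = "rv_mod")
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$segments, b$segments)
})

test_that("total cable length is non-decreasing in the coverage target", {
  sheet <- flat_sheet()
  cfg <- fix_cfg()
  purk <- cfg$purkinje
  lens <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(dc) {
    purk$delta_cov <- dc
    purk$generation_cap <- 12
    net <- grow_fascicle_network(sheet$frame, sheet$layer, sheet$root, purk,
                                 seed = 8, fascicle = "lv_sf")
    sum(net$segments$length)
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("fascicle networks share no nodes and PVJ stems sit at host midpoints", {
  net <- fix_net()
  ## pairwise disjoint: segments of different fascicles never share nodes
  ## (the His bundle connects them only at the roots)
  for (fa in c("lv_sf", "lv_af")) {
    na <- unique(c(net$segments$from[net$segments$fascicle == fa],
                   net$segments$to[net$segments$fascicle == fa]))
    for (fb in c("lv_pf", "rv_sf", "rv_mod")) {
      nb <- unique(c(net$segments$from[net$segments$fascicle == fb],
                     net$segments$to[net$segments$fascicle == fb]))
      expect_length(intersect(na, nb), 0)
    }
  }
  ## each stem base bisects its host segment
  deg <- network_degrees(net)
  samp <- net$pvj[seq(1, nrow(net$pvj), length.out = 25), ]
  for (i in seq_len(nrow(samp))) {
    base <- samp$stem_base[i]
    expect_equal(deg$parents[base], 1)
    expect_equal(deg$children[base], 2)
    par_seg <- which(net$segments$to == base)
    kids <- net$segments$to[net$segments$from == base]
    down <- setdiff(kids, samp$pvj[i])
    down <- down[net$role[down] != "PVJ" & net$role[down] != "PVJ_STEM"]
    if (length(down) == 1) {
      a <- net$nodes[net$segments$from[par_seg], ]
      b <- net$nodes[down, ]
      expect_equal(unname(net$nodes[base, ]), unname((a + b) / 2),
                   tolerance = 1e-9)
    }
  }
})

test_that("zero PVJ density adds no junctions", {
  chain <- chain_network()
  cfg <- fix_cfg()
  purk <- cfg$purkinje
  purk$delta_cov <- 0
  out <- place_pvjs(chain, purk, seed = 1)
  expect_equal(nrow(out$pvj), 0L)
  expect_equal(nrow(out$segments), nrow(chain$segments))
})

test_that("transmural extension with zero spread hits the prescribed depth", {
  g <- fix_geo()
  cfg <- fix_cfg()
  purk <- cfg$purkinje
  purk$sigma <- 0
  net <- suppressWarnings(place_pvjs(
    combine_networks(build_his_bundle(g$frame, purk, cfg$eas, fix_layer()),
                     list(lv_sf = grow_fascicle_network(
                       g$frame, fix_layer(), cfg$eas$b_lv_sf, purk,
                       seed = 2, fascicle = "lv_sf"))),
    purk, seed = 3, mesh = g$mesh))
  ext <- suppressWarnings(
    extend_transmural(net, g$mesh, cfg$eas, purk, seed = 4))
  ## every surviving PVJ sits at depth s_rho * D of its own ray pair
  samp <- ext$pvj[seq(1, nrow(ext$pvj), length.out = 20), ]
  for (i in seq_len(nrow(samp))) {
    base <- ext$nodes[samp$stem_base[i], ]
    tip <- ext$nodes[samp$pvj[i], ]
    rp <- surface_ray_pair(g$mesh, base, "LV_ENDO")
    depth <- sqrt(sum((tip - base)^2))
    expect_equal(depth, cfg$eas$s_rho * rp$distance, tolerance = 1e-6)
    expect_lte(depth, 0.95 * rp$distance)
  }
})
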