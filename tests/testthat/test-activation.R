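test_that("sub-endocardial edges conduct at the fast velocity", {
  g <- fix_geo()
  cfg <- fix_cfg()
  pg <- assemble_graph(g$mesh, layer = fix_layer(), sim = cfg$simulation)
  el <- igraph::as_edgelist(pg$graph)
  w <- igraph::E(pg$graph)$weight
  len <- sqrt(rowSums((g$mesh$nodes[el[, 1], ] - g$mesh$nodes[el[, 2], ])^2))
  fast <- abs(w - len / cfg$simulation$cv_purk) < 1e-12
  slow <- abs(w - len / cfg$simulation$cv_myo) < 1e-12
  expect_true(all(fast | slow))
  expect_gt(sum(fast), 0)
  inset <- logical(pg$n_tissue)
  inset[fix_layer()$nodes] <- TRUE
  ## fast edges connect sub-endocardial nodes only
  expect_true(all(inset[el[fast, 1]] & inset[el[fast, 2]]))
  ## a 3.7 mm fast edge would weigh exactly 1 ms: check the arithmetic on
  ## an actual fast edge scaled to its length
  e1 <- which(fast)[1]
  expect_equal(w[e1] * 3.7 / len[e1], 1.0, tolerance = 1e-12)
})

test_that("straight cable arrives at length over conduction velocity", {
  ## 10 segments of 3.7 mm at 3.70 m/s -> 10 ms
  n <- 11
  from <- 1:10; to <- 2:11
  w <- rep(3.7 / 3.70, 10)
  pg <- make_prop_graph(n, from, to, w)
  act <- solve_activation(pg, pacing_protocol("sinus", 1, 0))
  expect_equal(act[11], 10.0, tolerance = 1e-9)
})

test_that("PVJ crossings add the anterograde and retrograde delays", {
  sim <- fix_cfg()$simulation
  ## network node 1 -> cable -> PVJ node 2 -> tissue node 3
  pg <- make_prop_graph(3, c(1, 2), c(2, 3), c(2.5, sim$delay_antero),
                        n_tissue = 1)
  act <- solve_activation(pg, pacing_protocol("sinus", 1, 0))
  expect_equal(act[3] - act[2], 8)
  ## reversed fixture: tissue -> network costs the retrograde delay
  pg2 <- make_prop_graph(3, c(1, 2), c(2, 3), c(sim$delay_retro, 2.5),
                         n_tissue = 1)
  act2 <- solve_activation(pg2, pacing_protocol("sinus", 1, 0))
  expect_equal(act2[2] - act2[1], 3)
})

test_that("solver equals exhaustive path enumeration on random digraphs", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(3:8, 1)
    m <- sample(n:(n * (n - 1)), 1)
    from <- sample(n, m, replace = TRUE)
    to <- sample(n, m, replace = TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    if (!length(from)) next
    w <- round(runif(length(from), 0.1, 5), 3)
    src <- sample(n, sample(1:2, 1))
    t0 <- round(runif(length(src), 0, 2), 3)
    pg <- make_prop_graph(n, from, to, w)
    act <- solve_activation(pg, pacing_protocol("sinus", src, t0))
    oracle <- oracle_all_paths(n, from, to, w, src, t0)
    expect_equal(as.numeric(act), oracle)
  }
})

test_that("negative edge weights are rejected", {
  pg <- make_prop_graph(2, 1, 2, -1)
  expect_error(solve_activation(pg, pacing_protocol("sinus", 1, 0)),
               "negative")
})

test_that("one coupled solve equals alternating anterograde/retrograde passes", {
  sim <- fix_cfg()$simulation
  set.seed(77)
  for (k in 1:20) {
    nt <- sample(3:5, 1); nn <- sample(2:4, 1)
    n <- nt + nn
    ## random connected-ish tissue and network subgraphs + couplings
    t_e <- t(combn(nt, 2)); t_e <- t_e[runif(nrow(t_e)) < 0.8, , drop = FALSE]
    n_e <- t(combn(nn, 2)) + nt
    n_e <- n_e[runif(nrow(n_e)) < 0.8, , drop = FALSE]
    n_pvj <- sample(1:2, 1)
    pvj_net <- sample((nt + 1):n, n_pvj)
    pvj_tis <- sample(nt, n_pvj)
    from <- c(t_e[, 1], t_e[, 2], n_e[, 1], n_e[, 2], pvj_net, pvj_tis)
    to <- c(t_e[, 2], t_e[, 1], n_e[, 2], n_e[, 1], pvj_tis, pvj_net)
    wt <- round(runif(2 * nrow(t_e), 0.5, 4), 3)
    wn <- round(runif(2 * nrow(n_e), 0.2, 2), 3)
    w <- c(wt, wn, rep(sim$delay_antero, n_pvj), rep(sim$delay_retro, n_pvj))
    pg <- make_prop_graph(n, from, to, w, n_tissue = nt)
    src <- nt + 1
    act <- solve_activation(pg, pacing_protocol("sinus", src, 0))

    ## oracle: alternate passes between the two subdomains until fixed point
    best <- rep(Inf, n); best[src] <- 0
    for (sweep in 1:10) {
      prev <- best
      for (rep_bf in 1:2) {
        for (e in seq_along(from)) {
          cand <- best[from[e]] + w[e]
          if (cand < best[to[e]]) best[to[e]] <- cand
        }
      }
      if (identical(prev, best)) break
    }
    expect_equal(as.numeric(act), best)
  }
})

test_that("activation is 1-Lipschitz along every directed edge", {
  g <- fix_geo()
  cfg <- fix_cfg()
  hps <- build_fascicle_hps(g$frame, fix_layer(), cfg$eas, cfg$fascicle)
  out <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                      eas = cfg$eas)
  el <- igraph::as_edgelist(out$graph$graph)
  w <- igraph::E(out$graph$graph)$weight
  act <- as.numeric(out$act)
  samp <- seq(1, nrow(el), by = 13)
  expect_true(all(act[el[samp, 2]] <= act[el[samp, 1]] + w[samp] + 1e-9))
})

test_that("repeated solves of the same scenario are identical", {
  g <- fix_geo()
  cfg <- fix_cfg()
  hps <- build_fascicle_hps(g$frame, fix_layer(), cfg$eas, cfg$fascicle)
  a <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                    eas = cfg$eas)
  b <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                    eas = cfg$eas)
  expect_identical(as.numeric(a$act), as.numeric(b$act))
})

test_that("tissue edge count matches an independent adjacency recount", {
  g <- fix_geo()
  cfg <- fix_cfg()
  pg <- assemble_graph(g$mesh, sim = cfg$simulation)
  ## 1-ring: unique unordered tet edges
  el <- g$mesh$elems
  prs <- unique(rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                      el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)],
                      el[, c(2, 1)], el[, c(3, 1)], el[, c(4, 1)],
                      el[, c(3, 2)], el[, c(4, 2)], el[, c(4, 3)]))
  prs <- prs[prs[, 1] < prs[, 2], , drop = FALSE]
  n1 <- nrow(unique(prs))
  ## 2-ring: neighbours-of-neighbours not directly connected
  nbr <- split(c(prs[, 2], prs[, 1]), c(prs[, 1], prs[, 2]))
  nbr <- lapply(nbr, unique)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  direct <- unique(key(prs[, 1], prs[, 2]))
  two <- new.env(hash = TRUE, parent = emptyenv())
  for (v in as.integer(names(nbr))) {
    ns <- nbr[[as.character(v)]]
    for (u in ns) for (t in nbr[[as.character(u)]]) {
      if (t > v && !(key(v, t) %in% direct))
        assign(key(v, t), TRUE, envir = two)
    }
  }
  n2 <- length(ls(two))
  expect_equal(pg$n_edges, 2 * (n1 + n2))
})

test_that("graph eikonal times converge on a rod under refinement", {
  cfg <- fix_cfg()
  rod_mesh <- function(h) {
    nx <- round(40 / h)
    xs <- seq(0, 40, by = h)
    grid <- as.matrix(expand.grid(x = xs, y = c(0, h), z = c(0, h)))
    idx <- function(i, j, k)
      (k - 1) * 2 * (nx + 1) + (j - 1) * (nx + 1) + i
    hexes <- do.call(rbind, lapply(seq_len(nx), function(i)
      cbind(idx(i, 1, 1), idx(i + 1, 1, 1), idx(i, 2, 1), idx(i + 1, 2, 1),
            idx(i, 1, 2), idx(i + 1, 1, 2), idx(i, 2, 2), idx(i + 1, 2, 2))))
    tets <- hpstwin:::hex_to_tets(hexes)
    structure(list(nodes = grid, elems = tets), class = "biv_mesh")
  }
  errs <- vapply(c(4, 2, 1), function(h) {
    m <- rod_mesh(h)
    pg <- assemble_graph(m, sim = cfg$simulation)
    src <- which(m$nodes[, 1] == 0)[1]
    far <- which(m$nodes[, 1] == 40)[1]
    act <- solve_activation(pg, pacing_protocol("sinus", src, 0))
    abs(act[far] - 40 / cfg$simulation$cv_myo) / (40 / cfg$simulation$cv_myo)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_lte(errs[3], errs[1] + 1e-12)
})

test_that("Purkinje sinus activates LV roots before RV roots", {
  g <- fix_geo()
  cfg <- fix_cfg()
  out <- run_scenario(g$mesh, g$frame, fix_net(), cfg$simulation, "sinus",
                      eas = cfg$eas)
  r <- out$report
  expect_true(all(is.finite(r)) && all(r > 0))
  expect_lt(max(r[c("lv_sf", "lv_af", "lv_pf")]),
            min(r[c("rv_sf", "rv_mod")]))
})

test_that("RV apical pacing reaches an RV fascicle first", {
  g <- fix_geo()
  cfg <- fix_cfg()
  net <- fix_net()
  out <- run_scenario(g$mesh, g$frame, net, cfg$simulation, "rv_apical",
                      eas = cfg$eas)
  act <- as.numeric(out$act)
  nt <- out$graph$n_tissue
  first_t <- vapply(c("lv_sf", "lv_af", "lv_pf", "rv_sf", "rv_mod"),
                    function(fn) {
    ids <- which(net$fascicle == fn)
    min(act[ids + nt])
  }, numeric(1))
  expect_true(names(which.min(first_t)) %in% c("rv_sf", "rv_mod"))
})
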