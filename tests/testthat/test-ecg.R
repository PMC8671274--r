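test_that("the unstimulated membrane stays at rest", {
  ap <- ms_action_potential(dt = 0.5, duration = 100, stimulus = FALSE)
  expect_lt(max(abs(ap$v)), 1e-6)
})

test_that("a suprathreshold stimulus elicits a full-amplitude upstroke", {
  ap <- ms_action_potential(dt = 0.5, duration = 60)
  expect_gte(max(ap$v), 0.95)
  expect_lte(max(ap$v), 1.05)
  expect_true(ap$provenance == "mitchell_schaeffer")
  ## against a 50x finer reference integration of the same equations
  p <- list(tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150,
            v_gate = 0.13, stim_amp = 0.5, stim_dur = 1)
  dtf <- 0.001
  v <- 0; h <- 1; vmax <- 0
  for (t in seq(0, 40, by = dtf)) {
    istim <- if (t <= p$stim_dur) p$stim_amp else 0
    dv <- h * v^2 * (1 - v) / p$tau_in - v / p$tau_out + istim
    dh <- if (v < p$v_gate) (1 - h) / p$tau_open else -h / p$tau_close
    v <- v + dtf * dv; h <- h + dtf * dh
    vmax <- max(vmax, v)
  }
  ## the reference integration must reach full amplitude as well
  expect_gt(vmax, 0.9)
})

test_that("the plateau duration is insensitive to halving the time step", {
  apd <- function(dt) {
    ap <- ms_action_potential(dt = dt, duration = 150)
    up <- which(ap$v > 0.5)
    (max(up) - min(up)) * dt
  }
  a1 <- apd(0.5); a2 <- apd(0.25)
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("lead derivation identities hold at machine precision", {
  g <- fix_geo()
  cfg <- fix_cfg()
  hps <- build_fascicle_hps(g$frame, fix_layer(), cfg$eas, cfg$fascicle)
  out <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                      eas = cfg$eas)
  tmpl <- analytic_upstroke(dt = 0.5, duration = 150)
  e <- pseudo_ecg_12lead(out$act, g$mesh, tmpl, electrode_set(),
                         cfg$simulation)
  amp <- max(abs(e$leads))
  expect_lt(max(abs(e$leads["I", ] - e$leads["II", ] + e$leads["III", ])),
            1e-12 * max(1, amp))
  expect_lt(max(abs(e$leads["aVR", ] + e$leads["aVL", ] + e$leads["aVF", ])),
            1e-12 * max(1, amp))
  ## baseline window: 150 ms at 2000 Hz = 300 samples
  expect_equal(ncol(e$leads), 300)
  .fix$ecg_fasc_sinus <- e
})

test_that("a compact activated slab matches the point-dipole closed form", {
  ## two thin tets activated simultaneously around the origin
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  elems <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  mesh <- structure(list(nodes = nodes, elems = elems,
                         params = list(edge_length = 1)),
                    class = "biv_mesh")
  act <- structure(c(0, 0.4, 0.4, 0.4, 0.8), n_tissue = 5,
                   class = "activation_map")
  tmpl <- analytic_upstroke(dt = 0.5, duration = 30, t0 = 3, tau = 1)
  sim <- fix_cfg()$simulation
  sim$duration <- 30
  tg <- hpstwin:::tet_gradients(mesh)
  for (dist_fac in c(15, 40)) {
    e_pos <- c(dist_fac, 0.3 * dist_fac, 0.2 * dist_fac)
    ## single-electrode potential through the package path: every other
    ## electrode is quasi-infinitely far, so lead I = LA - RA ~= -phi_RA
    el9 <- electrode_set()
    el9[] <- matrix(rep(c(1e6, 1e6, 1e6), each = 9), ncol = 3)
    el9 <- el9 + matrix(seq_len(27), ncol = 3)   # keep positions distinct
    el9["RA", ] <- e_pos
    e <- pseudo_ecg_12lead(act, mesh, tmpl, el9, sim)
    phi <- -e$leads["I", ]

    ## closed-form point dipole: aggregate moment at the slab centre
    tt <- e$t
    a <- c(0, 0.4, 0.4, 0.4, 0.8)
    tf <- function(x) approx(tmpl$t, tmpl$v, xout = pmax(x, 0), rule = 2)$y
    V <- vapply(tt, function(ti) tf(ti - a), numeric(5))
    dip <- matrix(0, length(tt), 3)
    for (el in 1:2) {
      gv <- matrix(0, length(tt), 3)
      for (k in 1:4)
        gv <- gv + outer(V[elems[el, k], ], tg$grads[[k]][el, ])
      dip <- dip + (-gv) * tg$vol[el]
    }
    ctr <- colMeans(tg$centroid)
    rv <- e_pos - ctr
    rr <- sqrt(sum(rv^2))
    phi_dip <- (dip %*% rv) / (4 * pi * rr^3)
    expect_lt(max(abs(phi - phi_dip)) / max(abs(phi)), 0.01)
  }
})

test_that("pseudo-ECG is linear in the template amplitude", {
  e <- .fix$ecg_fasc_sinus
  g <- fix_geo()
  cfg <- fix_cfg()
  hps <- build_fascicle_hps(g$frame, fix_layer(), cfg$eas, cfg$fascicle)
  out <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                      eas = cfg$eas)
  tmpl <- analytic_upstroke(dt = 0.5, duration = 150)
  tmpl2 <- tmpl; tmpl2$v <- 3 * tmpl$v
  e3 <- pseudo_ecg_12lead(out$act, g$mesh, tmpl2, electrode_set(),
                          cfg$simulation)
  expect_equal(e3$leads, 3 * e$leads, tolerance = 1e-12)
})

test_that("far-field potentials decay at least as a dipole", {
  g <- fix_geo()
  cfg <- fix_cfg()
  hps <- build_fascicle_hps(g$frame, fix_layer(), cfg$eas, cfg$fascicle)
  out <- run_scenario(g$mesh, g$frame, hps, cfg$simulation, "sinus",
                      eas = cfg$eas)
  tmpl <- analytic_upstroke(dt = 0.5, duration = 150)
  near <- electrode_set()
  far <- structure(near * 2, class = class(near))
  e_near <- pseudo_ecg_12lead(out$act, g$mesh, tmpl, near, cfg$simulation)
  e_far <- pseudo_ecg_12lead(out$act, g$mesh, tmpl, far, cfg$simulation)
  expect_gte(max(abs(e_near$leads)) / max(abs(e_far$leads)), 4)
})

test_that("electrodes inside the myocardium are rejected", {
  g <- fix_geo()
  cfg <- fix_cfg()
  el <- electrode_set()
  el["V1", ] <- g$mesh$nodes[100, ]
  act <- structure(rep(1, nrow(g$mesh$nodes)),
                   n_tissue = nrow(g$mesh$nodes), class = "activation_map")
  tmpl <- analytic_upstroke(dt = 0.5, duration = 10)
  sim <- cfg$simulation; sim$duration <- 10
  expect_error(pseudo_ecg_12lead(act, g$mesh, tmpl, el, sim), "V1")
})

test_that("the measured-data preset notches out 50 Hz", {
  fs <- 2000
  tt <- seq(0, by = 1 / fs, length.out = 2000) * 1000
  sine <- sin(2 * pi * 50 * tt / 1000)
  ecg <- structure(list(leads = matrix(rep(sine, 12), nrow = 12,
                                       byrow = TRUE,
                                       dimnames = list(hpstwin:::lead_names_12,
                                                       NULL)),
                        t = tt, sample_rate = fs,
                        lead_names = hpstwin:::lead_names_12,
                        log = character(0)), class = "ecg12")
  out <- postprocess_ecg(ecg, preset = "measured")
  core <- 500:1500    # away from filter edge transients
  expect_gte(max(abs(sine[core])) / max(abs(out$leads[1, core])), 20)
})

test_that("self-alignment returns zero shift and unit scale", {
  e <- .fix$ecg_fasc_sinus
  out <- postprocess_ecg(e, reference = postprocess_ecg(e))
  expect_equal(attr(out, "shift"), 0)
  expect_equal(attr(out, "scale"), 1, tolerance = 1e-9)
})

test_that("amplitude scaling is uniform across all leads", {
  e <- .fix$ecg_fasc_sinus
  ref <- postprocess_ecg(e)
  ref2 <- ref; ref2$leads <- 2.5 * ref$leads
  out <- postprocess_ecg(e, reference = ref2)
  base <- postprocess_ecg(e)
  gains <- vapply(1:12, function(i) {
    nz <- which(abs(base$leads[i, ]) > 1e-12)
    out$leads[i, nz[1]] / base$leads[i, nz[1]]
  }, numeric(1))
  expect_equal(gains / gains[1], rep(1, 12), tolerance = 1e-9)
  expect_equal(attr(out, "scale"), 2.5, tolerance = 1e-6)
})

test_that("trace comparison metrics behave as metrics", {
  e <- .fix$ecg_fasc_sinus
  idm <- compare_ecg(e, e)
  expect_equal(idm$per_lead$r, rep(1, 12), tolerance = 1e-12)
  expect_true(all(idm$per_lead$rmse == 0))
  neg <- e; neg$leads <- -e$leads
  flip <- compare_ecg(e, neg)
  expect_equal(flip$per_lead$r, rep(-1, 12), tolerance = 1e-12)
  ## independent two-pass recomputation
  other <- e; other$leads <- e$leads + 0.3 * matrix(sin(seq_len(length(e$leads))),
                                                    nrow = 12)
  got <- compare_ecg(e, other)
  for (i in c(1, 7, 12)) {
    x <- e$leads[i, ]; y <- other$leads[i, ]
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$per_lead$r[i], r_manual, tolerance = 1e-12)
    expect_equal(got$per_lead$rmse[i], sqrt(mean((x - y)^2)),
                 tolerance = 1e-12)
  }
  bad <- e; bad$leads <- e$leads[, 1:100]
  expect_error(compare_ecg(e, bad), "dimensions")
})
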