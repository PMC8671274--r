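#' Mitchell-Schaeffer action-potential template
#'
#' Integrates the two-variable Mitchell-Schaeffer model
#' `dv/dt = h v^2 (1 - v) / tau_in - v / tau_out + I_stim`,
#' `dh/dt = (1 - h) / tau_open` for `v < v_gate`, else `-h / tau_close`,
#' from rest with a suprathreshold stimulus at `t = 0`, and returns the
#' normalized transmembrane waveform sampled at `dt`. Stability is
#' monitored by a step-halving check: if halving the internal step changes
#' the waveform materially the requested `dt` is rejected.
#'
#' @param params named list overriding `tau_in` (0.3 ms), `tau_out` (6 ms),
#'   `tau_open` (120 ms), `tau_close` (150 ms), `v_gate` (0.13),
#'   `stim_amp` (0.5/ms), `stim_dur` (1 ms).
#' @param dt sample step (ms); @param duration total duration (ms).
#' @param stimulus logical; `FALSE` integrates the unstimulated rest state.
#' @return object of class `ap_template`: `t`, `v`, `dt`,
#'   `provenance = "mitchell_schaeffer"`.
#' @export
ms_action_potential <- function(params = list(), dt = 0.5, duration = 150,
                                stimulus = TRUE) {
  p <- modifyList(list(tau_in = 0.3, tau_out = 6, tau_open = 120,
                       tau_close = 150, v_gate = 0.13,
                       stim_amp = 0.5, stim_dur = 1), params)
  if (dt <= 0 || duration <= 0)
    stop("ms_action_potential: dt and duration must be positive")
  deriv <- function(t, y, parms) {
    v <- y[1]; h <- y[2]
    istim <- if (stimulus && t >= 0 && t <= p$stim_dur) p$stim_amp else 0
    dv <- h * v * v * (1 - v) / p$tau_in - v / p$tau_out + istim
    dh <- if (v < p$v_gate) (1 - h) / p$tau_open else -h / p$tau_close
    list(c(dv, dh))
  }
  integrate_at <- function(step) {
    times <- seq(0, duration, by = step)
    out <- deSolve::ode(y = c(v = 0, h = 1), times = times, func = deriv,
                        parms = NULL, method = "rk4")
    out[, "v"]
  }
  step <- min(dt, 0.05)
  v_c <- integrate_at(step)
  v_f <- integrate_at(step / 2)
  diff_max <- max(abs(v_c - v_f[seq(1, length(v_f), by = 2)]))
  if (!is.finite(diff_max) || diff_max > 0.05)
    stop("ms_action_potential: dt too large for a stable integration ",
         "(step-halving check failed, max deviation ", signif(diff_max, 3), ")")
  tt <- seq(0, duration, by = dt)
  v <- approx(seq(0, duration, by = step), v_c, xout = tt, rule = 2)$y
  vmax <- max(v)
  if (stimulus && vmax > 0) v <- v / vmax
  structure(list(t = tt, v = v, dt = dt, provenance = "mitchell_schaeffer"),
            class = "ap_template")
}

#' Analytic upstroke template (tanh)
#'
#' A smooth normalized depolarization upstroke
#' `v(t) = 0.5 (1 + tanh((t - t0) / tau))`, available as a fallback when a
#' biophysical template is not required.
#'
#' @param dt,duration sampling (ms); @param t0 upstroke midpoint (ms);
#' @param tau upstroke time constant (ms).
#' @return an `ap_template` with `provenance = "analytic_upstroke"`.
#' @export
analytic_upstroke <- function(dt = 0.5, duration = 150, t0 = 2, tau = 0.8) {
  tt <- seq(0, duration, by = dt)
  structure(list(t = tt, v = 0.5 * (1 + tanh((tt - t0) / tau)), dt = dt,
                 provenance = "analytic_upstroke"),
            class = "ap_template")
}

#' Default electrode positions around the synthetic heart
#'
#' Nine electrodes (RA, LA, LL, V1-V6) on a torso-scale surface around the
#' synthetic biventricular mesh, with the precordial arc over the
#' anterior chest. Coordinates in mm in the mesh frame (septum towards +x,
#' anterior +y, base +z).
#'
#' @return object of class `electrode_set`: a 9 x 3 matrix with rownames.
#' @export
electrode_set <- function() {
  m <- rbind(RA = c(90, 50, 120),
             LA = c(-90, 50, 120),
             LL = c(-60, 30, -180),
             V1 = c(35, 80, 20),
             V2 = c(15, 85, 20),
             V3 = c(-5, 85, 0),
             V4 = c(-25, 80, -15),
             V5 = c(-45, 70, -20),
             V6 = c(-65, 55, -20))
  structure(m, class = c("electrode_set", "matrix"))
}

lead_names_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                   "V1", "V2", "V3", "V4", "V5", "V6")

## electrode potentials (9 x T) -> standard 12 leads via Wilson terminal
leads_from_electrodes <- function(phi) {
  RA <- phi["RA", ]; LA <- phi["LA", ]; LL <- phi["LL", ]
  wct <- (RA + LA + LL) / 3
  leads <- rbind(
    I = LA - RA,
    II = LL - RA,
    III = LL - LA,
    aVR = RA - (LA + LL) / 2,
    aVL = LA - (RA + LL) / 2,
    aVF = LL - (RA + LA) / 2,
    phi[paste0("V", 1:6), , drop = FALSE] - rep(wct, each = 6))
  rownames(leads) <- lead_names_12
  leads
}

## per-element linear shape-function gradients and volumes
tet_gradients <- function(mesh) {
  el <- mesh$elems
  a <- mesh$nodes[el[, 1], , drop = FALSE]
  b <- mesh$nodes[el[, 2], , drop = FALSE]
  cc <- mesh$nodes[el[, 3], , drop = FALSE]
  d <- mesh$nodes[el[, 4], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  e1 <- b - a; e2 <- cc - a; e3 <- d - a
  v6 <- rowSums(e1 * cr(e2, e3))
  gb <- cr(e2, e3) / v6
  gc <- cr(e3, e1) / v6
  gd <- cr(e1, e2) / v6
  ga <- -(gb + gc + gd)
  list(grads = list(ga, gb, gc, gd), vol = abs(v6) / 6,
       centroid = (a + b + cc + d) / 4)
}

#' Compute a 12-lead pseudo-ECG from an activation map
#'
#' The transmembrane voltage is modelled as `v(x, t) = tmpl(t - act(x))`;
#' each tetrahedral element contributes a current dipole proportional to
#' `-grad v` and the potential at electrode `e` in an unbounded homogeneous
#' conductor of unit conductivity is
#' `phi_e(t) = 1/(4 pi) * sum_elements (-grad v) . grad(1 / |x_c - x_e|) V_elem`.
#' Because the element gradients are linear in nodal voltages, the
#' electrode potentials reduce to a fixed coefficient matrix applied to the
#' nodal voltage time courses. Limb, augmented and precordial leads follow
#' from the Wilson central terminal. Unreached nodes are excluded with a
#' warning.
#'
#' @param act an `activation_map` (tissue part used).
#' @param mesh the `biv_mesh` the map lives on.
#' @param tmpl an `ap_template`.
#' @param electrodes an [electrode_set()].
#' @param sim a `simulation_config` (duration, sample rate).
#' @return object of class `ecg12`: `leads` (12 x T matrix, arbitrary
#'   units), `t` (ms), `sample_rate`, `lead_names`, `log`.
#' @export
pseudo_ecg_12lead <- function(act, mesh, tmpl, electrodes = electrode_set(),
                              sim) {
  n_tissue <- attr(act, "n_tissue") %||% nrow(mesh$nodes)
  a <- as.numeric(act)[seq_len(n_tissue)]
  if (length(a) != nrow(mesh$nodes))
    stop("pseudo_ecg_12lead: activation map does not match the mesh")
  unreached <- !is.finite(a)
  if (any(unreached)) {
    warning("pseudo_ecg_12lead: ", sum(unreached),
            " unreached node(s) excluded from the source model")
    a[unreached] <- Inf   # template evaluates to rest there
  }
  ## electrode containment check (bounding box is adequate for the shells)
  bb_lo <- apply(mesh$nodes, 2, min); bb_hi <- apply(mesh$nodes, 2, max)
  inside <- apply(electrodes, 1, function(e)
    all(e >= bb_lo & e <= bb_hi) &&
      sqrt(min(colSums((t(mesh$nodes) - e)^2))) < mesh$params$edge_length)
  if (any(inside))
    stop("pseudo_ecg_12lead: electrode(s) inside the mesh: ",
         paste(rownames(electrodes)[inside], collapse = ", "))

  tg <- tet_gradients(mesh)
  n_e <- nrow(electrodes)
  C <- matrix(0, n_e, nrow(mesh$nodes))
  for (e in seq_len(n_e)) {
    dx <- tg$centroid - matrix(electrodes[e, ], nrow(tg$centroid), 3,
                               byrow = TRUE)
    r3 <- pmax(row_norms(dx), 1e-9)^3
    gir <- -dx / r3                       # grad_x (1 / |x - x_e|)
    acc <- numeric(nrow(mesh$nodes))
    for (k in 1:4) {
      val <- -rowSums(tg$grads[[k]] * gir) * tg$vol / (4 * pi)
      s <- rowsum(val, mesh$elems[, k])
      acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s
    }
    C[e, ] <- acc
  }

  dt <- 1000 / sim$sample_rate
  tt <- seq(0, by = dt, length.out = round(sim$duration / dt))
  ## nodal voltage time courses from the shifted template
  tmpl_fun <- function(x) {
    xo <- ifelse(is.finite(x), x, -1)
    y <- approx(tmpl$t, tmpl$v, xout = xo, rule = 2)$y
    y[x < 0 | !is.finite(x)] <- tmpl$v[1]
    y
  }
  V <- vapply(tt, function(ti) tmpl_fun(ti - a), numeric(length(a)))
  phi <- C %*% V
  rownames(phi) <- rownames(electrodes)
  leads <- leads_from_electrodes(phi)
  structure(list(leads = leads, t = tt, sample_rate = sim$sample_rate,
                 lead_names = lead_names_12,
                 log = paste0("pseudo_ecg: ", tmpl$provenance, ", ",
                              length(tt), " samples")),
            class = "ecg12")
}

#' @export
print.ecg12 <- function(x, ...) {
  cat("ecg12:", ncol(x$leads), "samples at", x$sample_rate, "Hz; leads",
      paste(x$lead_names, collapse = " "), "\n")
  for (l in x$log) cat("  ", l, "\n")
  invisible(x)
}

#' Filter, align and scale a simulated 12-lead ECG
#'
#' Applies a zero-phase (forward-backward) low-pass filter at `lowpass_hz`.
#' With a reference trace, one global time shift maximizing the summed
#' cross-correlation over all leads is found, followed by one amplitude
#' factor, uniform across all leads, minimizing the total squared error;
#' both are recorded in the processing log. The `"measured"` preset applies
#' the clinical measured-data chain instead: 50 Hz notch, 0.5 Hz
#' high-pass, 60 Hz low-pass.
#'
#' @param sim_ecg an `ecg12`.
#' @param reference optional `ecg12` to align/scale against (matching
#'   sample rate required; a differing reference is resampled).
#' @param lowpass_hz low-pass corner (Hz), default 60.
#' @param preset `"simulated"` (low-pass only) or `"measured"`
#'   (notch + high-pass + low-pass).
#' @return the processed `ecg12` with `shift` (samples) and `scale`
#'   entries in its log (also as attributes `shift`, `scale`).
#' @export
postprocess_ecg <- function(sim_ecg, reference = NULL, lowpass_hz = 60,
                            preset = c("simulated", "measured")) {
  preset <- match.arg(preset)
  fs <- sim_ecg$sample_rate
  x <- sim_ecg$leads
  filt_row <- function(v, flt) as.numeric(signal::filtfilt(flt, v))
  apply_filter <- function(m, flt) t(apply(m, 1, filt_row, flt = flt))

  if (preset == "measured") {
    notch <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
    hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
    lp <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- apply_filter(apply_filter(apply_filter(x, notch), hp), lp)
    log_entry <- sprintf(
      "measured preset: 50 Hz notch, 0.5 Hz high-pass, %g Hz low-pass", lowpass_hz)
  } else {
    lp <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- apply_filter(x, lp)
    log_entry <- sprintf("zero-phase low-pass at %g Hz", lowpass_hz)
  }
  out <- sim_ecg
  out$leads <- x
  out$log <- c(out$log, log_entry)
  shift <- 0L; scale <- 1

  if (!is.null(reference)) {
    ref <- reference$leads
    if (reference$sample_rate != fs) {
      ref <- t(apply(ref, 1, function(v)
        approx(seq_along(v), v, xout = seq(1, length(v),
                                           length.out = ncol(x)))$y))
    }
    if (ncol(ref) != ncol(x))
      stop("postprocess_ecg: reference length mismatch after resampling")
    maxlag <- floor(ncol(x) / 2)
    lags <- -maxlag:maxlag
    ## score(S) = agreement of the trace delayed by S samples with the
    ## reference, so the best S can be applied directly via shift_trace()
    score <- vapply(lags, function(S) {
      idx_r <- max(1, 1 + S):min(ncol(x), ncol(x) + S)
      idx_x <- idx_r - S
      sum(x[, idx_x, drop = FALSE] * ref[, idx_r, drop = FALSE])
    }, numeric(1))
    shift <- lags[which.max(score)]
    xs <- shift_trace(x, shift)
    denom <- sum(xs * xs)
    if (denom < .Machine$double.eps) {
      warning("postprocess_ecg: zero-variance trace; scaling skipped")
      scale <- 1
    } else scale <- sum(xs * ref) / denom
    out$leads <- xs * scale
    out$log <- c(out$log,
                 sprintf("aligned: shift %d samples; uniform scale %.6g",
                         shift, scale))
  }
  attr(out, "shift") <- shift
  attr(out, "scale") <- scale
  out
}

## shift columns right by L samples (pad with edge values)
shift_trace <- function(m, L) {
  n <- ncol(m)
  if (L == 0) return(m)
  if (L > 0) cbind(m[, rep(1, L), drop = FALSE],
                   m[, 1:(n - L), drop = FALSE])
  else cbind(m[, (-L + 1):n, drop = FALSE], m[, rep(n, -L), drop = FALSE])
}

#' Compare two 12-lead ECGs
#'
#' Per-lead Pearson correlation and root-mean-square error, plus their
#' means; no thresholding is applied.
#'
#' @param a,b `ecg12` objects of equal length.
#' @return list with `per_lead` (data.frame: lead, r, rmse) and `summary`
#'   (mean_r, mean_rmse).
#' @export
compare_ecg <- function(a, b) {
  if (!all(dim(a$leads) == dim(b$leads)))
    stop("compare_ecg: traces have different dimensions")
  r <- vapply(seq_len(nrow(a$leads)), function(i) {
    sa <- stats::sd(a$leads[i, ]); sb <- stats::sd(b$leads[i, ])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a$leads[i, ], b$leads[i, ])
  }, numeric(1))
  rmse <- sqrt(rowMeans((a$leads - b$leads)^2))
  per_lead <- data.frame(lead = a$lead_names, r = r, rmse = rmse,
                         stringsAsFactors = FALSE)
  list(per_lead = per_lead,
       summary = c(mean_r = mean(r, na.rm = TRUE), mean_rmse = mean(rmse)))
}
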