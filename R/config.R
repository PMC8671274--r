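#' Baseline His-Purkinje system configuration
#'
#' Returns the four parameter vectors driving HPS construction and
#' simulation with their baseline values: five fascicular root locations
#' (earliest activation sites, EAS) and sub-endocardial (SE) layer bounds;
#' fascicle disc sizing and firing times; Purkinje growth, branching and
#' His-bundle bifurcation parameters; and conduction/simulation settings.
#'
#' Baselines: roots `b_lv_sf = (0.61, 0.0, 0.73, -1)`,
#' `b_lv_pf = (0.47, 0.0, -1.36, -1)`, `b_lv_af = (0.82, 0.0, 1.94, -1)`,
#' `b_rv_sf = (0.73, 1.0, -0.04, -1)`, `b_rv_mod = (0.63, 0.0, 0.21, +1)`;
#' SE bounds `s_z_min = 0.15`, `s_z_max = 0.9`, `s_rho = 0.1`; firing times
#' `t_his = (19.86, 24.81, 26.25, 37.30, 41.94)` ms (lv_af, lv_sf, lv_pf,
#' rv_sf, rv_mod) with disc radius `delta_rad = 0.05`; Purkinje coverage
#' `delta_cov = 0.6`, repulsion factor 0.25, branching angle `psi = 20` deg,
#' branch length `mu = 2100` um with relative spread `sigma = 0.4`,
#' His bifurcations `b_h0 = (1, 0.5, 0, -1)`, `b_h1 = (0.9, 0.5, 0, -1)`,
#' `b_h_rv = (0.85, 0.2, 0.21, -1)`, `b_h_lv = (0.85, 0.8, 0.21, -1)`,
#' `b_h_rv_mid = (0.3, 0.8, -0.2, -1)`, cable resolution 500 um; myocardial
#' conduction velocity 0.70 m/s, Purkinje 3.70 m/s, PVJ anterograde delay
#' 8 ms, retrograde 3 ms, duration 150 ms, sampling 2000 Hz.
#'
#' @return list with components `eas`, `fascicle`, `purkinje`, `simulation`,
#'   of classes `eas_config`, `fascicle_config`, `purkinje_config`,
#'   `simulation_config`.
#' @export
baseline_config <- function() {
  eas <- structure(list(
    b_lv_sf = uvc_coord(0.61, 0.0, 0.73, -1),
    b_lv_af = uvc_coord(0.82, 0.0, 1.94, -1),
    b_lv_pf = uvc_coord(0.47, 0.0, -1.36, -1),
    b_rv_sf = uvc_coord(0.73, 1.0, -0.04, -1),
    b_rv_mod = uvc_coord(0.63, 0.0, 0.21, +1),
    s_z_min = 0.15,
    s_z_max = 0.9,
    s_rho = 0.1
  ), class = "eas_config")
  fascicle <- structure(list(
    delta_rad = 0.05,
    t_his = c(lv_af = 19.86, lv_sf = 24.81, lv_pf = 26.25,
              rv_sf = 37.30, rv_mod = 41.94)
  ), class = "fascicle_config")
  purkinje <- structure(list(
    delta_cov = 0.6,
    mu = 2100,          # um
    sigma = 0.4,        # relative spread of branch length
    r = 0.25,           # repulsion factor
    psi = 20,           # branching angle, degrees
    b_h0 = uvc_coord(1.00, 0.50, 0.00, -1),
    b_h1 = uvc_coord(0.90, 0.50, 0.00, -1),
    b_h_rv = uvc_coord(0.85, 0.2, 0.21, -1),
    b_h_lv = uvc_coord(0.85, 0.8, 0.21, -1),
    b_h_rv_mid = uvc_coord(0.3, 0.8, -0.2, -1),
    segment_resolution = 500,  # um
    generation_cap = 40
  ), class = "purkinje_config")
  simulation <- structure(list(
    cv_myo = 0.70,      # m/s
    cv_purk = 3.70,     # m/s
    delay_antero = 8,   # ms, PVJ network -> tissue
    delay_retro = 3,    # ms, PVJ tissue -> network
    duration = 150,     # ms
    sample_rate = 2000, # Hz
    anisotropy_ratio = 1
  ), class = "simulation_config")
  list(eas = eas, fascicle = fascicle, purkinje = purkinje,
       simulation = simulation)
}

fascicle_names <- c("lv_sf", "lv_af", "lv_pf", "rv_sf", "rv_mod")

#' Validate HPS configuration objects
#'
#' Checks every type invariant of the configuration vectors and returns the
#' violations as data (an empty character vector means all checks pass);
#' invalid values never raise errors here.
#'
#' @param configs a list as returned by [baseline_config()]; any subset of
#'   the components `eas`, `fascicle`, `purkinje`, `simulation` is checked.
#' @return character vector of violations, each naming field and rule.
#' @export
validate_config <- function(configs) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  e <- configs$eas
  if (!is.null(e)) {
    if (!(e$s_z_min < e$s_z_max))
      add("eas: s_z_min < s_z_max violated")
    for (f in c("s_z_min", "s_z_max", "s_rho"))
      if (e[[f]] < 0 || e[[f]] > 1)
        add(paste0("eas: ", f, " outside [0, 1]"))
    roots <- paste0("b_", fascicle_names)
    for (rn in roots) {
      b <- e[[rn]]
      if (is.null(b)) { add(paste0("eas: missing root ", rn)); next }
      if (b[1] < 0 || b[1] > 1 || b[2] < 0 || b[2] > 1)
        add(paste0("eas: ", rn, " z/rho outside [0, 1]"))
      if (!b[4] %in% c(-1, 1)) add(paste0("eas: ", rn, " nu not in {-1, +1}"))
      if (e$s_z_min < e$s_z_max && (b[1] < e$s_z_min || b[1] > e$s_z_max))
        add(paste0("eas: ", rn, " z outside [s_z_min, s_z_max]"))
    }
  }
  fc <- configs$fascicle
  if (!is.null(fc)) {
    if (!(fc$delta_rad > 0)) add("fascicle: delta_rad must be > 0")
    if (length(fc$t_his) != 5) add("fascicle: t_his must have 5 timings")
    if (any(fc$t_his < 0)) add("fascicle: t_his timings must be >= 0")
  }
  pk <- configs$purkinje
  if (!is.null(pk)) {
    if (pk$delta_cov < 0 || pk$delta_cov > 1)
      add("purkinje: delta_cov outside [0, 1]")
    if (!(pk$mu > 0)) add("purkinje: mu must be > 0")
    if (pk$sigma < 0) add("purkinje: sigma must be >= 0")
    if (pk$r < 0 || pk$r > 1) add("purkinje: r outside [0, 1]")
    if (!(pk$psi > 0 && pk$psi < 90))
      add("purkinje: psi outside (0, 90) degrees")
    if (!(pk$segment_resolution > 0))
      add("purkinje: segment_resolution must be > 0")
  }
  s <- configs$simulation
  if (!is.null(s)) {
    for (f in c("cv_myo", "cv_purk", "delay_antero", "delay_retro",
                "duration", "sample_rate"))
      if (!(s[[f]] > 0)) add(paste0("simulation: ", f, " must be > 0"))
    if (s$delay_antero < s$delay_retro)
      add("simulation: delay_antero >= delay_retro violated")
  }
  v
}

config_to_plain <- function(configs) {
  lapply(configs, function(part)
    lapply(unclass(part), function(x) {
      if (inherits(x, "uvc_coord")) as.numeric(x) else x
    }))
}

plain_to_config <- function(plain) {
  base <- baseline_config()
  out <- base
  for (part in names(base)) {
    if (is.null(plain[[part]])) next
    for (f in names(base[[part]])) {
      if (is.null(plain[[part]][[f]])) next
      v <- plain[[part]][[f]]
      if (inherits(base[[part]][[f]], "uvc_coord"))
        v <- uvc_coord(v[1], v[2], v[3], v[4])
      if (f == "t_his") v <- stats::setNames(as.numeric(v),
                                             names(base[[part]][[f]]))
      out[[part]][[f]] <- v
    }
  }
  out
}

#' Read / write an HPS configuration file
#'
#' Configurations are stored as YAML with the four sections `eas`,
#' `fascicle`, `purkinje`, `simulation`; UVC coordinates are 4-vectors
#' `(z, rho, phi, nu)`. Missing fields fall back to the baseline, so a file
#' only needs to list overrides. Round-trips preserve full float precision.
#'
#' @param configs configuration list (see [baseline_config()]).
#' @param path file path.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(configs, path) {
  yaml::write_yaml(config_to_plain(configs), path,
                   precision = 17, handlers = list(
                     numeric = function(x) format(x, digits = 17)))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- yaml::read_yaml(path)
  plain <- rapply(plain, function(x) {
    if (is.character(x)) as.numeric(x) else x
  }, how = "replace")
  plain_to_config(plain)
}
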