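# Model assembly and simulation protocols for the SNc dopaminergic neuron
# model: spontaneous pacemaking and the calibrated hyperpolarizing-pulse
# rebound protocol.

#' Biophysical parameter set varied in the model database
#'
#' The four parameters swept in the database: somatodendritic A-current and
#' HCN maximal conductance densities, HCN activation half-voltage (which
#' sets the A-current half-inactivation through the v50 coupling) and the
#' A-current inactivation time constant. Defaults are the central grid
#' values.
#'
#' @param g_A A-current density (pS/um^2), grid range 15-150.
#' @param g_H HCN density (pS/um^2), grid range 0.25-2.5.
#' @param v50_h_act HCN activation v50 (mV), grid range -100 to -80.
#' @param tau_h_A A-current inactivation tau (ms), grid range 15-150.
#' @export
biophys_params <- function(g_A = 82.5, g_H = 1.375, v50_h_act = -90,
                           tau_h_A = 82.5) {
  stopifnot(g_A >= 0, g_H >= 0, tau_h_A > 0)
  structure(list(g_A = g_A, g_H = g_H, v50_h_act = v50_h_act,
                 tau_h_A = tau_h_A), class = "biophys_params")
}

#' Shell calcium model
#'
#' Calcium enters a thin submembrane shell in proportion to the L-type
#' calcium current (Faraday-based scaling) and decays first-order back to
#' baseline. `buffering` is the rapid-buffer approximation: the fraction of
#' entering calcium that remains free (default 0.025, endogenous buffer
#' capacity ~40), so the SK current acts phasically after spikes rather
#' than as a tonic clamp.
#'
#' @param shell_depth Shell depth (um).
#' @param decay_tau Decay time constant (ms).
#' @param baseline Resting concentration (mM).
#' @param buffering Free fraction of calcium influx, in (0, 1].
#' @export
calcium_model <- function(shell_depth = 0.1, decay_tau = 5,
                          baseline = 1e-4, buffering = 0.025) {
  stopifnot(shell_depth > 0, decay_tau > 0, baseline >= 0,
            buffering > 0, buffering <= 1)
  structure(list(shell_depth = shell_depth, decay_tau = decay_tau,
                 baseline = baseline, buffering = buffering),
            class = "calcium_model")
}

#' Simulation configuration
#'
#' @param dt Time step (ms).
#' @param duration Run duration (ms).
#' @param v_init Initialization potential (mV).
#' @param stabilization_spikes Number of initial spikes excluded from
#'   analysis while pacemaking stabilizes.
#' @param record_sites Named recording sites (see [integrate_model()]).
#' @export
sim_config <- function(dt = 0.02, duration = 8000, v_init = -70,
                       stabilization_spikes = 4L,
                       record_sites = c("soma", "ais")) {
  stopifnot(dt > 0, duration > 0)
  structure(list(dt = dt, duration = duration, v_init = v_init,
                 stabilization_spikes = as.integer(stabilization_spikes),
                 record_sites = record_sites), class = "sim_config")
}

#' Current-clamp stimulus protocol
#'
#' @param start,duration Segment onsets and durations (ms), equal length,
#'   non-overlapping.
#' @param amplitude_pA Segment amplitudes (pA; negative = hyperpolarizing).
#' @param site Injection site name (compartment lookup, default soma).
#' @export
stim_protocol <- function(start = numeric(0), duration = numeric(0),
                          amplitude_pA = numeric(0), site = "soma") {
  stopifnot(length(start) == length(duration),
            length(start) == length(amplitude_pA))
  if (length(start) > 1) {
    o <- order(start)
    if (any(start[o][-1] < (start + duration)[o][-length(start)])) {
      stop("stimulus segments must not overlap")
    }
  }
  structure(list(segments = data.frame(start = start, duration = duration,
                                       amplitude_pA = amplitude_pA),
                 site = site), class = "stim_protocol")
}

site_index <- function(comps, site) {
  kind <- switch(site, soma = "soma", ais = "ais", axon = "axon",
                 dend = "dendrite", stop("unknown site: ", site))
  idx <- which(comps$kind == kind)
  if (!length(idx)) stop("no compartment of kind ", kind)
  idx[ceiling(length(idx) / 2)]  # midpoint-of-section convention
}

#' Assemble a simulatable model from a morphology
#'
#' Places channels by region: somatodendritic compartments (soma, dendrites
#' and the axon-start section) carry all six active conductances; the AIS
#' and distal axon carry only fast sodium and delayed rectifier, at their
#' elevated densities. The leak conductance density is the reciprocal of
#' the specific membrane resistance everywhere. The A-current and HCN
#' kinetics are derived from `biophys` through the v50 coupling.
#'
#' @param morph A `kv_morphology`.
#' @param biophys A [biophys_params()].
#' @param defaults Channel configuration from [channel_defaults()].
#' @param passive A [passive_spec()].
#' @param calcium A [calcium_model()].
#' @param policy A [discretization_policy()].
#' @return Object of class `kv_model`.
#' @export
assemble_model <- function(morph, biophys = biophys_params(),
                           defaults = channel_defaults(),
                           passive = passive_spec(),
                           calcium = calcium_model(),
                           policy = discretization_policy()) {
  comps <- discretize(morph, policy, passive)
  bad <- setdiff(unique(comps$region), c("somadendritic", "ais", "axon"))
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "))
  n <- nrow(comps)
  ch <- defaults$channels
  leak_density <- 1e4 / passive$specific_membrane_resistance  # pS/um^2
  dens <- matrix(0, n, 7,
                 dimnames = list(NULL, c("na", "kdr", "a", "h", "cal",
                                         "sk", "leak")))
  for (reg in c("somadendritic", "ais", "axon")) {
    i <- comps$region == reg
    if (!any(i)) next
    key <- c(somadendritic = "somadendritic", ais = "ais", axon = "axon")[reg]
    dens[i, "na"] <- ch$Na$gmax[[key]]
    dens[i, "kdr"] <- ch$KDR$gmax[[key]]
    if (reg == "somadendritic") {
      dens[i, "a"] <- biophys$g_A
      dens[i, "h"] <- biophys$g_H
      dens[i, "cal"] <- ch$CaL$gmax[[key]]
      dens[i, "sk"] <- ch$SK$gmax[[key]]
    }
    dens[i, "leak"] <- leak_density
  }
  gmax_uS <- dens * comps$area_um2 * 1e-6
  cap_nF <- passive$specific_capacitance * comps$area_um2 * 1e-5
  ca_vol <- ifelse(comps$region == "somadendritic",
                   comps$area_um2 * calcium$shell_depth, 0)
  model <- structure(list(
    morphology_id = attr(comps, "morphology_id"),
    comps = comps, densities = dens, gmax_uS = gmax_uS, cap_nF = cap_nF,
    ca_vol_um3 = ca_vol, passive = passive, calcium = calcium,
    defaults = defaults, biophys = NULL, kin = NULL
  ), class = "kv_model")
  update_biophys(model, biophys)
}

#' Update the swept biophysical parameters of an assembled model
#'
#' Cheap re-parameterization used by the database sweep: rescales the
#' A-current and HCN conductances and re-derives the coupled kinetics
#' without re-discretizing the morphology.
#'
#' @param model A `kv_model`.
#' @param biophys A [biophys_params()].
#' @export
update_biophys <- function(model, biophys) {
  stopifnot(inherits(model, "kv_model"), inherits(biophys, "biophys_params"))
  sd_i <- model$comps$region == "somadendritic"
  model$densities[sd_i, "a"] <- biophys$g_A
  model$densities[sd_i, "h"] <- biophys$g_H
  model$gmax_uS[, "a"] <- model$densities[, "a"] * model$comps$area_um2 * 1e-6
  model$gmax_uS[, "h"] <- model$densities[, "h"] * model$comps$area_um2 * 1e-6
  ch <- model$defaults$channels
  cpl <- model$defaults$coupling
  ia <- coupled_ia_params(
    biophys$v50_h_act, biophys$tau_h_A,
    coupling = list(v50_slope = cpl$v50_slope,
                    v50_intercept = cpl$v50_intercept),
    link = list(ia_tau_ratio = cpl$ia_tau_ratio,
                ia_v50_shift = cpl$ia_v50_shift))
  model$kin <- list(
    na_vm = ch$Na$m$v50, na_km = ch$Na$m$k,
    na_vh = ch$Na$h$v50, na_kh = ch$Na$h$k,
    kdr_vm = ch$KDR$m$v50, kdr_km = ch$KDR$m$k,
    a_vm = ia$v50_act, a_km = ch$A$m$k,
    a_vh = ia$v50_inact, a_kh = ch$A$h$k,
    a_tau_m = ia$tau_m, a_tau_h = ia$tau_h,
    h_vm = biophys$v50_h_act, h_km = ch$H$m$k,
    cal_vm = ch$CaL$m$v50, cal_km = ch$CaL$m$k,
    sk_kd = ch$SK$hill$kd,
    erev_na = ch$Na$erev, erev_kdr = ch$KDR$erev, erev_a = ch$A$erev,
    erev_h = ch$H$erev, erev_cal = ch$CaL$erev, erev_sk = ch$SK$erev,
    erev_leak = model$passive$e_leak,
    ca_tau = model$calcium$decay_tau, ca_baseline = model$calcium$baseline,
    ca_buffering = model$calcium$buffering
  )
  model$biophys <- biophys
  model
}

#' Integrate a model under a stimulus protocol
#'
#' Backward-Euler branched-cable solve with exact-exponential gate updates
#' (see the package vignette). Errors if the voltage diverges beyond
#' 200 mV in magnitude.
#'
#' @param model A `kv_model` from [assemble_model()].
#' @param stim A [stim_protocol()] or `NULL` for no injected current.
#' @param cfg A [sim_config()].
#' @param state Optional initial state from a previous run's `$state`
#'   (voltages, gates, calcium); when `NULL`, gates start at steady state
#'   for `cfg$v_init`.
#' @param record_ca Record somatic shell calcium as well.
#' @return A `kv_traceset`: `time` (ms), `v` (mV; one column per recorded
#'   site), optional `ca` (mM), the injected-current waveform descriptor,
#'   `dt`, and the final `state`.
#' @export
integrate_model <- function(model, stim = NULL, cfg = sim_config(),
                            state = NULL, record_ca = FALSE) {
  comps <- model$comps
  rec_idx <- vapply(cfg$record_sites, function(s) site_index(comps, s), 1L)
  seg <- if (is.null(stim)) {
    matrix(numeric(0), 0, 3)
  } else {
    as.matrix(cbind(stim$segments$start, stim$segments$duration,
                    stim$segments$amplitude_pA / 1000))  # pA -> nA
  }
  stim_comp <- if (is.null(stim)) 0L else site_index(comps, stim$site)
  nsteps <- round(cfg$duration / cfg$dt)
  res <- simulate_cable(
    parent = comps$parent, cap_nF = model$cap_nF,
    g_axial_uS = comps$g_axial_uS, gmax_uS = model$gmax_uS,
    kin = model$kin, ca_vol_um3 = model$ca_vol_um3,
    dt = cfg$dt, nsteps = nsteps, stim = seg, stim_comp = stim_comp,
    record = rec_idx,
    ca_record = if (record_ca) site_index(comps, "soma") else 0L,
    init_state = state, v_init = cfg$v_init)
  v <- res$v
  colnames(v) <- cfg$record_sites
  structure(list(time = seq(0, by = cfg$dt, length.out = nsteps + 1),
                 v = v,
                 ca = if (record_ca) res$ca else NULL,
                 stim = stim, dt = cfg$dt, state = res$state,
                 morphology_id = model$morphology_id,
                 biophys = model$biophys),
            class = "kv_traceset")
}

#' @export
print.kv_traceset <- function(x, ...) {
  cat("<kv_traceset>", ncol(x$v), "site(s),",
      sprintf("%.0f ms at dt = %g ms\n", max(x$time), x$dt))
  invisible(x)
}

#' Serialize a trace set to long-format CSV
#'
#' Columns: `time_ms`, `site`, `variable`, `value`.
#' @param traces A `kv_traceset`.
#' @param path Output CSV path.
#' @param thin Keep every `thin`-th sample (default 1 = all).
#' @export
write_traceset_csv <- function(traces, path, thin = 1L) {
  keep <- seq(1, length(traces$time), by = thin)
  long <- do.call(rbind, lapply(colnames(traces$v), function(s) {
    data.frame(time_ms = traces$time[keep], site = s, variable = "v_mV",
               value = traces$v[keep, s])
  }))
  if (!is.null(traces$ca)) {
    long <- rbind(long, data.frame(time_ms = traces$time[keep],
                                   site = "soma", variable = "ca_mM",
                                   value = traces$ca[keep]))
  }
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Run the spontaneous pacemaking protocol
#'
#' Simulates with no injected current; the first
#' `cfg$stabilization_spikes` spikes are flagged as excluded from analysis.
#' A run with fewer than 6 spikes is flagged non-pacemaking (not an error).
#'
#' @param model A `kv_model`.
#' @param cfg A [sim_config()].
#' @return List: `traces`, `spikes` (all somatic spike times, ms),
#'   `stabilization_marker` (index of the first analyzed spike, 0-based
#'   count of excluded spikes), `analyzed_spikes`, `mean_isi_ms`,
#'   `cv_isi_pct`, `pacemaking` flag.
#' @export
run_pacemaking <- function(model, cfg = sim_config()) {
  traces <- integrate_model(model, NULL, cfg)
  train <- detect_spikes(traces, site = "soma")
  ns <- length(train$times)
  pacemaking <- ns >= 6
  marker <- if (pacemaking) cfg$stabilization_spikes else 0L
  analyzed <- if (ns > marker) train$times[-seq_len(marker)] else numeric(0)
  st <- if (length(analyzed) >= 3) isi_stats(analyzed) else
    list(mean_isi_ms = NA_real_, cv_isi_pct = NA_real_)
  list(traces = traces, spikes = train$times,
       stabilization_marker = marker, analyzed_spikes = analyzed,
       mean_isi_ms = st$mean_isi_ms, cv_isi_pct = st$cv_isi_pct,
       pacemaking = pacemaking)
}

#' Stabilize a model and return its state
#'
#' Runs the model with no stimulus so later protocol segments start from
#' established pacemaking rather than the initialization potential.
#'
#' @param model A `kv_model`.
#' @param cfg A [sim_config()]; `duration` is the stabilization period.
#' @export
stabilize_model <- function(model, cfg = sim_config(duration = 3000)) {
  integrate_model(model, NULL, cfg)$state
}

rebound_pulse_peak <- function(model, amplitude_pA, state, cfg,
                               pulse_start = 100, pulse_dur = 1000) {
  cfg2 <- cfg
  cfg2$duration <- pulse_start + pulse_dur + 20
  tr <- integrate_model(model,
                        stim_protocol(pulse_start, pulse_dur, amplitude_pA),
                        cfg2, state = state)
  win <- tr$time >= pulse_start & tr$time <= pulse_start + pulse_dur
  min(tr$v[win, "soma"])
}

#' Calibrate the hyperpolarizing pulse amplitude
#'
#' Bisects negative 1-s pulse amplitudes until the somatic peak
#' hyperpolarization during the pulse falls within `target_peak +/-
#' tolerance`, as the rebound protocol requires. Deterministic.
#'
#' @param model A `kv_model` (must fire spontaneously).
#' @param target_peak Target peak hyperpolarization (mV, default -120).
#' @param tolerance Acceptance band (mV, default 2).
#' @param cfg A [sim_config()].
#' @param state Optional stabilized state (computed if missing).
#' @param bounds Amplitude search bounds (pA, negative).
#' @param max_iter Bisection iteration cap.
#' @return List: `amplitude_pA`, `peak_mV`, `iterations`, `state` (the
#'   stabilized state, reusable for the rebound run).
#' @export
calibrate_hyperpolarizing_amplitude <- function(model, target_peak = -120,
                                                tolerance = 2,
                                                cfg = sim_config(),
                                                state = NULL,
                                                bounds = c(-4000, -5),
                                                max_iter = 40L) {
  if (is.null(state)) {
    state <- stabilize_model(model, sim_config(dt = cfg$dt, duration = 3000,
                                               v_init = cfg$v_init))
  }
  f <- function(a) rebound_pulse_peak(model, a, state, cfg)
  hi <- bounds[2]             # small |amplitude|: peak above target
  peak_hi <- f(hi); iter <- 1L
  if (peak_hi < target_peak - tolerance) {
    stop("pulse amplitude not bracketable: even ", hi,
         " pA hyperpolarizes below target")
  }
  if (abs(peak_hi - target_peak) <= tolerance) {
    return(list(amplitude_pA = hi, peak_mV = peak_hi, iterations = iter,
                state = state))
  }
  lo <- -160; peak_lo <- f(lo); iter <- 2L
  while (peak_lo > target_peak && lo > bounds[1]) {
    lo <- max(bounds[1], 2 * lo); peak_lo <- f(lo); iter <- iter + 1L
  }
  if (peak_lo > target_peak + tolerance) {
    stop("pulse amplitude not bracketable within bounds [", bounds[1], ", ",
         bounds[2], "] pA")
  }
  if (abs(peak_lo - target_peak) <= tolerance) {
    return(list(amplitude_pA = lo, peak_mV = peak_lo, iterations = iter,
                state = state))
  }
  if (abs(peak_hi - target_peak) <= tolerance) {
    return(list(amplitude_pA = hi, peak_mV = peak_hi, iterations = iter,
                state = state))
  }
  repeat {
    mid <- (lo + hi) / 2
    peak <- f(mid); iter <- iter + 1L
    if (abs(peak - target_peak) <= tolerance) {
      return(list(amplitude_pA = mid, peak_mV = peak, iterations = iter,
                  state = state))
    }
    if (iter >= max_iter) stop("calibration did not converge")
    if (peak > target_peak) hi <- mid else lo <- mid
  }
}

#' Run the postinhibitory rebound protocol
#'
#' From a stabilized state, injects a 1-s hyperpolarizing pulse and records
#' through a post-pulse window.
#'
#' @param model A `kv_model`.
#' @param amplitude_pA Pulse amplitude (pA, negative), typically from
#'   [calibrate_hyperpolarizing_amplitude()].
#' @param cfg A [sim_config()].
#' @param state Optional stabilized state.
#' @param pulse_start,pulse_dur,post_window Timing (ms).
#' @return List: `traces`, `pulse_offset` (ms on the trace time base).
#' @export
run_rebound <- function(model, amplitude_pA, cfg = sim_config(),
                        state = NULL, pulse_start = 100, pulse_dur = 1000,
                        post_window = 3000) {
  if (is.null(state)) {
    state <- stabilize_model(model, sim_config(dt = cfg$dt, duration = 3000,
                                               v_init = cfg$v_init))
  }
  cfg2 <- cfg
  cfg2$duration <- pulse_start + pulse_dur + post_window
  traces <- integrate_model(
    model, stim_protocol(pulse_start, pulse_dur, amplitude_pA), cfg2,
    state = state)
  list(traces = traces, pulse_offset = pulse_start + pulse_dur)
}
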