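# Current-clamp and voltage-clamp feature extraction: spike detection, ISI
# statistics, rebound delay, AP waveform, sag, excitability, A-current
# isolation and fits, HCN and delayed-rectifier protocols.

as_vtrace <- function(trace, site = "soma") {
  if (inherits(trace, "kv_traceset")) {
    list(time = trace$time, v = trace$v[, site])
  } else if (is.data.frame(trace)) {
    list(time = trace[[1]], v = trace[[2]])
  } else if (is.list(trace) && !is.null(trace$time)) {
    list(time = trace$time, v = trace$v)
  } else stop("cannot interpret trace input")
}

#' Detect action potentials
#'
#' Default criterion: upward crossing of dV/dt through 10 mV/ms with a 2-ms
#' refractory period; the spike time is the AP peak time, the threshold is
#' the voltage at the criterion crossing. Deterministic; an empty train is
#' allowed.
#'
#' @param trace A `kv_traceset`, a two-column data frame (time_ms, v_mV) or
#'   a list with `time` and `v`.
#' @param site Recorded site name when `trace` is a `kv_traceset`.
#' @param dvdt_threshold Criterion (mV/ms).
#' @param refractory Minimum spacing between detections (ms).
#' @return List of class `spike_train`: `times` (AP peak times, ms),
#'   `peaks_mV`, `threshold_mV` and `threshold_times` per spike, and the
#'   criterion metadata.
#' @export
detect_spikes <- function(trace, site = "soma", dvdt_threshold = 10,
                          refractory = 2) {
  tr <- as_vtrace(trace, site)
  t <- tr$time; v <- tr$v
  n <- length(v)
  if (n < 3) {
    return(structure(list(times = numeric(0), peaks_mV = numeric(0),
                          threshold_mV = numeric(0),
                          threshold_times = numeric(0),
                          criterion = list(dvdt = dvdt_threshold,
                                           refractory = refractory)),
                     class = "spike_train"))
  }
  dvdt <- diff(v) / diff(t)
  cross <- which(dvdt[-1] >= dvdt_threshold &
                   dvdt[-length(dvdt)] < dvdt_threshold) + 1L
  times <- peaks <- thr_v <- thr_t <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (t[i] - last < refractory) next
    j <- i
    while (j < n && v[j + 1] >= v[j]) j <- j + 1
    # require an actual peak above threshold crossing (excludes slow drift)
    if (j == i || v[j] <= v[i]) next
    if (length(times) && t[j] - times[length(times)] < refractory) next
    times <- c(times, t[j]); peaks <- c(peaks, v[j])
    thr_v <- c(thr_v, v[i]); thr_t <- c(thr_t, t[i])
    last <- t[i]
  }
  structure(list(times = times, peaks_mV = peaks, threshold_mV = thr_v,
                 threshold_times = thr_t,
                 criterion = list(dvdt = dvdt_threshold,
                                  refractory = refractory)),
            class = "spike_train")
}

spike_times_of <- function(train) {
  if (inherits(train, "spike_train")) train$times else as.numeric(train)
}

#' Interspike-interval statistics
#'
#' Mean ISI and its coefficient of variation, `CV = SD/mean * 100`, using
#' the sample SD (divide by n - 1).
#'
#' @param train A `spike_train` or numeric vector of spike times (ms).
#' @param analysis_window Optional `c(start, end)` (ms) restriction.
#' @return List: `mean_isi_ms`, `cv_isi_pct`, `n_isi`, `undefined` (TRUE
#'   when fewer than 3 spikes are available).
#' @export
isi_stats <- function(train, analysis_window = NULL) {
  st <- spike_times_of(train)
  if (!is.null(analysis_window)) {
    st <- st[st >= analysis_window[1] & st <= analysis_window[2]]
  }
  if (length(st) < 3) {
    return(list(mean_isi_ms = NA_real_, cv_isi_pct = NA_real_,
                n_isi = max(0L, length(st) - 1L), undefined = TRUE))
  }
  isi <- diff(st)
  list(mean_isi_ms = mean(isi), cv_isi_pct = stats::sd(isi) / mean(isi) * 100,
       n_isi = length(isi), undefined = FALSE)
}

#' Postinhibitory rebound delay
#'
#' Time from the hyperpolarizing-pulse offset to the first AP peak after
#' offset.
#'
#' @param trace Voltage trace (see [detect_spikes()]).
#' @param pulse_offset_time Pulse offset (ms on the trace time base).
#' @param window Search window after offset (ms); no spike within it flags
#'   the result censored.
#' @param site,... Passed to [detect_spikes()].
#' @return List: `delay_ms` (NA when censored), `censored`.
#' @export
rebound_delay <- function(trace, pulse_offset_time, window = 5000,
                          site = "soma", ...) {
  train <- detect_spikes(trace, site = site, ...)
  post <- train$times[train$times >= pulse_offset_time &
                        train$times <= pulse_offset_time + window]
  if (!length(post)) {
    return(list(delay_ms = NA_real_, censored = TRUE))
  }
  list(delay_ms = post[1] - pulse_offset_time, censored = FALSE)
}

#' Action-potential waveform features
#'
#' Per-spike features averaged over complete spikes: threshold (voltage at
#' the dV/dt criterion crossing), amplitude (peak minus threshold),
#' half-width (duration at halfway between threshold and peak, linearly
#' interpolated), AHP trough (post-spike minimum before the next spike),
#' AHP latency (peak to trough), and maximal rise / decay slopes. Spikes
#' truncated at the trace edge are skipped.
#'
#' @param trace Voltage trace.
#' @param train Optional `spike_train` (recomputed when missing).
#' @param site,... Passed to [detect_spikes()] when `train` is missing.
#' @return List of averaged features plus `n_spikes` used.
#' @export
ap_features <- function(trace, train = NULL, site = "soma", ...) {
  tr <- as_vtrace(trace, site)
  if (is.null(train)) train <- detect_spikes(trace, site = site, ...)
  t <- tr$time; v <- tr$v; n <- length(v)
  dvdt <- c(diff(v) / diff(t), 0)
  res <- list(threshold_mV = c(), amplitude_mV = c(), half_width_ms = c(),
              ahp_trough_mV = c(), ahp_latency_ms = c(),
              rise_slope = c(), decay_slope = c())
  ns <- length(train$times)
  for (k in seq_len(ns)) {
    thr_i <- which.min(abs(t - train$threshold_times[k]))
    pk_i <- which.min(abs(t - train$times[k]))
    end_i <- if (k < ns) which.min(abs(t - train$threshold_times[k + 1])) else n
    thr <- train$threshold_mV[k]; pk <- v[pk_i]
    half <- (thr + pk) / 2
    up <- which(v[thr_i:pk_i] >= half)
    down <- which(v[pk_i:end_i] <= half)
    if (!length(up) || !length(down) || end_i <= pk_i + 1) next  # truncated
    iu <- thr_i + up[1] - 1L
    t_up <- if (iu > 1 && v[iu] != v[iu - 1]) {
      t[iu - 1] + (half - v[iu - 1]) / (v[iu] - v[iu - 1]) * (t[iu] - t[iu - 1])
    } else t[iu]
    id <- pk_i + down[1] - 1L
    t_dn <- if (id > 1 && v[id] != v[id - 1]) {
      t[id - 1] + (half - v[id - 1]) / (v[id] - v[id - 1]) * (t[id] - t[id - 1])
    } else t[id]
    tr_i <- pk_i + which.min(v[pk_i:end_i]) - 1L
    if (tr_i >= n) next
    res$threshold_mV <- c(res$threshold_mV, thr)
    res$amplitude_mV <- c(res$amplitude_mV, pk - thr)
    res$half_width_ms <- c(res$half_width_ms, t_dn - t_up)
    res$ahp_trough_mV <- c(res$ahp_trough_mV, v[tr_i])
    res$ahp_latency_ms <- c(res$ahp_latency_ms, t[tr_i] - t[pk_i])
    res$rise_slope <- c(res$rise_slope, max(dvdt[thr_i:pk_i]))
    res$decay_slope <- c(res$decay_slope, min(dvdt[pk_i:tr_i]))
  }
  if (!length(res$threshold_mV)) stop("no complete spike to measure")
  out <- lapply(res, mean)
  out$n_spikes <- length(res$threshold_mV)
  out
}

#' Hyperpolarization-induced sag amplitude
#'
#' Peak hyperpolarization minus the mean voltage over the last 10% of the
#' pulse (a positive number for a sagging response).
#'
#' @param trace Voltage trace.
#' @param pulse_window `c(start, end)` of the hyperpolarizing pulse (ms).
#' @param site Recorded site.
#' @return Sag amplitude (mV).
#' @export
sag_amplitude <- function(trace, pulse_window, site = "soma") {
  tr <- as_vtrace(trace, site)
  pre <- tr$v[max(1, which(tr$time >= pulse_window[1])[1] - 1)]
  win <- tr$time >= pulse_window[1] & tr$time <= pulse_window[2]
  if (!any(win)) stop("pulse window outside trace")
  peak <- min(tr$v[win])
  if (peak >= pre) stop("pulse is not hyperpolarizing")
  late <- tr$time >= pulse_window[2] - 0.1 * diff(pulse_window) &
    tr$time <= pulse_window[2]
  mean(tr$v[late]) - peak
}

#' Excitability features from graded depolarizing steps
#'
#' For each step: start frequency = 1/(first ISI), end frequency = 1/(mean
#' of the last two ISIs). Gains are least-squares slopes of start/end
#' frequency against amplitude, expressed per 100 pA. The SFA index is
#' start/end frequency at the largest step where both are defined. The
#' start frequency at (closest to) 100 pA is reported separately.
#'
#' @param spike_trains List of spike-time vectors (ms, relative to step
#'   onset) or `spike_train` objects, one per step.
#' @param amplitudes_pA Step amplitudes (pA), same length.
#' @return List: `start_frequency_100pA_Hz`, `gain_start`, `gain_end`
#'   (Hz/100 pA), `sfa_index`, per-step table, `flagged` when fewer than
#'   2 usable steps.
#' @export
excitability <- function(spike_trains, amplitudes_pA) {
  stopifnot(length(spike_trains) == length(amplitudes_pA))
  per <- lapply(spike_trains, function(tr) {
    st <- spike_times_of(tr)
    isi <- diff(st)
    start_f <- if (length(isi) >= 1) 1000 / isi[1] else NA_real_
    end_f <- if (length(isi) >= 2) {
      1000 / mean(utils::tail(isi, 2))
    } else NA_real_
    c(start = start_f, end = end_f)
  })
  tab <- data.frame(amplitude_pA = amplitudes_pA,
                    start_Hz = vapply(per, `[[`, 1, "start"),
                    end_Hz = vapply(per, `[[`, 1, "end"))
  usable <- !is.na(tab$start_Hz)
  if (sum(usable) < 2) {
    return(list(start_frequency_100pA_Hz = NA_real_, gain_start = NA_real_,
                gain_end = NA_real_, sfa_index = NA_real_, steps = tab,
                flagged = TRUE))
  }
  gain <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(y[ok] ~ tab$amplitude_pA[ok]))[2] * 100)
  }
  both <- which(!is.na(tab$start_Hz) & !is.na(tab$end_Hz))
  sfa <- if (length(both)) {
    i <- both[which.max(tab$amplitude_pA[both])]
    tab$start_Hz[i] / tab$end_Hz[i]
  } else NA_real_
  i100 <- which.min(abs(tab$amplitude_pA - 100))
  list(start_frequency_100pA_Hz = tab$start_Hz[i100],
       gain_start = gain(tab$start_Hz), gain_end = gain(tab$end_Hz),
       sfa_index = sfa, steps = tab, flagged = FALSE)
}

as_itrace <- function(trace) {
  if (is.data.frame(trace)) list(time = trace[[1]], i = trace[[2]])
  else if (is.list(trace) && !is.null(trace$time)) {
    list(time = trace$time, i = if (!is.null(trace$i)) trace$i else trace$value)
  } else stop("cannot interpret current-trace input")
}

#' Isolate the A-current by trace subtraction
#'
#' Pointwise difference between the step current recorded after a -100 mV
#' prestep (A-current available) and after a -40 mV prestep (A-current
#' fully inactivated), then the residual baseline of the subtracted trace
#' (mean over `baseline_window`, default the last 5% of the sweep) is
#' removed. Linear leak present in both sweeps cancels.
#'
#' @param trace_prestep_minus100,trace_prestep_minus40 Two-column data
#'   frames (time_ms, i_pA) on identical time bases.
#' @param baseline_window Optional `c(start, end)` (ms).
#' @return Data frame (time_ms, i_pA) of the isolated transient.
#' @export
isolate_ia <- function(trace_prestep_minus100, trace_prestep_minus40,
                       baseline_window = NULL) {
  a <- as_itrace(trace_prestep_minus100)
  b <- as_itrace(trace_prestep_minus40)
  if (length(a$time) != length(b$time) ||
      max(abs(a$time - b$time)) > 1e-9) {
    stop("mismatched time bases")
  }
  d <- a$i - b$i
  if (is.null(baseline_window)) {
    tmax <- max(a$time)
    baseline_window <- c(tmax - 0.05 * (tmax - min(a$time)), tmax)
  }
  bl <- mean(d[a$time >= baseline_window[1] & a$time <= baseline_window[2]])
  data.frame(time_ms = a$time, i_pA = d - bl)
}

#' Boltzmann fit of steady-state inactivation
#'
#' Least-squares fit of `peak = A / (1 + exp(-(v - v50)/k))` (k negative for
#' inactivation) to peak current versus prestep voltage.
#'
#' @param peak_currents Peak currents (one per prestep).
#' @param prestep_voltages Prestep voltages (mV), at least 5 spanning the
#'   transition.
#' @param slope_start Starting slope factor (mV).
#' @return List: `v50`, `slope`, `amplitude`, `fitted`, `warnings`
#'   (character vector; "saturation" when the data do not span the
#'   transition, "non-monotonic" when residuals exceed 10% of the
#'   amplitude).
#' @export
fit_boltzmann_inactivation <- function(peak_currents, prestep_voltages,
                                       slope_start = -6) {
  stopifnot(length(peak_currents) == length(prestep_voltages))
  if (length(prestep_voltages) < 5) stop("need at least 5 prestep voltages")
  warns <- character(0)
  rng <- range(peak_currents)
  amp0 <- max(abs(peak_currents))
  if (amp0 == 0 || diff(rng) < 0.1 * amp0) {
    warns <- c(warns, "saturation")
  }
  o <- order(prestep_voltages)
  v <- prestep_voltages[o]; y <- peak_currents[o]
  v50_0 <- tryCatch(stats::approx(y, v, xout = (max(y) + min(y)) / 2,
                                  ties = mean)$y,
                    error = function(e) stats::median(v))
  if (is.na(v50_0)) v50_0 <- stats::median(v)
  fit <- minpack.lm::nlsLM(
    y ~ A / (1 + exp(-(v - v50) / k)),
    start = list(A = max(y), v50 = v50_0, k = slope_start),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  resid_rms <- sqrt(mean(stats::resid(fit)^2))
  if (amp0 > 0 && resid_rms > 0.1 * amp0) {
    warns <- c(warns, "non-monotonic")
  }
  if (length(warns)) {
    warning("boltzmann fit quality: ", paste(warns, collapse = ", "))
  }
  list(v50 = unname(cf["v50"]), slope = unname(cf["k"]),
       amplitude = unname(cf["A"]), fitted = stats::fitted(fit),
       warnings = warns)
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of `I = A * exp(-t/tau) + C` to a decaying current
#' segment; `tau > 0`. A residual RMS above 2% of the fitted amplitude
#' raises a fit-quality warning (e.g. bi-exponential input).
#'
#' @param time Time (ms), from the decay start.
#' @param current Current samples (same length).
#' @return List: `tau_ms`, `amplitude`, `offset`, `rmse`, `warnings`.
#' @export
fit_monoexp_decay <- function(time, current) {
  stopifnot(length(time) == length(current), length(time) >= 4)
  if (stats::cor(time, current) >= 0) stop("segment is not decaying")
  t0 <- time - time[1]
  dt_med <- stats::median(diff(t0))
  # offset from the late plateau, time constant from the 1/e crossing;
  # a small multi-start guards against the degenerate tau -> 0 optimum
  # that pure offset fits reach from a bad start on noisy tails
  c_est <- mean(utils::tail(current, max(3L, round(0.1 * length(current)))))
  a_est <- current[1] - c_est
  below <- which(current < c_est + a_est / exp(1))
  tau0 <- if (length(below)) max(t0[below[1]], 2 * dt_med) else
    diff(range(t0)) / 3
  fit <- NULL
  for (tau_s in unique(pmax(2 * dt_med, c(tau0, tau0 / 5, tau0 * 5)))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        current ~ A * exp(-t0 / tau) + C,
        start = list(A = a_est, tau = tau_s, C = c_est),
        lower = c(A = 0, tau = 2 * dt_med, C = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) stop("mono-exponential fit failed to converge")
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  warns <- character(0)
  if (cf["A"] > 0 && rmse > 0.02 * cf["A"]) {
    warns <- "poor-monoexponential-fit"
    warning("mono-exponential fit residual exceeds 2% of amplitude")
  }
  list(tau_ms = unname(cf["tau"]), amplitude = unname(cf["A"]),
       offset = unname(cf["C"]), rmse = rmse, warnings = warns)
}

#' Charge integral of a current transient
#'
#' Trapezoidal integral of the baseline-subtracted current over a window
#' (default length 500 ms), in pA s.
#'
#' @param time Time (ms).
#' @param current Current (pA).
#' @param window `c(start, end)` (ms); must lie within the trace.
#' @param baseline Baseline current (pA) subtracted before integration.
#' @return Charge (pA s).
#' @export
integrate_charge <- function(time, current, window = NULL, baseline = 0) {
  if (is.null(window)) window <- c(min(time), min(time) + 500)
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9) {
    stop("integration window exceeds trace")
  }
  keep <- time >= window[1] & time <= window[2]
  t <- time[keep]; y <- current[keep] - baseline
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / 1000
}

#' HCN current features from a two-step protocol family
#'
#' For each hyperpolarizing step the time-dependent component is the
#' steady-state current (mean over the last 10% of the step) minus the
#' instantaneous current (sample at `t_inst` after onset). The reported
#' amplitude is that difference at the most hyperpolarized step (magnitude,
#' pA); the activation v50 comes from a Boltzmann fit of the normalized
#' chord conductance against step voltage.
#'
#' @param family List with one element per step: `step_mV`, `time_ms`,
#'   `i_pA` (time base starting at the step onset).
#' @param t_inst Instantaneous-current sample time after onset (ms).
#' @param e_rev Assumed reversal potential (mV) for the chord conductance.
#' @return List: `amplitude_pA`, `v50_act`, `slope`, per-step table.
#' @export
ih_features <- function(family, t_inst = 10, e_rev = -40) {
  if (length(family) < 4) stop("need at least 4 steps")
  tab <- do.call(rbind, lapply(family, function(st) {
    tmax <- max(st$time_ms)
    inst <- st$i_pA[which.min(abs(st$time_ms - t_inst))]
    ss <- mean(st$i_pA[st$time_ms >= 0.9 * tmax])
    data.frame(step_mV = st$step_mV, i_inst_pA = inst, i_ss_pA = ss)
  }))
  tab$i_h_pA <- tab$i_ss_pA - tab$i_inst_pA
  g <- tab$i_h_pA / (tab$step_mV - e_rev)
  gmax <- max(abs(g))
  most <- which.min(tab$step_mV)
  if (gmax == 0) {
    return(list(amplitude_pA = 0, v50_act = NA_real_, slope = NA_real_,
                steps = tab))
  }
  gn <- g / max(g)
  vstep <- tab$step_mV
  fit <- minpack.lm::nlsLM(
    gn ~ 1 / (1 + exp(-(vstep - v50) / k)),
    start = list(v50 = stats::median(vstep), k = -7),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(amplitude_pA = abs(tab$i_h_pA[most]),
       v50_act = unname(cf["v50"]), slope = unname(cf["k"]), steps = tab)
}

#' Delayed-rectifier current-voltage relation
#'
#' Per-step peak and late steady-state (mean over the last 10% of the
#' step), aligned to step voltages.
#'
#' @param family List with one element per step: `step_mV`, `time_ms`,
#'   `i_pA`.
#' @return Data frame: `step_mV`, `peak_pA`, `ss_pA`, ordered by voltage.
#' @export
ikdr_iv <- function(family) {
  tab <- do.call(rbind, lapply(family, function(st) {
    tmax <- max(st$time_ms)
    data.frame(step_mV = st$step_mV, peak_pA = max(st$i_pA),
               ss_pA = mean(st$i_pA[st$time_ms >= 0.9 * tmax]))
  }))
  tab[order(tab$step_mV), ]
}
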