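# Synthetic-data generators: per-neuron biophysics/feature populations
# with the study's correlation structure, analytic voltage-clamp trace
# families, and 2x2 count tables. Every generator attaches a truth record
# sufficient to score downstream recovery.

#' Per-genotype marginal targets for the synthetic population generator
#'
#' Location/scale targets of the measured per-neuron distributions:
#' median/IQR for the positive, skewed quantities (ISI, rebound delay,
#' A-current inactivation tau, A-current amplitude, HCN amplitude) and
#' mean/SD for the two half-(in)activation voltages.
#'
#' @param genotype `"WT"` (wild type) or `"KO"` (Kv4.3 knockout).
#' @return Named list of per-variable target lists.
#' @export
genotype_targets <- function(genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  if (genotype == "WT") {
    list(
      isi_ms = list(median = 669.5, iqr = 334.5),
      rebound_delay_ms = list(median = 256, iqr = 199),
      ia_tau_ms = list(median = 30.9, iqr = 27.15),
      ia_amplitude_nA = list(median = 2.14, iqr = 2.79),
      ih_amplitude_pA = list(median = 453, iqr = 212.5),
      v50_a_inact_mV = list(mean = -68.91, sd = 5.10),
      v50_h_act_mV = list(mean = -88.41, sd = 4.24)
    )
  } else {
    list(
      isi_ms = list(median = 304, iqr = 118),
      rebound_delay_ms = list(median = 29, iqr = 18),
      ia_tau_ms = list(median = 12.9, iqr = 6.72),
      ia_amplitude_nA = list(median = 0.93, iqr = 0.64),
      ih_amplitude_pA = list(median = 575.3, iqr = 275.8),
      v50_a_inact_mV = list(mean = -73.31, sd = 3.84),
      v50_h_act_mV = list(mean = -88.42, sd = 3.81)
    )
  }
}

# log-normal sigma such that the distribution with median exp(mu) has the
# requested IQR
lognormal_sigma_from_iqr <- function(median, iqr) {
  q <- stats::qnorm(0.75)
  f <- function(s) median * (exp(q * s) - exp(-q * s)) - iqr
  stats::uniroot(f, c(1e-6, 5))$root
}

#' Population specification for the synthetic per-neuron generator
#'
#' Location/scale targets default to the wild-type or knockout medians/IQRs
#' (positive, skewed quantities get log-normal marginals) and means/SDs
#' (the two half-(in)activation voltages, normal marginals). The latent
#' correlation couples the two v50s (default 0.658) and log I_A tau with
#' log I_H amplitude (default -0.4, the sign reported for that pair).
#' Firing features derive from the biophysics through a linear model on
#' the standardized log scale plus Gaussian noise.
#'
#' @param genotype `"WT"` or `"KO"`.
#' @param n Number of neurons.
#' @param targets Marginal targets (see [genotype_targets()]).
#' @param cor_v50 Correlation between the A-current inactivation v50 and
#'   the HCN activation v50.
#' @param cor_tau_ih Correlation between log I_A tau and log I_H amplitude.
#' @param isi_coef,rebound_coef Generative coefficients of the firing
#'   features on the standardized latent biophysics (named by latent:
#'   `tau`, `ih`, `ia`, `v50a`, `v50h`).
#' @param isi_noise_sd,rebound_noise_sd Residual SD of the latent feature
#'   scores; `NULL` (default) completes the variance to 1 so the marginal
#'   scale targets are met.
#' @param seed Integer seed.
#' @export
population_spec <- function(genotype = "WT", n = 100,
                            targets = genotype_targets(genotype),
                            cor_v50 = 0.658, cor_tau_ih = -0.4,
                            isi_coef = c(tau = 0.6, ih = -0.3),
                            rebound_coef = c(tau = 0.55, ih = -0.3,
                                             v50a = 0.2),
                            isi_noise_sd = NULL,
                            rebound_noise_sd = NULL,
                            seed = 1L) {
  structure(list(genotype = genotype, n = n, targets = targets,
                 cor_v50 = cor_v50, cor_tau_ih = cor_tau_ih,
                 isi_coef = isi_coef, rebound_coef = rebound_coef,
                 isi_noise_sd = isi_noise_sd,
                 rebound_noise_sd = rebound_noise_sd, seed = seed),
            class = "population_spec")
}

latent_correlation <- function(spec) {
  lat <- c("tau", "ih", "ia", "v50a", "v50h")
  r <- diag(5)
  dimnames(r) <- list(lat, lat)
  r["tau", "ih"] <- r["ih", "tau"] <- spec$cor_tau_ih
  r["v50a", "v50h"] <- r["v50h", "v50a"] <- spec$cor_v50
  r
}

feature_noise_sd <- function(coef, r, requested) {
  if (!is.null(requested)) return(requested)
  b <- stats::setNames(rep(0, nrow(r)), rownames(r))
  b[names(coef)] <- coef
  expl <- drop(t(b) %*% r %*% b)
  if (expl >= 1) stop("generative coefficients explain variance >= 1; ",
                      "supply an explicit noise SD")
  sqrt(1 - expl)
}

#' Sample a synthetic per-neuron population
#'
#' Gaussian-copula draw of the five biophysical variables with the
#' spec's latent correlation and log-normal / normal marginals, then the
#' two firing features (ISI, rebound delay) generated from the latent
#' standardized biophysics via the spec's linear model plus noise, and
#' mapped to their own log-normal marginal scales. Deterministic per seed.
#'
#' @param spec A [population_spec()].
#' @return Data frame (one row per neuron) with attribute `truth`: the
#'   full generating parameter set (marginals, correlation matrix, feature
#'   coefficients and noise SDs, seed).
#' @export
sample_population <- function(spec) {
  r <- latent_correlation(spec)
  ch <- tryCatch(chol(r), error = function(e) {
    stop("correlation target is not positive definite")
  })
  tg <- spec$targets
  sig <- list(
    tau = lognormal_sigma_from_iqr(tg$ia_tau_ms$median, tg$ia_tau_ms$iqr),
    ih = lognormal_sigma_from_iqr(tg$ih_amplitude_pA$median,
                                  tg$ih_amplitude_pA$iqr),
    ia = lognormal_sigma_from_iqr(tg$ia_amplitude_nA$median,
                                  tg$ia_amplitude_nA$iqr),
    isi = lognormal_sigma_from_iqr(tg$isi_ms$median, tg$isi_ms$iqr),
    rebound = lognormal_sigma_from_iqr(tg$rebound_delay_ms$median,
                                       tg$rebound_delay_ms$iqr))
  isi_sd <- feature_noise_sd(spec$isi_coef, r, spec$isi_noise_sd)
  reb_sd <- feature_noise_sd(spec$rebound_coef, r, spec$rebound_noise_sd)
  df <- with_seed(spec$seed, {
    z <- matrix(stats::rnorm(spec$n * 5), spec$n, 5) %*% ch
    colnames(z) <- rownames(r)
    lin <- function(coef, sd) {
      b <- stats::setNames(rep(0, 5), rownames(r))
      b[names(coef)] <- coef
      drop(z %*% b) + stats::rnorm(spec$n, 0, sd)
    }
    data.frame(
      neuron = seq_len(spec$n),
      genotype = spec$genotype,
      ia_tau_ms = exp(log(tg$ia_tau_ms$median) + sig$tau * z[, "tau"]),
      ih_amplitude_pA = exp(log(tg$ih_amplitude_pA$median) +
                              sig$ih * z[, "ih"]),
      ia_amplitude_nA = exp(log(tg$ia_amplitude_nA$median) +
                              sig$ia * z[, "ia"]),
      v50_a_inact_mV = tg$v50_a_inact_mV$mean +
        tg$v50_a_inact_mV$sd * z[, "v50a"],
      v50_h_act_mV = tg$v50_h_act_mV$mean +
        tg$v50_h_act_mV$sd * z[, "v50h"],
      z_isi = lin(spec$isi_coef, isi_sd),
      z_rebound = lin(spec$rebound_coef, reb_sd)
    )
  })
  df$isi_ms <- exp(log(tg$isi_ms$median) + sig$isi * df$z_isi)
  df$rebound_delay_ms <- exp(log(tg$rebound_delay_ms$median) +
                               sig$rebound * df$z_rebound)
  attr(df, "truth") <- list(
    spec = spec, correlation = r, lognormal_sigma = sig,
    isi_noise_sd = isi_sd, rebound_noise_sd = reb_sd)
  df
}

#' Voltage-clamp trace family specification
#'
#' Parameters of the analytic transient-current generator: activation and
#' inactivation time constants (`tau_m < tau_h`), peak conductance scale,
#' baseline, Gaussian noise SD, sampling step and the prestep voltages of
#' the inactivation protocol.
#'
#' @param amplitude_nA Current scale A (nA).
#' @param tau_h_ms Inactivation (decay) time constant (ms).
#' @param tau_m_ms Activation time constant (ms), default `tau_h / 50`.
#' @param baseline_pA Baseline offset (pA).
#' @param noise_sd_pA Additive Gaussian noise SD (pA).
#' @param dt_ms Sampling step (ms).
#' @param duration_ms Step duration (ms).
#' @param prestep_mV Prestep voltages (mV), at least 5.
#' @param seed Integer seed.
#' @export
vc_trace_spec <- function(amplitude_nA = 2.14, tau_h_ms = 30.9,
                          tau_m_ms = tau_h_ms / 50, baseline_pA = 0,
                          noise_sd_pA = 0, dt_ms = 0.2, duration_ms = 500,
                          prestep_mV = seq(-110, -40, by = 10),
                          seed = 1L) {
  stopifnot(tau_m_ms < tau_h_ms, dt_ms > 0, length(prestep_mV) >= 5)
  structure(as.list(environment()), class = "vc_trace_spec")
}

#' Generate an analytic A-current voltage-clamp family
#'
#' For each prestep voltage the step current is
#' `I(t) = A * h_inf(prestep) * (1 - exp(-t/tau_m)) * exp(-t/tau_h) +
#' baseline + noise`, with `h_inf` the Boltzmann inactivation curve at
#' (`v50_inact`, `slope`). Returns the traces, the peak-vs-prestep table
#' and a truth record with every generating parameter.
#'
#' @param spec A [vc_trace_spec()].
#' @param v50_inact Half-inactivation voltage (mV).
#' @param slope Inactivation slope factor (mV, negative).
#' @return List: `traces` (list per prestep: `step_mV` = prestep,
#'   `time_ms`, `i_pA`), `peaks` (data frame prestep_mV, peak_pA),
#'   `truth`.
#' @export
generate_vc_family <- function(spec, v50_inact = -68.91, slope = -6) {
  tt <- seq(0, spec$duration_ms, by = spec$dt_ms)
  hinf <- 1 / (1 + exp(-(spec$prestep_mV - v50_inact) / slope))
  shape <- (1 - exp(-tt / spec$tau_m_ms)) * exp(-tt / spec$tau_h_ms)
  traces <- with_seed(spec$seed, {
    lapply(seq_along(spec$prestep_mV), function(k) {
      i <- 1000 * spec$amplitude_nA * hinf[k] * shape + spec$baseline_pA
      if (spec$noise_sd_pA > 0) {
        i <- i + stats::rnorm(length(tt), 0, spec$noise_sd_pA)
      }
      list(step_mV = spec$prestep_mV[k], time_ms = tt, i_pA = i)
    })
  })
  peaks <- data.frame(
    prestep_mV = spec$prestep_mV,
    peak_pA = vapply(traces, function(tr) max(tr$i_pA), 1))
  list(traces = traces, peaks = peaks,
       truth = list(spec = spec, v50_inact = v50_inact, slope = slope,
                    peak_shape_max = max(shape)))
}

#' Generate a 2x2 count table by binomial sampling
#'
#' Rows are the two groups, first column the positives:
#' `[[x1, n1 - x1], [x2, n2 - x2]]` with `x_g ~ Binomial(n_g, p_g)`.
#' Defaults emulate the Kv4.2-positive cell proportions of the wild-type
#' and knockout counts.
#'
#' @param p1,p2 Group proportions in `[0, 1]`.
#' @param n1,n2 Group sizes.
#' @param seed Integer seed.
#' @return 2x2 integer matrix with attribute `truth`.
#' @export
generate_count_table <- function(p1 = 0.047, n1 = 423, p2 = 0.05, n2 = 382,
                                 seed = 1L) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 > 0, n2 > 0)
  x <- with_seed(seed, stats::rbinom(2, c(n1, n2), c(p1, p2)))
  out <- matrix(c(x[1], n1 - x[1], x[2], n2 - x[2]), 2, 2, byrow = TRUE,
                dimnames = list(c("group1", "group2"),
                                c("positive", "negative")))
  attr(out, "truth") <- list(p1 = p1, n1 = n1, p2 = p2, n2 = n2, seed = seed)
  out
}
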