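# Cable integrator correctness: analytic oracles, region rules, stability
# and protocol drivers.

test_that("passive compartment follows the RC closed form within 0.5%", {
  mod <- passive_model()
  area <- mod$comps$area_um2
  g_uS <- mod$gmax_uS[1, "leak"]
  cap_nF <- mod$cap_nF[1]
  tau <- unname(cap_nF / g_uS)         # = Rm * Cm = 75 ms
  expect_equal(tau, 75, tolerance = 1e-9)
  amp_pA <- -20
  cfg <- soma_cfg(duration = 800, v_init = -50)
  tr <- integrate_model(mod, stim_protocol(0, 800, amp_pA), cfg)
  v_inf <- -50 + (amp_pA / 1000) / g_uS
  analytic <- v_inf + (-50 - v_inf) * exp(-tr$time / tau)
  rel_err <- abs(tr$v[-1, "soma"] - analytic[-1]) / abs(v_inf + 50)
  expect_lt(max(rel_err), 0.005)
  # charge bookkeeping at steady state: injected = leak current
  v_end <- tr$v[nrow(tr$v), "soma"]
  leak_nA <- unname(g_uS * (v_end - (-50)))
  expect_equal(leak_nA, amp_pA / 1000, tolerance = 1e-4)
})

test_that("a leak-only model equilibrates at the leak reversal (-50 mV)", {
  mod <- small_model()
  mod$gmax_uS[, c("na", "kdr", "a", "h", "cal", "sk")] <- 0
  tr <- integrate_model(mod, NULL, sim_config(duration = 600, v_init = -70))
  expect_equal(unname(tr$v[nrow(tr$v), ]), rep(-50, ncol(tr$v)),
               tolerance = 1e-3)
})

test_that("channel placement obeys the region rule", {
  mod <- small_model()
  ais <- mod$comps$region == "ais"
  axn <- mod$comps$region == "axon"
  sd_ <- mod$comps$region == "somadendritic"
  expect_true(all(mod$densities[ais, c("a", "h", "cal", "sk")] == 0))
  expect_true(all(mod$densities[axn, c("a", "h", "cal", "sk")] == 0))
  expect_true(all(mod$densities[ais, "na"] == 4000))
  expect_true(all(mod$densities[ais, "kdr"] == 4000))
  expect_true(all(mod$densities[axn, "na"] == 400))
  expect_true(all(mod$densities[sd_, "na"] == 75))
  expect_true(all(mod$densities[, "leak"] == 0.1))
  # axon-start carries the full channel set
  a0 <- mod$comps$kind == "axon_start"
  expect_true(all(mod$densities[a0, "cal"] > 0))
  # g_A = 0 zeroes the A conductance everywhere
  m0 <- update_biophys(mod, biophys_params(g_A = 0))
  expect_true(all(m0$gmax_uS[, "a"] == 0))
  # total somatodendritic A conductance scales linearly with g_A
  m1 <- update_biophys(mod, biophys_params(g_A = 30))
  m2 <- update_biophys(mod, biophys_params(g_A = 90))
  expect_equal(sum(m2$gmax_uS[, "a"]), 3 * sum(m1$gmax_uS[, "a"]),
               tolerance = 1e-12)
})

test_that("default model pacemakes with AP initiation in the AIS", {
  pace <- default_pace()
  expect_true(pace$pacemaking)
  expect_equal(pace$stabilization_marker, 4L)
  expect_gt(length(pace$spikes), 6)
  expect_lt(pace$cv_isi_pct, 10)  # regular tonic firing
  sp_soma <- detect_spikes(pace$traces, "soma")
  sp_ais <- detect_spikes(pace$traces, "ais")
  k <- min(length(sp_soma$times), length(sp_ais$times))
  lead <- sp_soma$threshold_times[1:k] - sp_ais$threshold_times[1:k]
  expect_true(all(lead > 0))
})

test_that("halving dt changes the post-stabilization ISI by < 1%", {
  mod <- small_model()
  isi <- vapply(c(0.02, 0.01), function(dt) {
    run_pacemaking(mod, sim_config(dt = dt, duration = 3000))$mean_isi_ms
  }, 1)
  expect_lt(abs(isi[1] - isi[2]) / isi[2], 0.01)
})

test_that("results are independent of section ordering", {
  m <- small_morph()
  perm <- rev(seq_len(nrow(m$sections)))
  m2 <- kv4pace:::new_morphology(m$sections[perm, ], id = m$id)
  tr1 <- integrate_model(assemble_model(m), NULL,
                         sim_config(duration = 500))
  tr2 <- integrate_model(assemble_model(m2), NULL,
                         sim_config(duration = 500))
  expect_equal(tr1$v[, "soma"], tr2$v[, "soma"], tolerance = 1e-9)
})

test_that("spatial refinement leaves passive steady state within 0.1%", {
  m <- small_morph()
  v_at <- vapply(c(0.1, 0.02), function(dl) {
    mod <- assemble_model(m, policy = discretization_policy(d_lambda = dl))
    mod$gmax_uS[, c("na", "kdr", "a", "h", "cal", "sk")] <- 0
    tr <- integrate_model(mod, stim_protocol(0, 500, -100),
                          sim_config(duration = 500, v_init = -50))
    tr$v[nrow(tr$v), "soma"]
  }, 1)
  expect_lt(abs(v_at[1] - v_at[2]) / abs(v_at[2] + 50), 0.001)
})

test_that("the divergence guard names the failing step", {
  mod <- passive_model()
  expect_error(
    integrate_model(mod, stim_protocol(0, 100, 1e6),
                    soma_cfg(duration = 100)),
    "diverged.*step")
})

test_that("a silent model is flagged, not an error", {
  mod <- small_model()
  mod$gmax_uS[, c("na", "kdr", "a", "h", "cal", "sk")] <- 0
  pace <- run_pacemaking(mod, sim_config(duration = 1000))
  expect_false(pace$pacemaking)
  expect_length(pace$spikes, 0)
  expect_equal(pace$stabilization_marker, 0L)
  expect_true(is.na(pace$mean_isi_ms))
})

test_that("doubling duration leaves the post-stabilization ISI stationary", {
  mod <- small_model()
  i1 <- run_pacemaking(mod, sim_config(duration = 3000))$mean_isi_ms
  i2 <- run_pacemaking(mod, sim_config(duration = 6000))$mean_isi_ms
  expect_lt(abs(i1 - i2) / i2, 0.01)
})

test_that("pulse calibration is self-consistent and loose tolerance is fast", {
  mod <- small_model()
  st <- stabilize_model(mod, sim_config(duration = 2000))
  cal <- calibrate_hyperpolarizing_amplitude(mod, state = st)
  expect_lte(abs(cal$peak_mV - (-120)), 2)
  # re-simulation reproduces the calibrated peak
  peak <- kv4pace:::rebound_pulse_peak(mod, cal$amplitude_pA, st,
                                       sim_config())
  expect_equal(peak, cal$peak_mV, tolerance = 1e-6)
  loose <- calibrate_hyperpolarizing_amplitude(mod, tolerance = 50,
                                               state = st)
  expect_lte(loose$iterations, 2)
})

test_that("trace sets serialize to long-format CSV", {
  tr <- default_pace()$traces
  p <- tempfile(fileext = ".csv")
  write_traceset_csv(tr, p, thin = 50L)
  d <- read.csv(p)
  expect_named(d, c("time_ms", "site", "variable", "value"))
  expect_setequal(unique(d$site), c("soma", "ais"))
  expect_true(all(is.finite(d$value)))
  unlink(p)
})
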