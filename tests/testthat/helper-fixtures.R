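# Shared fixtures. Expensive simulations are memoized so several test files
# can reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# compact morphology: keeps simulation tests fast while exercising a
# branched dendritic tree plus the full axon chain
small_template <- function() {
  morph_template(n_dendrites = c(3L, 3L), max_depth = 1L,
                 dend_length = c(80, 150))
}

small_morph <- function() {
  fixture("small_morph", generate_population(1, seed = 42,
                                             small_template())[[1]])
}

small_model <- function() fixture("small_model", assemble_model(small_morph()))

# one pacemaking run of the default model, reused across tests
default_pace <- function() {
  fixture("default_pace", run_pacemaking(small_model(),
                                         sim_config(duration = 6000)))
}

# single-compartment passive membrane (all active conductances zeroed);
# record at the soma only - there is no axon to record from
passive_model <- function(soma_diam = 25) {
  sec <- data.frame(id = 1L, kind = "soma", parent = 0L,
                    length_um = soma_diam, diam_um = soma_diam,
                    x = 0, y = 0, z = 0)
  m <- kv4pace:::new_morphology(sec, id = "passive")
  mod <- assemble_model(m)
  mod$gmax_uS[, c("na", "kdr", "a", "h", "cal", "sk")] <- 0
  mod
}

soma_cfg <- function(...) sim_config(..., record_sites = "soma")

# clean synthetic voltage trace with triangular APs (dt in ms)
triangle_spike_trace <- function(rate_hz = 2, duration_ms = 3000,
                                 dt = 0.1, baseline = -60, peak = 20,
                                 rise_ms = 1, fall_ms = 2) {
  t <- seq(0, duration_ms, by = dt)
  v <- rep(baseline, length(t))
  period <- 1000 / rate_hz
  starts <- seq(period / 2, duration_ms - 10, by = period)
  for (s in starts) {
    up <- t >= s & t < s + rise_ms
    dn <- t >= s + rise_ms & t < s + rise_ms + fall_ms
    v[up] <- baseline + (peak - baseline) * (t[up] - s) / rise_ms
    v[dn] <- peak - (peak - baseline) * (t[dn] - s - rise_ms) / fall_ms
  }
  list(time = t, v = v, peak_times = starts + rise_ms)
}
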