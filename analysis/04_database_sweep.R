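#!/usr/bin/env Rscript
# Reduced model-database sweep: run the biophysical parameter grid's
# corners plus central edges over a small morphology sample, marginalize
# over morphologies, stack the (partial) grid into heatmap layouts and
# quantify parameter influence with the standardized sensitivity
# regression. The full 13,750-run database follows the same code path;
# scale up via n_morphologies and the spec subset.
#
# Writes: results/sweep_records.csv, results/sweep_combinations.csv,
#         results/stack_isi.csv, results/stack_isi.png (and rebound
#         equivalents), results/sensitivity.json

suppressPackageStartupMessages(library(kv4pace))
dir.create("results", showWarnings = FALSE)
seed <- 20260904L
n_morphologies <- 2L

tpl <- morph_template(n_dendrites = c(3L, 3L), max_depth = 1L,
                      dend_length = c(80, 150))
morphs <- generate_population(n_morphologies, seed = seed, tpl)
grid <- build_grid()
specs <- reduced_sweep_points(enumerate_models(grid, morphs))
cat("sweep:", length(unique(specs$combination)), "grid points x",
    n_morphologies, "morphologies =", nrow(specs), "records\n")

rec <- run_sweep(specs, morphs, sim_config(duration = 8000),
                 progress = TRUE)
write.csv(rec, "results/sweep_records.csv", row.names = FALSE)
avg <- average_by_combination(rec)
write.csv(avg, "results/sweep_combinations.csv", row.names = FALSE)

for (feat in c(isi = "mean_isi_ms", rebound = "rebound_delay_ms")) {
  nm <- if (feat == "mean_isi_ms") "isi" else "rebound"
  st <- dimensional_stack(avg, stack_layout(feature = feat))
  write.csv(st$matrix, sprintf("results/stack_%s.csv", nm),
            row.names = FALSE)
  grDevices::png(sprintf("results/stack_%s.png", nm), 600, 600)
  graphics::image(t(st$matrix)[, rev(seq_len(nrow(st$matrix)))],
                  main = sprintf("log10 %s (partial grid)", feat),
                  xlab = "g_A (outer) x tau (inner)",
                  ylab = "v50 (outer) x g_H (inner)", axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"))
  grDevices::dev.off()
}

pars <- c("g_A", "tau_h_A", "g_H", "v50_h_act")
sens <- lapply(c(isi = "mean_isi_ms", rebound = "rebound_delay_ms"),
               function(resp) {
  fit <- sensitivity_regression(rec, resp, pars, log_response = TRUE)
  cat("\nstandardized sensitivities for log", resp,
      sprintf("(r2 = %.2f, n = %d):\n", fit$r2, fit$n))
  print(round(fit$coefficients, 3))
  list(coefficients = as.list(fit$coefficients), r2 = fit$r2, n = fit$n)
})
jsonlite::write_json(sens, "results/sensitivity.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

write_manifest("results/04_manifest.json", "database_sweep",
               config = list(n_morphologies = n_morphologies,
                             grid = unclass(grid),
                             duration_ms = 8000),
               seeds = list(morphologies = seed),
               outputs = c("results/sweep_records.csv",
                           "results/sweep_combinations.csv",
                           "results/sensitivity.json"))
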