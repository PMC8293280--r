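# Biophysical parameter grid, simulation sweep over a morphology
# population, marginalization over morphologies and dimensional stacking.

grid_default_ranges <- function() {
  list(g_A = c(15, 150), tau_h_A = c(15, 150),
       g_H = c(0.25, 2.5), v50_h_act = c(-100, -80))
}

#' Build the biophysical parameter grid
#'
#' Five equidistributed values per parameter over a 10-fold range for the
#' conductances and the inactivation time constant and a 20-mV range for
#' the HCN activation v50, endpoints included.
#'
#' @param ranges Named list of `c(min, max)` per parameter; defaults to the
#'   model's ranges (g_A 15-150 pS/um^2, tau_h_A 15-150 ms, g_H 0.25-2.5
#'   pS/um^2, v50_h_act -100 to -80 mV).
#' @param n Values per parameter (default 5).
#' @param spacing `"linear"` (default) or `"log"`.
#' @return Named list of value vectors, class `param_grid`.
#' @export
build_grid <- function(ranges = grid_default_ranges(), n = 5,
                       spacing = c("linear", "log")) {
  if (n < 2) stop("n must be >= 2")
  spacing <- match.arg(spacing)
  vals <- lapply(ranges, function(r) {
    stopifnot(length(r) == 2, r[1] < r[2])
    # log spacing only applies to positive ranges (voltage ranges such as
    # the v50 grid stay linear under the log switch)
    if (spacing == "linear" || r[1] <= 0) seq(r[1], r[2], length.out = n)
    else exp(seq(log(r[1]), log(r[2]), length.out = n))
  })
  structure(vals, class = "param_grid")
}

#' Enumerate model specifications from a grid and a morphology population
#'
#' One row per (grid point, morphology), in deterministic order:
#' lexicographic in parameter indices (g_A, tau_h_A, g_H, v50_h_act;
#' last index fastest) and then morphology.
#'
#' @param grid A [build_grid()] result.
#' @param morphologies List of `kv_morphology` or a character vector of ids.
#' @return Data frame with morphology id, 1-based parameter indices
#'   (`i_g_A`, ...), parameter values and a `combination` label.
#' @export
enumerate_models <- function(grid, morphologies) {
  ids <- if (is.character(morphologies)) morphologies
  else vapply(morphologies, function(m) m$id, "")
  pars <- names(grid)
  idx <- expand.grid(rev(lapply(grid, seq_along)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(pars)), drop = FALSE]
  names(idx) <- paste0("i_", pars)
  specs <- idx[rep(seq_len(nrow(idx)), each = length(ids)), , drop = FALSE]
  specs$morph_id <- rep(ids, nrow(idx))
  for (p in pars) specs[[p]] <- grid[[p]][specs[[paste0("i_", p)]]]
  specs$combination <- do.call(paste, c(specs[paste0("i_", pars)], sep = "."))
  rownames(specs) <- NULL
  specs[, c("morph_id", paste0("i_", pars), pars, "combination")]
}

#' Run the simulation sweep
#'
#' For every specification: assemble the model (morphology discretized
#' once, biophysics updated per grid point), run the pacemaking protocol
#' for the post-stabilization mean ISI, calibrate the hyperpolarizing pulse
#' to the target peak and run the rebound protocol. Silent or censored runs
#' are flagged, never dropped; individual failures are recorded per row and
#' the sweep continues. Deterministic: rerunning reproduces the table.
#'
#' @param specs Data frame from [enumerate_models()] (or a subset).
#' @param morphologies Named list (or list with `$id`s) of `kv_morphology`
#'   covering every `morph_id` in `specs`.
#' @param cfg A [sim_config()] for the pacemaking run.
#' @param rebound Run the calibrated rebound protocol as well.
#' @param rebound_target,rebound_tol Calibration target/tolerance (mV).
#' @param stabilization_ms Stabilization run length before pulse protocols.
#' @param progress Print one line per record.
#' @param ... Passed to [assemble_model()] (defaults, passive, calcium,
#'   policy).
#' @return `specs` with appended columns: `mean_isi_ms`, `cv_isi_pct`,
#'   `rebound_delay_ms`, `pulse_amplitude_pA`, `pacemaking`,
#'   `rebound_censored`, `status` ("ok" or the error message).
#' @export
run_sweep <- function(specs, morphologies, cfg = sim_config(),
                      rebound = TRUE, rebound_target = -120,
                      rebound_tol = 2, stabilization_ms = 3000,
                      progress = FALSE, ...) {
  ids <- vapply(morphologies, function(m) m$id, "")
  names(morphologies) <- ids
  missing_ids <- setdiff(unique(specs$morph_id), ids)
  if (length(missing_ids)) {
    stop("specs reference unknown morphologies: ",
         paste(missing_ids, collapse = ", "))
  }
  out <- specs
  out$mean_isi_ms <- out$cv_isi_pct <- out$rebound_delay_ms <-
    out$pulse_amplitude_pA <- NA_real_
  out$pacemaking <- out$rebound_censored <- NA
  out$status <- "ok"
  assembled <- list()
  for (r in seq_len(nrow(specs))) {
    row <- specs[r, ]
    res <- tryCatch({
      mid <- row$morph_id
      if (is.null(assembled[[mid]])) {
        assembled[[mid]] <- assemble_model(morphologies[[mid]], ...)
      }
      bp <- biophys_params(g_A = row$g_A, g_H = row$g_H,
                           v50_h_act = row$v50_h_act,
                           tau_h_A = row$tau_h_A)
      model <- update_biophys(assembled[[mid]], bp)
      pace <- run_pacemaking(model, cfg)
      rec <- list(mean_isi_ms = pace$mean_isi_ms,
                  cv_isi_pct = pace$cv_isi_pct,
                  pacemaking = pace$pacemaking,
                  rebound_delay_ms = NA_real_,
                  pulse_amplitude_pA = NA_real_, rebound_censored = NA)
      if (rebound && pace$pacemaking) {
        st <- stabilize_model(model, sim_config(dt = cfg$dt,
                                                duration = stabilization_ms,
                                                v_init = cfg$v_init))
        cal <- calibrate_hyperpolarizing_amplitude(
          model, target_peak = rebound_target, tolerance = rebound_tol,
          cfg = cfg, state = st)
        rb <- run_rebound(model, cal$amplitude_pA, cfg, state = st)
        rd <- rebound_delay(rb$traces, rb$pulse_offset)
        rec$rebound_delay_ms <- rd$delay_ms
        rec$pulse_amplitude_pA <- cal$amplitude_pA
        rec$rebound_censored <- rd$censored
      }
      rec
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      out$status[r] <- res$error
    } else {
      out$mean_isi_ms[r] <- res$mean_isi_ms
      out$cv_isi_pct[r] <- res$cv_isi_pct
      out$rebound_delay_ms[r] <- res$rebound_delay_ms
      out$pulse_amplitude_pA[r] <- res$pulse_amplitude_pA
      out$pacemaking[r] <- res$pacemaking
      out$rebound_censored[r] <- res$rebound_censored
    }
    if (progress) {
      message(sprintf("[%d/%d] %s %s isi=%.0f reb=%.0f", r, nrow(specs),
                      row$morph_id, row$combination,
                      out$mean_isi_ms[r], out$rebound_delay_ms[r]))
    }
  }
  out
}

#' Average sweep records over morphologies
#'
#' One row per combination of the four biophysical parameters, with the
#' mean of each feature over contributing (non-flagged) morphologies and
#' the contributing count. Combinations with no valid run keep an NA row.
#'
#' @param records Output of [run_sweep()].
#' @return Data frame with one row per combination.
#' @export
average_by_combination <- function(records) {
  stopifnot(nrow(records) > 0)
  pars <- c("g_A", "tau_h_A", "g_H", "v50_h_act")
  key_cols <- c(paste0("i_", pars), pars, "combination")
  split_idx <- split(seq_len(nrow(records)), records$combination)
  rows <- lapply(split_idx, function(ii) {
    sub <- records[ii, ]
    ok <- sub$status == "ok" & !is.na(sub$pacemaking) & sub$pacemaking
    cbind(sub[1, key_cols, drop = FALSE],
          data.frame(
            mean_isi_ms = if (any(ok)) mean(sub$mean_isi_ms[ok]) else NA_real_,
            rebound_delay_ms = if (any(ok & !is.na(sub$rebound_delay_ms)))
              mean(sub$rebound_delay_ms[ok], na.rm = TRUE) else NA_real_,
            n_valid = sum(ok), n_total = nrow(sub)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$i_g_A, out$i_tau_h_A, out$i_g_H, out$i_v50_h_act), ]
  rownames(out) <- NULL
  out
}

#' Reduced desk-scale sweep design
#'
#' Subsets an enumerated specification table to the 16 corners of the
#' 4-parameter grid plus, for each parameter, its minimum / central /
#' maximum value with the other three parameters held at their central
#' values (25 grid points in total for a 5-value grid). The corners span
#' the grid for sensitivity regression; the central edges expose each
#' parameter's marginal trend at central other parameters.
#'
#' @param specs Data frame from [enumerate_models()] over a 5-value grid.
#' @return The subset of `specs`.
#' @export
reduced_sweep_points <- function(specs) {
  ix <- c("i_g_A", "i_tau_h_A", "i_g_H", "i_v50_h_act")
  m <- as.matrix(specs[ix])
  corner <- apply(m, 1, function(r) all(r %in% c(1, 5)))
  edge <- apply(m, 1, function(r) sum(r == 3) >= 3 && all(r %in% c(1, 3, 5)))
  specs[corner | edge, , drop = FALSE]
}

#' Dimensional-stacking layout
#'
#' @param outer_x,outer_y,inner_x,inner_y Parameter names on the coarse and
#'   fine axes (defaults: g_A / v50 outer, tau / g_H inner).
#' @param feature Feature column to stack.
#' @param transform Cell transform (default `log10`).
#' @export
stack_layout <- function(outer_x = "g_A", outer_y = "v50_h_act",
                         inner_x = "tau_h_A", inner_y = "g_H",
                         feature = "mean_isi_ms", transform = log10) {
  structure(list(outer_x = outer_x, outer_y = outer_y, inner_x = inner_x,
                 inner_y = inner_y, feature = feature,
                 transform = transform), class = "stack_layout")
}

#' Dimensionally stack a combination table into a 2-D matrix
#'
#' Embeds the 4-D grid into a 25 x 25 heatmap: column
#' `x = n_inner * (i_outer_x - 1) + i_inner_x` and row
#' `y = n_inner * (i_outer_y - 1) + i_inner_y`. The mapping is a bijection
#' between cells and combinations; missing feature values become NA cells.
#'
#' @param table Output of [average_by_combination()] (complete grid).
#' @param layout A [stack_layout()].
#' @return List: `matrix` (rows = y), `x_index`, `y_index` (data frames
#'   mapping each axis position back to its two parameter indices), and the
#'   layout.
#' @export
dimensional_stack <- function(table, layout = stack_layout()) {
  if (anyDuplicated(table$combination)) {
    stop("duplicate combination rows")
  }
  iox <- table[[paste0("i_", layout$outer_x)]]
  ioy <- table[[paste0("i_", layout$outer_y)]]
  iix <- table[[paste0("i_", layout$inner_x)]]
  iiy <- table[[paste0("i_", layout$inner_y)]]
  nx_i <- max(iix); ny_i <- max(iiy)
  x <- nx_i * (iox - 1) + iix
  y <- ny_i * (ioy - 1) + iiy
  mat <- matrix(NA_real_, max(y), max(x))
  vals <- layout$transform(table[[layout$feature]])
  mat[cbind(y, x)] <- vals
  x_index <- data.frame(x = seq_len(max(x)),
                        outer = rep(seq_len(max(iox)), each = nx_i),
                        inner = rep(seq_len(nx_i), max(iox)))
  names(x_index)[2:3] <- paste0("i_", c(layout$outer_x, layout$inner_x))
  y_index <- data.frame(y = seq_len(max(y)),
                        outer = rep(seq_len(max(ioy)), each = ny_i),
                        inner = rep(seq_len(ny_i), max(ioy)))
  names(y_index)[2:3] <- paste0("i_", c(layout$outer_y, layout$inner_y))
  list(matrix = mat, x_index = x_index, y_index = y_index, layout = layout)
}
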