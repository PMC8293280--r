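# Parameter grid, model enumeration, sweep bookkeeping, marginalization
# and dimensional stacking.

test_that("the grid holds five equidistributed values per parameter", {
  g <- build_grid()
  expect_equal(g$g_A, c(15, 48.75, 82.5, 116.25, 150))
  expect_equal(g$v50_h_act, c(-100, -95, -90, -85, -80))
  expect_equal(g$tau_h_A, c(15, 48.75, 82.5, 116.25, 150))
  expect_equal(g$g_H, seq(0.25, 2.5, length.out = 5))
  expect_equal(prod(lengths(g)), 625)
  expect_error(build_grid(n = 1), ">= 2")
  glog <- build_grid(n = 5, spacing = "log")
  expect_equal(range(glog$g_A), c(15, 150))
})

test_that("enumeration is the grid x morphology cross product in fixed order", {
  g <- build_grid()
  ids22 <- sprintf("cell%02d", 1:22)
  specs <- enumerate_models(g, ids22)
  expect_equal(nrow(specs), 13750)
  expect_equal(nrow(enumerate_models(g, "cell01")), 625)
  expect_equal(length(unique(specs$combination)), 625)
  # deterministic, reproducible order
  specs2 <- enumerate_models(g, ids22)
  expect_identical(specs, specs2)
  # lexicographic in parameter indices, morphology innermost
  expect_equal(specs$morph_id[1:22], ids22)
  expect_equal(specs$i_g_A[1], 1)
  expect_equal(specs$i_v50_h_act[1:44], rep(1:2, each = 22))
  expect_equal(specs$i_g_A[nrow(specs)], 5)
})

test_that("a tiny sweep produces deterministic flagged records", {
  g <- build_grid()
  morphs <- generate_population(1, seed = 42, small_template())
  specs <- enumerate_models(g, morphs)
  sub <- specs[specs$combination %in% c("1.1.1.5", "5.1.1.5"), ]
  expect_equal(nrow(sub), 2)
  cfg <- sim_config(duration = 4000)
  rec <- run_sweep(sub, morphs, cfg, rebound = FALSE)
  expect_equal(rec$status, c("ok", "ok"))
  expect_true(all(rec$pacemaking))
  # g_A max slows firing relative to g_A min
  expect_gt(rec$mean_isi_ms[rec$i_g_A == 5], rec$mean_isi_ms[rec$i_g_A == 1])
  rec2 <- run_sweep(sub, morphs, cfg, rebound = FALSE)
  expect_equal(rec, rec2)
  expect_error(run_sweep(sub, morphs[0], cfg), "unknown morphologies")
})

test_that("averaging over morphologies marginalizes record tables", {
  # synthetic records: 2 morphologies x 4 combinations
  g <- build_grid()
  specs <- enumerate_models(g, c("a", "b"))
  sub <- specs[specs$i_tau_h_A == 1 & specs$i_g_H == 1 &
                 specs$i_v50_h_act == 1 & specs$i_g_A <= 2, ]
  sub$mean_isi_ms <- c(100, 200, 300, 500)
  sub$cv_isi_pct <- 1
  sub$rebound_delay_ms <- c(10, 20, 30, 50)
  sub$pulse_amplitude_pA <- -300
  sub$pacemaking <- TRUE
  sub$rebound_censored <- FALSE
  sub$status <- "ok"
  avg <- average_by_combination(sub)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$mean_isi_ms, c(150, 400))
  expect_equal(avg$n_valid, c(2L, 2L))
  # single morphology: averaging is the identity
  one <- sub[sub$morph_id == "a", ]
  avg1 <- average_by_combination(one)
  expect_equal(avg1$mean_isi_ms, one$mean_isi_ms)
  # flagged rows are excluded from means but keep the row
  sub$pacemaking[2] <- FALSE
  avg2 <- average_by_combination(sub)
  expect_equal(avg2$mean_isi_ms[1], 100)
  expect_equal(avg2$n_valid[1], 1L)
})

test_that("dimensional stacking is a lossless bijection", {
  g <- build_grid()
  tab <- average_by_combination(local({
    specs <- enumerate_models(g, "a")
    specs$mean_isi_ms <- seq_len(nrow(specs)) + 100
    specs$cv_isi_pct <- 1
    specs$rebound_delay_ms <- seq_len(nrow(specs))
    specs$pulse_amplitude_pA <- -300
    specs$pacemaking <- TRUE
    specs$rebound_censored <- FALSE
    specs$status <- "ok"
    specs
  }))
  st <- dimensional_stack(tab)
  expect_equal(dim(st$matrix), c(25, 25))
  expect_equal(sum(!is.na(st$matrix)), 625)
  # corner combination (all indices 1) lands in cell (1, 1)
  corner <- tab[tab$combination == "1.1.1.1", ]
  expect_equal(st$matrix[1, 1], log10(corner$mean_isi_ms))
  # inverting the index maps recovers the table exactly
  for (r in sample(nrow(tab), 40)) {
    x <- st$x_index$x[st$x_index$i_g_A == tab$i_g_A[r] &
                        st$x_index$i_tau_h_A == tab$i_tau_h_A[r]]
    y <- st$y_index$y[st$y_index$i_v50_h_act == tab$i_v50_h_act[r] &
                        st$y_index$i_g_H == tab$i_g_H[r]]
    expect_equal(st$matrix[y, x], log10(tab$mean_isi_ms[r]))
  }
  # swapping inner and outer axes permutes the same multiset of cells
  st2 <- dimensional_stack(tab, stack_layout(outer_x = "tau_h_A",
                                             inner_x = "g_A",
                                             outer_y = "g_H",
                                             inner_y = "v50_h_act"))
  expect_equal(sort(as.vector(st2$matrix)), sort(as.vector(st$matrix)))
  # duplicated combination rows are rejected
  expect_error(dimensional_stack(rbind(tab, tab[1, ])), "duplicate")
})
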