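# Ground-truth properties of the synthetic-data generators.

test_that("noiseless trace peaks sit exactly on the cosine maxima", {
  tr <- simulate_trace(trace_sim_spec(duration_h = 60, dt_h = 0.1,
                                      period_h = 24, phase_h = 6,
                                      amplitude = 1, noise_sd = 0, seed = 1))
  # grid maxima at 6, 30, 54
  v <- tr$value
  for (tpk in c(6, 30, 54)) {
    i <- which.min(abs(tr$time_h - tpk))
    expect_equal(v[i], max(v[abs(tr$time_h - tpk) <= 12]))
  }
  expect_equal(tr$truth$peak_times_h, c(6, 30, 54))
  # peak spacing of the sampled maxima equals the period exactly (grid-limited)
  pk <- find_peaks_troughs(tr, refine_window_h = 0)
  expect_equal(diff(pk$peak_times_h), c(24, 24))
})

test_that("epoch amplitude factor scales the peak-to-trough range linearly", {
  ep <- epoch_effect(72, 192, amplitude_factor = 0.15)
  tr <- simulate_trace(trace_sim_spec(duration_h = 240, dt_h = 0.1,
                                      noise_sd = 0, epochs = list(ep), seed = 1))
  inside <- tr$time_h >= 96 & tr$time_h < 192   # clear of the entry transition
  before <- tr$time_h < 72
  expect_equal(diff(range(tr$value[inside])),
               0.15 * diff(range(tr$value[before])), tolerance = 1e-6)
})

test_that("trace period is recoverable from a noisy trace within 0.2 h", {
  sp <- trace_sim_spec(duration_h = 124, dt_h = 0.1, period_h = 24,
                       phase_h = 6, amplitude = 1, noise_sd = 0.05, seed = 1)
  tr <- simulate_trace(sp)
  pk <- find_peaks_troughs(smooth_trace(tr, 5))
  expect_lt(abs(compute_period(pk) - sp$period_h), 0.2)
})

test_that("overlapping epochs are rejected", {
  expect_error(trace_sim_spec(epochs = list(epoch_effect(10, 50),
                                            epoch_effect(40, 80))),
               "overlap")
})

test_that("same seed gives bit-identical simulations", {
  s <- trace_sim_spec(noise_sd = 0.1, seed = 7)
  expect_identical(simulate_trace(s)$value, simulate_trace(s)$value)
  ps <- proteome_sim_spec(n_proteins = 50, seed = 7)
  expect_identical(simulate_proteome(ps)$table$values,
                   simulate_proteome(ps)$table$values)
  ct <- data.frame(name = "a", proportion = 1)
  ct$markers <- list("Gfap")
  cs <- cell_sim_spec(ct, n_cells = 100, n_genes = 20, seed = 7)
  expect_identical(simulate_cells(cs)$matrix$counts,
                   simulate_cells(cs)$matrix$counts)
})

test_that("proteome generator honours rhythmic fraction and noise structure", {
  # frac_rhythmic = 0, noise 0: all features flat
  sim0 <- simulate_proteome(proteome_sim_spec(n_proteins = 30,
                                              frac_rhythmic = 0,
                                              noise_sd = 0, missing_rate = 0,
                                              seed = 2))
  expect_true(all(apply(sim0$table$values, 1, stats::var) == 0))
  # rounding rule fixes the rhythmic count exactly
  sim1 <- simulate_proteome(proteome_sim_spec(n_proteins = 100,
                                              frac_rhythmic = 0.1, seed = 2))
  expect_identical(sum(sim1$truth$is_rhythmic), 10L)
  # masked fraction within the binomial 99% interval of the nominal rate
  sim2 <- simulate_proteome(proteome_sim_spec(n_proteins = 200,
                                              missing_rate = 0.3, seed = 2))
  n_cells <- length(sim2$table$values)
  ci <- binom_ci99(0.3, n_cells)
  expect_gte(mean(is.na(sim2$table$values)), ci["lower"])
  expect_lte(mean(is.na(sim2$table$values)), ci["upper"])
})

test_that("proteome generator rejects invalid specs", {
  expect_error(proteome_sim_spec(missing_rate = 1), "missing_rate")
  expect_error(proteome_sim_spec(timepoints = c(0, 6, 6)), "increasing")
})

test_that("cell generator plants recoverable co-expression partitions", {
  ct <- data.frame(name = c("astro", "neuron"), proportion = c(0.4, 0.6))
  ct$markers <- list(c("Gfap", "Aqp4"), c("Avp", "Vip"))
  # p_both = 1 for astro: every astro cell counted "both"
  cs <- cell_sim_spec(ct, n_cells = 500, n_genes = 40,
                      coexpr_pair = list(geneA = "Anxa2", geneB = "S100a10",
                                         probs = list(astro = c(0, 0, 0, 1),
                                                      neuron = c(1, 0, 0, 0))),
                      seed = 3)
  sim <- simulate_cells(cs)
  part <- coexpression_partition(sim$matrix, "Anxa2", "S100a10")
  astro <- part$by_type[part$by_type$cell_type == "astro", ]
  expect_equal(astro$pct_both, 100)
  neuron <- part$by_type[part$by_type$cell_type == "neuron", ]
  expect_equal(neuron$n_neither, neuron$n_total)

  # p_both = 0.5: observed fraction within the binomial 99% interval
  cs2 <- cell_sim_spec(ct, n_cells = 5000, n_genes = 40,
                       coexpr_pair = list(geneA = "Anxa2", geneB = "S100a10",
                                          probs = list(astro = c(0.5, 0, 0, 0.5),
                                                       neuron = c(1, 0, 0, 0))),
                       seed = 3)
  sim2 <- simulate_cells(cs2)
  part2 <- coexpression_partition(sim2$matrix, "Anxa2", "S100a10")
  astro2 <- part2$by_type[part2$by_type$cell_type == "astro", ]
  ci <- binom_ci99(0.5, astro2$n_total)
  expect_gte(astro2$n_both / astro2$n_total, ci["lower"])
  expect_lte(astro2$n_both / astro2$n_total, ci["upper"])
})

test_that("cell counts are non-negative integers and categories partition cells", {
  ct <- data.frame(name = c("a", "b"), proportion = c(0.5, 0.5))
  ct$markers <- list("Gfap", "Avp")
  sim <- simulate_cells(cell_sim_spec(ct, n_cells = 300, n_genes = 30,
                                      coexpr_pair = list(
                                        geneA = "x1", geneB = "x2",
                                        probs = list(a = rep(0.25, 4),
                                                     b = rep(0.25, 4))),
                                      seed = 5))
  cnt <- sim$matrix$counts
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  part <- coexpression_partition(sim$matrix, "x1", "x2")
  expect_equal(sum(part$overall[c("n_neither", "n_A_only", "n_B_only", "n_both")]),
               part$overall[["n_total"]])
  expect_equal(sum(part$by_type$n_total), part$overall[["n_total"]])
})

test_that("marker-neutral genes are exchangeable across types", {
  ct <- data.frame(name = c("a", "b"), proportion = c(0.5, 0.5))
  ct$markers <- list("Gfap", "Avp")
  sim <- simulate_cells(cell_sim_spec(ct, n_cells = 4000, n_genes = 30,
                                      marker_fold = 1, baseline_mean = 5,
                                      seed = 6))
  mns <- tapply(rowMeans(sim$matrix$counts), sim$matrix$cell_type, mean)
  expect_lt(abs(diff(mns)) / mean(mns), 0.05)
})

test_that("trace and table round-trip through their file formats", {
  dir <- withr::local_tempdir()
  tr <- simulate_trace(trace_sim_spec(duration_h = 60, dt_h = 0.5,
                                      noise_sd = 0.05,
                                      epochs = list(epoch_effect(30, 40)),
                                      seed = 1))
  p <- file.path(dir, "trace.csv")
  write_trace(tr, p)
  back <- read_trace(p)
  expect_equal(back$value, tr$value, tolerance = 1e-12)
  expect_equal(back$epochs$start_h, 30)

  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 20, seed = 1))
  tp <- file.path(dir, "table.tsv")
  write_timetable(sim$table, tp)
  tab <- read_timetable(tp)
  expect_equal(tab$values, sim$table$values, tolerance = 1e-12)
  expect_equal(tab$timepoints, sim$table$timepoints)

  ctypes <- data.frame(name = "a", proportion = 1)
  ctypes$markers <- list("Gfap")
  simc <- simulate_cells(cell_sim_spec(ctypes, n_cells = 50, n_genes = 10,
                                       seed = 2))
  cd <- file.path(dir, "cells")
  write_cells(simc$matrix, cd)
  backc <- read_cells(cd)
  expect_equal(unname(backc$counts), unname(simc$matrix$counts))
  expect_equal(backc$cell_type, simc$matrix$cell_type)
})
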