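# Dual-test circadian calling: single-feature behaviour, permutation
# validity, oracle agreement, scaling and phase clustering.

test_that("constant series carry no rhythm information", {
  y <- rep(1, 15)
  expect_equal(jtk_test(y, default_tp, n_perm = 200, seed = 1)$p, 1)
  expect_equal(jtk_test(y, default_tp, n_perm = 200, seed = 1)$tau_max, 0)
  expect_equal(umbrella_test(y, default_tp, n_perm = 200, seed = 1)$p, 1)
})

test_that("a noiseless cosine is recovered at its generating lag", {
  for (peak in c(0, 6, 12, 18)) {
    y <- cosine_obs(peak)
    r <- jtk_test(y, default_tp, n_perm = 500, seed = 1)
    expect_equal(r$best_lag_h, peak)
    # tau-b equals the maximum over lags computed independently by stats::cor
    taus <- vapply(c(0, 6, 12, 18), function(l) {
      ref <- cos(2 * pi * ((default_tp %% 24) - l) / 24)
      suppressWarnings(stats::cor(y, ref, method = "kendall"))
    }, numeric(1))
    expect_equal(r$tau_max, max(taus), tolerance = 1e-12)
    u <- umbrella_test(y, default_tp, n_perm = 500, seed = 1)
    expect_equal(u$best_peak_h, peak)
    expect_lt(u$p, 0.05)
  }
})

test_that("umbrella test handles monotone and unimodal toy shapes", {
  # strictly increasing then decreasing with apex CT12, no ties: apex found,
  # and the exhaustive p equals the minimal attainable for n = 4
  u <- umbrella_test(c(1, 3, 5, 2), c(0, 6, 12, 18), exact_bound = 30, seed = 1)
  expect_equal(u$best_peak_h, 12)
  expect_true(u$exact)
  all_p <- vapply(all_perms_list(4), function(p) {
    oracle_umbrella_p(c(1, 3, 5, 2)[p], c(0, 6, 12, 18), exhaustive = TRUE)
  }, numeric(1))
  expect_equal(u$p, min(all_p))
  # monotone increasing: boundary umbrella at the last candidate
  u2 <- umbrella_test(c(1, 2, 3, 4), c(0, 6, 12, 18), exact_bound = 30, seed = 1)
  expect_equal(u2$best_peak_h, 18)
})

test_that("permutation p-values agree with brute-force oracles", {
  # moderate-noise instances spread over the p scale; a lighter version of
  # the full oracle-equivalence suite run in the acceptance tests
  set.seed(100)
  B <- 4000
  for (i in 1:4) {
    peak <- sample(c(0, 6, 12, 18), 1)
    y <- cosine_obs(peak, amp = 0.6, sd = stats::runif(1, 0.4, 1.2))
    p_impl <- jtk_test(y, default_tp, n_perm = B, seed = 200 + i)$p
    set.seed(300 + i)
    p_or <- oracle_jtk_p(y, default_tp, B = B)
    se <- sqrt(max(p_impl, p_or) * (1 - min(p_impl, p_or)) * 2 / B) + 1e-6
    expect_lt(abs(p_impl - p_or), 3 * se)
  }
  for (i in 1:4) {
    peak <- sample(c(0, 6, 12, 18), 1)
    y <- cosine_obs(peak, amp = 0.6, sd = stats::runif(1, 0.4, 1.2))
    p_impl <- umbrella_test(y, default_tp, n_perm = B, seed = 400 + i)$p
    set.seed(500 + i)
    p_or <- oracle_umbrella_p(y, default_tp, B = B)
    se <- sqrt(max(p_impl, p_or) * (1 - min(p_impl, p_or)) * 2 / B) + 1e-6
    expect_lt(abs(p_impl - p_or), 3 * se)
  }
})

test_that("jtk p-values are invariant to strictly monotone transforms", {
  set.seed(42)
  y <- cosine_obs(6, sd = 0.5)
  a <- jtk_test(y, default_tp, n_perm = 1000, seed = 5)
  b <- jtk_test(exp(2 * y + 1), default_tp, n_perm = 1000, seed = 5)
  expect_equal(a$p, b$p)
  expect_equal(a$tau_max, b$tau_max)
})

test_that("permutation p-values are valid under the null", {
  # uniformity check: under exchangeable noise, P(p <= x) <= x + MC error
  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 400,
                                             frac_rhythmic = 0,
                                             missing_rate = 0, seed = 31))
  res <- call_circadian(sim$table, n_perm = 500, seed = 32)
  for (x in c(0.01, 0.05, 0.1, 0.25)) {
    slack <- 3 * sqrt(x * (1 - x) / 400) + 1 / 500
    expect_lte(mean(res$p_jtk <= x), x + slack)
    expect_lte(mean(res$p_umbrella <= x), x + slack)
  }
})

test_that("the dual criterion is at most as permissive as either test", {
  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 150,
                                             frac_rhythmic = 0.2, seed = 33))
  res <- call_circadian(sim$table, n_perm = 400, seed = 34)
  expect_lte(mean(res$is_circadian), mean(res$p_jtk < 0.05))
  expect_lte(mean(res$is_circadian), mean(res$p_umbrella < 0.05))
  expect_identical(res$is_circadian, res$p_jtk < 0.05 & res$p_umbrella < 0.05)
})

test_that("call_circadian handles missing values and is seed-deterministic", {
  sim <- simulate_proteome(proteome_sim_spec(n_proteins = 60,
                                             frac_rhythmic = 0.25,
                                             missing_rate = 0.2, seed = 35))
  a <- call_circadian(sim$table, n_perm = 300, seed = 36)
  b <- call_circadian(sim$table, n_perm = 300, seed = 36)
  expect_identical(a, b)
  expect_true(all(a$p_jtk >= 0 & a$p_jtk <= 1))
  expect_true(all(a$p_umbrella >= 0 & a$p_umbrella <= 1))
})

test_that("per-feature rescaling maps rows to [0, 1] with the 0.5 convention", {
  expect_equal(scale_by_feature(rbind(c(2, 4, 6, 4, 2)))[1, ],
               c(0, 0.5, 1, 0.5, 0))
  expect_equal(scale_by_feature(rbind(rep(3, 5)))[1, ], rep(0.5, 5))
  set.seed(1)
  m <- matrix(rnorm(50), 10)
  sc <- scale_by_feature(m)
  expect_equal(unname(apply(sc, 1, max)), rep(1, 10))
  expect_equal(unname(apply(sc, 1, min)), rep(0, 10))
})

test_that("phase clustering separates noiseless phase groups perfectly", {
  tp <- c(0, 6, 12, 18, 24)
  profiles <- do.call(rbind, lapply(rep(c(0, 6, 12, 18), each = 10),
                                    function(p) cos(2 * pi * ((tp %% 24) - p) / 24)))
  sc <- scale_by_feature(profiles)
  cl <- phase_cluster(sc, k = 4, seed = 9, timepoints = tp)
  truth <- rep(1:4, each = 10)
  expect_equal(length(unique(cl$cluster_of)), 4)
  # pure clusters: one-to-one mapping with the generating phases, and labels
  # ordered by centroid peak CT
  expect_identical(cl$cluster_of, truth)
  cl2 <- phase_cluster(sc, k = 4, seed = 9, timepoints = tp)
  expect_identical(cl$cluster_of, cl2$cluster_of)
  expect_identical(phase_cluster(sc, k = 1, seed = 9)$cluster_of,
                   rep(1L, 40))
  expect_error(phase_cluster(sc, k = 0), "k must be")
})

test_that("phase distribution normalizes over the four phase bins", {
  res <- data.frame(is_circadian = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    peak_phase_h = c(0, 6, 12, 18, 6))
  d <- phase_distribution(res)
  expect_equal(sum(d), 1)
  expect_equal(unname(d), rep(0.25, 4))
  expect_error(phase_distribution(data.frame(is_circadian = FALSE,
                                             peak_phase_h = 0)),
               "no circadian")
})
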