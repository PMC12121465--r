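# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms and base-R
# primitives, not the package's code paths.

# Monte-Carlo permutation oracle for the max-over-lags Kendall statistic:
# permute the observations, recompute every lag's tau with stats::cor, take
# the max, and count exceedances.
oracle_jtk_p <- function(values, timepoints, lags = c(0, 6, 12, 18),
                         period = 24, B = 10000) {
  refs <- lapply(lags, function(l) cos(2 * pi * ((timepoints %% 24) - l) / period))
  max_tau <- function(y) {
    max(vapply(refs, function(r) {
      suppressWarnings(stats::cor(y, r, method = "kendall"))
    }, numeric(1)), na.rm = TRUE)
  }
  obs <- max_tau(values)
  exceed <- sum(vapply(seq_len(B), function(i) {
    max_tau(sample(values)) >= obs - 1e-9
  }, logical(1)))
  (1 + exceed) / (1 + B)
}

# Umbrella-statistic oracle: per apex, unfold the cycle at the antipode and
# sum group-pairwise Mann-Whitney counts (ties = 1/2) along the rise and
# fall, divided by the number of scored pairs (concordance fraction); p is
# the permutation tail of the max fraction over apexes. Statistics are
# computed by explicit double loops over group pairs.
oracle_umbrella_stats <- function(y, g_pos) {
  # g_pos: list per apex of group positions (one per observation)
  vapply(g_pos, function(pos) {
    groups <- sort(unique(pos))
    A <- 0; n_pairs <- 0
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      gi <- groups[i]; gj <- groups[j]
      scored <- (gi < gj && gj <= 12) ||    # rise: expect later > earlier
        (12 <= gj && gj < gi)               # fall: expect earlier > later
      if (scored) {
        xi <- y[pos == gi]; xj <- y[pos == gj]
        A <- A + sum(outer(xj, xi, ">")) + 0.5 * sum(outer(xj, xi, "=="))
        n_pairs <- n_pairs + length(xi) * length(xj)
      }
    }
    A / n_pairs
  }, numeric(1))
}

oracle_umbrella_p <- function(values, timepoints, peaks = c(0, 6, 12, 18),
                              B = 10000, exhaustive = FALSE) {
  g <- timepoints %% 24
  g_pos <- lapply(peaks, function(k) (g - (k + 12)) %% 24)
  perm_set <- if (exhaustive) {
    all_perms_list(length(values))
  } else {
    lapply(seq_len(B), function(i) sample(seq_along(values)))
  }
  obs <- max(oracle_umbrella_stats(values, g_pos))
  stat <- vapply(perm_set, function(p)
    max(oracle_umbrella_stats(values[p], g_pos)), numeric(1))
  if (exhaustive) mean(stat >= obs - 1e-9)
  else (1 + sum(stat >= obs - 1e-9)) / (1 + length(perm_set))
}

all_perms_list <- function(m) {
  if (m == 1) return(list(1L))
  sub <- all_perms_list(m - 1L)
  out <- list()
  for (p in sub) for (k in 0:(m - 1)) {
    out[[length(out) + 1L]] <- append(p, m, after = k)
  }
  out
}

# hypergeometric upper-tail by explicit pmf summation
oracle_hyper_p <- function(k, K, N, n) {
  sum(vapply(k:min(n, K), function(x) stats::dhyper(x, K, N - K, n),
             numeric(1)))
}

# two-sided binomial 99% acceptance interval for a proportion
binom_ci99 <- function(p, n) {
  c(lower = stats::qbinom(0.005, n, p) / n,
    upper = stats::qbinom(0.995, n, p) / n)
}

# small fixture: cosine proteome values for one feature
cosine_obs <- function(peak, timepoints = rep(c(0, 6, 12, 18, 24), each = 3),
                       amp = 1, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amp * cos(2 * pi * ((timepoints %% 24) - peak) / 24) +
    stats::rnorm(length(timepoints), 0, sd)
}

default_tp <- rep(c(0, 6, 12, 18, 24), each = 3)
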