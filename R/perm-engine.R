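# Shared permutation engine for the rhythm tests.
#
# Both circadian tests (JTK-style Kendall tau and the umbrella trend test)
# reduce to statistics that are linear in the pairwise sign matrix
# S[a, b] = sign(y_a - y_b) of the observations. Permuting observations
# across timepoint slots is then equivalent to conjugating the fixed
# reference matrix by the permutation, so the whole permutation null for all
# features, lags/candidate peaks and permutations is computed with one matrix
# product. The max-over-lags (or max-over-peaks) statistic is taken within
# each permutation, which makes the permutation p-value absorb the lag/peak
# multiplicity exactly.

# all m! permutations as an (m! x m) matrix; only used for tiny m
all_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  row <- 1L
  for (k in seq_len(m)) {
    ins <- cbind(sub[, seq_len(k - 1L), drop = FALSE], m,
                 sub[, k - 1L + seq_len(m - k), drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- ins
    row <- row + nrow(sub)
  }
  out
}

# permutation index matrix (B x m); exhaustive when m! <= exact_bound.
# Caller owns the RNG state.
perm_indices <- function(m, n_perm, exact_bound) {
  if (factorial(m) <= exact_bound) {
    list(perms = all_permutations(m), exact = TRUE)
  } else {
    list(perms = t(vapply(seq_len(n_perm), function(i) sample.int(m),
                          integer(m))),
         exact = FALSE)
  }
}

# conjugate a template matrix by each permutation and return the vectorized
# results as an (m^2 x B) matrix: column b is vec(Tmpl[p_b, p_b])
conjugate_template <- function(tmpl, perms) {
  m <- ncol(perms)
  tv <- as.vector(tmpl)
  ci <- rep(seq_len(m), times = m)
  cj <- rep(seq_len(m), each = m)
  pt <- t(perms)                         # m x B
  a1 <- pt[ci, , drop = FALSE]           # m^2 x B
  a2 <- pt[cj, , drop = FALSE]
  matrix(tv[(a2 - 1L) * m + a1], m * m, nrow(perms))
}

# pairwise sign matrices of all rows of Y, flattened: F x m^2
sign_rows <- function(Y) {
  m <- ncol(Y)
  ci <- rep(seq_len(m), times = m)
  cj <- rep(seq_len(m), each = m)
  sign(Y[, ci, drop = FALSE] - Y[, cj, drop = FALSE])
}

# cosine reference sign templates for the JTK-style test
jtk_templates <- function(timepoints, lags_h, period_h) {
  lapply(lags_h, function(l) {
    ref <- cos(2 * pi * ((timepoints %% 24) - l) / period_h)
    sign(outer(ref, ref, "-"))
  })
}

# Mack-Wolfe umbrella weight templates: W[a, b] = 1 when the pair is scored
# as "expect y_b > y_a" under an umbrella with the given apex. The circadian
# cycle is circular, so for each candidate apex the cycle is unfolded at the
# apex's antipode: groups are positioned by circular distance past the
# antipode, the rise runs from the antipode up to the apex and the fall from
# the apex onward (CT24 folds into the CT0 group). Pairs on opposite flanks
# are not scored.
umbrella_templates <- function(timepoints, peaks_h) {
  g <- timepoints %% 24
  m <- length(g)
  lapply(peaks_h, function(k) {
    pos <- (g - (k + 12)) %% 24        # apex sits at position 12
    W <- matrix(0, m, m)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (pos[a] < pos[b] && pos[b] <= 12) W[a, b] <- 1    # rise
      if (12 <= pos[b] && pos[b] < pos[a]) W[a, b] <- 1    # fall
    }
    W
  })
}

# Run the permutation engine.
#
# Y: F x m matrix (no NAs), timepoints: length-m CT hours,
# perms: B x m permutation indices, templates: list of m x m matrices,
# kind: "tau" (scale columns to tau-b, skip studentization) or "umbrella"
# (studentize each candidate against the permutation ensemble).
#
# Returns list(stat_obs = F x L matrix, max_obs = F, p = F,
#              best = F index of argmax template).
perm_engine <- function(Y, perms, templates, kind = c("tau", "umbrella"),
                        exact = FALSE) {
  kind <- match.arg(kind)
  m <- ncol(Y)
  B <- nrow(perms)
  L <- length(templates)
  S <- sign_rows(Y)                                   # F x m^2
  n_pairs_y <- rowSums(abs(S)) / 2                    # untied pairs per row

  if (kind == "tau") {
    cols <- lapply(templates, function(R) {
      0.5 * as.vector(R) / sqrt(sum(abs(R)) / 2)
    })
  } else {
    # mean-concordance scaling of the Mack-Wolfe statistic:
    # A_k / sum(W_k) = 0.5 - 0.5 <W_k, S> / sum(W_k), so the column
    # -vec(W_k)/sum(W_k) gives a statistic affinely equivalent to the
    # concordance fraction, with null expectation 0 for every apex
    cols <- lapply(templates, function(W) -as.vector(W) / sum(W))
  }
  Cmat <- do.call(cbind, cols)                        # m^2 x L
  obs <- S %*% Cmat                                   # F x L

  Pbig <- do.call(cbind, lapply(seq_len(L), function(l) {
    block <- conjugate_template(templates[[l]], perms)
    if (kind == "tau")
      block <- 0.5 * block / sqrt(sum(abs(templates[[l]])) / 2)
    else block <- -block / sum(templates[[l]])
    block
  }))                                                 # m^2 x (L*B)
  perm_stats <- S %*% Pbig                            # F x (L*B)

  max_obs <- apply(obs, 1, max)
  best <- apply(obs, 1, which.max)
  # per-permutation max over templates (pmax over the L blocks)
  max_perm <- perm_stats[, 1:B, drop = FALSE]
  if (L > 1) for (l in 2:L)
    max_perm <- pmax(max_perm, perm_stats[, ((l - 1) * B + 1):(l * B),
                                          drop = FALSE])
  eps <- 1e-9
  exceed <- rowSums(max_perm >= max_obs - eps)
  p <- if (exact) exceed / B else (1 + exceed) / (1 + B)

  # features with no ordering information at all
  degenerate <- n_pairs_y == 0
  p[degenerate] <- 1
  list(stat_obs = obs, max_obs = max_obs, p = pmin(p, 1), best = best,
       n_pairs_y = n_pairs_y)
}
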