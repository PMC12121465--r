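# Dual-algorithm circadian calling on one-cycle, replicated time courses.
#
# A feature is called circadian only if BOTH a JTK-style Kendall-tau test and
# an umbrella (Mack-Wolfe) trend test reject at the chosen alpha — the
# conservative dual criterion appropriate for low-frequency sampling over a
# single cycle with an independently repeated CT24/0 timepoint. No
# across-feature multiplicity correction is applied.

normalize_obs <- function(values, timepoints) {
  if (is.list(values) && missing(timepoints)) {
    timepoints <- rep(as.numeric(names(values)), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  keep <- !is.na(values)
  values <- values[keep]
  timepoints <- timepoints[keep]
  stop_if_not(length(values) >= 2 && length(unique(timepoints)) >= 2,
              "need >= 2 distinct timepoints with >= 1 value each")
  list(values = as.numeric(values), timepoints = as.numeric(timepoints))
}

#' JTK-style Kendall-tau rhythmicity test
#'
#' For each candidate lag, computes Kendall's tau-b between the observations
#' and a cosine reference evaluated at each observation's timepoint (CT
#' folded mod 24, so CT24 replicates the CT0 phase). The statistic is the
#' maximum tau over lags; its p-value is the permutation tail probability of
#' the max-over-lags statistic with observations permuted across timepoint
#' slots — exhaustive when the number of arrangements is within
#' `exact_bound`, Monte-Carlo otherwise.
#'
#' @param values numeric vector of observations (or a list of vectors named
#'   by timepoint); `NA`s dropped.
#' @param timepoints CT hours, one per observation.
#' @param period_h reference period (hours).
#' @param lags_h candidate peak lags (CT hours).
#' @param n_perm Monte-Carlo permutation count.
#' @param exact_bound use exhaustive enumeration when `m! <= exact_bound`.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list: `tau_max`, `best_lag_h`, `p`, `exact`.
#' @export
jtk_test <- function(values, timepoints, period_h = 24,
                     lags_h = c(0, 6, 12, 18), n_perm = 10000,
                     exact_bound = 10000, seed = 1L) {
  obs <- normalize_obs(values, timepoints)
  set.seed(check_seed(seed))
  pi <- perm_indices(length(obs$values), n_perm, exact_bound)
  tmpl <- jtk_templates(obs$timepoints, lags_h, period_h)
  Y <- matrix(obs$values, nrow = 1)
  res <- perm_engine(Y, pi$perms, tmpl, kind = "tau", exact = pi$exact)
  tau <- if (res$n_pairs_y[1] > 0) res$max_obs[1] / sqrt(res$n_pairs_y[1]) else 0
  list(tau_max = tau, best_lag_h = lags_h[res$best[1]], p = res$p[1],
       exact = pi$exact)
}

#' Umbrella (Mack-Wolfe) rhythmicity test
#'
#' For each candidate peak, sums Mann-Whitney counts along the rise of the
#' umbrella up to the peak and along the fall after it (timepoints ordered by
#' CT with CT24 folded into the CT0 group; ties count one half). Because the
#' circadian cycle is circular, each candidate apex unfolds the cycle at its
#' antipode. Per-apex statistics are scaled to concordance fractions (every
#' apex has null expectation one half under permutation) and the p-value is
#' the permutation tail of the max over candidates, using the same
#' permutation engine and seed protocol as [jtk_test()].
#'
#' @inheritParams jtk_test
#' @param candidate_peaks_h candidate apex positions (CT hours).
#' @return list: `p`, `best_peak_h`, `exact`.
#' @export
umbrella_test <- function(values, timepoints, candidate_peaks_h = c(0, 6, 12, 18),
                          n_perm = 10000, exact_bound = 10000, seed = 1L) {
  obs <- normalize_obs(values, timepoints)
  set.seed(check_seed(seed))
  pi <- perm_indices(length(obs$values), n_perm, exact_bound)
  tmpl <- umbrella_templates(obs$timepoints, candidate_peaks_h)
  Y <- matrix(obs$values, nrow = 1)
  res <- perm_engine(Y, pi$perms, tmpl, kind = "umbrella", exact = pi$exact)
  list(p = res$p[1], best_peak_h = candidate_peaks_h[res$best[1]],
       exact = pi$exact)
}

#' Call circadian features with the dual test criterion
#'
#' Runs [jtk_test()] and [umbrella_test()] on every feature of an
#' [omics_timetable()]; a feature is circadian iff both p-values are below
#' `alpha`. Features are grouped by missingness pattern so each group shares
#' one permutation ensemble (drawn from a single seeded RNG stream), and the
#' two tests share the permutations within a group.
#'
#' @param table an [omics_timetable()].
#' @param alpha per-test significance threshold (raw p, no multiplicity
#'   correction across features).
#' @param period_h,lags_h,candidate_peaks_h,n_perm,exact_bound,seed as in the
#'   single-feature tests.
#' @return data frame with one row per feature: `feature_id`, `p_jtk`,
#'   `p_umbrella`, `tau_max`, `best_lag_h`, `peak_phase_h`, `is_circadian`.
#' @export
call_circadian <- function(table, alpha = 0.05, period_h = 24,
                           lags_h = c(0, 6, 12, 18),
                           candidate_peaks_h = c(0, 6, 12, 18),
                           n_perm = 10000, exact_bound = 10000, seed = 1L) {
  stop_if_not(inherits(table, "omics_timetable"), "table must be an omics_timetable")
  stop_if_not(nrow(table$values) > 0, "table is empty")
  V <- table$values
  n_feat <- nrow(V)
  pattern <- apply(!is.na(V), 1, function(z) paste(as.integer(z), collapse = ""))
  out <- data.frame(feature_id = table$feature_ids,
                    p_jtk = NA_real_, p_umbrella = NA_real_,
                    tau_max = NA_real_, best_lag_h = NA_real_,
                    peak_phase_h = NA_real_, is_circadian = NA)
  set.seed(check_seed(seed))
  for (pat in sort(unique(pattern))) {
    rows <- which(pattern == pat)
    keep_cols <- which(strsplit(pat, "")[[1]] == "1")
    if (length(keep_cols) < 2 ||
        length(unique(table$timepoints[keep_cols])) < 2) {
      out$p_jtk[rows] <- 1; out$p_umbrella[rows] <- 1
      out$tau_max[rows] <- 0; out$is_circadian[rows] <- FALSE
      next
    }
    tp <- table$timepoints[keep_cols]
    Y <- V[rows, keep_cols, drop = FALSE]
    m <- length(keep_cols)
    pi <- perm_indices(m, n_perm, exact_bound)
    jt <- perm_engine(Y, pi$perms, jtk_templates(tp, lags_h, period_h),
                      kind = "tau", exact = pi$exact)
    ut <- perm_engine(Y, pi$perms, umbrella_templates(tp, candidate_peaks_h),
                      kind = "umbrella", exact = pi$exact)
    out$p_jtk[rows] <- jt$p
    out$p_umbrella[rows] <- ut$p
    out$tau_max[rows] <- ifelse(jt$n_pairs_y > 0,
                                jt$max_obs / sqrt(jt$n_pairs_y), 0)
    out$best_lag_h[rows] <- lags_h[jt$best]
    out$is_circadian[rows] <- jt$p < alpha & ut$p < alpha
  }
  out$peak_phase_h <- out$best_lag_h
  out
}

#' Per-feature min-max rescaling of an abundance matrix
#'
#' Rescales every row to \[0, 1\] (constant rows map to 0.5), revealing the
#' shared dynamics of features with different oscillation amplitudes.
#'
#' @param matrix numeric matrix, features in rows.
#' @return matrix of the same shape with rows in \[0, 1\].
#' @export
scale_by_feature <- function(matrix) {
  t(apply(matrix, 1, minmax_scale))
}

#' K-means clustering of rescaled circadian profiles by phase
#'
#' Clusters per-feature rescaled profiles into `k` groups (default 4, the
#' phases expected from the sampling design) with a fixed seed and restarts;
#' clusters are relabelled in order of the CT at which their centroid peaks.
#'
#' @param scaled matrix of \[0, 1\]-rescaled profiles (features x timepoints).
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @param timepoints optional CT hours per column (used to order clusters by
#'   centroid peak time; defaults to column index).
#' @return list: `cluster_of` (integer per feature), `centers`, `k`,
#'   `scaled_matrix`.
#' @export
phase_cluster <- function(scaled, k = 4, seed = 1L, nstart = 25,
                          timepoints = NULL) {
  stop_if_not(k >= 1, "k must be >= 1")
  stop_if_not(k <= nrow(scaled), "k cannot exceed the number of features")
  if (is.null(timepoints)) timepoints <- seq_len(ncol(scaled))
  set.seed(check_seed(seed))
  km <- stats::kmeans(scaled, centers = k, nstart = nstart, iter.max = 100)
  peak_ct <- timepoints[apply(km$centers, 1, which.max)]
  relabel <- order(order(peak_ct))     # cluster ordered by centroid peak CT
  list(cluster_of = relabel[km$cluster],
       centers = km$centers[order(peak_ct), , drop = FALSE],
       k = k, scaled_matrix = scaled)
}

#' Distribution of peak phases among circadian features
#'
#' @param results data frame from [call_circadian()] (or any frame with
#'   `is_circadian` and `peak_phase_h`).
#' @param bins phase bins (CT hours); CT24 folds into CT0.
#' @return named numeric vector of fractions summing to 1.
#' @export
phase_distribution <- function(results, bins = c(0, 6, 12, 18)) {
  circ <- results[results$is_circadian, , drop = FALSE]
  stop_if_not(nrow(circ) > 0, "no circadian features")
  ph <- circ$peak_phase_h %% 24
  counts <- vapply(bins, function(b) sum(ph == b), numeric(1))
  stop_if_not(sum(counts) == nrow(circ),
              "peak phases outside the given bins")
  stats::setNames(counts / sum(counts), paste0("CT", bins))
}
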