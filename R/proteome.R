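# Assembly of the quantified proteome from raw SILAC ratio tables.
#
# Quantification rule: a protein is retained iff every circadian timepoint has
# at least two non-missing replicate ratios. The decision depends only on the
# missingness mask. Retained ratios are log2-transformed.

#' Construct a raw SILAC ratio table
#'
#' @param ratios numeric matrix of (linear-scale) SILAC ratios, features in
#'   rows, `NA` for missing cells; all present ratios must be positive.
#' @param timepoints,replicates per-column CT hours and replicate indices.
#' @param feature_ids row identifiers.
#' @return object of class `raw_silac_table`.
#' @export
raw_silac_table <- function(ratios, timepoints, replicates,
                            feature_ids = rownames(ratios)) {
  ratios <- as.matrix(ratios)
  bad <- which(!is.na(ratios) & ratios <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive SILAC ratio at feature '%s', column '%s'",
                 (feature_ids %||% rownames(ratios) %||% bad[1, 1])[bad[1, 1]],
                 sprintf("CT%g_rep%d", timepoints[bad[1, 2]],
                         replicates[bad[1, 2]])),
         call. = FALSE)
  }
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(ratios)))
  rownames(ratios) <- feature_ids
  structure(list(ratios = ratios, timepoints = as.numeric(timepoints),
                 replicates = as.integer(replicates),
                 feature_ids = feature_ids),
            class = "raw_silac_table")
}

#' Assemble the quantified proteome from raw SILAC ratios
#'
#' Applies the replicate-coverage filter (>= `min_reps_per_timepoint`
#' non-missing ratios at every timepoint), log2-transforms the retained
#' values, and reports identified/quantified/excluded counts.
#'
#' @param raw a [raw_silac_table()].
#' @param min_reps_per_timepoint minimum non-missing replicates required at
#'   every timepoint (default 2, the two-of-three rule).
#' @return list with `table` (an [omics_timetable()] of log2 ratios for the
#'   quantified features) and `report` (list: `n_identified`, `n_quantified`,
#'   `n_excluded`).
#' @export
assemble_quantified <- function(raw, min_reps_per_timepoint = 2) {
  stop_if_not(inherits(raw, "raw_silac_table"), "raw must be a raw_silac_table")
  present <- !is.na(raw$ratios)
  tps <- unique(raw$timepoints)
  per_tp <- vapply(tps, function(t) {
    rowSums(present[, raw$timepoints == t, drop = FALSE])
  }, numeric(nrow(raw$ratios)))
  if (is.null(dim(per_tp))) per_tp <- matrix(per_tp, nrow = 1)
  keep <- apply(per_tp >= min_reps_per_timepoint, 1, all)
  quantified <- log2(raw$ratios[keep, , drop = FALSE])
  list(table = omics_timetable(quantified, raw$timepoints, raw$replicates,
                               feature_ids = raw$feature_ids[keep]),
       report = list(n_identified = nrow(raw$ratios),
                     n_quantified = sum(keep),
                     n_excluded = sum(!keep)))
}

#' SILAC labeling efficiency from heavy and light peptide counts
#'
#' Reports the incorporation fraction `heavy / (heavy + light)` together with
#' the literal heavy-to-light ratio (both conventions circulate; the fraction
#' is the bounded one).
#'
#' @param n_heavy,n_light peptide counts (non-negative; not both zero).
#' @return list with `efficiency` (fraction in \[0, 1\]) and `heavy_light_ratio`.
#' @export
labeling_efficiency <- function(n_heavy, n_light) {
  stop_if_not(n_heavy >= 0 && n_light >= 0, "counts must be non-negative")
  stop_if_not(n_heavy + n_light > 0, "n_heavy + n_light must be positive")
  list(efficiency = n_heavy / (n_heavy + n_light),
       heavy_light_ratio = if (n_light > 0) n_heavy / n_light else Inf)
}

#' Summary arithmetic for a dual-algorithm circadian proteome
#'
#' Given the identified/quantified counts and the per-test and intersection
#' rhythmic counts, computes the proportions used to summarise a circadian
#' proteome: percent of the quantified proteome called rhythmic by each test,
#' percent called circadian by the dual criterion, and the share of each
#' single-test proteome retained by the intersection.
#'
#' @param n_identified,n_quantified identified and quantified feature counts.
#' @param n_umbrella,n_jtk features significant by the umbrella (RAIN-style)
#'   and JTK-style tests.
#' @param n_overlap features significant by both.
#' @return list of percentages (0-100 scale): `pct_quantified_umbrella`,
#'   `pct_quantified_jtk`, `pct_quantified_circadian`,
#'   `pct_umbrella_in_overlap`, `pct_jtk_in_overlap`, plus the input counts.
#' @export
circadian_call_summary <- function(n_identified, n_quantified, n_umbrella,
                                   n_jtk, n_overlap) {
  stop_if_not(n_overlap <= min(n_umbrella, n_jtk),
              "overlap cannot exceed either single-test count")
  stop_if_not(n_quantified <= n_identified,
              "quantified set must be a subset of the identified set")
  list(n_identified = n_identified, n_quantified = n_quantified,
       n_umbrella = n_umbrella, n_jtk = n_jtk, n_overlap = n_overlap,
       pct_quantified_umbrella = 100 * n_umbrella / n_quantified,
       pct_quantified_jtk = 100 * n_jtk / n_quantified,
       pct_quantified_circadian = 100 * n_overlap / n_quantified,
       pct_umbrella_in_overlap = 100 * n_overlap / n_umbrella,
       pct_jtk_in_overlap = 100 * n_overlap / n_jtk)
}
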