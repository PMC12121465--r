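# Feature x (timepoint x replicate) abundance tables on the log2 scale.
# Missing values are stored as NA in the value matrix; the missingness mask is
# therefore is.na(values).

#' Construct an omics time table
#'
#' Container for a feature x (timepoint x replicate) matrix of log2 SILAC
#' ratios (or any log-scale abundance) sampled over one circadian cycle.
#'
#' @param values numeric matrix, features in rows; `NA` marks missing cells.
#' @param timepoints numeric vector of CT hours, one per column.
#' @param replicates integer vector of replicate indices, one per column.
#' @param feature_ids character vector of row identifiers (defaults to
#'   rownames of `values`).
#' @return object of class `omics_timetable`.
#' @export
omics_timetable <- function(values, timepoints, replicates,
                            feature_ids = rownames(values)) {
  values <- as.matrix(values)
  stop_if_not(ncol(values) == length(timepoints) &&
                ncol(values) == length(replicates),
              "timepoints/replicates must match the number of columns")
  stop_if_not(all(is.finite(values) | is.na(values)),
              "all stored values must be finite or NA")
  ord <- order(timepoints, replicates)
  values <- values[, ord, drop = FALSE]
  timepoints <- timepoints[ord]
  replicates <- replicates[ord]
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  rownames(values) <- feature_ids
  colnames(values) <- sprintf("CT%g_rep%d", timepoints, replicates)
  structure(list(values = values, timepoints = as.numeric(timepoints),
                 replicates = as.integer(replicates),
                 feature_ids = feature_ids),
            class = "omics_timetable")
}

#' @export
print.omics_timetable <- function(x, ...) {
  cat(sprintf("<omics_timetable> %d features x %d samples (CT %s; %d replicates); %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$timepoints), collapse = "/"),
              max(x$replicates), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write / read an omics time table as TSV
#'
#' Columns are named `CT{t}_rep{r}`; empty cells encode missing values.
#'
#' @param table an `omics_timetable`.
#' @param path TSV file path.
#' @export
write_timetable <- function(table, path) {
  df <- data.frame(feature_id = table$feature_ids,
                   as.data.frame(table$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_timetable
#' @export
read_timetable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  parsed <- parse_ct_columns(colnames(mat))
  omics_timetable(mat, parsed$timepoint, parsed$replicate,
                  feature_ids = as.character(df[[1]]))
}

parse_ct_columns <- function(nm) {
  m <- regmatches(nm, regexec("^CT([0-9.]+)_rep([0-9]+)$", nm))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("column names must follow CT{t}_rep{r}: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  list(timepoint = as.numeric(vapply(m, `[`, character(1), 2)),
       replicate = as.integer(vapply(m, `[`, character(1), 3)))
}

# Proteome simulation ----------------------------------------------------

#' Specification for a simulated SILAC proteome time course
#'
#' Defaults mirror the one-cycle explant design: 5 circadian timepoints
#' (CT0/6/12/18/24, with CT24 an independently sampled repeat of the CT0
#' phase), 3 replicates per timepoint, and 10% rhythmic features.
#'
#' @param n_proteins number of simulated features.
#' @param frac_rhythmic fraction of features carrying a circadian cosine
#'   (count fixed by rounding, not resampled).
#' @param timepoints CT hours, strictly increasing.
#' @param n_replicates replicates per timepoint.
#' @param peak_phases allowed peak phases (CT hours) for rhythmic features.
#' @param rel_amplitude cosine amplitude on the log2 scale.
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param missing_rate Bernoulli missingness rate per cell, in \[0, 1).
#' @param seed integer seed.
#' @return object of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_proteins = 1000, frac_rhythmic = 0.1,
                              timepoints = c(0, 6, 12, 18, 24),
                              n_replicates = 3,
                              peak_phases = c(0, 6, 12, 18),
                              rel_amplitude = 1, noise_sd = 0.25,
                              missing_rate = 0.1, seed = 1L) {
  stop_if_not(frac_rhythmic >= 0 && frac_rhythmic <= 1,
              "frac_rhythmic must be in [0, 1]")
  stop_if_not(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  stop_if_not(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)")
  structure(list(n_proteins = n_proteins, frac_rhythmic = frac_rhythmic,
                 timepoints = timepoints, n_replicates = n_replicates,
                 peak_phases = peak_phases, rel_amplitude = rel_amplitude,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = check_seed(seed)),
            class = "proteome_sim_spec")
}

#' Simulate a SILAC proteome time course with known rhythmicity labels
#'
#' Rhythmic features follow an additive cosine on the log2 scale,
#' `rel_amplitude * cos(2*pi*(CT - peak)/24)`, evaluated with CT folded mod 24
#' so the CT24 samples replicate the CT0 phase with independent noise draws.
#' Flat features are constant at 0. Replicate noise and Bernoulli missingness
#' are applied to every cell. The number of rhythmic features is
#' `round(frac_rhythmic * n_proteins)` exactly.
#'
#' @param spec a [proteome_sim_spec()].
#' @return list with `table` (an [omics_timetable()]) and `truth`
#'   (data frame: `feature_id`, `is_rhythmic`, `peak_phase_h`).
#' @export
simulate_proteome <- function(spec) {
  stop_if_not(inherits(spec, "proteome_sim_spec"),
              "spec must be a proteome_sim_spec")
  set.seed(spec$seed)
  n <- spec$n_proteins
  n_rhythmic <- round(spec$frac_rhythmic * n)
  is_rhythmic <- c(rep(TRUE, n_rhythmic), rep(FALSE, n - n_rhythmic))
  peak <- rep(NA_real_, n)
  if (n_rhythmic > 0)
    peak[seq_len(n_rhythmic)] <- sample(spec$peak_phases, n_rhythmic,
                                        replace = TRUE)

  tp <- rep(spec$timepoints, each = spec$n_replicates)
  reps <- rep(seq_len(spec$n_replicates), times = length(spec$timepoints))
  m <- length(tp)

  signal <- matrix(0, n, m)
  if (n_rhythmic > 0) {
    ref <- outer(peak[seq_len(n_rhythmic)], tp %% 24,
                 function(p, t) cos(2 * pi * (t - p) / 24))
    signal[seq_len(n_rhythmic), ] <- spec$rel_amplitude * ref
  }
  noise <- matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
  values <- signal + noise
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    values[mask] <- NA_real_
  }
  ids <- sprintf("P%04d", seq_len(n))
  rownames(values) <- ids
  list(table = omics_timetable(values, tp, reps, feature_ids = ids),
       truth = data.frame(feature_id = ids, is_rhythmic = is_rhythmic,
                          peak_phase_h = peak))
}
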