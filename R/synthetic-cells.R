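# Synthetic cell x gene count matrices with known cell types, marker
# structure, a planted two-gene co-expression partition, and day/night
# differential expression. Counts are negative binomial (the standard
# overdispersed model for scRNA-seq counts).

#' Specification for a simulated cell x gene count matrix
#'
#' @param cell_types data frame with columns `name`, `proportion` and a list
#'   column `markers` (character vectors of marker genes per type);
#'   proportions must sum to 1.
#' @param n_cells,n_genes matrix dimensions. Gene names are `gene_0001`, ...
#'   with marker and co-expression pair genes substituted in.
#' @param baseline_mean,dispersion negative-binomial mean and dispersion
#'   (`size = 1/dispersion`).
#' @param marker_fold fold increase of a type's marker genes in cells of
#'   that type.
#' @param coexpr_pair optional list: `geneA`, `geneB`, and `probs`, a named
#'   list per cell type of length-4 probability vectors
#'   `c(neither, A_only, B_only, both)` (each summing to 1); types absent
#'   from `probs` default to `c(1, 0, 0, 0)`.
#' @param day_fraction fraction of cells labelled `"day"`.
#' @param day_night_lfc named numeric vector: gene -> log2 fold (day over
#'   night), applied symmetrically around the gene's baseline mean.
#' @param seed integer seed.
#' @return object of class `cell_sim_spec`.
#' @export
cell_sim_spec <- function(cell_types, n_cells = 2000, n_genes = 200,
                          baseline_mean = 2, dispersion = 0.5,
                          marker_fold = 8, coexpr_pair = NULL,
                          day_fraction = 0.5, day_night_lfc = NULL,
                          seed = 1L) {
  stop_if_not(is.data.frame(cell_types) &&
                all(c("name", "proportion", "markers") %in% names(cell_types)),
              "cell_types needs name, proportion, markers columns")
  stop_if_not(abs(sum(cell_types$proportion) - 1) < 1e-8,
              "cell type proportions must sum to 1")
  if (!is.null(coexpr_pair)) {
    stop_if_not(all(c("geneA", "geneB", "probs") %in% names(coexpr_pair)),
                "coexpr_pair needs geneA, geneB, probs")
    for (p in coexpr_pair$probs)
      stop_if_not(length(p) == 4 && abs(sum(p) - 1) < 1e-8,
                  "each co-expression probability vector must have 4 entries summing to 1")
  }
  structure(list(cell_types = cell_types, n_cells = n_cells,
                 n_genes = n_genes, baseline_mean = baseline_mean,
                 dispersion = dispersion, marker_fold = marker_fold,
                 coexpr_pair = coexpr_pair, day_fraction = day_fraction,
                 day_night_lfc = day_night_lfc, seed = check_seed(seed)),
            class = "cell_sim_spec")
}

#' Default SCN cell-type marker genes
#'
#' The marker panels used to annotate SCN explant single-cell clusters:
#' SCN neurons (Slc32a1, Nms, Avp, Vip), extra-SCN neurons (Slc17a6, Th,
#' Sst, Agrp), astrocytes (Gfap, Aldh1l1, Aqp4, Sox9), ependymocytes,
#' oligodendrocytes, NG2 cells, radial glia, tanycytes, microglia and
#' endothelial cells.
#'
#' @return named list of marker gene character vectors.
#' @export
scn_markers <- function() {
  list(
    scn_neuron = c("Slc32a1", "Nms", "Avp", "Vip"),
    extra_scn_neuron = c("Slc17a6", "Th", "Sst", "Agrp"),
    astrocyte = c("Gfap", "Aldh1l1", "Aqp4", "Sox9"),
    ependymocyte = c("Tmem212", "Tctex1d4"),
    oligodendrocyte = c("Mog", "Plp1"),
    ng2 = "Pdgfra",
    radial_glia = c("Ccnb1", "Ube2c"),
    tanycyte = "Col23a1",
    microglia = c("Ly86", "C1qa", "Hexb"),
    endothelial = c("Lum", "Dcn")
  )
}

#' Simulate a cell x gene count matrix with known ground truth
#'
#' Cells are assigned types by the stated proportions (largest-remainder
#' rounding, then shuffled); counts are negative binomial with a type's
#' marker genes scaled by `marker_fold`. If a co-expression pair is
#' specified, each cell draws a partition category from its type's
#' probabilities; the pair genes are then zeroed (not expressed) or forced
#' positive via a zero-truncated draw (expressed), so the planted category is
#' recoverable from the counts layer. Day/night labels are Bernoulli and the
#' listed genes receive their log2 fold change symmetrically (day mean
#' `* 2^(lfc/2)`, night mean `* 2^(-lfc/2)`).
#'
#' @param spec a [cell_sim_spec()].
#' @return list with `matrix` (a [cell_gene_matrix()]) and `truth` (data
#'   frame: `cell`, `cell_type`, `time_label`, `coexpr_category`).
#' @export
simulate_cells <- function(spec) {
  stop_if_not(inherits(spec, "cell_sim_spec"), "spec must be a cell_sim_spec")
  set.seed(spec$seed)
  n <- spec$n_cells
  types <- spec$cell_types$name

  genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
  special <- unique(c(unlist(spec$cell_types$markers),
                      spec$coexpr_pair$geneA, spec$coexpr_pair$geneB,
                      names(spec$day_night_lfc)))
  special <- special[!special %in% genes]
  stop_if_not(length(special) <= spec$n_genes,
              "n_genes too small for the named genes")
  genes[seq_along(special)] <- special

  # largest-remainder type allocation, then shuffle
  raw <- spec$cell_types$proportion * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  cell_type <- sample(rep(types, cnt))

  time_label <- ifelse(stats::runif(n) < spec$day_fraction, "day", "night")

  # per-cell x gene mean matrix
  mu <- matrix(spec$baseline_mean, n, spec$n_genes,
               dimnames = list(NULL, genes))
  for (i in seq_along(types)) {
    mk <- intersect(spec$cell_types$markers[[i]], genes)
    if (length(mk))
      mu[cell_type == types[i], mk] <- spec$baseline_mean * spec$marker_fold
  }
  if (!is.null(spec$day_night_lfc)) {
    for (g in names(spec$day_night_lfc)) {
      stop_if_not(g %in% genes, paste0("day_night_lfc gene not in universe: ", g))
      lfc <- spec$day_night_lfc[[g]]
      mu[time_label == "day", g] <- mu[time_label == "day", g] * 2^(lfc / 2)
      mu[time_label == "night", g] <- mu[time_label == "night", g] * 2^(-lfc / 2)
    }
  }

  size <- 1 / spec$dispersion
  counts <- matrix(stats::rnbinom(n * spec$n_genes, mu = as.vector(mu),
                                  size = size),
                   n, spec$n_genes, dimnames = list(NULL, genes))

  coexpr_category <- rep(NA_character_, n)
  if (!is.null(spec$coexpr_pair)) {
    gA <- spec$coexpr_pair$geneA; gB <- spec$coexpr_pair$geneB
    stop_if_not(gA %in% genes && gB %in% genes,
                "co-expression pair genes must be in the gene universe")
    cats <- c("neither", "A_only", "B_only", "both")
    default_p <- c(1, 0, 0, 0)
    for (ty in types) {
      idx <- which(cell_type == ty)
      p <- spec$coexpr_pair$probs[[ty]] %||% default_p
      coexpr_category[idx] <- sample(cats, length(idx), replace = TRUE, prob = p)
    }
    exprA <- coexpr_category %in% c("A_only", "both")
    exprB <- coexpr_category %in% c("B_only", "both")
    # zero-truncated draw where expression is required, hard zero otherwise
    counts[, gA] <- ifelse(exprA, 1L + stats::rnbinom(n, mu = mu[, gA], size = size), 0L)
    counts[, gB] <- ifelse(exprB, 1L + stats::rnbinom(n, mu = mu[, gB], size = size), 0L)
  }

  list(matrix = cell_gene_matrix(counts, cell_type, time_label),
       truth = data.frame(cell = seq_len(n), cell_type = cell_type,
                          time_label = time_label,
                          coexpr_category = coexpr_category))
}

#' Write / read a cell x gene matrix as MTX plus label TSVs
#'
#' `write_cells` writes `counts.mtx` (MatrixMarket, genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `labels.tsv` (cell type and optional
#' day/night label) into a directory; `read_cells` reads them back.
#'
#' @param matrix a [cell_gene_matrix()].
#' @param dir directory path.
#' @export
write_cells <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(matrix$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  writeLines(colnames(matrix$counts), file.path(dir, "genes.tsv"))
  writeLines(sprintf("cell_%05d", seq_len(nrow(matrix$counts))),
             file.path(dir, "barcodes.tsv"))
  lab <- data.frame(barcode = sprintf("cell_%05d", seq_len(nrow(matrix$counts))),
                    cell_type = matrix$cell_type)
  if (!is.null(matrix$time_label)) lab$time_label <- matrix$time_label
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cells
#' @export
read_cells <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "counts.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  counts <- t(as.matrix(m))
  colnames(counts) <- genes
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  cell_gene_matrix(counts, lab$cell_type,
                   time_label = lab$time_label %||% NULL)
}
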