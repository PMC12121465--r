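# Cell-type-resolved transcriptome analyses: marker-based cluster annotation,
# cluster-defining gene ranking, two-gene co-expression partitions,
# interactor expression profiles, day/night differential expression and the
# circadian-proteome x astrocyte-transcriptome intersection.
#
# A cell "expresses" a gene iff its raw count exceeds `min_count` (default 0,
# i.e. any non-zero count), taken from the counts layer.

#' Construct a cell x gene count matrix with labels
#'
#' @param counts non-negative integer matrix, cells in rows, genes in columns.
#' @param cell_type character/factor label per cell (cell type or cluster id).
#' @param time_label optional `"day"`/`"night"` label per cell.
#' @return object of class `cell_gene_matrix`.
#' @export
cell_gene_matrix <- function(counts, cell_type, time_label = NULL) {
  counts <- as.matrix(counts)
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  stop_if_not(length(cell_type) == nrow(counts),
              "cell_type must label every cell")
  if (!is.null(time_label))
    stop_if_not(length(time_label) == nrow(counts),
                "time_label must label every cell")
  stop_if_not(!is.null(colnames(counts)), "counts needs gene column names")
  structure(list(counts = counts, cell_type = as.character(cell_type),
                 time_label = time_label),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("<cell_gene_matrix> %d cells x %d genes; %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_type))))
  invisible(x)
}

#' Annotate clusters by marker-gene expression
#'
#' Scores each (cluster, type) pair as the mean over the type's markers of
#' the cluster's z-scored mean expression (z taken across clusters), assigns
#' the argmax type, and emits `"unclassified"` when the top score is <= 0 or
#' tied.
#'
#' @param matrix a [cell_gene_matrix()].
#' @param cluster_ids cluster label per cell (defaults to the stored
#'   `cell_type` slot, useful when that slot holds cluster ids).
#' @param markers named list: cell type -> character vector of marker genes.
#' @return named character vector: cluster -> assigned type.
#' @export
annotate_clusters <- function(matrix, cluster_ids = matrix$cell_type, markers) {
  stop_if_not(is.list(markers) && length(markers) > 0 &&
                !is.null(names(markers)), "markers must be a named list")
  clusters <- sort(unique(cluster_ids))
  genes <- colnames(matrix$counts)
  all_markers <- unique(unlist(markers))
  missing <- setdiff(all_markers, genes)
  if (length(missing) == length(all_markers))
    stop("none of the marker genes are present in the matrix", call. = FALSE)
  if (length(missing))
    warning("markers absent from matrix, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)

  use <- intersect(all_markers, genes)
  # cluster x marker mean expression, z-scored across clusters
  mean_expr <- t(vapply(clusters, function(cl) {
    colMeans(matrix$counts[cluster_ids == cl, use, drop = FALSE])
  }, numeric(length(use))))
  if (length(clusters) == 1) mean_expr <- base::matrix(mean_expr, nrow = 1)
  dimnames(mean_expr) <- list(clusters, use)
  z <- scale(mean_expr)
  z[is.nan(z)] <- 0                     # markers constant across clusters

  score <- vapply(names(markers), function(ty) {
    mk <- intersect(markers[[ty]], use)
    if (!length(mk)) return(rep(NA_real_, length(clusters)))
    rowMeans(z[, mk, drop = FALSE])
  }, numeric(length(clusters)))
  if (length(clusters) == 1) score <- base::matrix(score, nrow = 1,
                                                   dimnames = list(clusters, names(markers)))

  assign <- apply(score, 1, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) return("unclassified")
    top <- max(s)
    if (top <= 0 || sum(abs(s - top) < 1e-12) > 1) return("unclassified")
    names(s)[which.max(s)]
  })
  stats::setNames(assign, clusters)
}

#' Rank cluster-defining genes by one-sided rank-sum test
#'
#' For each cluster, tests every gene cluster-vs-rest with a one-sided
#' (greater) Wilcoxon rank-sum test, BH-adjusts within the cluster, keeps
#' genes with adjusted p < `alpha`, orders by adjusted p then raw p then
#' symbol, and truncates to `top_n`.
#'
#' @param matrix a [cell_gene_matrix()].
#' @param cluster_ids cluster label per cell.
#' @param top_n genes retained per cluster (default 250).
#' @param alpha adjusted-p threshold.
#' @return named list: cluster -> data frame (`gene`, `p`, `p_adj`).
#' @export
rank_cluster_markers <- function(matrix, cluster_ids = matrix$cell_type,
                                 top_n = 250, alpha = 0.05) {
  clusters <- sort(unique(cluster_ids))
  stop_if_not(length(clusters) >= 2, "need >= 2 clusters")
  counts <- matrix$counts
  out <- lapply(clusters, function(cl) {
    inside <- cluster_ids == cl
    p <- vapply(seq_len(ncol(counts)), function(j) {
      x <- counts[inside, j]; y <- counts[!inside, j]
      if (all(x == x[1]) && all(y == x[1])) return(1)
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
    }, numeric(1))
    df <- data.frame(gene = colnames(counts), p = p,
                     p_adj = stats::p.adjust(p, "BH"))
    df <- df[df$p_adj < alpha, , drop = FALSE]
    df <- df[order(df$p_adj, df$p, df$gene), , drop = FALSE]
    utils::head(df, top_n)
  })
  stats::setNames(out, clusters)
}

#' Two-gene co-expression partition
#'
#' Partitions cells into the four mutually exclusive categories neither /
#' A-only / B-only / both by raw-count expression of two genes, overall and
#' per cell type.
#'
#' @param matrix a [cell_gene_matrix()].
#' @param geneA,geneB gene symbols (must be present).
#' @param min_count a cell expresses a gene iff count > `min_count`.
#' @return list with `overall` (named counts: `n_neither`, `n_A_only`,
#'   `n_B_only`, `n_both`, `n_total`), `by_type` (data frame of per-type
#'   counts and `pct_both`), and the gene names.
#' @export
coexpression_partition <- function(matrix, geneA, geneB, min_count = 0) {
  genes <- colnames(matrix$counts)
  stop_if_not(geneA %in% genes, paste0("gene not found: ", geneA))
  stop_if_not(geneB %in% genes, paste0("gene not found: ", geneB))
  a <- matrix$counts[, geneA] > min_count
  b <- matrix$counts[, geneB] > min_count
  cat4 <- ifelse(a & b, "both", ifelse(a, "A_only", ifelse(b, "B_only", "neither")))
  tab <- function(idx) {
    c(n_neither = sum(cat4[idx] == "neither"),
      n_A_only = sum(cat4[idx] == "A_only"),
      n_B_only = sum(cat4[idx] == "B_only"),
      n_both = sum(cat4[idx] == "both"),
      n_total = sum(idx))
  }
  overall <- tab(rep(TRUE, length(cat4)))
  types <- sort(unique(matrix$cell_type))
  by_type <- do.call(rbind, lapply(types, function(ty) {
    v <- tab(matrix$cell_type == ty)
    data.frame(cell_type = ty, t(v), pct_both = 100 * v["n_both"] / v["n_total"],
               row.names = NULL)
  }))
  list(geneA = geneA, geneB = geneB, overall = overall, by_type = by_type,
       category = cat4)
}

#' Interactor expression profile across cell types
#'
#' Sums raw counts per (gene, cell type) and min-max normalizes each gene's
#' row across types (constant rows map to 0.5).
#'
#' @param matrix a [cell_gene_matrix()].
#' @param gene_list character vector of gene symbols; absent genes are
#'   dropped with a warning (error if none remain).
#' @return genes x cell-types matrix in \[0, 1\].
#' @export
interactor_profile <- function(matrix, gene_list) {
  genes <- intersect(gene_list, colnames(matrix$counts))
  if (!length(genes))
    stop("none of the listed genes are present", call. = FALSE)
  if (length(genes) < length(gene_list))
    warning("genes absent from matrix, skipped: ",
            paste(setdiff(gene_list, genes), collapse = ", "), call. = FALSE)
  types <- sort(unique(matrix$cell_type))
  sums <- vapply(types, function(ty) {
    colSums(matrix$counts[matrix$cell_type == ty, genes, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) sums <- base::matrix(sums, nrow = 1,
                                               dimnames = list(genes, types))
  t(apply(sums, 1, minmax_scale))
}

#' Day/night differential expression within one cell type
#'
#' Per gene: log2 fold change of day vs night mean counts (pseudocount 1)
#' and a two-sided Wilcoxon rank-sum p-value, BH-adjusted across genes.
#'
#' @param matrix a [cell_gene_matrix()] restricted to one cell type, with a
#'   `time_label` slot.
#' @param day_label,night_label the two labels to contrast (log2FC is
#'   day over night).
#' @param min_cells minimum cells required per label.
#' @return data frame: `gene`, `log2fc`, `p`, `p_adj`.
#' @export
day_night_de <- function(matrix, day_label = "day", night_label = "night",
                         min_cells = 3) {
  stop_if_not(!is.null(matrix$time_label), "matrix has no time_label")
  day <- matrix$time_label == day_label
  night <- matrix$time_label == night_label
  stop_if_not(sum(day) >= min_cells && sum(night) >= min_cells,
              sprintf("each label needs >= %d cells", min_cells))
  counts <- matrix$counts
  res <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[day, j]; y <- counts[night, j]
    lfc <- log2((mean(x) + 1) / (mean(y) + 1))
    p <- if (all(c(x, y) == x[1])) 1 else
      stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)$p.value
    c(lfc, p)
  }, numeric(2))
  data.frame(gene = colnames(counts), log2fc = res[1, ], p = res[2, ],
             p_adj = stats::p.adjust(res[2, ], "BH"))
}

#' Intersect circadian features with cell-type-enriched transcripts
#'
#' Case-insensitive symbol match after applying an optional protein-to-gene
#' identifier map.
#'
#' @param circadian_features character vector of circadian protein symbols.
#' @param enriched_genes character vector of enriched transcript symbols.
#' @param id_map optional named character vector mapping protein ids to gene
#'   symbols before matching.
#' @return data frame of overlapping symbols with both source annotations.
#' @export
intersect_circadian_enriched <- function(circadian_features, enriched_genes,
                                         id_map = NULL) {
  stop_if_not(length(circadian_features) > 0 && length(enriched_genes) > 0,
              "both input sets must be non-empty")
  mapped <- circadian_features
  if (!is.null(id_map)) {
    hit <- mapped %in% names(id_map)
    mapped[hit] <- id_map[mapped[hit]]
  }
  key_p <- toupper(mapped)
  key_g <- toupper(enriched_genes)
  idx <- match(key_p, key_g)
  keep <- !is.na(idx) & !duplicated(key_p)
  data.frame(symbol = mapped[keep],
             protein_id = circadian_features[keep],
             transcript_symbol = enriched_genes[idx[keep]])
}
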