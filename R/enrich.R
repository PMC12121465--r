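# Generic over-representation analysis (ORA) over user-supplied gene sets
# (e.g. a GMT export of molecular-function terms), with per-cluster
# comparison and category-network (term-gene bipartite) construction.

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then genes.
#'
#' @param path GMT file path.
#' @return `read_gmt`: list with `sets` (named list of character vectors)
#'   and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stop_if_not(all(lengths(parts) >= 3), "malformed GMT line (need >= 3 fields)")
  nm <- vapply(parts, `[`, character(1), 1)
  stop_if_not(!anyDuplicated(nm), "duplicate set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  list(sets = stats::setNames(sets, nm),
       descriptions = stats::setNames(vapply(parts, `[`, character(1), 2), nm))
}

#' @rdname read_gmt
#' @param sets named list of gene character vectors.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions)) descriptions[[nm]] %||% "na" else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set, tests whether the query list overlaps the set more
#' than expected under hypergeometric sampling from the universe; p-values
#' are upper-tail hypergeometric, BH-adjusted across sets. Symbols are
#' case-normalized before matching. The default universe is the union of all
#' set genes and the query.
#'
#' @param query character vector of gene symbols.
#' @param sets named list of gene character vectors (or the `sets` element
#'   of [read_gmt()] output).
#' @param universe optional background gene list.
#' @return data frame sorted by adjusted p: `term`, `k` (overlap), `n`
#'   (query size in universe), `K` (set size in universe), `N` (universe
#'   size), `gene_ratio`, `p`, `p_adj`, `genes` (overlap, "/"-separated).
#' @export
ora <- function(query, sets, universe = NULL) {
  if (is.list(sets) && !is.null(sets$sets)) sets <- sets$sets
  stop_if_not(length(query) > 0, "empty query")
  stop_if_not(length(sets) > 0 && !is.null(names(sets)), "sets must be named")
  norm <- function(x) unique(toupper(x))
  query <- norm(query)
  sets_n <- lapply(sets, norm)
  universe <- if (is.null(universe)) unique(c(unlist(sets_n), query)) else norm(universe)
  stop_if_not(length(universe) > 0, "empty universe")
  query <- intersect(query, universe)
  stop_if_not(length(query) > 0, "query has no genes in the universe")

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets_n), function(nm) {
    set <- intersect(sets_n[[nm]], universe)
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, n = n, K = K, N = N,
               gene_ratio = k / n, p = p,
               genes = paste(ov, collapse = "/"))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p_adj, out$p, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "k", "n", "K", "N", "gene_ratio", "p", "p_adj", "genes")]
}

#' Per-cluster enrichment comparison with deduplicated top terms
#'
#' Runs [ora()] for each cluster's gene list and reports the union of each
#' cluster's `top_n` most significant terms, deduplicated — so clusters with
#' overlapping top terms contribute fewer than `top_n * n_clusters` terms.
#'
#' @param cluster_lists named list: cluster -> query gene vector.
#' @param sets,universe as in [ora()].
#' @param top_n top terms per cluster entering the union (default 2).
#' @return list with `tables` (per-cluster ORA tables) and `top_terms`
#'   (character vector, the deduplicated union).
#' @export
compare_clusters <- function(cluster_lists, sets, universe = NULL, top_n = 2) {
  stop_if_not(length(cluster_lists) >= 1, "need >= 1 cluster list")
  tables <- lapply(cluster_lists, ora, sets = sets, universe = universe)
  top <- unlist(lapply(tables, function(tb) utils::head(tb$term, top_n)),
                use.names = FALSE)
  list(tables = tables, top_terms = unique(top))
}

#' Term-gene bipartite network from an enrichment table
#'
#' Connects each of the `top_k` most significant terms to its overlapping
#' query genes; a gene contributing to several terms appears as one shared
#' node, so its degree counts the terms it bridges (nexus detection).
#'
#' @param table an [ora()] result.
#' @param top_k number of top terms to include.
#' @return list with `edges` (data frame `term`, `gene`) and `gene_degree`
#'   (named vector: terms per gene).
#' @export
term_gene_network <- function(table, top_k = 10) {
  stop_if_not(nrow(table) > 0, "empty enrichment table")
  top <- utils::head(table, top_k)
  edges <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    gv <- strsplit(top$genes[i], "/", fixed = TRUE)[[1]]
    gv <- gv[nzchar(gv)]
    if (!length(gv)) return(NULL)
    data.frame(term = top$term[i], gene = gv)
  }))
  if (is.null(edges)) edges <- data.frame(term = character(0), gene = character(0))
  deg <- if (nrow(edges)) base::table(edges$gene) else integer(0)
  list(edges = edges,
       gene_degree = stats::setNames(as.integer(deg), names(deg)))
}
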