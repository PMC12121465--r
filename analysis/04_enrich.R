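#!/usr/bin/env Rscript
# Step 4 -- gene-set over-representation on cluster-defining genes.
#
# Builds a small molecular-function-style gene-set collection around the
# simulated markers, runs hypergeometric ORA per cluster, reports the
# deduplicated union of each cluster's top-2 terms, and extracts the
# term-gene category network of the top terms (shared genes appear as
# single nodes, exposing nexus genes).

suppressMessages(library(clockworks))
dir.create("results", showWarnings = FALSE)

cells <- read_cells("results/data/cells")
mk <- lapply(list.files("results", pattern = "^markers_", full.names = TRUE),
             utils::read.delim)
names(mk) <- sub("^markers_(.*)\\.tsv$", "\\1",
                 list.files("results", pattern = "^markers_"))

## gene-set collection: functional groupings over the simulated universe
universe <- colnames(cells$counts)
sets <- list(
  s100_protein_binding = c("Anxa2", "S100a10", "Gfap", "Aqp4"),
  astrocyte_identity = c("Gfap", "Aldh1l1", "Aqp4", "Sox9"),
  neuropeptide_signaling = c("Avp", "Vip", "Nms"),
  gaba_transport = c("Slc32a1", "Avp"),
  cilium_assembly = c("Tmem212", "Tctex1d4"),
  housekeeping = grep("^gene_00[0-4]", universe, value = TRUE)
)
write_gmt(sets, "results/gene_sets.gmt")

cluster_lists <- lapply(mk, `[[`, "gene")
cc <- compare_clusters(cluster_lists, sets, universe = universe, top_n = 2)
message("top-2 terms per cluster, deduplicated union of ",
        length(cc$top_terms), ": ", paste(cc$top_terms, collapse = ", "))
for (cl in names(cc$tables))
  utils::write.table(cc$tables[[cl]], sprintf("results/ora_%s.tsv", cl),
                     sep = "\t", row.names = FALSE, quote = FALSE)

## category network of the astrocyte cluster's top terms
net <- term_gene_network(cc$tables$astrocyte, top_k = 10)
utils::write.table(net$edges, "results/astro_term_gene_edges.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
deg <- sort(net$gene_degree, decreasing = TRUE)
message("highest-degree network genes: ",
        paste(names(deg)[1:min(3, length(deg))],
              deg[1:min(3, length(deg))], sep = "=", collapse = ", "))
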