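#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study datasets.
#
# Produces the three inputs the downstream analyses consume, with ground
# truth recorded alongside: (a) a raw SILAC ratio proteome table over one
# circadian cycle (CT0/6/12/18/24, 3 replicates, 10% rhythmic features),
# (b) a cell x gene count matrix with SCN cell types, planted marker genes
# and an astrocyte-enriched two-gene co-expression pair, and (c) a cohort of
# treatment/washout reporter traces (period 24.8 h, amplitude suppressed to
# 15% during treatment).

suppressMessages(library(clockworks))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## proteome: simulate log2 ratios, write the raw (linear-ratio) table
prot <- simulate_proteome(proteome_sim_spec(n_proteins = 500,
                                            frac_rhythmic = 0.1,
                                            rel_amplitude = 1,
                                            noise_sd = 0.25,
                                            missing_rate = 0.1, seed = 11))
write_timetable(prot$table, "results/data/proteome_log2.tsv")
utils::write.table(prot$truth, "results/data/proteome_truth.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("proteome: ", nrow(prot$table$values), " features, ",
        sum(prot$truth$is_rhythmic), " rhythmic (truth)")

## cells: three SCN cell types with markers, co-expression pair planted in
## astrocytes at the half-coexpressing level, day/night effect on Aqp4
ct <- data.frame(name = c("astrocyte", "scn_neuron", "ependymocyte"),
                 proportion = c(0.25, 0.55, 0.20))
ct$markers <- list(c("Gfap", "Aldh1l1", "Aqp4", "Sox9"),
                   c("Slc32a1", "Nms", "Avp", "Vip"),
                   c("Tmem212", "Tctex1d4"))
cells <- simulate_cells(cell_sim_spec(
  ct, n_cells = 4000, n_genes = 150, baseline_mean = 2, marker_fold = 8,
  coexpr_pair = list(geneA = "Anxa2", geneB = "S100a10",
                     probs = list(astrocyte = c(0.24, 0.11, 0.143, 0.507),
                                  scn_neuron = c(0.75, 0.05, 0.15, 0.05),
                                  ependymocyte = c(0.55, 0.05, 0.20, 0.20))),
  day_night_lfc = c(Aqp4 = -0.58), seed = 12))
write_cells(cells$matrix, "results/data/cells")
utils::write.table(cells$truth, "results/data/cells_truth.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("cells: ", nrow(cells$matrix$counts), " cells x ",
        ncol(cells$matrix$counts), " genes")

## traces: 6 slices per condition (advance +2 h, delay -3 h), PMT-like dt
dir.create("results/data/traces", showWarnings = FALSE)
for (cond in c("advance", "delay")) {
  offset <- if (cond == "advance") 2 else -3
  for (i in 1:6) {
    ep <- epoch_effect(120, 192, amplitude_factor = 0.15,
                       phase_offset_h = offset, recovery_halflife_h = 24)
    tr <- simulate_trace(trace_sim_spec(duration_h = 288, dt_h = 0.1,
                                        period_h = 24.8, phase_h = 6,
                                        noise_sd = 0.05, epochs = list(ep),
                                        seed = 100 + 10 * (cond == "delay") + i))
    write_trace(tr, sprintf("results/data/traces/%s_slice%02d.csv", cond, i))
  }
}
message("traces: 12 treatment recordings written")
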