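#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study data set.
#
# A two-condition (WT vs MUT), two-replicate accessibility experiment with
# 12.5% loss / 5.2% gain peak classes at +/-1.5 log2 effect, gene models
# with TSS annotation, histone-mark region sets consistent with the
# enhancer taxonomy, motif sites, and per-condition paired-end fragments
# whose mononucleosomal dyads are planted at +/-120 bp (WT) vs +/-101 bp
# (MUT) around motif centers. Everything downstream reads these files.

suppressMessages(library(chromarc))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 1, n_peaks = 2000, n_fragments = 1e5)

sim <- simulate_peak_counts(cfg)
genes <- simulate_genes(cfg, n_genes = 300)
marks <- simulate_marks_and_features(cfg, sim$peaks, genes$tss,
                                     truth = sim$truth)

# every generator is a pure function of (cfg, seed), so later stages
# rebuild these objects exactly instead of re-reading bulky files; only
# compact summaries are persisted here
write_bed(genes$tss, "results/data/tss.bed")
utils::write.table(sim$truth, "results/data/peak_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
set_sizes <- data.frame(
  set = c("peaks", "genes", "k4me", "k4me3", "k27ac", "motifs", "swisnf",
          "k27ac_down", "fra1"),
  n = c(nrow(sim$peaks), nrow(genes$genes), nrow(marks$k4me),
        nrow(marks$k4me3), nrow(marks$k27ac), nrow(marks$motifs),
        nrow(marks$swisnf), nrow(marks$k27ac_down), nrow(marks$fra1))
)
utils::write.table(set_sizes, "results/data/set_sizes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d peaks (%d loss / %d gain planted), %d genes,",
                nrow(sim$peaks), sum(sim$truth$label == "loss"),
                sum(sim$truth$label == "gain"), nrow(genes$genes)))
message(sprintf("%d K4me1 / %d K4me3 / %d K27ac regions, %d motif sites",
                nrow(marks$k4me), nrow(marks$k4me3), nrow(marks$k27ac),
                nrow(marks$motifs)))
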