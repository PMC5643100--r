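#!/usr/bin/env Rscript

# Stage 7: co-regulated-site cascade and per-cluster expression folds.
#
# Intersects the decreased-accessibility sites with remodeler binding,
# reduced K27ac and AP-1 factor binding, maps survivors to their nearest
# TSS and intersects with the down-regulated genes; then summarises
# expression fold changes of the top-25%-expressed nearest genes per
# accessibility cluster.

suppressMessages(library(chromarc))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1, n_peaks = 2000, n_fragments = 1e5)
sim <- simulate_peak_counts(cfg)
genes <- simulate_genes(cfg, n_genes = 300)
marks <- simulate_marks_and_features(cfg, sim$peaks, genes$tss,
                                     truth = sim$truth)
diff <- differential_peaks(sim, "WT", "MUT")

# expression: genes nearest to loss peaks planted down, gain peaks up
ann <- nearest_tss(sim$peaks, genes$tss)
eff <- numeric(nrow(genes$tss))
names(eff) <- genes$tss$name
loss_genes <- unique(ann$gene[sim$truth$label == "loss" & !ann$unannotated])
gain_genes <- unique(ann$gene[sim$truth$label == "gain" & !ann$unannotated])
eff[loss_genes] <- -1.5
eff[gain_genes] <- 1.5
exprs <- simulate_expression(cfg, genes$tss$name, log2fc = unname(eff))
l2 <- log2((rowMeans(exprs$fpkm[, 3:4]) + 0.5) /
             (rowMeans(exprs$fpkm[, 1:2]) + 0.5))
de_down <- names(l2)[l2 <= -log2(1.5)]
message(sprintf("%d genes called down at the 1.5-fold expression rule",
                length(de_down)))

cas <- coregulation_cascade(diff[diff$call == "down", ], marks$swisnf,
                            marks$k27ac_down, marks$fra1, de_down,
                            genes$tss)
utils::write.table(cas$stages, "results/cascade.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(cas$stages)
message(sprintf("%d (%.0f%%) of decreased sites overlap remodeler binding",
                cas$stages$count[2],
                percent_changed(cas$stages$count[2], cas$stages$count[1],
                                decimals = 0)))
message(sprintf("cascade ends at %d co-regulated down genes",
                length(cas$genes)))

# per-cluster expression folds (top 25% expressed nearest genes)
td <- lapply(stats::setNames(cfg$conditions, cfg$conditions), function(cond)
  tag_density(sim$peaks, simulate_fragments(cfg, marks$motifs, cond)))
km <- suppressWarnings(
  kmeans_centered_correlation(clustering_features(td$WT, td$MUT),
                              k = 7, seed = cfg$seed))
ef <- expression_fold_by_cluster(km$cluster, sim$peaks, exprs, genes$tss,
                                 reference = "WT", condition = "MUT")
utils::write.table(ef$clusters, "results/cluster_expression.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(ef$clusters)
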