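#!/usr/bin/env Rscript

# Stage 2: replicate-aware differential accessibility.
#
# The generators are pure functions of the config seed, so this stage
# rebuilds stage 1's objects exactly and runs the NB exact-style test
# (moderated common dispersion, BH-FDR) at the 1.5-fold / q < 0.05 call
# thresholds, then scores the calls against the planted truth.

suppressMessages(library(chromarc))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1, n_peaks = 2000, n_fragments = 1e5)
sim <- simulate_peak_counts(cfg)

res <- differential_peaks(sim, "WT", "MUT")
out <- res
out[c("log2fc", "p", "q")] <- lapply(out[c("log2fc", "p", "q")], signif, 4)
write_differential(out, "results/differential.tsv")

n_down <- sum(res$call == "down")
n_up <- sum(res$call == "up")
message(sprintf("%d peaks: %d decreased (%.1f%%), %d increased (%.1f%%)",
                nrow(res), n_down, percent_changed(n_down, nrow(res)),
                n_up, percent_changed(n_up, nrow(res))))

truth <- sim$truth
conf <- table(truth = truth$label, call = res$call)
print(conf)
power_down <- mean(res$call[truth$label == "loss"] == "down")
power_up <- mean(res$call[truth$label == "gain"] == "up")
fp <- mean(res$call[truth$label == "unchanged"] != "unchanged")
message(sprintf("power: %.2f (loss) / %.2f (gain); false-call rate %.3f",
                power_down, power_up, fp))
utils::write.table(as.data.frame(conf), "results/differential_confusion.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
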