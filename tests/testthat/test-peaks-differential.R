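test_that("call_peaks returns nothing on a flat track", {
  set.seed(1)
  cov <- list(chr1 = rpois(50000, 2))
  expect_equal(nrow(call_peaks(cov, mode = "atac")), 0)
})

test_that("call_peaks finds a single planted enrichment block", {
  set.seed(2)
  lam <- rep(2, 50000)
  lam[20000:21000] <- 20
  cov <- list(chr1 = rpois(50000, lam))
  p <- call_peaks(cov, mode = "atac")
  expect_equal(nrow(p), 1)
  expect_lte(p$start, 20000)
  expect_gte(p$end, 21000)
})

test_that("chip mode requires an input track and applies the input filter", {
  set.seed(3)
  lam <- rep(2, 60000)
  lam[10000:10800] <- 20   # signal-only block
  lam2 <- lam
  lam2[40000:40800] <- 20  # block present in signal AND input
  sig <- list(chr1 = rpois(60000, lam2))
  expect_error(call_peaks(sig, mode = "chip"), "input")
  inp_lam <- rep(2, 60000)
  inp_lam[40000:40800] <- 20
  inp <- list(chr1 = rpois(60000, inp_lam))
  p <- call_peaks(sig, inp, mode = "chip")
  # the input-matched block must be rejected by the 2x-over-input rule
  expect_false(any(p$start < 41000 & p$end > 40000))
})

test_that("planted blocks are recovered with high recall", {
  set.seed(4)
  L <- 2e6
  lam <- rep(2, L)
  starts <- sort(sample.int(L - 2000, 50))
  for (s in starts) lam[s:(s + 799)] <- 10
  p <- call_peaks(list(chr1 = rpois(L, lam)), mode = "atac")
  truth <- interval_set("chr1", starts, starts + 800)
  expect_gte(overlap_sets(truth, p)$proportion, 0.9)
})

test_that("count_in_peaks applies half-open midpoint containment", {
  peaks <- interval_set("chr1", c(100, 500), c(200, 600), name = c("p1", "p2"))
  frag <- function(dyad) data.frame(chrom = "chr1", start = dyad - 50,
                                    end = dyad + 50, length = 100L,
                                    dyad = dyad, sample = "s1",
                                    stringsAsFactors = FALSE)
  # midpoint exactly at peak start is inside; at peak end it is not
  cm <- count_in_peaks(peaks, list(s1 = rbind(frag(100L), frag(200L),
                                              frag(550L))))
  expect_equal(as.vector(cm$counts[, 1]), c(1L, 1L))
  empty <- count_in_peaks(peaks, list(s1 = frag(100L)[0, ]))
  expect_true(all(empty$counts == 0))
})

test_that("count_in_peaks matches a brute-force midpoint scan", {
  set.seed(5)
  peaks <- sort_intervals(random_intervals(80, chrom_len = 5e4))
  peaks <- merge_intervals(peaks)  # disjoint so containment is unambiguous
  peaks$name <- sprintf("p%03d", seq_len(nrow(peaks)))
  dyads <- sample.int(5e4, 2000)
  fr <- data.frame(chrom = "chr1", start = dyads - 10, end = dyads + 10,
                   length = 20L, dyad = dyads, sample = "s1",
                   stringsAsFactors = FALSE)
  cm <- count_in_peaks(peaks, list(s1 = fr))
  brute <- vapply(seq_len(nrow(peaks)), function(i)
    sum(dyads >= peaks$start[i] & dyads < peaks$end[i]), 0L)
  expect_equal(as.vector(cm$counts[, 1]), brute)
  expect_equal(cm$lib_sizes[["s1"]], 2000L)
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("identical counts give zero fold changes and no calls", {
  peaks <- random_intervals(20)
  peaks$name <- sprintf("p%02d", 1:20)
  counts <- matrix(rep(50L, 80), 20, 4,
                   dimnames = list(peaks$name, c("WT_1", "WT_2", "M_1", "M_2")))
  cm <- list(peaks = peaks, counts = counts,
             samples = data.frame(sample = colnames(counts),
                                  condition = rep(c("WT", "M"), each = 2),
                                  replicate = rep(1:2, 2)),
             lib_sizes = colSums(counts))
  res <- differential_peaks(cm, "WT", "M")
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$call == "unchanged"))
})

test_that("differential_peaks is antisymmetric in the condition order", {
  cfg <- sim_config(seed = 7, n_peaks = 300)
  sim <- simulate_peak_counts(cfg)
  ab <- differential_peaks(sim, "WT", "MUT")
  ba <- differential_peaks(sim, "MUT", "WT")
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p, ab$p, tolerance = 1e-10)
  expect_equal(sum(ab$call == "up"), sum(ba$call == "down"))
})

test_that("tightening the fold-change threshold shrinks the called set", {
  cfg <- sim_config(seed = 8, n_peaks = 1000)
  sim <- simulate_peak_counts(cfg)
  loose <- differential_peaks(sim, "WT", "MUT", fc_threshold = 1.5)
  tight <- differential_peaks(sim, "WT", "MUT", fc_threshold = 2)
  called <- function(r) which(r$call != "unchanged")
  expect_true(all(called(tight) %in% called(loose)))
})

test_that("differential_peaks validates conditions and library sizes", {
  cfg <- sim_config(seed = 9, n_peaks = 50)
  sim <- simulate_peak_counts(cfg)
  expect_error(differential_peaks(sim, "WT", "nope"), "not found")
  bad <- sim
  bad$lib_sizes[1] <- 0
  expect_error(differential_peaks(bad, "WT", "MUT"), "library size")
})

test_that("single-replicate designs fall back to a Poisson test with warning", {
  cfg <- sim_config(seed = 10, n_peaks = 100)
  sim <- simulate_peak_counts(cfg)
  sub <- list(peaks = sim$peaks, counts = sim$counts[, c(1, 3)],
              samples = sim$samples[c(1, 3), ],
              lib_sizes = sim$lib_sizes[c(1, 3)])
  expect_warning(res <- differential_peaks(sub, "WT", "MUT"),
                 "single replicate")
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("the NB test agrees with edgeR's exact test on shared input", {
  library(edgeR)
  cfg <- sim_config(seed = 42, n_peaks = 2000)
  sim <- simulate_peak_counts(cfg)
  mine <- differential_peaks(sim, "WT", "MUT")
  y <- edgeR::DGEList(counts = sim$counts, group = sim$samples$condition)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("WT", "MUT"))
  q_e <- bh_adjust(et$table$PValue)
  call_e <- ifelse(abs(et$table$logFC) >= log2(1.5) & q_e < 0.05,
                   ifelse(et$table$logFC > 0, "up", "down"), "unchanged")
  expect_gt(cor(mine$log2fc, et$table$logFC), 0.99)
  expect_gt(cor(-log10(mine$p + 1e-300), -log10(et$table$PValue + 1e-300)),
            0.95)
  expect_gt(mean(mine$call == call_e), 0.9)
})
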