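test_that("sim_config validates its invariants", {
  expect_error(sim_config(cluster_spec = data.frame(
    label = "a", fraction = 0.5, effect = 0)), "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(nuc_spacing = c(WT = -5, MUT = 100)), "positive")
  expect_error(sim_config(decoy_frac = 1), "decoy_frac")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(seed = 9, n_peaks = 123, decoy_frac = 0.25,
                    nuc_spacing = c(WT = 110, MUT = 90))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    seed = 9, n_peaks = 123, decoy_frac = 0.25,
    nuc_spacing = list(WT = 110, MUT = 90),
    cluster_spec = list(
      list(label = "unchanged", fraction = 0.823, effect = 0),
      list(label = "gain", fraction = 0.052, effect = 1.5),
      list(label = "loss", fraction = 0.125, effect = -1.5)
    )
  ), path)
  got <- read_sim_config(path)
  expect_equal(got$n_peaks, cfg$n_peaks)
  expect_equal(got$nuc_spacing, cfg$nuc_spacing)
  expect_equal(got$cluster_spec$fraction, cfg$cluster_spec$fraction)
})

test_that("generators are deterministic given the config seed", {
  cfg <- sim_config(seed = 5, n_peaks = 200, n_fragments = 2000,
                    n_interactions = 300, n_bg_anchors = 50)
  expect_identical(simulate_peak_counts(cfg), simulate_peak_counts(cfg))
  g <- simulate_genes(cfg, n_genes = 50)
  expect_identical(g, simulate_genes(cfg, n_genes = 50))
  sim <- simulate_peak_counts(cfg)
  marks <- simulate_marks_and_features(cfg, sim$peaks, g$tss, sim$truth)
  expect_identical(marks,
                   simulate_marks_and_features(cfg, sim$peaks, g$tss,
                                               sim$truth))
  fr <- simulate_fragments(cfg, marks$motifs, "WT")
  expect_identical(fr, simulate_fragments(cfg, marks$motifs, "WT"))
  feat <- labeled_features(40, c("A", "B"), cfg$chrom_len)
  expect_identical(simulate_interactions(cfg, feat),
                   simulate_interactions(cfg, feat))
})

test_that("generator streams are independent of one another", {
  cfg <- sim_config(seed = 5, n_peaks = 200, n_fragments = 2000)
  sim1 <- simulate_peak_counts(cfg)
  # interleaving another generator must not perturb the counts stream
  invisible(simulate_genes(cfg, n_genes = 20))
  expect_identical(simulate_peak_counts(cfg), sim1)
})

test_that("a global-null config marks every peak non-differential", {
  cfg <- sim_config(seed = 2, n_peaks = 500, cluster_spec = data.frame(
    label = "unchanged", fraction = 1, effect = 0))
  sim <- simulate_peak_counts(cfg)
  expect_false(any(sim$truth$differential))
  expect_true(all(sim$truth$effect == 0))
})

test_that("planted count effects realize the configured fold change", {
  cfg <- sim_config(seed = 3, n_peaks = 10000)
  sim <- simulate_peak_counts(cfg)
  f <- mean(sim$lib_sizes) / sim$lib_sizes
  norm <- sweep(sim$counts, 2, f, `*`)
  is_wt <- sim$samples$condition == "WT"
  l2 <- log2((rowMeans(norm[, !is_wt]) + 0.5) / (rowMeans(norm[, is_wt]) + 0.5))
  loss <- sim$truth$label == "loss"
  gain <- sim$truth$label == "gain"
  expect_lt(abs(mean(l2[loss]) - (-1.5)), 0.1)
  expect_lt(abs(mean(l2[gain]) - 1.5), 0.1)
  expect_lt(abs(mean(l2[sim$truth$label == "unchanged"])), 0.05)
})

test_that("fragment lengths follow the mixture and dyads sit at offsets", {
  cfg <- sim_config(seed = 4, n_fragments = 20000,
                    frag_len_mix = data.frame(mean = 200, sd = 10, weight = 1))
  motifs <- interval_set("chr1", seq(5e5, 9.5e6, by = 1e5) - 3,
                         seq(5e5, 9.5e6, by = 1e5) + 4)
  fr <- simulate_fragments(cfg, motifs, "WT")
  # single component mean 200 sd 10: essentially all mass within +/-4 sd
  expect_gt(mean(fr$length >= 160 & fr$length <= 240), 0.99)
  # planted dyads: histogram maxima at motif +/- 120
  centers <- interval_midpoint(motifs)
  prof <- dyad_profile(fr, motifs, window = 300)
  up <- prof$offsets[prof$offsets < 0][which.max(prof$density[prof$offsets < 0])]
  dn <- prof$offsets[prof$offsets > 0][which.max(prof$density[prof$offsets > 0])]
  expect_lt(abs(up + 120), 6)
  expect_lt(abs(dn - 120), 6)
  # dyad is the floor midpoint of the written coordinates
  expect_identical(fr$dyad, fr$start + (fr$end - fr$start) %/% 2L)
})

test_that("n_fragments = 0 yields an empty fragment set", {
  cfg <- sim_config(seed = 1, n_fragments = 0)
  motifs <- interval_set("chr1", 1000, 1010)
  fr <- simulate_fragments(cfg, motifs, "WT")
  expect_equal(nrow(fr), 0)
})

test_that("mark generation respects the taxonomy configuration", {
  cfg0 <- sim_config(seed = 6, n_peaks = 400, active_frac = 0)
  sim <- simulate_peak_counts(cfg0)
  g <- simulate_genes(cfg0, n_genes = 100)
  marks0 <- simulate_marks_and_features(cfg0, sim$peaks, g$tss, sim$truth)
  expect_equal(nrow(marks0$k27ac), 0)
  cls <- classify_enhancers(marks0$k4me, marks0$k4me3, marks0$k27ac, g$tss)
  expect_false(any(cls$class %in% c("active_enhancer", "super_enhancer")))
  # the tangent cutoff responds to the score tail: heavier tails (smaller
  # Pareto exponent) concentrate density in fewer extreme regions, so the
  # called super-enhancer set becomes smaller and more exclusive
  n_super <- vapply(c(3, 1.2, 0.6), function(alpha) {
    cfg <- sim_config(seed = 6, n_peaks = 400, k27ac_tail_alpha = alpha)
    m <- simulate_marks_and_features(cfg, sim$peaks, g$tss, sim$truth)
    cl <- classify_enhancers(m$k4me, m$k4me3, m$k27ac, g$tss)
    sum(cl$class == "super_enhancer")
  }, 0)
  expect_true(all(diff(n_super) <= 0))
  expect_lt(n_super[3], n_super[1])
  expect_gt(n_super[3], 0)
})

test_that("interaction decoys are produced at the configured fraction", {
  feat <- local({
    set.seed(31)
    labeled_features(80, c("A", "B"), 1e7)
  })
  cfg <- sim_config(seed = 8, n_interactions = 2000, decoy_frac = 0.3,
                    n_bg_anchors = 100)
  si <- simulate_interactions(cfg, feat)
  expect_equal(mean(si$truth$decoy), 0.3, tolerance = 0.01)
  kept <- filter_interactions(si$interactions)
  frac_kept <- nrow(kept) / nrow(si$interactions)
  # binomial error around the 0.7 retention target
  expect_lt(abs(frac_kept - 0.7), 3 * sqrt(0.3 * 0.7 / nrow(si$interactions)))
  # retained set equals a brute-force filter on span and UMI equality
  span <- ifelse(si$interactions$chrom1 == si$interactions$chrom2,
                 abs(floor((si$interactions$start2 + si$interactions$end2) / 2) -
                       floor((si$interactions$start1 + si$interactions$end1) / 2)),
                 NA)
  manual <- !is.na(span) & span >= 5000 & span <= 1e6 &
    si$interactions$umi1 == si$interactions$umi2
  expect_equal(nrow(kept), sum(manual))
})

test_that("simulated files round-trip through the package readers", {
  cfg <- sim_config(seed = 10, n_peaks = 100, n_interactions = 200,
                    n_bg_anchors = 30)
  sim <- simulate_peak_counts(cfg)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(sim$peaks, bed)
  back <- read_bed(bed)
  expect_identical(back$start, sim$peaks$start)
  expect_identical(back$end, sim$peaks$end)
  feat <- local({ set.seed(11); labeled_features(60, c("A", "B"), 1e7) })
  si <- simulate_interactions(cfg, feat)
  pe <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(si$interactions, pe)
  back2 <- read_bedpe(pe)
  expect_identical(back2$start1, si$interactions$start1)
  expect_identical(back2$umi2, si$interactions$umi2)
})
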