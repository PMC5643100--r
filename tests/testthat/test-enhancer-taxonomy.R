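test_that("promoter-proximal H3K4me1 is excluded from the enhancer class", {
  tss <- interval_set("chr1", 10000, 10001, name = "geneA", strand = "+")
  k4me3 <- interval_set("chr1", 500000, 501000)
  k27ac <- interval_set("chr1", 1, 2)[0, ]
  near <- interval_set("chr1", 10501, 11501)   # 500 bp from the TSS
  far <- interval_set("chr1", 50000, 51000)    # well beyond 1 kb
  cls <- classify_enhancers(rbind(near, far), k4me3, k27ac, tss)
  expect_equal(nrow(cls), 1)
  expect_equal(cls$start, 50000L)
  expect_equal(cls$class, "poised_enhancer")
})

test_that("H3K27ac overlap separates poised from active enhancers", {
  tss <- interval_set("chr1", 1, 2, name = "geneA", strand = "+")
  k4me3 <- interval_set("chr2", 1, 2)
  k4me <- interval_set("chr1", c(50000, 80000), c(51000, 81000))
  k27ac <- interval_set("chr1", 80500, 80600, score = 10)
  cls <- classify_enhancers(k4me, k4me3, k27ac, tss)
  expect_equal(cls$class[cls$start == 50000], "poised_enhancer")
  expect_equal(cls$class[cls$start == 80000], "active_enhancer")
  expect_equal(cls$score[cls$start == 80000], 10)
})

test_that("classification matches brute-force rule evaluation", {
  set.seed(21)
  tss_pos <- sample.int(1e5, 20)
  tss <- interval_set("chr1", tss_pos, tss_pos + 1,
                      name = sprintf("g%02d", 1:20), strand = "+")
  k4me <- random_intervals(60, chrom_len = 1e5)
  k4me3 <- random_intervals(15, chrom_len = 1e5)
  k27ac <- random_intervals(25, chrom_len = 1e5)
  k27ac$score <- runif(25, 1, 5)
  cls <- classify_enhancers(k4me, k4me3, k27ac, tss)
  gapdist <- function(s1, e1, s2, e2) {
    # bp strictly between two 0-based half-open intervals (0 if they touch
    # or overlap)
    pmax(0, pmax(s2 - e1, s1 - e2))
  }
  for (i in seq_len(nrow(k4me))) {
    d_t <- min(gapdist(k4me$start[i], k4me$end[i], tss$start, tss$end))
    d_k <- min(gapdist(k4me$start[i], k4me$end[i], k4me3$start, k4me3$end))
    is_enh <- d_t > 1000 && d_k > 1000
    in_cls <- any(cls$start == k4me$start[i] & cls$end == k4me$end[i])
    expect_equal(in_cls, is_enh)
    if (is_enh) {
      has_k27 <- any(k27ac$start < k4me$end[i] & k27ac$end > k4me$start[i])
      row <- cls[cls$start == k4me$start[i] & cls$end == k4me$end[i], ]
      expect_equal(row$class != "poised_enhancer", has_k27)
    }
  }
})

test_that("widening the exclusion radius can only shrink the enhancer set", {
  set.seed(22)
  tss_pos <- sample.int(1e5, 15)
  tss <- interval_set("chr1", tss_pos, tss_pos + 1,
                      name = sprintf("g%02d", 1:15), strand = "+")
  k4me <- random_intervals(50, chrom_len = 1e5)
  k4me3 <- random_intervals(10, chrom_len = 1e5)
  k27ac <- random_intervals(10, chrom_len = 1e5)
  n <- vapply(c(500, 1000, 2000, 5000), function(r)
    nrow(classify_enhancers(k4me, k4me3, k27ac, tss, tss_exclusion = r)), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("tangent cutoff on constructed curves", {
  # one extreme outlier: only it exceeds unit slope
  s <- call_super_enhancers(c(1, 1, 1, 1, 100))
  expect_equal(which(s$super), 5)
  expect_equal(s$cutoff_rank, 4)
  # an exactly linear curve has slope 1 everywhere: nothing is called
  lin <- call_super_enhancers(seq(2, 20, by = 2))
  expect_equal(sum(lin$super), 0)
  expect_warning(eq <- call_super_enhancers(rep(3, 5)), "equal")
  expect_equal(sum(eq$super), 0)
  expect_error(call_super_enhancers(c(1, 2)), "length")
})

test_that("tangent cutoff equals the exhaustive slope-scan oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:300, 1)
    scores <- switch(sample(3, 1),
                     exp(rnorm(n, 0, 1.5)),
                     runif(n)^(-1 / runif(1, 0.5, 3)),
                     cumsum(rexp(n)))
    got <- call_super_enhancers(scores)
    expect_equal(got$super, oracle_super(scores))
  }
})

test_that("the super-enhancer set is an upper set of the score ranking", {
  set.seed(24)
  for (rep in 1:10) {
    scores <- exp(rnorm(100, 0, 2))
    s <- call_super_enhancers(scores)
    if (any(s$super)) {
      min_super <- min(scores[s$super])
      expect_true(all(s$super[scores > min_super]))
    }
  }
})

test_that("element labels partition sites and match the brute-force oracle", {
  cfg <- sim_config(seed = 25)
  g <- simulate_genes(cfg, n_genes = 60)
  elements <- make_gene_elements(g$genes)
  set.seed(26)
  sites <- random_intervals(300, chrom_len = 1e6,
                            chroms = c("chr1", "chr2"), max_width = 500)
  lab <- annotate_elements(sites, elements)
  expect_equal(lab, oracle_element_label(sites, elements))
  expect_equal(sum(table(lab)), nrow(sites))
})

test_that("element enrichment is near 1 for background-drawn sites and exact for point masses", {
  cfg <- sim_config(seed = 27)
  g <- simulate_genes(cfg, n_genes = 100)
  elements <- make_gene_elements(g$genes)
  set.seed(28)
  pos <- sample.int(cfg$chrom_len - 1000, 2000)
  bg <- interval_set(sample(c("chr1", "chr2"), 2000, TRUE), pos, pos + 300)
  enr_self <- element_enrichment(bg, elements, bg)
  expect_true(all(abs(enr_self$log2_ratio) < 0.01))
  expect_equal(sum(enr_self$observed), nrow(bg))
  # all sites inside one category
  prom <- elements$promoter[1:20, ]
  enr_p <- element_enrichment(prom, elements, bg)
  expect_equal(enr_p$observed[enr_p$category == "promoter"], 20L)
  expect_equal(sum(enr_p$observed), 20L)
  expect_gt(enr_p$log2_ratio[enr_p$category == "promoter"],
            max(enr_p$log2_ratio[enr_p$category != "promoter"]))
})
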