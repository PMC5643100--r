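test_that("interval validation names the offending record", {
  expect_error(interval_set("chr1", 10, 10), "record 1")
  expect_error(interval_set(c("chr1", ""), c(0, 5), c(10, 15)), "record 2")
  expect_error(interval_set("chr1", -1, 5), "record 1")
  expect_silent(validate_intervals(interval_set("chr1", 0, 1)))
})

test_that("merge_intervals handles empty and singleton sets", {
  empty <- interval_set(character(), integer(), integer())
  expect_equal(nrow(merge_intervals(empty, gap = 1000)), 0)
  one <- interval_set("chr1", 100, 200)
  m <- merge_intervals(one, gap = 1000)
  expect_equal(m[, c("chrom", "start", "end")],
               one[, c("chrom", "start", "end")])
})

test_that("merge_intervals joins at the gap boundary", {
  # 1 bp between [0,5) and [6,10): merged at gap 1, kept apart at gap 0
  x <- interval_set("chr1", c(0, 6), c(5, 10))
  expect_equal(nrow(merge_intervals(x, gap = 0)), 2)
  expect_equal(merge_intervals(x, gap = 1)[, c("start", "end")],
               data.frame(start = 0L, end = 10L))
})

test_that("merge_intervals matches the per-bp occupancy oracle", {
  set.seed(101)
  for (rep in 1:10) {
    x <- random_intervals(200, chrom_len = 1e5, chroms = c("chr1", "chr2"))
    gap <- sample(c(0, 10, 1000), 1)
    got <- merge_intervals(x, gap = gap)
    want <- oracle_merge(x, gap)
    expect_equal(got[, c("chrom", "start", "end")], want)
  }
})

test_that("merge_intervals is idempotent and order-invariant", {
  set.seed(7)
  x <- random_intervals(100)
  m1 <- merge_intervals(x, gap = 500)
  expect_equal(merge_intervals(m1, gap = 500), m1)
  xp <- x[sample.int(nrow(x)), ]
  expect_equal(merge_intervals(xp, gap = 500), m1)
})

test_that("overlap_sets classifies self-overlap and disjoint sets", {
  a <- interval_set("chr1", c(0, 100), c(50, 150))
  self <- overlap_sets(a, a)
  expect_equal(self$proportion, 1.0)
  expect_equal(self$band, "high")
  b <- interval_set("chr1", c(500, 600), c(550, 650))
  dis <- overlap_sets(a, b)
  expect_equal(dis$proportion, 0.0)
  expect_equal(dis$band, "low")
  expect_error(overlap_sets(a[0, ], b), "undefined")
})

test_that("overlap_sets matches the quadratic oracle and is monotone in b", {
  set.seed(13)
  a <- random_intervals(500)
  b <- random_intervals(500)
  got <- overlap_sets(a, b)
  expect_equal(got$hits, oracle_overlap_hits(a, b))
  expect_equal(got$proportion, mean(oracle_overlap_hits(a, b)))
  # growing b can only increase the proportion
  b2 <- rbind(b, random_intervals(200))
  expect_gte(overlap_sets(a, b2)$proportion, got$proportion)
  expect_true(got$proportion >= 0 && got$proportion <= 1)
})

test_that("nearest_tss distances, signs, ties and the distal boundary", {
  tss <- interval_set("chr1", c(1000, 5000), c(1001, 5001),
                      strand = c("+", "-"), name = c("geneA", "geneB"))
  # site midpoint exactly at a TSS
  at <- nearest_tss(interval_set("chr1", 990, 1010), tss)
  expect_equal(at$distance, 0L)
  expect_false(at$distal)
  # 3001 bp away from the only TSS on its chromosome -> distal
  tss1 <- interval_set("chr1", 0, 1, name = "geneA", strand = "+")
  far <- nearest_tss(interval_set("chr1", 3000, 3002), tss1)
  expect_equal(far$distance, 3001L)
  expect_true(far$distal)
  expect_false(nearest_tss(interval_set("chr1", 2999, 3001), tss1)$distal)
  # sign follows gene orientation: downstream positive
  minus <- nearest_tss(interval_set("chr1", 4000, 4200), tss)  # mid 4100
  expect_equal(minus$gene, "geneB")
  expect_equal(minus$distance, 900L)  # left of a - TSS is downstream
  # equidistant ties resolve to the lexicographically smaller gene id
  tie_tss <- interval_set("chr1", c(100, 300), c(101, 301),
                          strand = "+", name = c("geneZ", "geneA"))
  tie <- nearest_tss(interval_set("chr1", 195, 205), tie_tss)
  expect_equal(tie$gene, "geneA")
  # unannotated chromosome flagged, not dropped
  un <- nearest_tss(interval_set("chrX", 0, 10), tss)
  expect_true(un$unannotated)
  expect_true(is.na(un$gene))
})

test_that("nearest_tss matches exhaustive search and ignores far TSSs", {
  set.seed(17)
  sites <- random_intervals(300, chrom_len = 1e5)
  pos <- sample.int(1e5, 50)
  tss <- interval_set("chr1", pos, pos + 1,
                      strand = sample(c("+", "-"), 50, TRUE),
                      name = sprintf("g%03d", sample.int(999, 50)))
  got <- nearest_tss(sites, tss)
  want <- oracle_nearest(sites, tss)
  expect_equal(got$gene, want[, 1])
  expect_equal(got$distance, as.integer(want[, 2]))
  # adding TSSs farther than the current nearest changes nothing
  far <- interval_set("chr1", 9e5 + seq_len(20) * 1000,
                      9e5 + seq_len(20) * 1000 + 1,
                      strand = "+", name = sprintf("far%02d", 1:20))
  got2 <- nearest_tss(sites, rbind(tss, far))
  expect_equal(got2$gene, got$gene)
  expect_equal(got2$distance, got$distance)
})

test_that("BED round-trips reproduce coordinates exactly", {
  set.seed(23)
  x <- random_intervals(50)
  x$name <- sprintf("iv%02d", seq_len(50))
  x$score <- round(runif(50, 0, 100), 3)
  x$strand <- sample(c("+", "-", "."), 50, TRUE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_identical(y$chrom, x$chrom)
  expect_identical(y$start, x$start)
  expect_identical(y$end, x$end)
  expect_identical(y$strand, x$strand)
  expect_equal(y$score, x$score)
  expect_identical(y$name, x$name)
})

test_that("readers tolerate comment and track lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=\"demo\"",
               "chr1\t0\t100", "chr2\t50\t80"), path)
  x <- read_bed(path)
  expect_equal(nrow(x), 2)
  expect_equal(x$start, c(0L, 50L))
})

test_that("BEDPE round-trips in both UMI dialects", {
  x <- data.frame(
    chrom1 = "chr1", start1 = c(1000L, 2000L), end1 = c(1200L, 2200L),
    chrom2 = "chr1", start2 = c(50000L, 70000L), end2 = c(50200L, 70200L),
    name = ".", score = c(1.5, NA), strand1 = ".", strand2 = ".",
    umi1 = c("AACD", "BBCA"), umi2 = c("AACD", "BBCC"),
    stringsAsFactors = FALSE
  )
  for (dialect in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".bedpe")
    write_bedpe(x, path, umi_columns = dialect)
    y <- read_bedpe(path)
    expect_equal(y$start1, x$start1)
    expect_equal(y$end2, x$end2)
    expect_equal(y$umi1, x$umi1)
    expect_equal(y$umi2, x$umi2)
  }
})

test_that("bedGraph writer emits a track header and the bins", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph("chr1", c(0, 10), c(10, 20), c(1.5, 0), path, name = "cov")
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(length(lines), 3)
})
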