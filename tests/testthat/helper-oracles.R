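# Independent brute-force oracles and small fixture generators. These are
# deliberately naive (per-bp occupancy scans, quadratic loops, exhaustive
# searches) so they share no code path with the implementation they check.

random_intervals <- function(n, chrom_len = 1e5, chroms = "chr1",
                             max_width = 2000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(chrom, start, start + width)
}

# Per-bp occupancy merge: mark covered positions, dilate gaps <= gap by
# joining runs, read the runs back off.
oracle_merge <- function(x, gap, chrom_len = 1e5 + 5000) {
  out <- list()
  for (chrom in sort(unique(x$chrom))) {
    xi <- x[x$chrom == chrom, ]
    occ <- logical(chrom_len)
    for (r in seq_len(nrow(xi))) occ[(xi$start[r] + 1):xi$end[r]] <- TRUE
    runs <- rle(occ)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    cov <- which(runs$values)
    if (length(cov) == 0) next
    merged <- list(c(starts[cov[1]], ends[cov[1]]))
    for (k in cov[-1]) {
      last <- merged[[length(merged)]]
      if (starts[k] - last[2] - 1 <= gap)
        merged[[length(merged)]][2] <- ends[k]
      else merged[[length(merged) + 1]] <- c(starts[k], ends[k])
    }
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = vapply(merged, `[`, 0, 1) - 1L,
      end = vapply(merged, `[`, 0, 2),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Quadratic pairwise bp-intersection scan.
oracle_overlap_hits <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, TRUE)
}

# Exhaustive nearest-TSS search with the same tie rule (smaller gene id).
oracle_nearest <- function(sites, tss) {
  mids <- floor((sites$start + sites$end) / 2)
  t(vapply(seq_len(nrow(sites)), function(i) {
    idx <- which(tss$chrom == sites$chrom[i])
    if (length(idx) == 0) return(c(NA_character_, NA_character_))
    d <- abs(tss$start[idx] - mids[i])
    cand <- idx[d == min(d)]
    j <- cand[order(tss$name[cand])][1]
    signed <- mids[i] - tss$start[j]
    if (tss$strand[j] == "-") signed <- -signed
    c(tss$name[j], as.character(signed))
  }, c("", "")))
}

# Brute-force tag-density binning.
oracle_tag_density <- function(peaks, fragments, window = 500, bin = 10,
                               lib_size = nrow(fragments), per = 1e7) {
  nb <- (2 * window) %/% bin
  centers <- floor((peaks$start + peaks$end) / 2)
  m <- matrix(0, nrow(peaks), nb)
  for (p in seq_len(nrow(peaks))) {
    for (f in seq_len(nrow(fragments))) {
      if (fragments$chrom[f] != peaks$chrom[p]) next
      off <- fragments$dyad[f] - (centers[p] - window)
      if (off >= 0 && off < 2 * window)
        m[p, off %/% bin + 1] <- m[p, off %/% bin + 1] + 1
    }
  }
  m / (lib_size / per)
}

# Exhaustive tangent-cutoff search: evaluate the discrete slope at every
# consecutive pair of the ascending unit-rescaled curve, take the first
# exceeding 1, call everything above it.
oracle_super <- function(scores) {
  n <- length(scores)
  ord <- order(scores, seq_len(n))
  s <- scores[ord]
  if (max(s) == min(s)) return(rep(FALSE, n))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  cut <- NA
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) > 1) { cut <- i; break }
  }
  super <- rep(FALSE, n)
  if (!is.na(cut)) super[ord[(cut + 1):n]] <- TRUE
  super
}

# Brute-force primary element labeling with the documented priority.
oracle_element_label <- function(sites, elements) {
  vapply(seq_len(nrow(sites)), function(i) {
    for (cat in names(elements)) {
      el <- elements[[cat]]
      hit <- any(el$chrom == sites$chrom[i] & el$start < sites$end[i] &
                   el$end > sites$start[i])
      if (hit) return(cat)
    }
    "intergenic"
  }, "")
}

# Two planted profile shapes (narrow gain-like vs broad loss-like) with
# multiplicative amplitude variation and additive noise.
two_shape_matrix <- function(n_per = 500, noise = 0.05, n_bins = 100) {
  shape1 <- dnorm(seq(-50, 49), 0, 12)
  shape2 <- dnorm(seq(-50, 49), 0, 30) * 2
  m <- rbind(
    t(replicate(n_per, shape1 * runif(1, 5, 15) + rnorm(n_bins, 0, noise))),
    t(replicate(n_per, shape2 * runif(1, 5, 15) + rnorm(n_bins, 0, noise)))
  )
  list(m = m, truth = rep(1:2, each = n_per))
}

# Feature layout for interaction tests: equal-sized labeled categories at
# random positions on one chromosome.
labeled_features <- function(n_per_cat, cats, chrom_len, margin = 2e5) {
  do.call(rbind, lapply(cats, function(lab) {
    pos <- sort(sample.int(chrom_len - 2 * margin, n_per_cat) + margin)
    data.frame(chrom = "chr1", start = pos - 100, end = pos + 100,
               label = lab, stringsAsFactors = FALSE)
  }))
}
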