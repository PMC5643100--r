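# Edge-to-edge bp distance from each interval of `x` to the nearest
# interval of `y` (Inf when y has nothing on that chromosome).
nearest_distance <- function(x, y) {
  if (nrow(x) == 0) return(numeric(0))
  if (nrow(y) == 0) return(rep(Inf, nrow(x)))
  # absent chromosomes are handled below (distance Inf); silence the
  # seqlevel-mismatch warning GRanges emits for them
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(as_granges(x), as_granges(y),
                                     ignore.strand = TRUE))
  d <- rep(Inf, nrow(x))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  d
}

#' Classify enhancers from histone-mark region sets
#'
#' An enhancer is an H3K4me1 region whose nearest TSS and nearest H3K4me3
#' region are both more than `tss_exclusion` bp away (promoter-proximal
#' H3K4me1 is excluded). Enhancers without any H3K27ac overlap (>= 1 bp)
#' are `poised_enhancer`; the rest are `active_enhancer`, and the
#' exceptional top of the active class by H3K27ac tag density is carved
#' out as `super_enhancer` by [call_super_enhancers()]. The per-enhancer
#' H3K27ac density score is the sum of scores of overlapping H3K27ac
#' intervals (total overlap width in kb when the mark set carries no
#' scores).
#'
#' @param k4me,k4me3,k27ac Stitched mark region sets (interval data
#'   frames); `k27ac` may carry tag-density scores.
#' @param tss TSS annotation (interval data frame).
#' @param tss_exclusion Minimum distance (bp) from TSS and H3K4me3;
#'   regions at or below it are dropped from the enhancer class.
#' @return Interval data frame of enhancers with columns `class`,
#'   `score` (H3K27ac density), `dist_tss`, `dist_k4me3`.
#' @export
classify_enhancers <- function(k4me, k4me3, k27ac, tss,
                               tss_exclusion = 1000) {
  validate_intervals(k4me)
  validate_intervals(k4me3)
  validate_intervals(k27ac)
  empty <- cbind(complete_intervals(data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer())),
                 data.frame(class = character(), dist_tss = numeric(),
                            dist_k4me3 = numeric(), stringsAsFactors = FALSE))
  if (nrow(k4me) == 0) return(empty)
  d_tss <- nearest_distance(k4me, tss)
  d_k4me3 <- nearest_distance(k4me, k4me3)
  keep <- d_tss > tss_exclusion & d_k4me3 > tss_exclusion
  enh <- complete_intervals(k4me[keep, , drop = FALSE])
  if (nrow(enh) == 0) return(empty)
  enh$dist_tss <- d_tss[keep]
  enh$dist_k4me3 <- d_k4me3[keep]
  if (nrow(k27ac) > 0) {
    hit <- GenomicRanges::findOverlaps(as_granges(enh), as_granges(k27ac),
                                       ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hit)
    si <- S4Vectors::subjectHits(hit)
    k27 <- complete_intervals(k27ac)
    sc <- k27$score[si]
    if (all(is.na(k27$score))) {
      ov_w <- GenomicRanges::width(IRanges::pintersect(
        as_granges(enh)[qi], as_granges(k27)[si]))
      sc <- ov_w / 1000
    }
    dens <- rep(0, nrow(enh))
    if (length(qi) > 0) {
      agg <- tapply(sc, qi, sum, na.rm = TRUE)
      dens[as.integer(names(agg))] <- as.numeric(agg)
    }
    has_k27 <- seq_len(nrow(enh)) %in% qi
  } else {
    dens <- rep(0, nrow(enh))
    has_k27 <- rep(FALSE, nrow(enh))
  }
  enh$score <- dens
  enh$class <- ifelse(has_k27, "active_enhancer", "poised_enhancer")
  active <- which(enh$class == "active_enhancer")
  if (length(active) >= 3) {
    se <- call_super_enhancers(enh$score[active])
    enh$class[active[se$super]] <- "super_enhancer"
  }
  rownames(enh) <- NULL
  enh
}

#' Super-enhancer calling by the rank-curve tangent cutoff
#'
#' Regions are ranked ascending by score; rank and score are rescaled to
#' the unit square and the cutoff is the ranked point at which the
#' discrete slope between consecutive points first exceeds 1 (scanning
#' ascending). Every region above the cutoff is a super-enhancer, so the
#' called set is an upper set of the score ranking. An exactly linear
#' curve has slope identically 1 and yields no super-enhancers; all-equal
#' scores yield none, with a warning.
#'
#' @param scores Non-negative numeric vector of tag-density scores (>= 3
#'   values).
#' @return A list: `super` (logical per input element), `cutoff_rank`
#'   (ascending rank of the cutoff point, `NA` when nothing is called),
#'   `cutoff_score`.
#' @export
call_super_enhancers <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 3, all(scores >= 0))
  n <- length(scores)
  if (max(scores) == min(scores)) {
    warning("all scores equal; no super-enhancers called")
    return(list(super = rep(FALSE, n), cutoff_rank = NA_integer_,
                cutoff_score = NA_real_))
  }
  ord <- order(scores, seq_len(n))  # ascending; ties by original index
  s <- scores[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  slope <- diff(y) / diff(x)
  first <- which(slope > 1)
  if (length(first) == 0)
    return(list(super = rep(FALSE, n), cutoff_rank = NA_integer_,
                cutoff_score = NA_real_))
  cut <- first[1]  # cutoff point: rank `cut`; supers are ranks above it
  super_ranks <- ord[seq(cut + 1, n)]
  super <- rep(FALSE, n)
  super[super_ranks] <- TRUE
  list(super = super, cutoff_rank = cut, cutoff_score = s[cut])
}

#' Build a genomic-element partition from simple gene models
#'
#' Derives the standard element categories from gene bodies: promoter
#' (TSS +/- `promoter_halfwidth`), TTS (transcript end +/-
#' `tts_halfwidth`), 5' and 3' UTRs (strand-aware leading/trailing
#' segments of the gene body), exons (supplied, or synthesized as evenly
#' spaced blocks), introns (gene body minus exons/UTRs) and intergenic
#' (everything else).
#'
#' @param genes Gene-body interval data frame with strand and gene ids in
#'   `name`.
#' @param exons Optional exon interval data frame; when `NULL`, each gene
#'   body gets `n_exons` evenly spaced exon blocks.
#' @param promoter_halfwidth,tts_halfwidth Half-widths in bp.
#' @param utr5_len,utr3_len UTR lengths in bp (truncated for short
#'   genes).
#' @param n_exons Synthesized exons per gene when `exons` is `NULL`.
#' @return Named list of interval data frames, ordered by labeling
#'   priority: `promoter`, `tts`, `utr5`, `utr3`, `exon`, `intron`.
#' @export
make_gene_elements <- function(genes, exons = NULL,
                               promoter_halfwidth = 1000,
                               tts_halfwidth = 1000,
                               utr5_len = 200, utr3_len = 300,
                               n_exons = 3) {
  validate_intervals(genes)
  genes <- complete_intervals(genes)
  plus <- genes$strand != "-"
  tss_pos <- ifelse(plus, genes$start, genes$end - 1L)
  tts_pos <- ifelse(plus, genes$end - 1L, genes$start)
  promoter <- interval_set(genes$chrom, pmax(0L, tss_pos - promoter_halfwidth),
                           tss_pos + promoter_halfwidth)
  tts <- interval_set(genes$chrom, pmax(0L, tts_pos - tts_halfwidth),
                      tts_pos + tts_halfwidth)
  gl <- genes$end - genes$start
  u5 <- pmin(utr5_len, pmax(1L, gl %/% 10L))
  u3 <- pmin(utr3_len, pmax(1L, gl %/% 10L))
  utr5 <- interval_set(genes$chrom,
                       ifelse(plus, genes$start, genes$end - u5),
                       ifelse(plus, genes$start + u5, genes$end))
  utr3 <- interval_set(genes$chrom,
                       ifelse(plus, genes$end - u3, genes$start),
                       ifelse(plus, genes$end, genes$start + u3))
  if (is.null(exons)) {
    ex <- list()
    for (g in seq_len(nrow(genes))) {
      inner_start <- genes$start[g] + u5[g]
      inner_end <- genes$end[g] - u3[g]
      if (inner_end - inner_start < 2 * n_exons) next
      w <- (inner_end - inner_start) %/% (2 * n_exons)
      es <- inner_start + (seq_len(n_exons) - 1) * 2 * w
      ex[[g]] <- data.frame(chrom = genes$chrom[g], start = es,
                            end = es + w, stringsAsFactors = FALSE)
    }
    exdf <- do.call(rbind, ex)
    if (is.null(exdf))
      exdf <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
    exons <- complete_intervals(exdf)
  }
  intron <- merge_intervals(genes)  # introns resolved by priority order
  list(promoter = promoter, tts = tts, utr5 = utr5, utr3 = utr3,
       exon = sort_intervals(complete_intervals(exons)), intron = intron)
}

#' Assign a primary genomic-element label to each site
#'
#' Sites are labeled by >= 1 bp overlap under the fixed priority
#' `promoter > tts > utr5 > utr3 > exon > intron > intergenic` (the gene
#' body stands in for introns at the lowest gene-derived priority, so any
#' gene-body overlap not claimed by a higher category resolves to
#' intron). Every site receives exactly one primary label, so label
#' counts partition the site set.
#'
#' @param sites Interval data frame.
#' @param elements Named list of category interval sets in priority order
#'   (see [make_gene_elements()]).
#' @return Character vector of primary labels (with `"intergenic"` for
#'   unclaimed sites).
#' @export
annotate_elements <- function(sites, elements) {
  validate_intervals(sites)
  lab <- rep(NA_character_, nrow(sites))
  if (nrow(sites) == 0) return(lab)
  sg <- as_granges(sites)
  for (cat in names(elements)) {
    el <- elements[[cat]]
    if (nrow(el) == 0) next
    hit <- IRanges::overlapsAny(sg, as_granges(el), ignore.strand = TRUE)
    lab[is.na(lab) & hit] <- cat
  }
  lab[is.na(lab)] <- "intergenic"
  lab
}

#' Observed/expected enrichment of sites over genomic elements
#'
#' Each site (and each background interval) gets one primary element
#' label via [annotate_elements()]; `observed` is the per-category site
#' count and `expected` is `|sites|` times the background category
#' fraction. The ratio carries a pseudocount of 0.5 on both numerator and
#' denominator so empty categories stay finite.
#'
#' @param sites Interval data frame of query sites.
#' @param elements Element annotation (named list, priority order).
#' @param background Interval data frame of the comparison universe
#'   (typically all accessible sites).
#' @return Data frame: `category`, `observed`, `expected`, `log2_ratio`.
#' @export
element_enrichment <- function(sites, elements, background) {
  validate_intervals(sites)
  validate_intervals(background)
  if (nrow(sites) == 0) stop("no query sites")
  if (nrow(background) == 0) stop("empty background")
  cats <- c(names(elements), "intergenic")
  site_lab <- factor(annotate_elements(sites, elements), levels = cats)
  bg_lab <- factor(annotate_elements(background, elements), levels = cats)
  observed <- as.integer(table(site_lab))
  expected <- nrow(sites) * as.integer(table(bg_lab)) / nrow(background)
  data.frame(
    category = cats,
    observed = observed,
    expected = expected,
    log2_ratio = log2((observed + 0.5) / (expected + 0.5)),
    stringsAsFactors = FALSE
  )
}
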