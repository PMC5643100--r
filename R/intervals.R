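#' Construct an interval set
#'
#' An interval set is a plain `data.frame` with columns `chrom`, `start`,
#' `end`, `strand`, `score`, `name`, using 0-based half-open coordinates.
#' All higher-level functions in the package accept and return this shape.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open `[start, end)`.
#' @param strand Strand per interval, one of `"+"`, `"-"`, `"."`.
#' @param score Optional numeric score (`NA` when absent).
#' @param name Optional label (`NA` when absent).
#' @return A validated interval `data.frame`.
#' @examples
#' interval_set("chr1", c(100, 500), c(200, 900))
#' @export
interval_set <- function(chrom, start, end, strand = ".", score = NA_real_,
                         name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    score = rep_len(as.numeric(score), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval set
#'
#' Checks the interval-set invariants: non-empty chromosome names,
#' `start >= 0`, `end > start`, strand in `{+, -, .}` and no NaN scores.
#' The error message names the first offending record.
#'
#' @param x Interval `data.frame`.
#' @return `x`, invisibly, if valid.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("interval set is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | x$chrom == "")
  if (length(bad) > 0)
    stop("record ", bad[1], ": empty chromosome name")
  bad <- which(is.na(x$start) | x$start < 0)
  if (length(bad) > 0)
    stop("record ", bad[1], ": start must be >= 0 (got ", x$start[bad[1]], ")")
  bad <- which(is.na(x$end) | x$end <= x$start)
  if (length(bad) > 0)
    stop("record ", bad[1], ": end must exceed start (",
         x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")")
  if ("strand" %in% names(x)) {
    bad <- which(!x$strand %in% c("+", "-", "."))
    if (length(bad) > 0)
      stop("record ", bad[1], ": invalid strand '", x$strand[bad[1]], "'")
  }
  if ("score" %in% names(x)) {
    bad <- which(is.nan(x$score))
    if (length(bad) > 0)
      stop("record ", bad[1], ": NaN score")
  }
  invisible(x)
}

# Fill optional columns so downstream code can rely on the full shape.
complete_intervals <- function(x) {
  if (!"strand" %in% names(x)) x$strand <- rep(".", nrow(x))
  if (!"score" %in% names(x)) x$score <- rep(NA_real_, nrow(x))
  if (!"name" %in% names(x)) x$name <- rep(NA_character_, nrow(x))
  x
}

#' Sort an interval set by (chrom, start, end)
#'
#' @param x Interval `data.frame`.
#' @return The sorted data frame, row names reset.
#' @export
sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# 0-based half-open data frame -> 1-based closed GRanges.
as_granges <- function(x) {
  x <- complete_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

granges_to_intervals <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(s == "*", ".", s),
    score = NA_real_,
    name = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Interval midpoints
#'
#' Midpoint of `[start, end)` as `floor((start + end) / 2)`, the convention
#' used for peak centers, fragment dyads and anchor positions throughout.
#'
#' @param x Interval `data.frame`.
#' @return Integer vector of midpoints (0-based positions).
#' @export
interval_midpoint <- function(x) {
  as.integer(floor((as.numeric(x$start) + as.numeric(x$end)) / 2))
}

#' Merge intervals closer than or equal to a gap
#'
#' Produces the minimal set of disjoint intervals covering the input in
#' which any two intervals separated by at most `gap` bp are joined.
#' `gap = 0` gives the plain union; `gap = 1000` reproduces the stitching
#' used to assemble ChIP-seq regions from nearby peaks. Idempotent and
#' invariant under permutation of the input.
#'
#' @param x Interval `data.frame`.
#' @param gap Non-negative bp; intervals with at most this many bp strictly
#'   between them are merged.
#' @return Sorted interval `data.frame` of disjoint merged intervals
#'   (strand and scores are dropped).
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(length(gap) == 1, gap >= 0)
  validate_intervals(x)
  if (nrow(x) == 0) return(complete_intervals(x[0, , drop = FALSE]))
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1,
                              ignore.strand = TRUE)
  sort_intervals(granges_to_intervals(gr))
}

#' Overlap report between two interval sets
#'
#' An interval of `a` counts as overlapping if it shares at least one bp
#' with any interval of `b`. The set-level proportion `hits / |a|` is
#' classified into bands: `"high"` at proportion >= 0.5, `"low"` at <= 0.1,
#' `"intermediate"` otherwise.
#'
#' @param a,b Interval `data.frame`s.
#' @return A list with `hits` (logical per interval of `a`), `n_hits`,
#'   `proportion` and `band`.
#' @export
overlap_sets <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0)
    stop("overlap proportion is undefined for an empty query set")
  if (nrow(b) == 0) {
    hits <- rep(FALSE, nrow(a))
  } else {
    hits <- IRanges::overlapsAny(as_granges(a), as_granges(b),
                                 ignore.strand = TRUE)
  }
  prop <- mean(hits)
  band <- if (prop >= 0.5) "high" else if (prop <= 0.1) "low" else "intermediate"
  list(hits = hits, n_hits = sum(hits), proportion = prop, band = band)
}

#' Annotate sites with their nearest TSS
#'
#' Distance is measured from the site midpoint to the TSS bp and signed in
#' the gene's orientation: positive when the site lies downstream of the
#' TSS (to the right for `+` genes, to the left for `-` genes). Sites more
#' than `distal_cutoff` bp from the nearest TSS are flagged distal. Ties at
#' equal absolute distance are broken toward the lexicographically smaller
#' gene id, making assignments reproducible. Sites on chromosomes absent
#' from the annotation are flagged `unannotated` rather than dropped.
#'
#' @param sites Interval `data.frame` of query sites.
#' @param tss Interval `data.frame` of single-bp TSS records (`end ==
#'   start + 1`) with gene ids in `name` and strand set.
#' @param distal_cutoff Distal flag threshold in bp (default 3000).
#' @return A data frame with one row per site: `gene`, `distance` (signed),
#'   `distal`, `unannotated`.
#' @export
nearest_tss <- function(sites, tss, distal_cutoff = 3000) {
  validate_intervals(sites)
  validate_intervals(tss)
  tss <- complete_intervals(tss)
  if (nrow(tss) == 0 || any(is.na(tss$name)))
    stop("TSS annotation must be non-empty and carry gene ids in 'name'")
  if (any(tss$end != tss$start + 1L))
    stop("TSS records must be single-bp (end == start + 1)")
  n <- nrow(sites)
  out <- data.frame(
    gene = rep(NA_character_, n),
    distance = rep(NA_integer_, n),
    distal = rep(NA, n),
    unannotated = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(out)
  mids <- interval_midpoint(sites)
  tss_by_chrom <- split(seq_len(nrow(tss)), tss$chrom)
  for (i in seq_len(n)) {
    idx <- tss_by_chrom[[sites$chrom[i]]]
    if (is.null(idx)) {
      out$unannotated[i] <- TRUE
      next
    }
    d_abs <- abs(tss$start[idx] - mids[i])
    dmin <- min(d_abs)
    cand <- idx[d_abs == dmin]
    j <- cand[order(tss$name[cand])][1]
    signed <- mids[i] - tss$start[j]
    if (tss$strand[j] == "-") signed <- -signed
    out$gene[i] <- tss$name[j]
    out$distance[i] <- as.integer(signed)
    out$distal[i] <- dmin > distal_cutoff
  }
  out
}
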