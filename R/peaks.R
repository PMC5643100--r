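#' Call peaks from per-bp coverage with a local-background filter
#'
#' Fixed-width sliding windows are tested against a local background
#' estimated from the flanking regions. A window is kept when its count
#' exceeds `fold_local` times the library-scaled local background (the
#' per-bp mean over `flank` bp on either side, floored at the
#' chromosome-global rate so empty flanks cannot promote isolated counts).
#' In `chip` mode an input track is required and windows must additionally
#' exceed `fold_input` times the library-scaled input count and pass a
#' Poisson upper-tail test at BH-FDR `fdr` against the local rate. Kept
#' windows are merged with gap 0 (`atac`) or 1000 bp (`chip`), mirroring
#' the stitching used to build ChIP regions from nearby peaks.
#'
#' @param signal_coverage Named list of per-bp numeric coverage vectors,
#'   one per chromosome.
#' @param input_coverage Optional input/control coverage in the same
#'   shape; required for `mode = "chip"`.
#' @param mode `"atac"` (local filter only) or `"chip"` (local + input +
#'   Poisson FDR).
#' @param window,step Window width and step in bp.
#' @param flank Local-background flank size in bp on each side.
#' @param fold_local,fold_input Enrichment thresholds.
#' @param fdr BH-FDR threshold for the Poisson test (`chip` mode).
#' @return Interval data frame of merged peaks; `score` holds
#'   `-log10(q)` of the best window in each peak (capped at 350).
#' @export
call_peaks <- function(signal_coverage, input_coverage = NULL,
                       mode = c("atac", "chip"), window = 500, step = 100,
                       flank = 10000, fold_local = 4, fold_input = 2,
                       fdr = 0.001) {
  mode <- match.arg(mode)
  stopifnot(is.list(signal_coverage), length(signal_coverage) > 0)
  if (mode == "chip" && is.null(input_coverage))
    stop("mode 'chip' requires an input coverage track")
  sig_total <- sum(vapply(signal_coverage, sum, 0))
  inp_total <- if (!is.null(input_coverage))
    sum(vapply(input_coverage, sum, 0)) else NA_real_
  win <- list()
  for (chrom in names(signal_coverage)) {
    cov <- signal_coverage[[chrom]]
    L <- length(cov)
    if (L < window) next
    cs <- c(0, cumsum(cov))
    starts <- seq(0L, L - window, by = step)
    wcount <- cs[starts + window + 1] - cs[starts + 1]
    lo <- pmax(0L, starts - flank)
    hi <- pmin(L, starts + window + flank)
    flank_count <- (cs[hi + 1] - cs[lo + 1]) - wcount
    flank_len <- (hi - lo) - window
    local_rate <- ifelse(flank_len > 0, flank_count / flank_len, 0)
    lambda <- pmax(local_rate, sum(cov) / L) * window
    keep <- wcount > fold_local * lambda
    if (mode == "chip") {
      icov <- input_coverage[[chrom]]
      if (is.null(icov)) stop("input coverage missing for ", chrom)
      ics <- c(0, cumsum(icov))
      icount <- ics[pmin(length(icov), starts + window) + 1] -
        ics[pmin(length(icov), starts) + 1]
      keep <- keep & wcount > fold_input * icount * (sig_total / inp_total)
    }
    p <- stats::ppois(wcount - 1, lambda, lower.tail = FALSE)
    win[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + window, p = p, keep = keep,
                               stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, win)
  empty <- complete_intervals(data.frame(chrom = character(),
                                         start = integer(), end = integer()))
  if (is.null(win) || nrow(win) == 0) return(empty)
  win$q <- bh_adjust(win$p)
  if (mode == "chip") win$keep <- win$keep & win$q < fdr
  win <- win[win$keep, , drop = FALSE]
  if (nrow(win) == 0) return(empty)
  gap <- if (mode == "chip") 1000 else 0
  peaks <- merge_intervals(win[, c("chrom", "start", "end")], gap = gap)
  hit <- GenomicRanges::findOverlaps(as_granges(win), as_granges(peaks))
  best <- tapply(win$q[S4Vectors::queryHits(hit)],
                 S4Vectors::subjectHits(hit), min)
  peaks$score <- pmin(350, -log10(as.numeric(best)[match(
    seq_len(nrow(peaks)), as.integer(names(best)))]))
  peaks
}

#' Count fragment midpoints in peaks
#'
#' A fragment is counted in a peak when its midpoint (dyad) lies within
#' the half-open peak interval; each fragment counts at most once per
#' sample (first peak by position when peaks overlap). Library size is the
#' total number of fragments in the sample.
#'
#' @param peaks Interval data frame.
#' @param fragments Named list of fragment data frames, one per sample
#'   (see [simulate_fragments()]).
#' @param samples Optional sample data frame (`sample`, `condition`,
#'   `replicate`); defaults to the list names with unknown condition.
#' @return A count-matrix list: `peaks`, `counts`, `samples`,
#'   `lib_sizes`.
#' @export
count_in_peaks <- function(peaks, fragments, samples = NULL) {
  validate_intervals(peaks)
  stopifnot(is.list(fragments), length(fragments) > 0)
  if (is.null(names(fragments)))
    names(fragments) <- paste0("sample_", seq_along(fragments))
  peaks <- sort_intervals(peaks)
  pg <- as_granges(peaks)
  counts <- matrix(0L, nrow(peaks), length(fragments),
                   dimnames = list(peaks$name, names(fragments)))
  for (s in seq_along(fragments)) {
    fr <- fragments[[s]]
    if (nrow(fr) == 0) next
    dg <- GenomicRanges::GRanges(fr$chrom,
                                 IRanges::IRanges(fr$dyad + 1L, fr$dyad + 1L))
    hit <- GenomicRanges::findOverlaps(dg, pg, select = "first")
    tab <- table(hit[!is.na(hit)])
    counts[as.integer(names(tab)), s] <- as.integer(tab)
  }
  if (is.null(samples))
    samples <- data.frame(sample = names(fragments),
                          condition = NA_character_,
                          replicate = NA_integer_, stringsAsFactors = FALSE)
  list(peaks = peaks, counts = counts, samples = samples,
       lib_sizes = vapply(fragments, nrow, 0L))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over the standard BH procedure (with monotonicity
#' enforcement) so every FDR correction in the package goes through one
#' audited entry point.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Moderated common dispersion: median of per-peak method-of-moments
# dispersion estimates on library-size-normalized counts, floored at 0.01.
estimate_common_dispersion <- function(norm_counts, cond, floor = 0.01) {
  conds <- unique(cond)
  num <- 0; den <- 0
  ss <- matrix(0, nrow(norm_counts), length(conds))
  mm <- matrix(0, nrow(norm_counts), length(conds))
  nn <- integer(length(conds))
  for (k in seq_along(conds)) {
    idx <- which(cond == conds[k])
    nn[k] <- length(idx)
    mm[, k] <- rowMeans(norm_counts[, idx, drop = FALSE])
    ss[, k] <- apply(norm_counts[, idx, drop = FALSE], 1, stats::var)
  }
  if (all(nn < 2)) return(floor)
  w <- pmax(nn - 1, 0)
  pooled_var <- as.vector(ss %*% w) / sum(w)
  grand_mean <- rowMeans(norm_counts)
  phi <- (pooled_var - grand_mean) / grand_mean^2
  phi <- phi[is.finite(phi) & grand_mean > 0]
  if (length(phi) == 0) return(floor)
  max(stats::median(phi), floor)
}

# Two-sided NB exact-style p-value conditioning on the total of the two
# condition sums: outcomes with probability <= the observed outcome's.
nb_exact_p <- function(sa, total, n_a, n_b, phi) {
  if (total == 0) return(1)
  mu0 <- total / (n_a + n_b)
  k <- 0:total
  if (phi > 1e-8) {
    la <- stats::dnbinom(k, size = n_a / phi, mu = n_a * mu0, log = TRUE)
    lb <- stats::dnbinom(total - k, size = n_b / phi, mu = n_b * mu0, log = TRUE)
  } else {
    la <- stats::dpois(k, n_a * mu0, log = TRUE)
    lb <- stats::dpois(total - k, n_b * mu0, log = TRUE)
  }
  lp <- la + lb
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[sa + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Replicate-aware differential accessibility test
#'
#' Per-peak negative-binomial exact-style test with a single moderated
#' common dispersion (median of method-of-moments per-peak dispersions on
#' library-size-normalized counts, floored at 0.01), conditioning on the
#' total of the two condition sums. Log2 fold changes are computed from
#' library-size-normalized condition means with a pseudocount of 0.5, and
#' peaks are called `up` / `down` when `|log2FC| >= log2(fc_threshold)`
#' and the BH q-value is below `fdr`, `unchanged` otherwise. With a single
#' replicate per condition the test degenerates to a conditional Poisson
#' (binomial) test, with a warning, as a documented lower-power mode.
#'
#' @param cm Count-matrix list (see [count_in_peaks()] or
#'   [simulate_peak_counts()]).
#' @param cond_a,cond_b Condition labels; fold changes are `cond_b`
#'   versus `cond_a`.
#' @param fc_threshold Fold-change call threshold (linear scale).
#' @param fdr BH-FDR call threshold.
#' @return Data frame with one row per peak: `chrom`, `start`, `end`,
#'   `log2fc`, `p`, `q`, `call`.
#' @export
differential_peaks <- function(cm, cond_a, cond_b, fc_threshold = 1.5,
                               fdr = 0.05) {
  stopifnot(all(c("peaks", "counts", "samples", "lib_sizes") %in% names(cm)))
  cond <- cm$samples$condition
  if (!cond_a %in% cond) stop("condition '", cond_a, "' not found")
  if (!cond_b %in% cond) stop("condition '", cond_b, "' not found")
  if (any(cm$lib_sizes <= 0)) stop("zero library size")
  use <- cond %in% c(cond_a, cond_b)
  counts <- cm$counts[, use, drop = FALSE]
  cond <- cond[use]
  lib <- cm$lib_sizes[use]
  f <- mean(lib) / lib
  norm <- sweep(counts, 2, f, `*`)
  ia <- which(cond == cond_a)
  ib <- which(cond == cond_b)
  if (length(ia) < 2 || length(ib) < 2) {
    warning("single replicate in at least one condition; ",
            "falling back to a conditional Poisson test (lower power)")
    phi <- 0
  } else {
    phi <- estimate_common_dispersion(norm, cond)
  }
  ma <- rowMeans(norm[, ia, drop = FALSE])
  mb <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  sa <- round(rowSums(norm[, ia, drop = FALSE]))
  sb <- round(rowSums(norm[, ib, drop = FALSE]))
  total <- sa + sb
  p <- vapply(seq_along(sa), function(i)
    nb_exact_p(sa[i], total[i], length(ia), length(ib), phi), 0)
  q <- bh_adjust(p)
  thr <- log2(fc_threshold)
  call <- ifelse(log2fc >= thr & q < fdr, "up",
                 ifelse(log2fc <= -thr & q < fdr, "down", "unchanged"))
  out <- cm$peaks[, c("chrom", "start", "end")]
  out$name <- cm$peaks$name
  out$log2fc <- log2fc
  out$p <- p
  out$q <- q
  out$call <- call
  rownames(out) <- NULL
  out
}

#' Write a differential result as TSV
#'
#' @param res Result of [differential_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(res, path) {
  write_tsv(res[, c("chrom", "start", "end", "log2fc", "p", "q", "call")],
            path)
}
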