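interaction_span <- function(x) {
  mid1 <- floor((as.numeric(x$start1) + as.numeric(x$end1)) / 2)
  mid2 <- floor((as.numeric(x$start2) + as.numeric(x$end2)) / 2)
  ifelse(x$chrom1 == x$chrom2, abs(mid2 - mid1), NA_real_)
}

#' Filter raw interactions by span and UMI agreement
#'
#' Keeps intra-chromosomal pairs whose anchor-midpoint span lies in
#' `[min_span, max_span]` (inclusive) and, when `require_umi_match` is
#' set, whose two ends carry the same UMI barcode.
#'
#' @param x Interaction data frame (BEDPE columns plus `umi1`, `umi2`).
#' @param min_span,max_span Inclusive span bounds in bp.
#' @param require_umi_match Drop pairs whose UMIs differ.
#' @param dedupe_umi Additionally keep at most one interaction per
#'   (chrom1, mid1, chrom2, mid2, UMI) combination.
#' @return The filtered interaction data frame with a `span` column.
#' @export
filter_interactions <- function(x, min_span = 5000, max_span = 1e6,
                                require_umi_match = TRUE,
                                dedupe_umi = FALSE) {
  span <- interaction_span(x)
  keep <- !is.na(span) & span >= min_span & span <= max_span
  if (require_umi_match)
    keep <- keep & !is.na(x$umi1) & !is.na(x$umi2) & x$umi1 == x$umi2
  out <- x[keep, , drop = FALSE]
  out$span <- span[keep]
  if (dedupe_umi && nrow(out) > 0) {
    key <- paste(out$chrom1, floor((out$start1 + out$end1) / 2),
                 out$chrom2, floor((out$start2 + out$end2) / 2), out$umi1)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assign interaction endpoints to feature categories
#'
#' Every endpoint gets every category whose nearest feature lies within
#' `radius` bp, measured midpoint-to-midpoint (anchor midpoint to feature
#' midpoint). Endpoints matching no category stay in the endpoint
#' universe as unassigned potential interaction end-points, which is what
#' the permutation null randomizes over.
#'
#' @param x Filtered interaction data frame.
#' @param catalog Named list of feature interval data frames, one per
#'   category.
#' @param radius Assignment radius in bp.
#' @return A list: `endpoints` (unique anchors with `chrom`, `mid`),
#'   `membership` (endpoints x categories logical matrix), `pairs`
#'   (per-interaction endpoint indices `e1`, `e2`), `categories`.
#' @export
assign_endpoints <- function(x, catalog, radius = 3000) {
  stopifnot(is.list(catalog), length(catalog) > 0,
            !is.null(names(catalog)))
  n <- nrow(x)
  mid1 <- floor((as.numeric(x$start1) + as.numeric(x$end1)) / 2)
  mid2 <- floor((as.numeric(x$start2) + as.numeric(x$end2)) / 2)
  all_chrom <- c(x$chrom1, x$chrom2)
  all_mid <- c(mid1, mid2)
  key <- paste0(all_chrom, ":", all_mid)
  ukey <- !duplicated(key)
  endpoints <- data.frame(chrom = all_chrom[ukey], mid = all_mid[ukey],
                          stringsAsFactors = FALSE)
  idx <- match(key, key[ukey])
  pairs <- data.frame(e1 = idx[seq_len(n)], e2 = idx[n + seq_len(n)])
  membership <- matrix(FALSE, nrow(endpoints), length(catalog),
                       dimnames = list(NULL, names(catalog)))
  for (cat in names(catalog)) {
    feat <- catalog[[cat]]
    if (nrow(feat) == 0) next
    fm <- interval_midpoint(feat)
    by_chrom <- split(fm, feat$chrom)
    for (chrom in names(by_chrom)) {
      ei <- which(endpoints$chrom == chrom)
      if (length(ei) == 0) next
      pos <- sort(by_chrom[[chrom]])
      j <- findInterval(endpoints$mid[ei], pos)
      d_lo <- ifelse(j >= 1, abs(endpoints$mid[ei] - pos[pmax(j, 1)]), Inf)
      d_hi <- ifelse(j < length(pos),
                     abs(pos[pmin(j + 1, length(pos))] - endpoints$mid[ei]),
                     Inf)
      membership[ei, cat] <- pmin(d_lo, d_hi) <= radius
    }
  }
  list(endpoints = endpoints, membership = membership, pairs = pairs,
       categories = names(catalog))
}

count_pairs <- function(m, pairs, cat_pairs) {
  m1 <- m[pairs$e1, , drop = FALSE]
  m2 <- m[pairs$e2, , drop = FALSE]
  vapply(seq_len(nrow(cat_pairs)), function(r) {
    a <- cat_pairs$a[r]; b <- cat_pairs$b[r]
    sum((m1[, a] & m2[, b]) | (m1[, b] & m2[, a]))
  }, 0)
}

#' Pairwise interaction enrichment against a label-permutation null
#'
#' For every unordered category pair (A, B), `observed` is the number of
#' interactions with one endpoint labeled A and the other labeled B
#' (counted once per interaction). The expectation comes from `n_perm`
#' permutations in which the endpoint label sets are shuffled uniformly
#' across all potential interaction end-points — the interaction graph
#' and the label multiset stay fixed, only which endpoint carries which
#' labels is randomized. The log2 ratio uses a pseudocount of 0.5 on both
#' observed and expected; a permutation z-score and upper-tail empirical
#' p-value are reported per pair.
#'
#' @param assigned Result of [assign_endpoints()].
#' @param n_perm Number of permutations (>= 10).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame: `cat_a`, `cat_b`, `observed`, `expected_mean`,
#'   `expected_sd`, `log2_ratio`, `z`, `p_emp`; attributes `n_perm` and
#'   `seed`.
#' @export
pairwise_enrichment <- function(assigned, n_perm = 1000, seed = 1) {
  if (n_perm < 10) stop("n_perm must be at least 10 for a usable null")
  m <- assigned$membership
  pairs <- assigned$pairs
  cats <- assigned$categories
  if (!any(m[pairs$e1, , drop = FALSE]) || !any(m[pairs$e2, , drop = FALSE]))
    stop("no assigned category on at least one interaction side")
  grid <- expand.grid(ai = seq_along(cats), bi = seq_along(cats))
  grid <- grid[grid$ai <= grid$bi, ]
  cat_pairs <- data.frame(a = cats[grid$ai], b = cats[grid$bi],
                          stringsAsFactors = FALSE)
  observed <- count_pairs(m, pairs, cat_pairs)
  ne <- nrow(m)
  perm_counts <- matrix(0, n_perm, nrow(cat_pairs))
  with_local_seed(seed, {
    for (p in seq_len(n_perm)) {
      mp <- m[sample.int(ne), , drop = FALSE]
      perm_counts[p, ] <- count_pairs(mp, pairs, cat_pairs)
    }
  })
  exp_mean <- colMeans(perm_counts)
  exp_sd <- apply(perm_counts, 2, stats::sd)
  out <- data.frame(
    cat_a = cat_pairs$a,
    cat_b = cat_pairs$b,
    observed = observed,
    expected_mean = exp_mean,
    expected_sd = exp_sd,
    log2_ratio = log2((observed + 0.5) / (exp_mean + 0.5)),
    z = ifelse(exp_sd > 0, (observed - exp_mean) / exp_sd, NA_real_),
    p_emp = vapply(seq_along(observed), function(i)
      (1 + sum(perm_counts[, i] >= observed[i])) / (n_perm + 1), 0),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Symmetric observed-count lookup from an enrichment table
#'
#' @param enrichment Result of [pairwise_enrichment()].
#' @param a,b Category names (order-free).
#' @return The matching row of the table.
#' @export
enrichment_pair <- function(enrichment, a, b) {
  hit <- (enrichment$cat_a == a & enrichment$cat_b == b) |
    (enrichment$cat_a == b & enrichment$cat_b == a)
  enrichment[hit, , drop = FALSE]
}
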