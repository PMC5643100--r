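#' Tag-density matrix around peak centers
#'
#' Bins fragment midpoints into fixed-width bins relative to each peak
#' center (default +/-500 bp in 10 bp bins, i.e. a 1000 bp window) and
#' normalizes to fragments per 10 million: bin `b` of peak `p` counts
#' midpoints in `[center + b*bin - window, center + (b+1)*bin - window)`,
#' divided by `library size / 1e7`.
#'
#' @param peaks Interval data frame; centers are interval midpoints.
#' @param fragments Fragment data frame (needs `chrom` and `dyad`).
#' @param window Half-window in bp.
#' @param bin Bin width in bp; must divide `2 * window`.
#' @param lib_size Library size; defaults to `nrow(fragments)`.
#' @param per Normalization denominator unit (default 1e7).
#' @return Numeric matrix (peaks x bins) with attributes `window`, `bin`,
#'   `offsets` (bin left edges relative to center).
#' @export
tag_density <- function(peaks, fragments, window = 500, bin = 10,
                        lib_size = NULL, per = 1e7) {
  validate_intervals(peaks)
  stopifnot((2 * window) %% bin == 0)
  if (is.null(lib_size)) lib_size <- nrow(fragments)
  nb <- (2 * window) %/% bin
  centers <- interval_midpoint(peaks)
  m <- matrix(0, nrow(peaks), nb,
              dimnames = list(peaks$name, NULL))
  attr(m, "window") <- window
  attr(m, "bin") <- bin
  attr(m, "offsets") <- seq(-window, window - bin, by = bin)
  if (nrow(fragments) == 0 || lib_size == 0) return(m)
  wg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(centers - window + 1L,
                                                centers + window))
  dg <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$dyad + 1L,
                                                fragments$dyad + 1L))
  hit <- GenomicRanges::findOverlaps(dg, wg)
  if (length(hit) > 0) {
    pi <- S4Vectors::subjectHits(hit)
    di <- S4Vectors::queryHits(hit)
    off <- fragments$dyad[di] - (centers[pi] - window)
    bidx <- off %/% bin + 1L
    ok <- bidx >= 1 & bidx <= nb
    lin <- pi[ok] + (bidx[ok] - 1L) * nrow(peaks)
    cnt <- tabulate(lin, nbins = nrow(peaks) * nb)
    m[] <- m + cnt
  }
  res <- m / (lib_size / per)
  attr(res, "window") <- window
  attr(res, "bin") <- bin
  attr(res, "offsets") <- attr(m, "offsets")
  res
}

# Row-standardize for the centered-correlation metric: subtract the row
# mean, scale to unit norm. Zero-variance rows come back as all-NA.
standardize_rows <- function(m) {
  c_m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(c_m^2))
  out <- c_m / nrm
  out[nrm == 0, ] <- NA_real_
  list(x = out, zero_var = nrm == 0)
}

#' k-means with the centered-correlation similarity metric
#'
#' Lloyd iterations under the distance `1 - r`, with `r` the Pearson
#' correlation of mean-centered rows. Rows are standardized (centered,
#' unit norm) so the distance becomes half the squared Euclidean distance
#' to a unit-norm centroid, and the minimizing centroid of a cluster is
#' its standardized mean profile; the within-cluster objective is
#' therefore non-increasing across iterations. Initialization is
#' k-means++-style and fully determined by `seed`. Zero-variance rows have
#' distance 1 to every centroid; they are assigned to the largest cluster,
#' with a warning.
#'
#' @param m Numeric matrix (rows = peaks, columns = profile bins), e.g. a
#'   [tag_density()] matrix or a per-condition concatenation.
#' @param k Number of clusters (>= 1, <= number of rows).
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @param nstart Number of independent initializations; the run with the
#'   lowest final objective is kept (Lloyd converges to local optima, so
#'   several restarts are standard practice).
#' @return A list: `cluster` (per-row id in 1..k), `centers` (k x ncol
#'   mean raw profiles), `objective` (per-iteration within-cluster
#'   `1 - r` sum), `iterations`, `converged`, `k`, `seed`.
#' @export
kmeans_centered_correlation <- function(m, k, seed = 1, max_iter = 300,
                                        nstart = 10) {
  stopifnot(is.matrix(m), nrow(m) >= 1, nstart >= 1)
  if (k > nrow(m)) stop("k exceeds the number of rows")
  if (k < 1) stop("k must be at least 1")
  std <- standardize_rows(m)
  usable <- which(!std$zero_var)
  if (length(usable) < k)
    stop("fewer non-degenerate rows than clusters")
  x <- std$x[usable, , drop = FALSE]
  n <- nrow(x)

  one_run <- function() {
    # k-means++ seeding in the 1 - r metric
    centers_idx <- sample.int(n, 1)
    if (k > 1) {
      for (c in 2:k) {
        sim <- x %*% t(x[centers_idx, , drop = FALSE])
        d2 <- apply(1 - sim, 1, min)
        d2 <- pmax(d2, 0)^2
        if (sum(d2) == 0)
          centers_idx <- c(centers_idx, sample.int(n, 1))
        else
          centers_idx <- c(centers_idx, sample.int(n, 1, prob = d2))
      }
    }
    cent <- x[centers_idx, , drop = FALSE]
    assign_prev <- rep(0L, n)
    objective <- numeric(0)
    converged <- FALSE
    iter <- 0
    while (iter < max_iter) {
      iter <- iter + 1
      sim <- x %*% t(cent)
      assign <- max.col(sim, ties.method = "first")
      objective <- c(objective, sum(1 - sim[cbind(seq_len(n), assign)]))
      if (identical(assign, assign_prev)) {
        converged <- TRUE
        break
      }
      assign_prev <- assign
      for (c in seq_len(k)) {
        idx <- which(assign == c)
        if (length(idx) == 0) next
        mu <- colMeans(x[idx, , drop = FALSE])
        mu <- mu - mean(mu)
        nm <- sqrt(sum(mu^2))
        if (nm > 0) cent[c, ] <- mu / nm
      }
      # re-seed emptied clusters at the worst-fitting row so Lloyd cannot
      # collapse to fewer than k clusters
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) > 0) {
        fit <- sim[cbind(seq_len(n), assign)]
        for (c in empty) {
          worst <- which.min(fit)
          cent[c, ] <- x[worst, ]
          fit[worst] <- Inf
        }
      }
    }
    list(assign = assign, objective = objective, iterations = iter,
         converged = converged)
  }

  with_local_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      run <- one_run()
      if (is.null(best) ||
          tail(run$objective, 1) < tail(best$objective, 1) - 1e-12)
        best <- run
    }
    assign <- best$assign
    cluster <- integer(nrow(m))
    cluster[usable] <- assign
    if (any(std$zero_var)) {
      warning(sum(std$zero_var),
              " zero-variance row(s) assigned to the largest cluster")
      largest <- as.integer(names(which.max(table(assign))))
      cluster[std$zero_var] <- largest
    }
    centers <- t(vapply(seq_len(k), function(c) {
      idx <- which(cluster == c)
      if (length(idx) == 0) rep(NA_real_, ncol(m))
      else colMeans(m[idx, , drop = FALSE])
    }, numeric(ncol(m))))
    list(cluster = cluster, centers = centers, objective = best$objective,
         iterations = best$iterations, converged = best$converged, k = k,
         seed = seed)
  })
}

#' Build the clustering feature matrix from two conditions
#'
#' Row-wise concatenation of the reference-condition profile and the
#' per-bin log2 change profile (`log2((other + c) / (ref + c))` with a
#' small pseudocount), so the clustering sees both peak shape and its
#' condition dependence in one metric space.
#'
#' @param ref,other [tag_density()] matrices for the reference and
#'   comparison condition (same shape).
#' @param pseudocount Added to both terms of the ratio.
#' @return Numeric matrix with `2 * ncol(ref)` columns.
#' @export
clustering_features <- function(ref, other, pseudocount = 0.5) {
  stopifnot(all(dim(ref) == dim(other)))
  cbind(ref, log2((other + pseudocount) / (ref + pseudocount)))
}

#' Per-cluster average density profiles per condition
#'
#' @param assign Cluster assignment vector (as from
#'   [kmeans_centered_correlation()]`$cluster`).
#' @param matrices Named list of [tag_density()] matrices, one per
#'   condition, rows aligned with `assign`.
#' @return Long data frame: `bin_offset`, `cluster`, `condition`,
#'   `mean_density`.
#' @export
cluster_condition_profiles <- function(assign, matrices) {
  stopifnot(is.list(matrices), length(matrices) > 0)
  out <- list()
  for (cond in names(matrices)) {
    m <- matrices[[cond]]
    stopifnot(nrow(m) == length(assign))
    offs <- attr(m, "offsets")
    if (is.null(offs)) offs <- seq_len(ncol(m))
    for (c in sort(unique(assign))) {
      idx <- which(assign == c)
      out[[length(out) + 1]] <- data.frame(
        bin_offset = offs, cluster = c, condition = cond,
        mean_density = colMeans(m[idx, , drop = FALSE]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
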