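#' Co-regulated-site intersection cascade
#'
#' Sequentially intersects (>= 1 bp overlap) the decreased-accessibility
#' sites with remodeler-bound sites, then reduced-H3K27ac sites, then
#' AP-1 factor-bound sites; the surviving co-regulated sites are annotated
#' to their nearest TSS and intersected with the down-regulated gene set.
#' Stage counts are monotone non-increasing by construction and asserted.
#'
#' @param atac_down Interval data frame of decreased accessible sites.
#' @param swisnf_bound,k27ac_down,fra1_bound Interval data frames for the
#'   successive overlap filters.
#' @param de_down_genes Character vector of down-regulated gene ids.
#' @param tss TSS annotation (gene ids in `name`).
#' @return A list: `stages` (data frame of stage names and surviving
#'   counts), `sites` (list of surviving interval sets per stage), and
#'   `genes` (the final gene ids).
#' @export
coregulation_cascade <- function(atac_down, swisnf_bound, k27ac_down,
                                 fra1_bound, de_down_genes, tss) {
  validate_intervals(atac_down)
  take <- function(x, filter) {
    if (nrow(x) == 0 || nrow(filter) == 0) return(x[0, , drop = FALSE])
    x[overlap_sets(x, filter)$hits, , drop = FALSE]
  }
  s1 <- take(atac_down, swisnf_bound)
  s2 <- take(s1, k27ac_down)
  s3 <- take(s2, fra1_bound)
  genes <- character(0)
  if (nrow(s3) > 0) {
    ann <- nearest_tss(s3, tss)
    genes <- sort(intersect(unique(ann$gene[!ann$unannotated]),
                            de_down_genes))
  }
  counts <- c(nrow(atac_down), nrow(s1), nrow(s2), nrow(s3), length(genes))
  stopifnot(all(diff(counts) <= 0))
  list(
    stages = data.frame(
      stage = c("atac_down", "swisnf_bound", "k27ac_down", "fra1_bound",
                "de_down_genes"),
      count = counts,
      stringsAsFactors = FALSE
    ),
    sites = list(atac_down = atac_down, swisnf_bound = s1,
                 k27ac_down = s2, fra1_bound = s3),
    genes = genes
  )
}

#' Percentage of changed sites
#'
#' `100 * n_subset / n_total`, rounded half away from zero to `decimals`
#' places — the convention used for printed percentages of changed
#' accessible sites.
#'
#' @param n_subset,n_total Counts with `0 <= n_subset <= n_total`,
#'   `n_total > 0`.
#' @param decimals Decimal places.
#' @return The rounded percentage.
#' @export
percent_changed <- function(n_subset, n_total, decimals = 1) {
  stopifnot(n_total > 0, n_subset >= 0, n_subset <= n_total)
  x <- 100 * n_subset / n_total
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Expression fold change of top-expressed nearest genes, per cluster
#'
#' Peaks are annotated to their nearest gene; within each cluster only
#' genes in the top `top_fraction` by reference-condition expression are
#' kept, and per-gene `log2((FPKM_cond + 0.5) / (FPKM_ref + 0.5))` is
#' reported (replicate means per condition). Each cluster's distribution
#' is compared with the unchanged cluster's by a two-sided Wilcoxon
#' rank-sum test with BH correction across clusters.
#'
#' @param assign Per-peak cluster id.
#' @param peaks Interval data frame aligned with `assign`.
#' @param expr Expression list (`fpkm` matrix, `samples` data frame), as
#'   from [simulate_expression()].
#' @param tss TSS annotation.
#' @param reference,condition Condition labels (fold change is
#'   `condition` versus `reference`).
#' @param top_fraction Kept fraction of genes by reference expression.
#' @param unchanged_cluster Cluster id used as the comparison
#'   distribution; defaults to the cluster with the smallest median
#'   absolute fold change.
#' @return A list: `genes` (per-gene data frame with `cluster`, `gene`,
#'   `log2fc`) and `clusters` (per-cluster `n`, `median_log2fc`, `p`,
#'   `q`).
#' @export
expression_fold_by_cluster <- function(assign, peaks, expr, tss,
                                       reference, condition,
                                       top_fraction = 0.25,
                                       unchanged_cluster = NULL) {
  stopifnot(length(assign) == nrow(peaks), top_fraction > 0,
            top_fraction <= 1)
  ann <- nearest_tss(peaks, tss)
  samples <- expr$samples
  ref_cols <- samples$sample[samples$condition == reference]
  cond_cols <- samples$sample[samples$condition == condition]
  if (length(ref_cols) == 0 || length(cond_cols) == 0)
    stop("reference or comparison condition missing from expression table")
  ref_fpkm <- rowMeans(expr$fpkm[, ref_cols, drop = FALSE])
  cond_fpkm <- rowMeans(expr$fpkm[, cond_cols, drop = FALSE])
  per_gene <- list()
  for (c in sort(unique(assign))) {
    genes <- unique(ann$gene[assign == c & !ann$unannotated])
    genes <- genes[genes %in% rownames(expr$fpkm)]
    if (length(genes) == 0) next
    keep_n <- max(1L, ceiling(top_fraction * length(genes)))
    top <- genes[order(ref_fpkm[genes], decreasing = TRUE)][seq_len(keep_n)]
    per_gene[[length(per_gene) + 1]] <- data.frame(
      cluster = c, gene = top,
      log2fc = log2((cond_fpkm[top] + 0.5) / (ref_fpkm[top] + 0.5)),
      stringsAsFactors = FALSE
    )
  }
  gene_df <- do.call(rbind, per_gene)
  rownames(gene_df) <- NULL
  med <- tapply(gene_df$log2fc, gene_df$cluster, stats::median)
  if (is.null(unchanged_cluster))
    unchanged_cluster <- as.integer(names(which.min(abs(med))))
  base <- gene_df$log2fc[gene_df$cluster == unchanged_cluster]
  cl_ids <- sort(unique(gene_df$cluster))
  p <- vapply(cl_ids, function(c) {
    if (c == unchanged_cluster) return(NA_real_)
    x <- gene_df$log2fc[gene_df$cluster == c]
    stats::wilcox.test(x, base, exact = FALSE)$p.value
  }, 0)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  list(
    genes = gene_df,
    clusters = data.frame(
      cluster = cl_ids,
      n = as.integer(table(factor(gene_df$cluster, levels = cl_ids))),
      median_log2fc = as.numeric(med[as.character(cl_ids)]),
      p = p, q = q,
      unchanged = cl_ids == unchanged_cluster,
      stringsAsFactors = FALSE
    )
  )
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in dependency order — simulate, differential
#' accessibility, tag-density clustering, enhancer taxonomy and element
#' enrichment, nucleosome spacing, interaction enrichment, co-regulation
#' cascade — writing every stage output as TSV under `out_dir` together
#' with a machine-readable `summary.json` holding the headline counts and
#' percentages. Reruns with the same configuration are bit-identical.
#'
#' @param config A [sim_config()], or the path of a YAML file for
#'   [read_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param k Number of accessibility clusters.
#' @param n_perm Permutations for the interaction null.
#' @param verbose Print stage progress to stderr.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, k = 4, n_perm = 200,
                         verbose = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    read_sim_config(config)
  } else config
  validate_sim_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  say("simulating peak counts")
  sim <- simulate_peak_counts(cfg)
  genes <- simulate_genes(cfg)
  marks <- simulate_marks_and_features(cfg, sim$peaks, genes$tss,
                                       truth = sim$truth)
  write_bed(sim$peaks, file.path(out_dir, "peaks.bed"))

  say("differential accessibility")
  diff <- differential_peaks(sim, cfg$conditions[1], cfg$conditions[2])
  write_differential(diff, file.path(out_dir, "differential.tsv"))
  n_down <- sum(diff$call == "down")
  n_up <- sum(diff$call == "up")

  say("fragment simulation and clustering")
  frags <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
                  function(cond) simulate_fragments(cfg, marks$motifs, cond))
  td <- lapply(frags, function(fr) tag_density(sim$peaks, fr))
  feat <- clustering_features(td[[1]], td[[2]])
  km <- kmeans_centered_correlation(feat, k = k, seed = cfg$seed)
  write_tsv(cbind(sim$peaks[, c("chrom", "start", "end")],
                  cluster = km$cluster),
            file.path(out_dir, "clusters.tsv"))
  profiles <- cluster_condition_profiles(km$cluster, td)
  write_tsv(profiles, file.path(out_dir, "cluster_profiles.tsv"))

  say("enhancer taxonomy and element enrichment")
  enh <- classify_enhancers(merge_intervals(marks$k4me, gap = 1000),
                            merge_intervals(marks$k4me3, gap = 1000),
                            marks$k27ac, genes$tss)
  write_tsv(enh[, c("chrom", "start", "end", "class", "score")],
            file.path(out_dir, "enhancers.tsv"))
  elements <- make_gene_elements(genes$genes)
  down_sites <- diff[diff$call == "down", c("chrom", "start", "end")]
  enr <- if (nrow(down_sites) > 0)
    element_enrichment(down_sites, elements,
                       sim$peaks[, c("chrom", "start", "end")]) else NULL
  if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "element_enrichment.tsv"))

  say("nucleosome spacing")
  spacing <- lapply(frags, function(fr) {
    mono <- select_mononucleosome(fr)
    estimate_spacing(dyad_profile(mono, marks$motifs, bandwidth = 10))
  })
  sp <- spacing_delta(spacing, reference = cfg$conditions[1])
  write_tsv(sp, file.path(out_dir, "nucleosome_spacing.tsv"))

  say("interaction enrichment")
  catalog <- list(
    atac_down = diff[diff$call == "down", ],
    atac_up = diff[diff$call == "up", ],
    k27ac_down = marks$k27ac_down,
    tss = genes$tss
  )
  catalog <- Filter(function(f) nrow(f) > 0, catalog)
  features <- do.call(rbind, lapply(names(catalog), function(cat) {
    f <- catalog[[cat]][, c("chrom", "start", "end")]
    f$label <- cat
    f
  }))
  ints <- simulate_interactions(cfg, features)
  kept <- filter_interactions(ints$interactions)
  assigned <- assign_endpoints(kept, catalog)
  enrich <- pairwise_enrichment(assigned, n_perm = n_perm, seed = cfg$seed)
  write_tsv(enrich, file.path(out_dir, "interaction_enrichment.tsv"))

  say("co-regulation cascade")
  exprs <- simulate_expression(cfg, genes$tss$name,
                               log2fc = sample_gene_effects(cfg, genes$tss$name))
  de <- gene_differential(exprs)
  cascade <- coregulation_cascade(
    diff[diff$call == "down", ], marks$swisnf, marks$k27ac_down,
    marks$fra1, de$down, genes$tss
  )
  write_tsv(cascade$stages, file.path(out_dir, "cascade.tsv"))

  summary <- list(
    seed = cfg$seed,
    n_peaks = nrow(sim$peaks),
    n_down = n_down,
    n_up = n_up,
    pct_down = percent_changed(n_down, nrow(sim$peaks)),
    pct_up = percent_changed(n_up, nrow(sim$peaks)),
    k = k,
    cluster_sizes = as.integer(table(factor(km$cluster, levels = 1:k))),
    n_enhancers = nrow(enh),
    n_super_enhancers = sum(enh$class == "super_enhancer"),
    spacing = stats::setNames(sp$spacing, sp$condition),
    spacing_delta = stats::setNames(sp$delta_vs_reference, sp$condition),
    n_interactions_kept = nrow(kept),
    cascade_counts = stats::setNames(cascade$stages$count,
                                     cascade$stages$stage),
    pct_cascade_bound = if (nrow(down_sites) > 0)
      percent_changed(cascade$stages$count[2], cascade$stages$count[1],
                      decimals = 0) else NA
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# Per-gene planted expression effects: genes nearest to loss peaks tend
# down, gain peaks up; used only by the pipeline demo.
sample_gene_effects <- function(cfg, gene_ids) {
  with_local_seed(derive_seed(cfg$seed, "gene_effects"), {
    n <- length(gene_ids)
    eff <- numeric(n)
    idx <- sample.int(n, round(0.3 * n))
    eff[idx] <- sample(c(-1.5, 1.5), length(idx), replace = TRUE,
                       prob = c(0.7, 0.3))
    eff
  })
}

# Minimal DE gene caller on the FPKM table: 1.5-fold replicate-mean rule.
gene_differential <- function(exprs, fc = 1.5) {
  s <- exprs$samples
  conds <- unique(s$condition)
  m1 <- rowMeans(exprs$fpkm[, s$sample[s$condition == conds[1]], drop = FALSE])
  m2 <- rowMeans(exprs$fpkm[, s$sample[s$condition == conds[2]], drop = FALSE])
  l2 <- log2((m2 + 0.5) / (m1 + 0.5))
  list(down = rownames(exprs$fpkm)[l2 <= -log2(fc)],
       up = rownames(exprs$fpkm)[l2 >= log2(fc)],
       log2fc = l2)
}
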