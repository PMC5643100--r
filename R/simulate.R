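#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' encode the study conditions the pipeline is meant to emulate: a
#' two-condition, two-replicate accessibility experiment in which 12.5% of
#' accessible sites lose and 5.2% gain accessibility at a planted effect of
#' +/-1.5 log2 units; an ATAC-like fragment-length mixture with a
#' sub-nucleosomal and a mononucleosomal mode; flanking-nucleosome dyads
#' planted at +/-120 bp (reference) versus +/-101 bp (mutant) around motif
#' centers (a 38 bp spacing reduction); and feature-anchored interactions
#' carrying unique molecular identifiers.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param n_chrom,chrom_len Number and length (bp) of toy chromosomes.
#' @param n_peaks Number of accessible peaks.
#' @param cluster_spec Data frame with columns `label`, `fraction`,
#'   `effect` (log2 effect applied to condition 2); fractions must sum
#'   to 1.
#' @param frag_len_mix Data frame with columns `mean`, `sd`, `weight`
#'   describing the fragment-length mixture; weights must sum to 1.
#'   Components with mean >= 180 bp are treated as mononucleosomal.
#' @param nuc_spacing Named numeric vector of per-condition flanking dyad
#'   offsets (bp, positive) around motif centers.
#' @param dyad_sd Gaussian sd (bp) of planted dyad positions.
#' @param dyad_background Fraction of mononucleosome fragments placed
#'   uniformly instead of at planted offsets.
#' @param n_fragments Fragments per simulated sample.
#' @param n_interactions Valid interactions to generate.
#' @param umi_alphabet_size,umi_length Alphabet size and length of UMI
#'   barcodes.
#' @param dispersion Negative-binomial dispersion of replicate counts.
#' @param base_mean,base_sdlog Log-normal parameters of per-peak baseline
#'   intensity.
#' @param peak_width Range (bp) of simulated peak widths.
#' @param lib_factor_range Range of per-sample library-size factors.
#' @param conditions Names of the two conditions (reference first).
#' @param enhancer_frac Fraction of distal peaks given an H3K4me1 region.
#' @param active_frac Fraction of enhancers given H3K27ac (active class).
#' @param k27ac_tail_alpha Pareto tail exponent of H3K27ac scores; smaller
#'   values give heavier tails and more super-enhancer-like outliers.
#' @param motif_frac Fraction of peaks carrying a TF motif site.
#' @param promoter_k4me_frac Fraction of TSSs with promoter-proximal
#'   H3K4me1 (excluded from the enhancer class by the classifier).
#' @param swisnf_frac_loss,swisnf_frac_other Probability that a
#'   loss-class / other peak is remodeler-bound.
#' @param k27acdown_frac_cascade,k27acdown_frac_other Probability of
#'   reduced H3K27ac given (loss and bound) / otherwise.
#' @param fra1_frac_cascade,fra1_frac_other Probability of AP-1 factor
#'   binding given (loss, bound, K27ac-down) / otherwise.
#' @param enrich_pairs Data frame (`cat_a`, `cat_b`, `factor`) of planted
#'   pairwise interaction enrichments; empty for a null experiment.
#' @param decoy_frac Fraction of emitted interactions that are decoys
#'   (span outside the window or mismatched UMIs).
#' @param n_bg_anchors Unlabeled background anchors added to the endpoint
#'   pool.
#' @param anchor_width Width (bp) of interaction anchors.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 2,
                       chrom_len = 1e7,
                       n_peaks = 2000,
                       cluster_spec = data.frame(
                         label = c("unchanged", "gain", "loss"),
                         fraction = c(0.823, 0.052, 0.125),
                         effect = c(0, 1.5, -1.5),
                         stringsAsFactors = FALSE
                       ),
                       frag_len_mix = data.frame(
                         mean = c(75, 200),
                         sd = c(25, 20),
                         weight = c(0.6, 0.4)
                       ),
                       nuc_spacing = c(WT = 120, MUT = 101),
                       dyad_sd = 20,
                       dyad_background = 0.2,
                       n_fragments = 1e5,
                       n_interactions = 5000,
                       umi_alphabet_size = 4,
                       umi_length = 6,
                       dispersion = 0.05,
                       base_mean = 100,
                       base_sdlog = 0.7,
                       peak_width = c(200, 600),
                       lib_factor_range = c(0.7, 1.3),
                       conditions = c("WT", "MUT"),
                       enhancer_frac = 0.5,
                       active_frac = 0.6,
                       k27ac_tail_alpha = 1.2,
                       motif_frac = 0.3,
                       promoter_k4me_frac = 0.2,
                       swisnf_frac_loss = 0.39,
                       swisnf_frac_other = 0.08,
                       k27acdown_frac_cascade = 0.44,
                       k27acdown_frac_other = 0.05,
                       fra1_frac_cascade = 0.79,
                       fra1_frac_other = 0.10,
                       enrich_pairs = data.frame(cat_a = character(),
                                                 cat_b = character(),
                                                 factor = numeric(),
                                                 stringsAsFactors = FALSE),
                       decoy_frac = 0,
                       n_bg_anchors = 500,
                       anchor_width = 200,
                       assign_radius = 3000) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (abs(sum(cfg$cluster_spec$fraction) - 1) > 1e-8)
    stop("cluster_spec fractions must sum to 1")
  if (abs(sum(cfg$frag_len_mix$weight) - 1) > 1e-8)
    stop("frag_len_mix weights must sum to 1")
  if (any(c(cfg$n_chrom, cfg$chrom_len, cfg$n_peaks) <= 0))
    stop("n_chrom, chrom_len and n_peaks must be positive")
  if (cfg$n_fragments < 0 || cfg$n_interactions < 0)
    stop("n_fragments and n_interactions must be non-negative")
  if (any(cfg$nuc_spacing <= 0))
    stop("nuc_spacing dyad offsets must be positive")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$decoy_frac < 0 || cfg$decoy_frac >= 1)
    stop("decoy_frac must lie in [0, 1)")
  if (length(cfg$conditions) != 2) stop("exactly two conditions are required")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat `key: value` YAML; table-valued parameters (`cluster_spec`,
#' `frag_len_mix`, `enrich_pairs`) are given as lists of records. Keys not
#' present fall back to the [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("cluster_spec", "frag_len_mix", "enrich_pairs")) {
    if (!is.null(raw[[key]]))
      raw[[key]] <- do.call(rbind, lapply(raw[[key]], function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.null(raw$nuc_spacing)) raw$nuc_spacing <- unlist(raw$nuc_spacing)
  do.call(sim_config, raw)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chrom))

#' Simulate an accessibility peak count experiment
#'
#' Places non-overlapping peaks on toy chromosomes and draws replicate
#' counts for a 2 condition x 2 replicate design from a negative-binomial
#' model: `NB(mean = library factor x baseline x 2^effect, dispersion)`,
#' where the planted log2 `effect` (condition 2 versus condition 1) comes
#' from the configured peak classes and is 0 for null peaks. Library-size
#' factors are drawn uniformly from `cfg$lib_factor_range`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `peaks` (interval data frame), `counts` (peaks x
#'   samples integer matrix), `samples` (sample/condition/replicate data
#'   frame), `lib_sizes`, and `truth` (per-peak class label, effect and
#'   differential status).
#' @export
simulate_peak_counts <- function(cfg) {
  validate_sim_config(cfg)
  with_local_seed(derive_seed(cfg$seed, "peak_counts"), {
    chroms <- sim_chrom_names(cfg)
    n <- cfg$n_peaks
    slot <- max(cfg$peak_width) + 200
    slots_per_chrom <- floor(cfg$chrom_len / slot)
    if (n > slots_per_chrom * cfg$n_chrom)
      stop("chromosomes too short for the requested number of peaks")
    slot_ids <- sort(sample.int(slots_per_chrom * cfg$n_chrom, n))
    chrom_idx <- ((slot_ids - 1) %/% slots_per_chrom) + 1
    within <- ((slot_ids - 1) %% slots_per_chrom)
    width <- sample(seq(cfg$peak_width[1], cfg$peak_width[2]), n, replace = TRUE)
    start <- within * slot + sample.int(200, n, replace = TRUE) - 1L
    peaks <- interval_set(chroms[chrom_idx], start, start + width,
                          name = sprintf("peak_%05d", seq_len(n)))
    labels <- sample(cfg$cluster_spec$label, n, replace = TRUE,
                     prob = cfg$cluster_spec$fraction)
    effect <- cfg$cluster_spec$effect[match(labels, cfg$cluster_spec$label)]
    base <- stats::rlnorm(n, log(cfg$base_mean), cfg$base_sdlog)
    samples <- data.frame(
      sample = paste(rep(cfg$conditions, each = 2), 1:2, sep = "_"),
      condition = rep(cfg$conditions, each = 2),
      replicate = rep(1:2, 2),
      stringsAsFactors = FALSE
    )
    libf <- stats::runif(4, cfg$lib_factor_range[1], cfg$lib_factor_range[2])
    counts <- matrix(0L, n, 4, dimnames = list(peaks$name, samples$sample))
    for (j in 1:4) {
      mu <- base * libf[j] *
        2^(effect * (samples$condition[j] == cfg$conditions[2]))
      counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }
    list(
      peaks = peaks,
      counts = counts,
      samples = samples,
      lib_sizes = colSums(counts),
      truth = data.frame(peak = peaks$name, label = labels, effect = effect,
                         differential = effect != 0,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate paired-end fragments with planted flanking-nucleosome dyads
#'
#' Fragment lengths are drawn from the configured mixture. Fragments from
#' mononucleosomal components (mean >= 180 bp) are placed, with
#' probability `1 - cfg$dyad_background`, so that their midpoint (the dyad
#' surrogate) is `Normal(motif center +/- offset, cfg$dyad_sd)` where the
#' offset is the configured flanking-nucleosome position for `condition`;
#' the remainder, and all sub-nucleosomal fragments, are placed uniformly.
#'
#' @param cfg A [sim_config()]; `condition` must name an entry of
#'   `cfg$nuc_spacing`.
#' @param motifs Interval data frame of motif sites (centers used).
#' @param condition Condition label.
#' @return A fragment data frame: `chrom`, `start`, `end`, `length`,
#'   `dyad`, `sample`.
#' @export
simulate_fragments <- function(cfg, motifs, condition) {
  validate_sim_config(cfg)
  if (!condition %in% names(cfg$nuc_spacing))
    stop("no planted dyad offset for condition '", condition, "'")
  if (nrow(motifs) == 0) stop("motifs must be non-empty")
  n <- cfg$n_fragments
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), dyad = integer(),
                      sample = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  with_local_seed(derive_seed(cfg$seed, paste0("fragments_", condition)), {
    mix <- cfg$frag_len_mix
    comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    len <- pmax(20L, as.integer(round(stats::rnorm(n, mix$mean[comp], mix$sd[comp]))))
    mono <- mix$mean[comp] >= 180
    planted <- mono & (stats::runif(n) >= cfg$dyad_background)
    chroms <- sim_chrom_names(cfg)
    chrom <- sample(chroms, n, replace = TRUE)
    dyad <- as.integer(sample.int(cfg$chrom_len - 500L, n) + 250L)
    if (any(planted)) {
      k <- sum(planted)
      mi <- sample.int(nrow(motifs), k, replace = TRUE)
      centers <- interval_midpoint(motifs)[mi]
      sign <- sample(c(-1L, 1L), k, replace = TRUE)
      offset <- cfg$nuc_spacing[[condition]]
      dyad[planted] <- as.integer(round(
        centers + sign * offset + stats::rnorm(k, 0, cfg$dyad_sd)))
      chrom[planted] <- motifs$chrom[mi]
    }
    start <- dyad - len %/% 2L
    shift <- pmax(0L, -start)
    start <- start + shift
    over <- pmax(0L, (start + len) - as.integer(cfg$chrom_len))
    start <- start - over
    data.frame(chrom = chrom, start = start, end = start + len,
               length = len, dyad = start + len %/% 2L,
               sample = condition, stringsAsFactors = FALSE)
  })
}

#' Simulate histone-mark region sets, motif sites and factor binding
#'
#' Emits mark sets consistent with the enhancer taxonomy the classifier
#' expects: H3K4me3 at promoters, H3K4me1 at promoters plus a configurable
#' fraction of TSS-distal peaks (candidate enhancers), and H3K27ac over a
#' fraction of those enhancers with heavy-tailed (Pareto) scores so a
#' small top fraction forms a super-enhancer-like elbow. When per-peak
#' ground truth is supplied, remodeler (SWI/SNF-like) binding, reduced
#' H3K27ac and AP-1 factor binding are planted with the configured
#' conditional fractions so the co-regulation cascade has known structure.
#'
#' @param cfg A [sim_config()].
#' @param peaks Peak interval data frame (from [simulate_peak_counts()]).
#' @param tss TSS annotation (interval data frame, gene ids in `name`).
#' @param truth Optional per-peak truth from [simulate_peak_counts()].
#' @return A list of interval data frames: `k4me`, `k4me3`, `k27ac`,
#'   `motifs`, `swisnf`, `k27ac_down`, `fra1`.
#' @export
simulate_marks_and_features <- function(cfg, peaks, tss, truth = NULL) {
  validate_sim_config(cfg)
  with_local_seed(derive_seed(cfg$seed, "marks"), {
    ann <- nearest_tss(peaks, tss, distal_cutoff = 1000)
    distal <- which(!ann$unannotated & ann$distal)
    k4me3 <- interval_set(tss$chrom, pmax(0L, tss$start - 500L),
                          tss$start + 500L)
    n_prom_k4 <- round(cfg$promoter_k4me_frac * nrow(tss))
    prom_idx <- if (n_prom_k4 > 0) sample(seq_len(nrow(tss)), n_prom_k4) else integer()
    enh_idx <- if (length(distal) > 0)
      sort(sample(distal, round(cfg$enhancer_frac * length(distal)))) else integer()
    k4me_prom <- if (length(prom_idx) > 0)
      interval_set(tss$chrom[prom_idx], pmax(0L, tss$start[prom_idx] - 800L),
                   tss$start[prom_idx] + 800L) else NULL
    k4me_enh <- if (length(enh_idx) > 0)
      interval_set(peaks$chrom[enh_idx], pmax(0L, peaks$start[enh_idx] - 1000L),
                   peaks$end[enh_idx] + 1000L) else NULL
    k4me <- rbind(k4me_enh, k4me_prom)
    if (is.null(k4me))
      k4me <- complete_intervals(data.frame(chrom = character(),
                                            start = integer(), end = integer()))
    # heavy-tailed K27ac scores: Pareto with configurable tail exponent
    n_active <- round(cfg$active_frac * length(enh_idx))
    act_idx <- if (n_active > 0) sort(sample(enh_idx, n_active)) else integer()
    k27ac <- if (length(act_idx) > 0) {
      interval_set(peaks$chrom[act_idx], pmax(0L, peaks$start[act_idx] - 500L),
                   peaks$end[act_idx] + 500L,
                   score = stats::runif(length(act_idx))^(-1 / cfg$k27ac_tail_alpha))
    } else complete_intervals(data.frame(chrom = character(),
                                         start = integer(), end = integer()))
    n_motif <- round(cfg$motif_frac * nrow(peaks))
    motif_idx <- if (n_motif > 0) sort(sample(seq_len(nrow(peaks)), n_motif)) else integer()
    centers <- interval_midpoint(peaks)[motif_idx]
    motifs <- if (n_motif > 0)
      interval_set(peaks$chrom[motif_idx], centers - 3L, centers + 4L)
    else complete_intervals(data.frame(chrom = character(),
                                       start = integer(), end = integer()))
    # cascade structure: planted conditional membership fractions
    is_loss <- if (!is.null(truth)) truth$label == "loss" else rep(FALSE, nrow(peaks))
    p_sw <- ifelse(is_loss, cfg$swisnf_frac_loss, cfg$swisnf_frac_other)
    sw <- stats::runif(nrow(peaks)) < p_sw
    p_kd <- ifelse(is_loss & sw, cfg$k27acdown_frac_cascade,
                   cfg$k27acdown_frac_other)
    kd <- stats::runif(nrow(peaks)) < p_kd
    p_fr <- ifelse(is_loss & sw & kd, cfg$fra1_frac_cascade,
                   cfg$fra1_frac_other)
    fr <- stats::runif(nrow(peaks)) < p_fr
    subset_peaks <- function(keep) {
      out <- peaks[keep, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    list(k4me = sort_intervals(k4me), k4me3 = sort_intervals(k4me3),
         k27ac = sort_intervals(k27ac), motifs = motifs,
         swisnf = subset_peaks(sw), k27ac_down = subset_peaks(kd),
         fra1 = subset_peaks(fr))
  })
}

random_umis <- function(n, alphabet_size, len) {
  letters_pool <- LETTERS[seq_len(alphabet_size)]
  chars <- sample(letters_pool, n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1, paste, collapse = "")
}

#' Simulate feature-anchored chromatin interactions with UMIs
#'
#' Builds an endpoint pool from the midpoints of the labeled features plus
#' unlabeled background anchors, then draws interactions as uniform anchor
#' pairs constrained to the 5 kb - 1 Mb span window. Planted pairwise
#' enrichments (`cfg$enrich_pairs`) add category-restricted pairs on top
#' of the base draw, calibrated against the realized base rate so the
#' observed/expected ratio targets the configured factor. A configured
#' fraction of decoys is appended: half with spans drawn log-uniformly
#' outside the window, half with mismatched UMIs.
#'
#' @param cfg A [sim_config()].
#' @param features Interval data frame with a `label` column naming the
#'   feature category of each row.
#' @return A list: `interactions` (BEDPE-shaped data frame with `umi1`,
#'   `umi2`), `anchors` (the endpoint pool with labels), and `truth`
#'   (planted enrichment pairs and per-row decoy flags).
#' @export
simulate_interactions <- function(cfg, features) {
  validate_sim_config(cfg)
  stopifnot("label" %in% names(features))
  with_local_seed(derive_seed(cfg$seed, "interactions"), {
    chroms <- unique(features$chrom)
    pool <- data.frame(
      chrom = c(features$chrom, sample(chroms, cfg$n_bg_anchors, replace = TRUE)),
      mid = c(interval_midpoint(features),
              as.integer(sample.int(cfg$chrom_len - 2000L, cfg$n_bg_anchors) + 1000L)),
      label = c(features$label, rep(NA_character_, cfg$n_bg_anchors)),
      stringsAsFactors = FALSE
    )
    np <- nrow(pool)
    # effective category membership at the downstream assignment radius:
    # any anchor within assign_radius of a category's feature carries that
    # label for calibration purposes, exactly as endpoint assignment will
    # see it
    cats <- unique(features$label)
    eff <- matrix(FALSE, np, length(cats), dimnames = list(NULL, cats))
    for (cat in cats) {
      fsel <- features$label == cat
      fpos <- split(interval_midpoint(features)[fsel], features$chrom[fsel])
      for (chrom in names(fpos)) {
        ai <- which(pool$chrom == chrom)
        if (length(ai) == 0) next
        p <- sort(fpos[[chrom]])
        j <- findInterval(pool$mid[ai], p)
        d_lo <- ifelse(j >= 1, abs(pool$mid[ai] - p[pmax(j, 1)]), Inf)
        d_hi <- ifelse(j < length(p),
                       abs(p[pmin(j + 1, length(p))] - pool$mid[ai]), Inf)
        eff[ai, cat] <- pmin(d_lo, d_hi) <= cfg$assign_radius
      }
    }
    draw_window_pairs <- function(k, from = seq_len(np), to = seq_len(np)) {
      got_i <- integer(); got_j <- integer()
      tries <- 0
      while (length(got_i) < k && tries < 60) {
        m <- max(1000L, 6L * (k - length(got_i)))
        i <- sample(from, m, replace = TRUE)
        j <- sample(to, m, replace = TRUE)
        span <- abs(pool$mid[i] - pool$mid[j])
        ok <- pool$chrom[i] == pool$chrom[j] & span >= 5000 & span <= 1e6 & i != j
        got_i <- c(got_i, i[ok]); got_j <- c(got_j, j[ok])
        tries <- tries + 1
      }
      if (length(got_i) < k)
        stop("could not draw enough window-satisfying anchor pairs; ",
             "increase chrom_len or the feature density")
      data.frame(i = got_i[seq_len(k)], j = got_j[seq_len(k)])
    }
    base <- draw_window_pairs(cfg$n_interactions)
    pair_flag <- function(pairs, a, b) {
      (eff[pairs$i, a] & eff[pairs$j, b]) | (eff[pairs$i, b] & eff[pairs$j, a])
    }
    extra <- base[0, ]
    ep <- cfg$enrich_pairs
    if (nrow(ep) > 0) {
      for (r in seq_len(nrow(ep))) {
        c0 <- sum(pair_flag(base, ep$cat_a[r], ep$cat_b[r]))
        qhat <- c0 / nrow(base)
        denom <- 1 - ep$factor[r] * qhat
        if (denom <= 0)
          stop("enrichment factor ", ep$factor[r], " for pair (",
               ep$cat_a[r], ", ", ep$cat_b[r], ") is unattainably large")
        e <- round(c0 * (ep$factor[r] - 1) / denom)
        if (e > 0) {
          from <- which(eff[, ep$cat_a[r]])
          to <- which(eff[, ep$cat_b[r]])
          if (length(from) == 0 || length(to) == 0)
            stop("no pool anchors for planted pair (", ep$cat_a[r], ", ",
                 ep$cat_b[r], ")")
          extra <- rbind(extra, draw_window_pairs(e, from, to))
        }
      }
    }
    valid <- rbind(base, extra)
    n_valid <- nrow(valid)
    n_decoy <- if (cfg$decoy_frac > 0)
      round(cfg$decoy_frac / (1 - cfg$decoy_frac) * n_valid) else 0L
    mk_rows <- function(chrom1, mid1, chrom2, mid2, umi1, umi2) {
      hw <- as.integer(cfg$anchor_width %/% 2)
      mid1 <- as.integer(mid1)
      mid2 <- as.integer(mid2)
      data.frame(
        chrom1 = chrom1, start1 = pmax(0L, mid1 - hw), end1 = mid1 + hw,
        chrom2 = chrom2, start2 = pmax(0L, mid2 - hw), end2 = mid2 + hw,
        name = ".", score = NA_real_, strand1 = ".", strand2 = ".",
        umi1 = umi1, umi2 = umi2, stringsAsFactors = FALSE
      )
    }
    umi_v <- random_umis(n_valid, cfg$umi_alphabet_size, cfg$umi_length)
    rows <- mk_rows(pool$chrom[valid$i], pool$mid[valid$i],
                    pool$chrom[valid$j], pool$mid[valid$j], umi_v, umi_v)
    decoy_flag <- rep(FALSE, n_valid)
    if (n_decoy > 0) {
      n_span <- n_decoy %/% 2L
      n_umi <- n_decoy - n_span
      if (n_span > 0) {
        i <- sample.int(np, n_span, replace = TRUE)
        low <- stats::runif(n_span) < 0.5
        span <- ifelse(low,
                       round(exp(stats::runif(n_span, log(200), log(4999)))),
                       round(exp(stats::runif(n_span, log(1e6 + 1), log(2e6)))))
        pos2 <- pool$mid[i] + span
        flip <- pos2 > cfg$chrom_len - 1000
        pos2[flip] <- pool$mid[i][flip] - span[flip]
        pos2 <- pmax(1000L, as.integer(pos2))
        u <- random_umis(n_span, cfg$umi_alphabet_size, cfg$umi_length)
        rows <- rbind(rows, mk_rows(pool$chrom[i], pool$mid[i],
                                    pool$chrom[i], pos2, u, u))
      }
      if (n_umi > 0) {
        dp <- draw_window_pairs(n_umi)
        u1 <- random_umis(n_umi, cfg$umi_alphabet_size, cfg$umi_length)
        u2 <- paste0(substr(u1, 2, cfg$umi_length),
                     LETTERS[(match(substr(u1, 1, 1), LETTERS) %% cfg$umi_alphabet_size) + 1L])
        rows <- rbind(rows, mk_rows(pool$chrom[dp$i], pool$mid[dp$i],
                                    pool$chrom[dp$j], pool$mid[dp$j], u1, u2))
      }
      decoy_flag <- c(decoy_flag, rep(TRUE, n_span + n_umi))
    }
    ord <- sample.int(nrow(rows))
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
    list(
      interactions = rows,
      anchors = pool,
      truth = list(enrich_pairs = ep, decoy = decoy_flag[ord],
                   n_valid = n_valid, n_decoy = n_decoy)
    )
  })
}

#' Simulate a TSS annotation with gene bodies
#'
#' Genes are placed on the toy chromosomes with uniform starts, random
#' strand and log-uniform lengths; the TSS is the strand-appropriate gene
#' edge. Used both as the nearest-TSS annotation and (through
#' [make_gene_elements()]) as the basis of the genomic-element partition.
#'
#' @param cfg A [sim_config()].
#' @param n_genes Number of genes.
#' @return A list with `tss` (single-bp TSS intervals, gene ids in
#'   `name`) and `genes` (gene-body intervals with strand).
#' @export
simulate_genes <- function(cfg, n_genes = 300) {
  validate_sim_config(cfg)
  with_local_seed(derive_seed(cfg$seed, "genes"), {
    chroms <- sim_chrom_names(cfg)
    chrom <- sample(chroms, n_genes, replace = TRUE)
    len <- as.integer(round(exp(stats::runif(n_genes, log(2000), log(2e5)))))
    start <- as.integer(vapply(len, function(l)
      sample.int(cfg$chrom_len - l - 2000L, 1) + 1000L, 1L))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    genes <- interval_set(chrom, start, start + len, strand = strand,
                          name = gene_id)
    tss_pos <- ifelse(strand == "+", start, start + len - 1L)
    tss <- interval_set(chrom, tss_pos, tss_pos + 1L, strand = strand,
                        name = gene_id)
    list(tss = sort_intervals(tss), genes = sort_intervals(genes))
  })
}

#' Simulate a gene expression table
#'
#' Log-normal baseline FPKM with per-gene log2 fold changes applied to the
#' second condition, two replicates per condition with multiplicative
#' noise.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Character vector of gene ids.
#' @param log2fc Per-gene log2 fold change (condition 2 vs 1); recycled.
#' @param noise_sdlog Replicate noise on the log scale.
#' @return A list with `fpkm` (genes x samples matrix) and `samples`.
#' @export
simulate_expression <- function(cfg, gene_ids, log2fc = 0, noise_sdlog = 0.15) {
  validate_sim_config(cfg)
  with_local_seed(derive_seed(cfg$seed, "expression"), {
    n <- length(gene_ids)
    log2fc <- rep_len(log2fc, n)
    base <- stats::rlnorm(n, log(20), 1)
    samples <- data.frame(
      sample = paste(rep(cfg$conditions, each = 2), 1:2, sep = "_"),
      condition = rep(cfg$conditions, each = 2),
      replicate = rep(1:2, 2), stringsAsFactors = FALSE
    )
    fpkm <- matrix(0, n, 4, dimnames = list(gene_ids, samples$sample))
    for (j in 1:4) {
      mu <- base * 2^(log2fc * (samples$condition[j] == cfg$conditions[2]))
      fpkm[, j] <- mu * stats::rlnorm(n, 0, noise_sdlog)
    }
    list(fpkm = fpkm, samples = samples)
  })
}
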