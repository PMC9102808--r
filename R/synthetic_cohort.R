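# Synthetic mCRC-like cohort generator.  Every downstream stage of the
# pipeline is exercised on these cohorts because the motivating
# patient-level data (WGS + RNA-seq + clinical follow-up) are
# access-restricted.  The generator plants the structure the analysis is
# designed to recover: sparse replication-origin spacing across CFS
# regions versus dense spacing elsewhere, deletions concentrated at the
# midpoints of large expressed genes with duplications at their flanks, a
# latent high-deletion (RSF) sample subset, junction-spanning split reads,
# and exponential progression-free survival with a configurable hazard
# ratio.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 13 CFS-like
#' regions, ~1.6 Mb origin-free inter-peak intervals at CFS versus a 25 kb
#' background inter-peak median, deletions of 10 kb-1 Mb centered on gene
#' midpoints, a latent RSF+ fraction with elevated deletion burden, and a
#' true progression hazard ratio of 3 for RSF+ samples.  Genome scale is
#' 3 synthetic chromosomes of 60 Mb: large enough to host all planted
#' regions plus background, small enough for seconds-scale runs.  The
#' background deletion rate (3 per sample) matches the per-megabase
#' background deletion density of a ~3 Gb cohort carrying ~20 background
#' deletions per sample, rescaled to the 180 Mb synthetic genome.
#'
#' @param n_samples number of tumor samples.
#' @param n_cfs_regions number of planted CFS-like hotspot regions.
#' @param n_background_genes number of large non-CFS genes planted between
#'   origin peaks (the expression comparison group).
#' @param cfs_gene_length_range bp range for CFS gene lengths; the upper
#'   bound must be below `cfs_interpeak_distance` so the gene fits strictly
#'   between its bordering peaks.
#' @param background_gene_length_range bp range for non-CFS large genes.
#' @param cfs_interpeak_distance bp between the two origin peaks bracketing
#'   each CFS gene (no peak in between).
#' @param background_interpeak_median median bp between origin peaks
#'   elsewhere in the genome.
#' @param trdoff_del_rate expected deletions per sample per expressed CFS
#'   gene (non-RSF samples).
#' @param del_midpoint_sd standard deviation of deletion midpoints, as a
#'   fraction of gene length, in (0, 0.5].
#' @param del_size_range bp range of CFS deletion sizes (uniform).
#' @param dup_rate expected duplications per sample per CFS gene.
#' @param dup_flank_positions relative gene positions at which duplication
#'   midpoints concentrate (mixture).
#' @param dup_flank_sd standard deviation of duplication midpoints as a
#'   fraction of gene length.
#' @param dup_size_range bp range of duplication sizes.
#' @param background_del_rate expected background deletions per sample,
#'   uniform over the genome.
#' @param background_del_size_range bp range of background deletion sizes
#'   (log-uniform).
#' @param rsf_fraction fraction of samples designated as latent high-DEL
#'   (RSF+) samples.
#' @param rsf_multiplier multiplier on `trdoff_del_rate` for RSF+ samples.
#' @param true_hr progression hazard ratio for RSF+ versus RSF- samples.
#' @param baseline_hazard per-day baseline progression hazard (default:
#'   median PFS of 250 days for RSF- samples).
#' @param censor_rate expected fraction of samples censored.
#' @param zero_expression_fraction fraction of non-CFS large genes simulated
#'   as not expressed at all.
#' @param cfs_expr_meanlog,background_expr_meanlog log-scale location of
#'   the expression law for CFS and non-CFS genes.
#' @param expr_sdlog log-scale spread of expression across samples.
#' @param junction_del_fraction fraction of CFS deletions that receive
#'   junction-spanning split reads.
#' @param max_reads_per_junction maximum split reads per supported deletion.
#' @param decoy_read_rate decoy (non-junction) read pairs emitted per
#'   junction read.
#' @param read_segment_length bp length of each aligned read segment.
#' @param n_chromosomes,chromosome_size synthetic genome dimensions.
#' @param cfs_at_fraction A+T fraction of the reference sequence inside CFS
#'   gene bodies (~0.5 elsewhere).
#' @param seed integer seed; every generator draws from a named substream
#'   derived from it, so a config is fully deterministic.
#' @return a validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_samples = 20, seed = 7)
#' @export
sim_config <- function(n_samples = 200,
                       n_cfs_regions = 13,
                       n_background_genes = 40,
                       cfs_gene_length_range = c(6e5, 1.4e6),
                       background_gene_length_range = c(5.5e5, 1.4e6),
                       cfs_interpeak_distance = 1.6e6,
                       background_interpeak_median = 2.5e4,
                       trdoff_del_rate = 1.0,
                       del_midpoint_sd = 0.08,
                       del_size_range = c(1e4, 1e6),
                       dup_rate = 0.25,
                       dup_flank_positions = c(0.05, 0.95),
                       dup_flank_sd = 0.03,
                       dup_size_range = c(5e3, 5e4),
                       background_del_rate = 3,
                       background_del_size_range = c(1e3, 2e6),
                       rsf_fraction = 0.15,
                       rsf_multiplier = 4,
                       true_hr = 3,
                       baseline_hazard = log(2) / 250,
                       censor_rate = 0.2,
                       zero_expression_fraction = 0.3,
                       cfs_expr_meanlog = log(25),
                       background_expr_meanlog = log(5),
                       expr_sdlog = 1,
                       junction_del_fraction = 0.05,
                       max_reads_per_junction = 3,
                       decoy_read_rate = 0.5,
                       read_segment_length = 100,
                       n_chromosomes = 3,
                       chromosome_size = 6e7,
                       cfs_at_fraction = 0.65,
                       seed = 1L) {
  cfg <- mget(names(formals()))
  rates <- c("trdoff_del_rate", "dup_rate", "background_del_rate",
             "junction_del_fraction", "decoy_read_rate", "censor_rate")
  for (r in rates)
    if (cfg[[r]] < 0) .stopf("sim_config: '%s' must be >= 0", r)
  if (cfg$rsf_fraction < 0 || cfg$rsf_fraction > 1)
    .stopf("sim_config: 'rsf_fraction' must be in [0, 1]")
  if (cfg$true_hr <= 0) .stopf("sim_config: 'true_hr' must be > 0")
  if (cfg$del_midpoint_sd <= 0 || cfg$del_midpoint_sd > 0.5)
    .stopf("sim_config: 'del_midpoint_sd' must be in (0, 0.5]")
  if (cfg$cfs_gene_length_range[2] >= cfg$cfs_interpeak_distance)
    .stopf(paste("sim_config: CFS gene length upper bound (%g) must be",
                 "below cfs_interpeak_distance (%g) so the gene fits",
                 "strictly between its bordering peaks"),
           cfg$cfs_gene_length_range[2], cfg$cfs_interpeak_distance)
  if (cfg$n_samples < 1) .stopf("sim_config: need at least one sample")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

.sample_ids <- function(n) sprintf("S%03d", seq_len(n))

# uniform random AT/GC-balanced (or AT-skewed) DNA as a single string
.random_dna <- function(n, at_fraction = 0.5) {
  p <- c(at_fraction / 2, (1 - at_fraction) / 2,
         (1 - at_fraction) / 2, at_fraction / 2)
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE, prob = p))
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

#' Generate synthetic genome annotation
#'
#' Lays out the synthetic genome: each CFS gene is bracketed by exactly two
#' origin peaks separated by `cfs_interpeak_distance` with no peak in
#' between; non-CFS large genes are likewise placed in origin-free windows
#' (so they enter the expression comparison); the rest of the genome
#' carries origin peaks with exponentially distributed spacing whose median
#' is `background_interpeak_median`.  TAD boundary intervals are placed
#' just outside each CFS inter-peak window plus at random background
#' positions.  The reference sequence is AT-rich inside CFS gene bodies and
#' base-balanced elsewhere.
#'
#' @param config a [sim_config()].
#' @param include_sequence generate the reference sequence (a few seconds
#'   and ~180 MB of text at the default genome size); set `FALSE` when only
#'   coordinates are needed.
#' @return list with elements `chrom_sizes` (named numeric), `genes`
#'   (data.frame with `is_cfs`, `expressed`, and the bracketing peak
#'   midpoints `left_peak`/`right_peak`), `peaks`, `tads`, `reference`
#'   (named character vector or `NULL`) and `config`.
#' @export
generate_annotation <- function(config, include_sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  n_chr <- config$n_chromosomes
  chr_size <- config$chromosome_size
  chroms <- paste0("chr", seq_len(n_chr))
  chrom_sizes <- setNames(rep(chr_size, n_chr), chroms)

  n_blocks <- config$n_cfs_regions + config$n_background_genes
  block_type <- sample(c(rep("cfs", config$n_cfs_regions),
                         rep("bg", config$n_background_genes)))
  blocks_per_chr <- tabulate(rep_len(seq_len(n_chr), n_blocks), n_chr)
  buffer <- 2e5
  bracket_margin <- 2.5e4
  peak_halfwidth <- 500
  max_block <- max(config$cfs_interpeak_distance,
                   config$background_gene_length_range[2] +
                     2 * bracket_margin)
  min_slot <- chr_size / max(blocks_per_chr)
  if (min_slot < max_block + 2 * buffer)
    .stopf(paste("generate_annotation: chromosomes of %g bp cannot host %d",
                 "regions of up to %g bp"), chr_size, max(blocks_per_chr),
           max_block)

  genes <- list(); peaks <- list(); tads <- list()
  reserved <- list()  # windows where background peaks are excluded
  bi <- 0L; n_cfs_seen <- 0L; n_bg_seen <- 0L
  for (ci in seq_len(n_chr)) {
    k <- blocks_per_chr[ci]
    if (k == 0) next
    slot_w <- chr_size / k
    for (si in seq_len(k)) {
      bi <- bi + 1L
      slot_start <- (si - 1) * slot_w
      if (block_type[bi] == "cfs") {
        n_cfs_seen <- n_cfs_seen + 1L
        W <- config$cfs_interpeak_distance
        L <- round(runif(1, config$cfs_gene_length_range[1],
                         config$cfs_gene_length_range[2]))
        p_left <- round(slot_start + buffer +
                          runif(1, 0, slot_w - W - 2 * buffer))
        p_right <- p_left + W
        g_start <- round(p_left + (W - L) / 2)
        gid <- sprintf("CFS%02d", n_cfs_seen)
        genes[[bi]] <- data.frame(
          gene_id = gid, name = gid, chrom = chroms[ci],
          start = g_start, end = g_start + L,
          strand = sample(c("+", "-"), 1),
          is_cfs = TRUE, expressed = TRUE,
          left_peak = p_left, right_peak = p_right,
          stringsAsFactors = FALSE)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chroms[ci],
          start = c(p_left, p_right) - peak_halfwidth,
          end = c(p_left, p_right) + peak_halfwidth,
          stringsAsFactors = FALSE)
        tads[[length(tads) + 1L]] <- data.frame(
          chrom = chroms[ci],
          start = c(p_left - 5.5e4, p_right + 4.5e4),
          end = c(p_left - 4.5e4, p_right + 5.5e4),
          stringsAsFactors = FALSE)
        reserved[[length(reserved) + 1L]] <- data.frame(
          chrom = chroms[ci], start = p_left - 2 * peak_halfwidth,
          end = p_right + 2 * peak_halfwidth, stringsAsFactors = FALSE)
      } else {
        n_bg_seen <- n_bg_seen + 1L
        L <- round(runif(1, config$background_gene_length_range[1],
                         config$background_gene_length_range[2]))
        W <- L + 2 * bracket_margin
        p_left <- round(slot_start + buffer +
                          runif(1, 0, slot_w - W - 2 * buffer))
        p_right <- p_left + W
        g_start <- p_left + bracket_margin
        gid <- sprintf("BGL%02d", n_bg_seen)
        genes[[bi]] <- data.frame(
          gene_id = gid, name = gid, chrom = chroms[ci],
          start = g_start, end = g_start + L,
          strand = sample(c("+", "-"), 1),
          is_cfs = FALSE,
          expressed = runif(1) > config$zero_expression_fraction,
          left_peak = p_left, right_peak = p_right,
          stringsAsFactors = FALSE)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chroms[ci],
          start = c(p_left, p_right) - peak_halfwidth,
          end = c(p_left, p_right) + peak_halfwidth,
          stringsAsFactors = FALSE)
        reserved[[length(reserved) + 1L]] <- data.frame(
          chrom = chroms[ci], start = p_left - 2 * peak_halfwidth,
          end = p_right + 2 * peak_halfwidth, stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, genes)
  genes$length <- genes$end - genes$start
  reserved <- do.call(rbind, reserved)

  # background origin peaks: exponential spacing, median as configured
  rate <- log(2) / config$background_interpeak_median
  for (ci in seq_len(n_chr)) {
    n_exp <- ceiling(chr_size * rate * 1.3)
    mids <- cumsum(rexp(n_exp, rate))
    mids <- mids[mids < chr_size - peak_halfwidth & mids > peak_halfwidth]
    res <- reserved[reserved$chrom == chroms[ci], , drop = FALSE]
    if (nrow(res)) {
      drop <- rep(FALSE, length(mids))
      for (ri in seq_len(nrow(res)))
        drop <- drop | (mids > res$start[ri] & mids < res$end[ri])
      mids <- mids[!drop]
    }
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = chroms[ci],
      start = round(mids) - peak_halfwidth,
      end = round(mids) + peak_halfwidth,
      stringsAsFactors = FALSE)
    # background TAD boundaries every ~800 kb, outside reserved windows
    tmids <- cumsum(rexp(ceiling(chr_size / 8e5 * 1.5), 1 / 8e5))
    tmids <- tmids[tmids < chr_size - 1e4 & tmids > 1e4]
    if (nrow(res)) {
      drop <- rep(FALSE, length(tmids))
      for (ri in seq_len(nrow(res)))
        drop <- drop | (tmids > res$start[ri] & tmids < res$end[ri])
      tmids <- tmids[!drop]
    }
    tads[[length(tads) + 1L]] <- data.frame(
      chrom = chroms[ci], start = round(tmids) - 5e3,
      end = round(tmids) + 5e3, stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  peaks$midpoint <- floor((peaks$start + peaks$end) / 2)
  rownames(peaks) <- NULL
  tads <- do.call(rbind, tads)
  tads <- tads[order(tads$chrom, tads$start), ]
  rownames(tads) <- NULL

  reference <- NULL
  if (include_sequence) {
    reference <- setNames(character(n_chr), chroms)
    for (ci in seq_len(n_chr)) {
      s <- .random_dna(chr_size, 0.5)
      cg <- genes[genes$is_cfs & genes$chrom == chroms[ci], , drop = FALSE]
      for (gi in seq_len(nrow(cg)))
        substr(s, cg$start[gi] + 1, cg$end[gi]) <-
          .random_dna(cg$end[gi] - cg$start[gi], config$cfs_at_fraction)
      reference[ci] <- s
    }
  }

  structure(list(chrom_sizes = chrom_sizes, genes = genes, peaks = peaks,
                 tads = tads, reference = reference, config = config),
            class = "sim_annotation")
}

#' Generate the synthetic structural-variant cohort
#'
#' For each sample and each expressed CFS gene, a Poisson number of
#' deletions (rate `trdoff_del_rate`, multiplied by `rsf_multiplier` for
#' latent RSF+ samples) is drawn; deletion midpoints follow a truncated
#' normal around the gene midpoint and sizes are uniform on
#' `del_size_range`, constrained so the whole deletion lies strictly
#' between the bracketing origin peaks.  Duplications concentrate at the
#' gene flanks; background deletions are uniform over the genome with
#' log-uniform sizes.  Multiple overlapping deletions per gene per sample
#' are expected (clonal heterogeneity).
#'
#' @param annotation output of [generate_annotation()].
#' @param config the same [sim_config()].
#' @return list with `sv` (data.frame of calls, plus provenance columns
#'   `origin` and `planted_gene`), `rsf` (named logical, the latent
#'   designation) and `samples` (character vector of sample ids).
#' @export
generate_sv_cohort <- function(annotation, config) {
  stopifnot(inherits(annotation, "sim_annotation"))
  set.seed(config$seed + 202L)
  n <- config$n_samples
  samples <- .sample_ids(n)
  rsf <- setNames(logical(n), samples)
  n_pos <- round(config$rsf_fraction * n)
  if (n_pos > 0) rsf[sample(n, n_pos)] <- TRUE

  out <- list()
  cfs <- annotation$genes[annotation$genes$is_cfs &
                            annotation$genes$expressed, , drop = FALSE]
  for (gi in seq_len(nrow(cfs))) {
    g <- cfs[gi, ]
    L <- g$end - g$start
    gmid <- (g$start + g$end) / 2
    W <- g$right_peak - g$left_peak
    lam <- config$trdoff_del_rate *
      ifelse(rsf, config$rsf_multiplier, 1)
    counts <- rpois(n, lam)
    m <- sum(counts)
    if (m > 0) {
      sizes <- runif(m, config$del_size_range[1],
                     min(config$del_size_range[2], W))
      half <- sizes / 2
      mid <- .rtruncnorm(m, gmid, config$del_midpoint_sd * L,
                         g$left_peak + half + 1, g$right_peak - half - 1)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rep(samples, counts), chrom = g$chrom,
        start = round(mid - half), end = round(mid + half),
        sv_type = "DEL", origin = "cfs", planted_gene = g$gene_id,
        stringsAsFactors = FALSE)
    }
    dcounts <- rpois(n, config$dup_rate)
    m2 <- sum(dcounts)
    if (m2 > 0) {
      rel <- sample(config$dup_flank_positions, m2, replace = TRUE) +
        rnorm(m2, 0, config$dup_flank_sd)
      rel <- pmin(pmax(rel, 0.005), 0.995)
      dmid <- g$start + rel * L
      dsz <- runif(m2, config$dup_size_range[1], config$dup_size_range[2])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = rep(samples, dcounts), chrom = g$chrom,
        start = pmax(0, round(dmid - dsz / 2)),
        end = round(dmid + dsz / 2),
        sv_type = "DUP", origin = "cfs", planted_gene = g$gene_id,
        stringsAsFactors = FALSE)
    }
  }

  bcounts <- rpois(n, config$background_del_rate)
  mb <- sum(bcounts)
  if (mb > 0) {
    chroms <- names(annotation$chrom_sizes)
    ch <- sample(chroms, mb, replace = TRUE,
                 prob = annotation$chrom_sizes / sum(annotation$chrom_sizes))
    sz <- exp(runif(mb, log(config$background_del_size_range[1]),
                    log(config$background_del_size_range[2])))
    st <- floor(runif(mb) * (annotation$chrom_sizes[ch] - sz))
    out[[length(out) + 1L]] <- data.frame(
      sample_id = rep(samples, bcounts), chrom = ch,
      start = round(st), end = round(st + sz),
      sv_type = "DEL", origin = "background", planted_gene = NA_character_,
      stringsAsFactors = FALSE)
  }

  sv <- if (length(out)) do.call(rbind, out)
        else data.frame(sample_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        sv_type = character(), origin = character(),
                        planted_gene = character(), stringsAsFactors = FALSE)
  if (nrow(sv)) {
    sv <- sv[order(sv$chrom, sv$start, sv$end, sv$sample_id), ]
    rownames(sv) <- NULL
    sv$size <- sv$end - sv$start
  } else sv$size <- numeric()
  list(sv = sv, rsf = rsf, samples = samples)
}

#' Generate the synthetic expression table
#'
#' Expressed genes get log-normal expression; CFS genes have a higher
#' location than non-CFS large genes; unexpressed genes are all-zero.
#'
#' @param annotation output of [generate_annotation()].
#' @param config the same [sim_config()].
#' @return numeric gene-by-sample matrix.
#' @export
generate_expression <- function(annotation, config) {
  stopifnot(inherits(annotation, "sim_annotation"))
  set.seed(config$seed + 303L)
  g <- annotation$genes
  n <- config$n_samples
  samples <- .sample_ids(n)
  meanlog <- ifelse(g$is_cfs, config$cfs_expr_meanlog,
                    config$background_expr_meanlog) + rnorm(nrow(g), 0, 0.3)
  m <- matrix(rlnorm(nrow(g) * n, rep(meanlog, n), config$expr_sdlog),
              nrow = nrow(g), ncol = n,
              dimnames = list(g$gene_id, samples))
  m[!g$expressed, ] <- 0
  m
}

#' Generate junction-spanning split reads with decoys
#'
#' A configurable subset of the supplied deletions receives read pairs of
#' two aligned segments: segment A ending exactly at the deletion start and
#' segment B starting exactly at the deletion end, sharing a read id with
#' ordered read offsets.  Decoy read pairs (contiguous alignments with a
#' short internal gap that cannot correspond to any deletion) and the truth
#' mapping are also emitted.
#'
#' @param dels data.frame of deletions (typically the CFS deletions of
#'   [generate_sv_cohort()]).
#' @param config the [sim_config()].
#' @return data.frame of aligned segments with an attribute
#'   `"junction_truth"`: data.frame of `read_id` and the row index of the
#'   supported deletion in `dels`.
#' @export
generate_junction_reads <- function(dels, config) {
  set.seed(config$seed + 404L)
  L0 <- config$read_segment_length
  segs <- list(); truth <- list()
  if (nrow(dels)) {
    supported <- which(runif(nrow(dels)) < config$junction_del_fraction &
                         dels$start >= L0)
    rid <- 0L
    for (di in supported) {
      k <- sample.int(config$max_reads_per_junction, 1)
      for (r in seq_len(k)) {
        rid <- rid + 1L
        id <- sprintf("JR%06d", rid)
        segs[[length(segs) + 1L]] <- data.frame(
          read_id = id, sample_id = dels$sample_id[di],
          chrom = dels$chrom[di],
          start = c(dels$start[di] - L0, dels$end[di]),
          end = c(dels$start[di], dels$end[di] + L0),
          read_offset = c(0, L0), stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <-
          data.frame(read_id = id, del_index = di, stringsAsFactors = FALSE)
      }
    }
  }
  n_junction <- length(truth)
  n_decoy <- ceiling(config$decoy_read_rate * max(n_junction, 1))
  if (config$junction_del_fraction == 0) n_decoy <- ceiling(
    config$decoy_read_rate * max(nrow(dels), 1))
  if (n_decoy > 0 && nrow(dels)) {
    ch <- sample(unique(dels$chrom), n_decoy, replace = TRUE)
    p <- round(runif(n_decoy, L0, 1e6))
    sid <- sample(unique(dels$sample_id), n_decoy, replace = TRUE)
    for (i in seq_len(n_decoy)) {
      # internal gap of 37 bp: smaller than any simulated deletion, so a
      # decoy pair can never abut a real junction
      segs[[length(segs) + 1L]] <- data.frame(
        read_id = sprintf("DR%06d", i), sample_id = sid[i], chrom = ch[i],
        start = c(p[i], p[i] + L0 + 37),
        end = c(p[i] + L0, p[i] + 2 * L0 + 37),
        read_offset = c(0, L0), stringsAsFactors = FALSE)
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs)
          else data.frame(read_id = character(), sample_id = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), read_offset = numeric(),
                          stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  attr(segs, "junction_truth") <-
    if (length(truth)) do.call(rbind, truth)
    else data.frame(read_id = character(), del_index = integer())
  segs
}

#' Generate synthetic clinical records
#'
#' Progression-free survival is exponential with hazard
#' `baseline_hazard * true_hr` for RSF-designated samples and
#' `baseline_hazard` otherwise; censoring is independent with the
#' configured expected fraction.  Prior treatment lines follow a small
#' Poisson law and prior platinum exposure is consistent with them.
#'
#' @param samples character vector of sample ids.
#' @param rsf named logical of latent RSF designations (from
#'   [generate_sv_cohort()]).
#' @param config the [sim_config()].
#' @return clinical data.frame (see [read_clinical()] for columns).
#' @export
generate_clinical <- function(samples, rsf, config) {
  set.seed(config$seed + 505L)
  n <- length(samples)
  h <- config$baseline_hazard * ifelse(rsf[samples], config$true_hr, 1)
  t_event <- rexp(n, h)
  if (config$censor_rate > 0) {
    t_cens <- rexp(n, h * config$censor_rate / (1 - config$censor_rate))
    pfs <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
  } else {
    pfs <- t_event
    event <- rep(TRUE, n)
  }
  prior_lines <- rpois(n, 0.8)
  prior_platinum <- prior_lines > 0 & runif(n) < 0.6
  data.frame(sample_id = samples,
             prior_lines = prior_lines,
             prior_platinum = prior_platinum,
             platinum_after_biopsy = TRUE,
             pfs_days = pmax(pfs, 0.5),
             progression_event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generators off one seeded configuration: annotation, SV calls,
#' expression, junction-spanning reads (for the CFS deletions) and clinical
#' records.
#'
#' @param config a [sim_config()].
#' @param include_sequence forwarded to [generate_annotation()].
#' @return list of class `"sim_cohort"` with elements `annotation`, `sv`,
#'   `rsf`, `samples`, `expression`, `segments`, `clinical`, `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 30, seed = 3),
#'                           include_sequence = FALSE)
#' table(cohort$sv$sv_type)
#' @export
simulate_cohort <- function(config = sim_config(), include_sequence = TRUE) {
  annotation <- generate_annotation(config, include_sequence)
  svc <- generate_sv_cohort(annotation, config)
  expression <- generate_expression(annotation, config)
  cfs_dels <- svc$sv[svc$sv$sv_type == "DEL" & svc$sv$origin == "cfs", ,
                     drop = FALSE]
  segments <- generate_junction_reads(cfs_dels, config)
  clinical <- generate_clinical(svc$samples, svc$rsf, config)
  structure(list(annotation = annotation, sv = svc$sv, rsf = svc$rsf,
                 samples = svc$samples, expression = expression,
                 segments = segments, clinical = clinical, config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits FASTA (reference, if generated), BED (peaks, TADs), TSV (genes,
#' SVs, expression, segments, clinical, latent RSF designation) and a YAML
#' manifest recording the configuration, seed and per-file checksums.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- cohort$annotation
  files <- character()
  p <- function(f) file.path(dir, f)
  if (!is.null(ann$reference)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ann$reference),
                                p("reference.fa"))
    files <- c(files, p("reference.fa"))
  }
  write_bed(ann$peaks, p("peaks.bed")); files <- c(files, p("peaks.bed"))
  write_bed(ann$tads, p("tads.bed")); files <- c(files, p("tads.bed"))
  write_gene_table(ann$genes, p("genes.tsv"))
  files <- c(files, p("genes.tsv"))
  write_sv_calls(cohort$sv, p("svs.tsv")); files <- c(files, p("svs.tsv"))
  write_expression(cohort$expression, p("expression.tsv"))
  files <- c(files, p("expression.tsv"))
  write_segments(cohort$segments, p("segments.tsv"))
  files <- c(files, p("segments.tsv"))
  write_clinical(cohort$clinical, p("clinical.tsv"))
  files <- c(files, p("clinical.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$rsf), rsf_designated = cohort$rsf),
    p("rsf_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p("rsf_truth.tsv"))
  manifest <- list(
    seed = cohort$config$seed,
    config = lapply(unclass(cohort$config), function(x)
      if (is.numeric(x)) as.numeric(x) else x),
    files = lapply(setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, p("cohort_manifest.yaml"))
  invisible(manifest)
}
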