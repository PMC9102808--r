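# End-to-end orchestration: each stage reads its inputs from the output
# directory (written by the simulate stage or supplied by the user), writes
# TSV outputs plus a YAML manifest with config hash, seed, checksums and
# row counts.  All randomness flows from the single config seed through
# named per-stage substreams, so a config + seed pair is fully
# reproducible.

.pipeline_defaults <- function() {
  list(min_size = 1e4, max_size = 1e6, min_events = 150, merge_gap = 1e5,
       tolerance = 5, min_gene_length = 5e5, rsf_threshold = NULL,
       n_bins = 20, tad_mode = "midpoint", seed = 1L, sim = list())
}

.load_pipeline_config <- function(config = NULL, seed = NULL) {
  cfg <- .pipeline_defaults()
  if (!is.null(config)) {
    user <- if (is.character(config)) {
      if (!file.exists(config)) .stopf("config file not found: %s", config)
      yaml::read_yaml(config)
    } else config
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (cfg$min_events < 1)
    .stopf("pipeline config: min_events must be >= 1 (got %s)",
           cfg$min_events)
  if (cfg$min_size >= cfg$max_size)
    .stopf("pipeline config: min_size must be < max_size")
  if (cfg$tolerance < 0) .stopf("pipeline config: tolerance must be >= 0")
  cfg
}

.stage_inputs <- function(outdir, files, stage) {
  paths <- file.path(outdir, files)
  miss <- !file.exists(paths)
  if (any(miss))
    .stopf("stage '%s': missing input file(s): %s", stage,
           paste(files[miss], collapse = ", "))
  setNames(paths, files)
}

.write_stage_manifest <- function(outdir, stage, cfg, outputs, inputs) {
  cfg_file <- file.path(outdir, sprintf("config_%s.yaml", stage))
  writeLines(yaml::as.yaml(cfg[sort(names(cfg))]), cfg_file)
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = lapply(as.list(inputs), function(f)
      list(md5 = unname(tools::md5sum(f)))),
    outputs = lapply(setNames(as.list(outputs), basename(outputs)),
                     function(f) {
      n <- length(readLines(f, warn = FALSE))
      list(md5 = unname(tools::md5sum(f)), rows = n)
    }))
  yaml::write_yaml(manifest, file.path(outdir,
                                       sprintf("manifest_%s.yaml", stage)))
  manifest
}

.write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (write a synthetic cohort into `outdir`),
#' `hotspots`, `forks`, `positions`, `expression`, `junctions`, `rsf`,
#' `survival`, or `all` (the seven analysis stages in order).  Each stage
#' reads its inputs from `outdir` (the simulate stage's outputs double as
#' the input contract for user-supplied data), writes TSV outputs, and
#' records a manifest with the config hash, seed, input/output checksums
#' and row counts.  Missing inputs raise a named error before anything is
#' written; re-running a stage with unchanged inputs is idempotent.
#'
#' @param stage one of the stage names above.
#' @param config path to a YAML config file or a named list; recognized
#'   keys: `min_size`, `max_size` (DEL size bounds, bp), `min_events`,
#'   `merge_gap` (hotspot clustering), `tolerance` (junction matching,
#'   bp), `min_gene_length` (expression gene selection), `rsf_threshold`
#'   (explicit override of the changepoint threshold), `n_bins`,
#'   `tad_mode` (`"midpoint"`/`"gap"`), `seed`, and a `sim` sublist of
#'   [sim_config()] arguments.
#' @param outdir output (and input) directory.
#' @param seed optional seed overriding the config's.
#' @return invisibly, the stage manifest (for `all`, the list of stage
#'   manifests).
#' @export
run_pipeline <- function(stage = c("all", "simulate", "hotspots", "forks",
                                   "positions", "expression", "junctions",
                                   "rsf", "survival"),
                         config = NULL, outdir = "cfsdel_out", seed = NULL) {
  stage <- match.arg(stage)
  cfg <- .load_pipeline_config(config, seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    stages <- c("hotspots", "forks", "positions", "expression",
                "junctions", "rsf", "survival")
    res <- lapply(stages, function(s) run_pipeline(s, cfg, outdir))
    names(res) <- stages
    manifest <- list(stages = lapply(res, function(m) m$outputs))
    yaml::write_yaml(manifest, file.path(outdir, "manifest_all.yaml"))
    return(invisible(res))
  }
  runner <- switch(stage,
                   simulate = .stage_simulate, hotspots = .stage_hotspots,
                   forks = .stage_forks, positions = .stage_positions,
                   expression = .stage_expression,
                   junctions = .stage_junctions, rsf = .stage_rsf,
                   survival = .stage_survival)
  invisible(runner(cfg, outdir))
}

.stage_simulate <- function(cfg, outdir) {
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(scfg)
  write_cohort(cohort, outdir)
  outputs <- file.path(outdir, c("svs.tsv", "genes.tsv", "peaks.bed",
                                 "tads.bed", "expression.tsv",
                                 "segments.tsv", "clinical.tsv",
                                 "rsf_truth.tsv"))
  .write_stage_manifest(outdir, "simulate", cfg, outputs, character())
}

.read_stage_hotspots <- function(outdir, stage) {
  path <- file.path(outdir, "hotspots.tsv")
  if (!file.exists(path))
    .stopf("stage '%s': missing input file(s): hotspots.tsv (run the %s)",
           stage, "'hotspots' stage first")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.stage_hotspots <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, c("svs.tsv", "genes.tsv"), "hotspots")
  svs <- read_sv_calls(ins["svs.tsv"])
  genes <- read_gene_table(ins["genes.tsv"])
  dels <- filter_dels_by_size(svs, cfg$min_size, cfg$max_size)
  hs <- call_hotspots(dels, min_events = cfg$min_events,
                      merge_gap = cfg$merge_gap, genes = genes)
  out1 <- .write_tsv_out(as.data.frame(hs), file.path(outdir, "hotspots.tsv"))
  out2 <- file.path(outdir, "hotspots.bed")
  if (nrow(hs)) write_bed(hs, out2) else writeLines(character(), out2)
  .write_stage_manifest(outdir, "hotspots", cfg, c(out1, out2), ins)
}

.stage_forks <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, c("svs.tsv", "peaks.bed", "tads.bed"),
                       "forks")
  hs <- .read_stage_hotspots(outdir, "forks")
  svs <- read_sv_calls(ins["svs.tsv"])
  dels <- filter_dels_by_size(svs, cfg$min_size, cfg$max_size)
  peaks <- read_bed(ins["peaks.bed"])
  tads <- read_bed(ins["tads.bed"])
  piv <- consecutive_interpeak_intervals(peaks)
  tiv <- tad_intervals(tads, mode = cfg$tad_mode)
  rec <- containment_table(dels, piv, tiv, hs)
  out1 <- .write_tsv_out(rec, file.path(outdir, "containment.tsv"))

  summ <- list()
  for (flag in c("peaks", "tads")) {
    tbl <- containment_contingency(rec, flag)
    or <- odds_ratio(tbl)
    cs <- chi_square_test(tbl)
    summ[[flag]] <- data.frame(
      flag = flag, a = tbl$a, b = tbl$b, c = tbl$c, d = tbl$d,
      pct_inside = tbl$pct_inside, pct_outside = tbl$pct_outside,
      odds_ratio = or$or, or_ci_low = or$ci95[1], or_ci_high = or$ci95[2],
      chisq = cs$statistic, chisq_p = cs$p, stringsAsFactors = FALSE)
  }
  out2 <- .write_tsv_out(do.call(rbind, summ),
                         file.path(outdir, "contingency.tsv"))
  logi <- logistic_enrichment(rec)
  out3 <- .write_tsv_out(logi, file.path(outdir, "logistic.tsv"))

  stats_all <- interpeak_distance_stats(piv)
  dist_df <- data.frame(subset = "all",
                        median = stats_all$median, ci_low = stats_all$ci_low,
                        ci_high = stats_all$ci_high, p95 = stats_all$p95,
                        n = stats_all$n, stringsAsFactors = FALSE)
  if (nrow(hs)) {
    st_h <- interpeak_distance_stats(piv, hs)
    dist_df <- rbind(dist_df, data.frame(
      subset = "hotspot", median = st_h$median, ci_low = st_h$ci_low,
      ci_high = st_h$ci_high, p95 = st_h$p95, n = st_h$n,
      stringsAsFactors = FALSE))
  }
  out4 <- .write_tsv_out(dist_df, file.path(outdir, "interpeak_stats.tsv"))

  prof_in <- position_profile(rec$rel_position[rec$in_hotspot], cfg$n_bins)
  prof_out <- position_profile(rec$rel_position[!rec$in_hotspot],
                               cfg$n_bins)
  hist_df <- data.frame(
    group = rep(c("hotspot", "background"), each = cfg$n_bins),
    bin_low = c(prof_in$edges[-(cfg$n_bins + 1)],
                prof_out$edges[-(cfg$n_bins + 1)]),
    bin_high = c(prof_in$edges[-1], prof_out$edges[-1]),
    count = c(prof_in$counts, prof_out$counts),
    density = c(prof_in$density, prof_out$density))
  out5 <- .write_tsv_out(hist_df, file.path(outdir, "relpos_hist.tsv"))
  .write_stage_manifest(outdir, "forks", cfg,
                        c(out1, out2, out3, out4, out5), ins)
}

.stage_positions <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, c("svs.tsv", "genes.tsv"), "positions")
  hs <- .read_stage_hotspots(outdir, "positions")
  svs <- read_sv_calls(ins["svs.tsv"])
  genes <- read_gene_table(ins["genes.tsv"])
  svs <- svs[svs$sv_type == "DUP" |
               (svs$size >= cfg$min_size & svs$size <= cfg$max_size), ,
             drop = FALSE]
  hit <- .overlaps_any(svs$chrom, svs$start, svs$end,
                       hs$chrom, hs$start, hs$end)
  pos <- strand_corrected_position(svs[hit, , drop = FALSE], genes)
  out1 <- .write_tsv_out(
    pos[, c("sample_id", "gene_id", "sv_type", "rel_pos")],
    file.path(outdir, "gene_positions.tsv"))
  rows <- list()
  for (tp in c("DEL", "DUP")) {
    pr <- position_profile(pos$rel_pos[pos$sv_type == tp], cfg$n_bins)
    rows[[tp]] <- data.frame(sv_type = tp,
                             bin_low = pr$edges[-(cfg$n_bins + 1)],
                             bin_high = pr$edges[-1], count = pr$counts,
                             density = pr$density)
  }
  out2 <- .write_tsv_out(do.call(rbind, rows),
                         file.path(outdir, "position_hist.tsv"))
  .write_stage_manifest(outdir, "positions", cfg, c(out1, out2), ins)
}

.stage_expression <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, c("genes.tsv", "peaks.bed",
                                 "expression.tsv"), "expression")
  hs <- .read_stage_hotspots(outdir, "expression")
  genes <- read_gene_table(ins["genes.tsv"])
  peaks <- read_bed(ins["peaks.bed"])
  expr <- read_expression(ins["expression.tsv"])
  piv <- consecutive_interpeak_intervals(peaks)
  sel <- select_candidate_genes(genes, piv, hs, cfg$min_gene_length)
  med_in <- median_expression_per_gene(expr, sel$inside$gene_id)
  med_out <- median_expression_per_gene(expr, sel$outside$gene_id)
  gene_df <- data.frame(
    gene_id = c(names(med_in), names(med_out)),
    group = rep(c("inside", "outside"), c(length(med_in), length(med_out))),
    median_expression = c(med_in, med_out), stringsAsFactors = FALSE)
  out1 <- .write_tsv_out(gene_df, file.path(outdir, "expression_groups.tsv"))
  mw <- mann_whitney_u(med_in, med_out)
  out2 <- .write_tsv_out(
    data.frame(n_inside = length(med_in), n_outside = length(med_out),
               median_inside = stats::median(med_in),
               median_outside = stats::median(med_out),
               U = mw$U, p = mw$p),
    file.path(outdir, "expression_test.tsv"))
  .write_stage_manifest(outdir, "expression", cfg, c(out1, out2), ins)
}

.stage_junctions <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, c("svs.tsv", "segments.tsv"), "junctions")
  hs <- .read_stage_hotspots(outdir, "junctions")
  svs <- read_sv_calls(ins["svs.tsv"])
  dels <- svs[svs$sv_type == "DEL", , drop = FALSE]
  segs <- read_segments(ins["segments.tsv"])
  matches <- match_junction_reads(segs, dels, tolerance = cfg$tolerance)
  out1 <- .write_tsv_out(matches, file.path(outdir, "junction_matches.tsv"))
  summ <- summarize_support(matches, dels, hs)
  out2 <- .write_tsv_out(summ$per_sample_region,
                         file.path(outdir, "junction_sample_region.tsv"))
  out3 <- .write_tsv_out(
    data.frame(total_reads = summ$total_reads, n_samples = summ$n_samples),
    file.path(outdir, "junction_totals.tsv"))
  .write_stage_manifest(outdir, "junctions", cfg, c(out1, out2, out3), ins)
}

.stage_rsf <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, "svs.tsv", "rsf")
  hs <- .read_stage_hotspots(outdir, "rsf")
  svs <- read_sv_calls(ins["svs.tsv"])
  dels <- filter_dels_by_size(svs, cfg$min_size, cfg$max_size)
  samples <- sort(unique(svs$sample_id))
  counts <- hotspot_del_counts(dels, hs, samples = samples)
  fit <- NULL
  threshold <- cfg$rsf_threshold
  if (is.null(threshold)) {
    fit <- fit_changepoints(counts)
    threshold <- fit$threshold_count
  }
  calls <- suppressMessages(classify_rsf(counts, threshold))
  out1 <- .write_tsv_out(calls, file.path(outdir, "rsf_calls.tsv"))
  fit_df <- if (is.null(fit))
    data.frame(cp1 = NA, cp2 = NA, rss = NA, threshold_count = threshold,
               degenerate = NA, source = "override")
  else data.frame(cp1 = fit$cp1, cp2 = fit$cp2, rss = fit$rss,
                  threshold_count = fit$threshold_count,
                  degenerate = fit$degenerate, source = "changepoint")
  out2 <- .write_tsv_out(fit_df, file.path(outdir, "rsf_fit.tsv"))
  .write_stage_manifest(outdir, "rsf", cfg, c(out1, out2), ins)
}

.stage_survival <- function(cfg, outdir) {
  ins <- .stage_inputs(outdir, "clinical.tsv", "survival")
  calls_path <- file.path(outdir, "rsf_calls.tsv")
  if (!file.exists(calls_path))
    .stopf("stage 'survival': missing input file(s): rsf_calls.tsv %s",
           "(run the 'rsf' stage first)")
  clinical <- read_clinical(ins["clinical.tsv"])
  calls <- utils::read.delim(calls_path, stringsAsFactors = FALSE)
  cl <- clinical[clinical$platinum_after_biopsy &
                   clinical$sample_id %in% calls$sample_id, , drop = FALSE]
  groups <- setNames(calls$status, calls$sample_id)
  km <- km_estimator(cl, groups)
  km_df <- do.call(rbind, lapply(names(km), function(g)
    data.frame(group = g, km[[g]], stringsAsFactors = FALSE)))
  out1 <- .write_tsv_out(km_df, file.path(outdir, "km_curves.tsv"))
  lr <- logrank_test(cl, groups)
  cov <- merge(data.frame(sample_id = calls$sample_id,
                          rsf = as.numeric(calls$status == "RSF+"),
                          stringsAsFactors = FALSE),
               cl[, c("sample_id", "prior_platinum", "prior_lines")],
               by = "sample_id")
  cov$prior_platinum <- as.numeric(cov$prior_platinum)
  cox <- cox_ph(cl, cov)
  out2 <- .write_tsv_out(
    data.frame(logrank_stat = lr$statistic, logrank_p = lr$p),
    file.path(outdir, "survival_test.tsv"))
  out3 <- .write_tsv_out(cox, file.path(outdir, "cox_model.tsv"))
  .write_stage_manifest(outdir, "survival", cfg, c(out1, out2, out3), ins)
}
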