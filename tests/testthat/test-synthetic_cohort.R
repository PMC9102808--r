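# The synthetic cohort generator: determinism and planted structure.

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 9)
  a <- simulate_cohort(cfg, include_sequence = FALSE)
  b <- simulate_cohort(cfg, include_sequence = FALSE)
  expect_identical(a$sv, b$sv)
  expect_identical(a$rsf, b$rsf)
  expect_identical(a$expression, b$expression)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
})

test_that("annotation plants the configured CFS regions with origin-free gene bodies", {
  cfg <- sim_config(n_cfs_regions = 13, seed = 7)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  cfs <- ann$genes[ann$genes$is_cfs, ]
  expect_equal(nrow(cfs), 13)
  mids <- floor((ann$peaks$start + ann$peaks$end) / 2)
  for (i in seq_len(nrow(cfs))) {
    inside <- ann$peaks$chrom == cfs$chrom[i] &
      mids > cfs$start[i] & mids < cfs$end[i]
    expect_equal(sum(inside), 0)
    # exactly two peaks bound the inter-peak window, spaced as configured
    at_bounds <- ann$peaks$chrom == cfs$chrom[i] &
      mids %in% c(cfs$left_peak[i], cfs$right_peak[i])
    expect_equal(sum(at_bounds), 2)
    expect_equal(cfs$right_peak[i] - cfs$left_peak[i],
                 cfg$cfs_interpeak_distance)
  }
})

test_that("background versus CFS inter-peak spacing matches the configured medians", {
  ann <- generate_annotation(sim_config(seed = 21), include_sequence = FALSE)
  iv <- consecutive_interpeak_intervals(ann$peaks)
  cfs <- ann$genes[ann$genes$is_cfs, ]
  at_cfs <- logical(nrow(iv))
  for (i in seq_len(nrow(cfs)))
    at_cfs <- at_cfs | (iv$chrom == cfs$chrom[i] &
                          iv$left == cfs$left_peak[i] &
                          iv$right == cfs$right_peak[i])
  expect_equal(sum(at_cfs), nrow(cfs))
  bg_median <- median(iv$width[!at_cfs])
  expect_gt(bg_median, 1.5e4)
  expect_lt(bg_median, 4e4)
  expect_equal(unique(iv$width[at_cfs]), 1.6e6)
})

test_that("reference sequence is AT-rich inside CFS gene bodies only", {
  cfg <- sim_config(n_cfs_regions = 2, n_background_genes = 2,
                    n_chromosomes = 1, chromosome_size = 1.2e7, seed = 5)
  ann <- generate_annotation(cfg, include_sequence = TRUE)
  at_frac <- function(s) {
    v <- utf8ToInt(s)
    mean(v == 65L | v == 84L)
  }
  cfs <- ann$genes[ann$genes$is_cfs, ]
  for (i in seq_len(nrow(cfs))) {
    body <- substr(ann$reference[cfs$chrom[i]], cfs$start[i] + 1, cfs$end[i])
    expect_gte(at_frac(body), 0.6)
  }
  outside <- substr(ann$reference[[1]], 1, min(ann$genes$start) - 1)
  expect_lt(abs(at_frac(outside) - 0.5), 0.02)
})

test_that("zero rates produce an empty SV cohort", {
  cfg <- tiny_sim_config(seed = 1, trdoff_del_rate = 0,
                         background_del_rate = 0, dup_rate = 0)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  svc <- generate_sv_cohort(ann, cfg)
  expect_equal(nrow(svc$sv), 0)
})

test_that("CFS deletions center on gene midpoints and stay between the peaks", {
  cfg <- sim_config(seed = 13)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  svc <- generate_sv_cohort(ann, cfg)
  dels <- svc$sv[svc$sv$origin == "cfs" & svc$sv$sv_type == "DEL", ]
  g <- ann$genes[match(dels$planted_gene, ann$genes$gene_id), ]
  rel <- ((dels$start + dels$end) / 2 - g$start) / (g$end - g$start)
  expect_gt(mean(rel), 0.45)
  expect_lt(mean(rel), 0.55)
  expect_true(all(dels$start > g$left_peak & dels$end < g$right_peak))
  expect_true(all(dels$size >= 1e4 & dels$size <= 1e6))
})

test_that("RSF-designated samples carry a higher hotspot deletion burden", {
  cfg <- sim_config(seed = 17)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  svc <- generate_sv_cohort(ann, cfg)
  counts <- table(factor(svc$sv$sample_id[svc$sv$origin == "cfs" &
                                            svc$sv$sv_type == "DEL"],
                         levels = svc$samples))
  expect_gt(median(counts[svc$rsf]), median(counts[!svc$rsf]))
})

test_that("expression is higher for CFS genes, with the configured zero fraction outside", {
  cfg <- sim_config(seed = 19)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  expr <- generate_expression(ann, cfg)
  expect_true(all(expr >= 0))
  med <- apply(expr, 1, median)
  is_cfs <- ann$genes$is_cfs
  expect_gt(median(med[is_cfs]), median(med[!is_cfs]))
  zero_frac <- mean(rowSums(expr[!is_cfs, ]) == 0)
  expect_gt(zero_frac, 0.1)
  expect_lt(zero_frac, 0.55)
  expect_true(all(rowSums(expr[is_cfs, ]) > 0))
})

test_that("junction reads abut their deletion exactly and decoys never do", {
  cfg <- tiny_sim_config(seed = 23, junction_del_fraction = 0.2)
  ann <- generate_annotation(cfg, include_sequence = FALSE)
  svc <- generate_sv_cohort(ann, cfg)
  dels <- svc$sv[svc$sv$sv_type == "DEL" & svc$sv$origin == "cfs", ]
  segs <- generate_junction_reads(dels, cfg)
  truth <- attr(segs, "junction_truth")
  expect_gt(nrow(truth), 0)
  for (i in seq_len(min(nrow(truth), 20))) {
    s <- segs[segs$read_id == truth$read_id[i], ]
    s <- s[order(s$read_offset), ]
    d <- dels[truth$del_index[i], ]
    expect_equal(s$end[1], d$start)
    expect_equal(s$start[2], d$end)
  }
  # zero junction rate emits only decoys
  cfg0 <- tiny_sim_config(seed = 23, junction_del_fraction = 0)
  segs0 <- generate_junction_reads(dels, cfg0)
  expect_equal(nrow(attr(segs0, "junction_truth")), 0)
  expect_true(all(startsWith(segs0$read_id, "DR")))
})

test_that("clinical generator honors censoring and consistency invariants", {
  cfg <- tiny_sim_config(seed = 29, censor_rate = 0)
  samples <- sprintf("S%03d", 1:40)
  rsf <- setNames(rep(c(TRUE, FALSE), c(6, 34)), samples)
  clin <- generate_clinical(samples, rsf, cfg)
  expect_true(all(clin$progression_event))
  expect_true(all(clin$pfs_days > 0))
  expect_true(all(clin$prior_lines[clin$prior_platinum] >= 1))

  cfg2 <- tiny_sim_config(seed = 29, censor_rate = 0.4)
  clin2 <- generate_clinical(samples, rsf, cfg2)
  expect_true(any(!clin2$progression_event))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(rsf_fraction = 1.2), "rsf_fraction")
  expect_error(sim_config(true_hr = 0), "true_hr")
  expect_error(sim_config(del_midpoint_sd = 0.8), "del_midpoint_sd")
  expect_error(sim_config(cfs_gene_length_range = c(6e5, 1.7e6)),
               "between its bordering peaks")
  expect_error(sim_config(trdoff_del_rate = -1), "trdoff_del_rate")
})
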