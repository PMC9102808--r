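# In-code fixtures shared across test files.

make_svs <- function(start, end, chrom = "chr1", sample_id = "S1",
                     sv_type = "DEL") {
  df <- data.frame(sample_id = sample_id, chrom = chrom, start = start,
                   end = end, sv_type = sv_type, stringsAsFactors = FALSE)
  df$size <- df$end - df$start
  df
}

make_intervals <- function(left, right, chrom = "chr1") {
  data.frame(chrom = chrom, left = left, right = right,
             width = right - left, stringsAsFactors = FALSE)
}

# a desk-scale config for plumbing tests (not the study conditions)
tiny_sim_config <- function(seed = 42, ...) {
  sim_config(n_samples = 40, n_cfs_regions = 5, n_background_genes = 8,
             n_chromosomes = 2, chromosome_size = 2.5e7, seed = seed, ...)
}

write_mini_vcf <- function(path, chrom, pos, end, svtype,
                           sample = "S1") {
  header <- c("##fileformat=VCFv4.2",
              '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
              '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample, sep = "\t"))
  body <- sprintf("%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d\tGT\t0/1",
                  chrom, pos, seq_along(pos), svtype, svtype, end)
  writeLines(c(header, body), path)
  path
}

random_clinical <- function(n, hr = 1, frac_pos = 0.3) {
  sample_id <- sprintf("P%03d", seq_len(n))
  grp <- runif(n) < frac_pos
  data.frame(sample_id = sample_id,
             prior_lines = rpois(n, 1) + 1,
             prior_platinum = FALSE,
             platinum_after_biopsy = TRUE,
             pfs_days = rexp(n, 0.01 * ifelse(grp, hr, 1)),
             progression_event = runif(n) > 0.2,
             group = ifelse(grp, "RSF+", "RSF-"),
             stringsAsFactors = FALSE)
}
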