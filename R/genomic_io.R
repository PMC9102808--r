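# Readers and writers for every on-disk format the pipeline touches, and the
# one place coordinate conventions are enforced.  Internal coordinates are
# 0-based half-open everywhere: VCF input (1-based POS) is converted here at
# the boundary, BED and the package's own TSV dialects are already 0-based
# half-open.

.read_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stopf("%s '%s' is missing required column(s): %s",
           what, path, paste(miss, collapse = ", "))
  df
}

.check_numeric <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    .stopf("non-numeric value '%s' in column '%s' of %s (row %d)",
           x[bad[1]], col, path, bad[1])
  v
}

.parse_flag <- function(x, col, path) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    .stopf("non-boolean value '%s' in column '%s' of %s (row %d)",
           x[bad[1]], col, path, bad[1])
  as.logical(out)
}

.validate_sv <- function(sv) {
  bad <- which(sv$end <= sv$start)
  if (length(bad))
    .stopf("SV record %d has end (%s) <= start (%s)",
           bad[1], format(sv$end[bad[1]], scientific = FALSE),
           format(sv$start[bad[1]], scientific = FALSE))
  if (any(sv$start < 0)) .stopf("SV record with negative start position")
  sv$size <- sv$end - sv$start
  sv
}

#' Read cohort structural-variant calls
#'
#' Accepts either the package TSV dialect (columns `sample_id`, `chrom`,
#' `start`, `end`, `sv_type`, 0-based half-open coordinates) or a simplified
#' VCF 4.x subset whose INFO field carries `SVTYPE` (`DEL`/`DUP`) and `END`,
#' with 1-based `POS`.  VCF records are converted to the internal 0-based
#' half-open convention (`start = POS - 1`, `end = END`); SV types other
#' than DEL/DUP are skipped with a logged count.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param sample_id sample identifier used for VCF input when the file has
#'   no genotype column.
#' @param chrom_style chromosome-name normalization, see [normalize_chrom()].
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `sv_type`, `size`.
#' @seealso [write_sv_calls()], [filter_dels_by_size()]
#' @export
read_sv_calls <- function(path, format = c("auto", "tsv", "vcf"),
                          sample_id = NULL,
                          chrom_style = c("asis", "strip", "add")) {
  format <- match.arg(format)
  chrom_style <- match.arg(chrom_style)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  sv <- if (format == "vcf") .read_sv_vcf(path, sample_id)
        else .read_sv_tsv(path)
  sv$chrom <- normalize_chrom(as.character(sv$chrom), chrom_style)
  .validate_sv(sv)
}

.read_sv_tsv <- function(path) {
  df <- .read_tsv(path, c("sample_id", "chrom", "start", "end", "sv_type"),
                  "SV table")
  if (nrow(df) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      sv_type = character(), stringsAsFactors = FALSE))
  df$start <- .check_numeric(df$start, "start", path)
  df$end <- .check_numeric(df$end, "end", path)
  keep <- df$sv_type %in% c("DEL", "DUP")
  if (any(!keep))
    .msgf("read_sv_calls: skipped %d record(s) with unsupported sv_type",
          sum(!keep))
  df <- df[keep, c("sample_id", "chrom", "start", "end", "sv_type"),
           drop = FALSE]
  rownames(df) <- NULL
  df
}

.read_sv_vcf <- function(path, sample_id) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  n_records <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      sv_type = character(), stringsAsFactors = FALSE)
  if (n_records == 0) return(empty)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty)
  info <- fix[, "INFO"]
  if (all(!grepl("(^|;)SVTYPE=", info)))
    .stopf("VCF '%s' lacks the required INFO field 'SVTYPE'", path)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  keep <- !is.na(svtype) & svtype %in% c("DEL", "DUP")
  if (any(!keep))
    .msgf("read_sv_calls: skipped %d record(s) with unsupported sv_type",
          sum(!keep))
  if (!any(keep)) return(empty)
  endv <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  pos <- as.numeric(fix[, "POS"])
  miss <- which(keep & is.na(endv))
  if (length(miss))
    .stopf("VCF record %d is missing the required INFO field 'END'", miss[1])
  bad <- which(keep & endv <= pos)
  if (length(bad))
    .stopf("VCF record %d has END (%s) <= POS (%s)", bad[1],
           format(endv[bad[1]], scientific = FALSE),
           format(pos[bad[1]], scientific = FALSE))
  sid <- if (!is.null(v@gt) && ncol(v@gt) > 1) colnames(v@gt)[2]
         else if (!is.null(sample_id)) sample_id else "sample"
  data.frame(sample_id = sid,
             chrom = fix[keep, "CHROM"],
             start = pos[keep] - 1,
             end = endv[keep],
             sv_type = svtype[keep],
             stringsAsFactors = FALSE)
}

#' Write structural-variant calls as TSV
#'
#' @param sv SV data.frame as returned by [read_sv_calls()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sv_calls <- function(sv, path) {
  utils::write.table(sv[, c("sample_id", "chrom", "start", "end", "sv_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Standard BED: 0-based half-open, no header.  Row order is preserved;
#' sorting is the caller's job.  Lines starting with `#`, `track` or
#' `browser` are ignored.
#'
#' @param path BED file.
#' @param chrom_style see [normalize_chrom()].
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  data_rows <- which(nzchar(trimws(lines)) &
                     !grepl("^(#|track|browser)", lines))
  if (!length(data_rows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines[data_rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    .stopf("invalid BED record at line %d: fewer than 3 fields",
           data_rows[which(nf < 3)[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    .stopf("invalid BED record at line %d: non-numeric coordinate",
           data_rows[which(is.na(start) | is.na(end))[1]])
  bad <- which(end <= start)
  if (length(bad))
    .stopf("invalid BED record at line %d: end (%s) <= start (%s)",
           data_rows[bad[1]],
           format(end[bad[1]], scientific = FALSE),
           format(start[bad[1]], scientific = FALSE))
  data.frame(chrom = normalize_chrom(chrom, chrom_style),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Write intervals as BED3
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' TSV with columns `gene_id`, `name`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open; strand `+`/`-`, the Unicode minus is accepted).
#'
#' @param path input TSV.
#' @param chrom_style see [normalize_chrom()].
#' @return data.frame with the input columns plus derived `length`.
#' @export
read_gene_table <- function(path, chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  df <- .read_tsv(path, c("gene_id", "name", "chrom", "start", "end",
                          "strand"), "gene table")
  df$start <- .check_numeric(df$start, "start", path)
  df$end <- .check_numeric(df$end, "end", path)
  df$strand <- gsub("−", "-", as.character(df$strand))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    .stopf("unknown strand symbol '%s' in %s (row %d)",
           df$strand[bad[1]], path, bad[1])
  bad <- which(df$end <= df$start)
  if (length(bad))
    .stopf("gene record %d has end <= start", bad[1])
  df$chrom <- normalize_chrom(as.character(df$chrom), chrom_style)
  df$length <- df$end - df$start
  df
}

#' Write a gene-model table as TSV
#' @param genes gene data.frame (see [read_gene_table()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "name", "chrom", "start", "end",
                               "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression table
#'
#' TSV whose first column is `gene_id` and remaining columns are samples;
#' values are non-negative (TPM-like).
#'
#' @param path input TSV.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path, "gene_id", "expression table")
  if (ncol(df) < 2) .stopf("expression table '%s' has no sample columns", path)
  genes <- as.character(df$gene_id)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    .stopf("non-numeric expression value for gene '%s', sample '%s'",
           genes[idx[1]], colnames(m)[idx[2]])
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    .stopf("negative expression value (%g) for gene '%s', sample '%s'",
           m[idx[1], idx[2]], genes[idx[1]], colnames(m)[idx[2]])
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix, genes in rows.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient clinical records
#'
#' TSV with columns `sample_id`, `prior_lines`, `prior_platinum`,
#' `platinum_after_biopsy`, `pfs_days`, `progression_event`.
#' `pfs_days` must be positive; `progression_event` is TRUE for progression
#' and FALSE for censoring; `prior_platinum` implies `prior_lines >= 1`.
#'
#' @param path input TSV.
#' @return data.frame of typed clinical records.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path, c("sample_id", "prior_lines", "prior_platinum",
                          "platinum_after_biopsy", "pfs_days",
                          "progression_event"), "clinical table")
  df$prior_lines <- .check_numeric(df$prior_lines, "prior_lines", path)
  df$pfs_days <- .check_numeric(df$pfs_days, "pfs_days", path)
  df$prior_platinum <- .parse_flag(df$prior_platinum, "prior_platinum", path)
  df$platinum_after_biopsy <-
    .parse_flag(df$platinum_after_biopsy, "platinum_after_biopsy", path)
  df$progression_event <-
    .parse_flag(df$progression_event, "progression_event", path)
  bad <- which(df$pfs_days <= 0)
  if (length(bad))
    .stopf("clinical record %d has non-positive pfs_days (%g)",
           bad[1], df$pfs_days[bad[1]])
  bad <- which(df$prior_lines < 0)
  if (length(bad)) .stopf("clinical record %d has negative prior_lines", bad[1])
  bad <- which(df$prior_platinum & df$prior_lines < 1)
  if (length(bad))
    .stopf("clinical record %d has prior_platinum but prior_lines = 0", bad[1])
  df
}

#' Write clinical records as TSV
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read aligned read segments
#'
#' TSV of pre-tabulated split-read segments with columns `read_id`,
#' `sample_id`, `chrom`, `start`, `end`, `read_offset` (and optionally
#' `mapq`); 0-based half-open reference coordinates, `read_offset` is the
#' segment's position within the read.
#'
#' @param path input TSV.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path, c("read_id", "sample_id", "chrom", "start", "end",
                          "read_offset"), "segment table")
  df$start <- .check_numeric(df$start, "start", path)
  df$end <- .check_numeric(df$end, "end", path)
  df$read_offset <- .check_numeric(df$read_offset, "read_offset", path)
  bad <- which(df$end <= df$start)
  if (length(bad)) .stopf("segment record %d has end <= start", bad[1])
  bad <- which(df$read_offset < 0)
  if (length(bad))
    .stopf("segment record %d has negative read_offset", bad[1])
  df
}

#' Write aligned read segments as TSV
#' @param segments segment data.frame (see [read_segments()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
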