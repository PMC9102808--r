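# Expression comparison of large genes inside versus outside hotspot
# regions.  Selection mirrors the positional logic of the fork analysis:
# only genes that themselves lie between consecutive origin peaks enter,
# so the comparison isolates transcription rather than genomic context.

#' Select large candidate genes inside and outside hotspots
#'
#' Keeps genes with length strictly greater than `min_length` whose entire
#' interval lies strictly between one consecutive peak-midpoint pair, then
#' partitions them by overlap with any hotspot region.  The partition is
#' exhaustive and disjoint.
#'
#' @param genes gene table.
#' @param interpeak_intervals output of
#'   [consecutive_interpeak_intervals()].
#' @param hotspots hotspot regions from [call_hotspots()].
#' @param min_length bp threshold (strict; default 500 kb).
#' @return list with data.frames `inside` and `outside`.
#' @export
select_candidate_genes <- function(genes, interpeak_intervals, hotspots,
                                   min_length = 5e5) {
  big <- genes[genes$length > min_length, , drop = FALSE]
  if (nrow(big)) {
    contained <- classify_containment(
      data.frame(chrom = big$chrom, start = big$start, end = big$end),
      interpeak_intervals)
    big <- big[contained, , drop = FALSE]
  }
  inside <- .overlaps_any(big$chrom, big$start, big$end,
                          hotspots$chrom, hotspots$start, hotspots$end)
  list(inside = {x <- big[inside, , drop = FALSE]; rownames(x) <- NULL; x},
       outside = {x <- big[!inside, , drop = FALSE]; rownames(x) <- NULL; x})
}

#' Per-gene median expression across samples
#'
#' @param expr gene-by-sample matrix (see [read_expression()]).
#' @param gene_ids genes to summarize; genes absent from the table are
#'   skipped with a logged count.
#' @return named numeric vector of per-gene medians.
#' @export
median_expression_per_gene <- function(expr, gene_ids) {
  present <- gene_ids %in% rownames(expr)
  if (any(!present))
    .msgf("median_expression_per_gene: %d gene(s) absent from the table",
          sum(!present))
  ids <- gene_ids[present]
  apply(expr[ids, , drop = FALSE], 1, stats::median)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test reporting the U statistic of the first group.
#' With both groups of size at most 8 and no ties the p-value is computed
#' by exact enumeration of the U distribution; otherwise the normal
#' approximation with tie correction is used (no continuity correction).
#' Two constant, equal groups give `p = 1`.
#'
#' @param group_a,group_b numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   with respect to `group_a`.
#' @return list with `U` (for `group_a`) and `p`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(group_a) || !length(group_b))
    .stopf("mann_whitney_u: both groups need >= 1 value")
  pooled <- c(group_a, group_b)
  n1 <- length(group_a); n2 <- length(group_b)
  if (length(unique(pooled)) == 1)
    return(list(U = n1 * n2 / 2, p = 1))
  exact <- n1 <= 8 && n2 <= 8 && !anyDuplicated(pooled)
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = min(unname(wt$p.value), 1))
}
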