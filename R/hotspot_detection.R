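# Hotspot calling: single-linkage clustering of size-selected deletions
# into recurrent regions, region annotation, and breakpoint base
# composition.

#' Filter deletions by size
#'
#' Retains DEL records whose size lies in `[min_size, max_size]` (inclusive
#' at both ends); DUPs and out-of-range DELs are removed.  The defaults
#' select the 10 kb-1 Mb deletions characteristic of common fragile sites.
#'
#' @param svs SV data.frame (see [read_sv_calls()]).
#' @param min_size,max_size inclusive size bounds in bp.
#' @return the filtered SV data.frame.
#' @export
filter_dels_by_size <- function(svs, min_size = 1e4, max_size = 1e6) {
  if (min_size >= max_size)
    .stopf("filter_dels_by_size: min_size must be < max_size")
  sz <- if ("size" %in% names(svs)) svs$size else svs$end - svs$start
  out <- svs[svs$sv_type == "DEL" & sz >= min_size & sz <= max_size, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call deletion hotspot regions
#'
#' Per chromosome, deletions are clustered by single linkage: two
#' deletions join one cluster when their intervals overlap or lie within
#' `merge_gap` of each other.  Clusters with at least `min_events` member
#' deletions become hotspot regions spanning the first deletion start to
#' the last deletion end.  "Events" count deletion records, not distinct
#' samples: recurrently hit samples typically carry several overlapping
#' deletions in one region.
#'
#' @param dels size-filtered deletions (see [filter_dels_by_size()]).
#' @param min_events minimum deletion records per cluster (default 150).
#' @param merge_gap bp gap within which deletions are linked (default
#'   100 kb).
#' @param genes optional gene table; when supplied each region is annotated
#'   with its nearest gene (see [annotate_nearest_gene()]).
#' @return data.frame of class `"cfs_hotspots"`, sorted by chromosome then
#'   start, with columns `chrom`, `start`, `end`, `n_events`,
#'   `n_samples_multi` (samples with more than one deletion intersecting
#'   the region) and, when `genes` is given, `nearest_gene` and
#'   `gene_distance`.
#' @examples
#' dels <- data.frame(sample_id = "S1", chrom = "chr1",
#'                    start = rep(1e6, 150), end = rep(1.2e6, 150),
#'                    sv_type = "DEL", size = 2e5)
#' call_hotspots(dels)
#' @export
call_hotspots <- function(dels, min_events = 150, merge_gap = 1e5,
                          genes = NULL) {
  if (min_events < 1) .stopf("call_hotspots: min_events must be >= 1")
  if (merge_gap < 0) .stopf("call_hotspots: merge_gap must be >= 0")
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_events = integer(),
                      n_samples_multi = integer(), stringsAsFactors = FALSE)
  if (nrow(dels) == 0) {
    class(empty) <- c("cfs_hotspots", "data.frame")
    return(empty)
  }
  out <- list()
  for (ch in sort(unique(dels$chrom))) {
    d <- dels[dels$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(.ir(d$start, d$end),
                           min.gapwidth = merge_gap + 1, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    n_ev <- lengths(revmap)
    keep <- which(n_ev >= min_events)
    for (k in keep) {
      members <- d[revmap[[k]], , drop = FALSE]
      region_start <- min(members$start)
      region_end <- max(members$end)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = region_start, end = region_end,
        n_events = n_ev[k],
        n_samples_multi = .n_multi(members$sample_id),
        stringsAsFactors = FALSE)
    }
  }
  hs <- if (length(out)) do.call(rbind, out) else empty
  hs <- hs[order(hs$chrom, hs$start), , drop = FALSE]
  rownames(hs) <- NULL
  if (!is.null(genes) && nrow(hs)) {
    ann <- annotate_nearest_gene(hs, genes)
    hs$nearest_gene <- ann$nearest_gene
    hs$gene_distance <- ann$gene_distance
  }
  class(hs) <- c("cfs_hotspots", "data.frame")
  hs
}

.n_multi <- function(sample_ids) {
  sum(table(sample_ids) >= 2)
}

#' @export
print.cfs_hotspots <- function(x, ...) {
  cat(sprintf("Deletion hotspot regions: %d\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  total events: %d; span %.1f-%.1f kb\n",
                sum(x$n_events), min(x$end - x$start) / 1e3,
                max(x$end - x$start) / 1e3))
    print.data.frame(as.data.frame(x), ...)
  }
  invisible(x)
}

#' Count samples with multiple deletions in a region
#'
#' Number of distinct samples having at least two deletions whose
#' intervals intersect the region.
#'
#' @param region a single-row data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param dels size-filtered deletions.
#' @return integer count.
#' @export
count_multi_del_samples <- function(region, dels) {
  hit <- dels$chrom == region$chrom[1] & dels$start < region$end[1] &
    dels$end > region$start[1]
  .n_multi(dels$sample_id[hit])
}

#' Annotate regions with their nearest gene
#'
#' Distance is 0 for any overlap; ties are broken by the smaller gene
#' start.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes gene table (see [read_gene_table()]).
#' @return data.frame with `nearest_gene` and `gene_distance` per region.
#' @export
annotate_nearest_gene <- function(regions, genes) {
  if (!nrow(genes)) .stopf("annotate_nearest_gene: empty gene table")
  n <- nrow(regions)
  nearest <- character(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(g)) { nearest[i] <- NA_character_; dist[i] <- NA_real_; next }
    d <- .interval_distance(regions$start[i], regions$end[i],
                            g$start, g$end)
    ord <- order(d, g$start)
    nearest[i] <- g$gene_id[ord[1]]
    dist[i] <- d[ord[1]]
  }
  data.frame(nearest_gene = nearest, gene_distance = dist,
             stringsAsFactors = FALSE)
}

#' Base frequencies around deletion breakpoints
#'
#' Pools both breakpoints of every deletion (the 0-based start and end
#' positions), extracts windows of `flank` bp on either side from the
#' reference, and tabulates per-offset base frequencies.  Offset 0 is the
#' breakpoint base itself.  Windows truncated at chromosome ends are
#' skipped with a logged count.
#'
#' @param dels deletion data.frame.
#' @param reference named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param flank window half-width in bp (default 20).
#' @return 4 x (2*flank+1) matrix of frequencies (rows A, C, G, T; columns
#'   named by offset), with attributes `n_windows` and `n_skipped`.  Each
#'   column sums to 1.
#' @export
breakpoint_base_frequencies <- function(dels, reference, flank = 20) {
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  miss <- setdiff(unique(dels$chrom), names(reference))
  if (length(miss))
    .stopf("breakpoint_base_frequencies: chromosome '%s' absent from %s",
           miss[1], "the reference")
  bp_chrom <- rep(dels$chrom, 2)
  bp_pos <- c(dels$start, dels$end)
  width <- 2 * flank + 1
  chrom_len <- setNames(nchar(reference), names(reference))
  ok <- bp_pos - flank >= 0 & bp_pos + flank + 1 <= chrom_len[bp_chrom]
  if (any(!ok))
    .msgf("breakpoint_base_frequencies: skipped %d window(s) at %s",
          sum(!ok), "chromosome ends")
  bp_chrom <- bp_chrom[ok]; bp_pos <- bp_pos[ok]
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"),
                                   as.character(-flank:flank)))
  if (length(bp_pos)) {
    win <- substring(reference[bp_chrom], bp_pos - flank + 1,
                     bp_pos + flank + 1)
    chars <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                    nrow = width)
    for (j in seq_len(width)) {
      tab <- table(factor(chars[j, ], levels = c("A", "C", "G", "T")))
      counts[, j] <- as.integer(tab)
    }
  }
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1L), "/")
  attr(freq, "n_windows") <- length(bp_pos)
  attr(freq, "n_skipped") <- sum(!ok)
  freq
}
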