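# Transcription-orientation-corrected positions of SVs within hotspot
# genes.  Under double-fork failure, deletions concentrate at the gene
# midpoint and duplications at the flanks, independent of strand.

#' Strand-corrected relative position of SVs within genes
#'
#' Each SV is assigned to the gene containing its midpoint (an SV whose
#' midpoint falls in no gene is unassigned, `NA`), and its relative
#' position `r = (midpoint - gene_start) / gene_length` is flipped to
#' `1 - r` for minus-strand genes, so 0 is always the transcription start
#' and 1 the transcription end.  Midpoint assignment gives every SV at
#' most one position per gene, the single-point summary that a
#' "centered around the midpoint" statement needs; where two genes share
#' an origin-free window, each SV goes to the gene containing its
#' midpoint.
#'
#' @param svs SV data.frame.
#' @param genes gene table with strand.
#' @return the SV data.frame plus columns `gene_id` (NA when unassigned)
#'   and `rel_pos` in `[0, 1]`.
#' @export
strand_corrected_position <- function(svs, genes) {
  if (any(genes$end <= genes$start))
    .stopf("strand_corrected_position: zero-length gene")
  mid <- (svs$start + svs$end) / 2
  gene_id <- rep(NA_character_, nrow(svs))
  rel <- rep(NA_real_, nrow(svs))
  for (ch in unique(svs$chrom)) {
    i <- which(svs$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$start), , drop = FALSE]
    k <- findInterval(mid[i], g$start)
    ok <- k >= 1
    ok[ok] <- mid[i][ok] < g$end[k[ok]]
    hit <- i[ok]; gk <- k[ok]
    gene_id[hit] <- g$gene_id[gk]
    r <- (mid[hit] - g$start[gk]) / (g$end[gk] - g$start[gk])
    rel[hit] <- ifelse(g$strand[gk] == "-", 1 - r, r)
  }
  svs$gene_id <- gene_id
  svs$rel_pos <- rel
  svs
}

#' Histogram of relative positions
#'
#' Equal-width bins on `[0, 1]`; the last bin is right-closed.  Densities
#' integrate to 1 (`sum(density) * binwidth = 1`).
#'
#' @param positions numeric vector in `[0, 1]` (NAs dropped).
#' @param n_bins number of bins (default 20).
#' @return list with `edges` (length `n_bins + 1`), `counts`, `density`,
#'   `n`.
#' @export
position_profile <- function(positions, n_bins = 20) {
  if (n_bins < 2) .stopf("position_profile: n_bins must be >= 2")
  positions <- positions[!is.na(positions)]
  edges <- seq(0, 1, length.out = n_bins + 1)
  if (!length(positions))
    return(list(edges = edges, counts = integer(n_bins),
                density = numeric(n_bins), n = 0L))
  idx <- findInterval(positions, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  width <- 1 / n_bins
  list(edges = edges, counts = counts,
       density = counts / (sum(counts) * width), n = length(positions))
}

#' Test that deletions are more midpoint-concentrated than duplications
#'
#' One-sided two-sample Mann-Whitney test on the distances of relative
#' positions from 0.5: deletions are expected to lie closer to the
#' midpoint (smaller `|position - 0.5|`) than duplications.
#'
#' @param del_positions,dup_positions relative positions in `[0, 1]`.
#' @return list with `statistic` (the U of the deletion group) and `p`
#'   (one-sided).
#' @export
midpoint_concentration_test <- function(del_positions, dup_positions) {
  del_positions <- del_positions[!is.na(del_positions)]
  dup_positions <- dup_positions[!is.na(dup_positions)]
  if (length(del_positions) < 2 || length(dup_positions) < 2)
    .stopf("midpoint_concentration_test: need >= 2 positions per group")
  mann_whitney_u(abs(del_positions - 0.5), abs(dup_positions - 0.5),
                 alternative = "less")
}
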