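# Split-read junction support: RNA-seq reads whose two aligned segments
# abut a deletion's breakpoints demonstrate transcription across the
# deletion junction.

#' Match split reads to deletion junctions
#'
#' Segments sharing a `read_id` and `sample_id` are paired, ordered by
#' `read_offset` (reads with three or more segments use the first and last
#' segment).  A pair matches a deletion of the same sample when segment A
#' ends within `tolerance` bp of the deletion start and segment B starts
#' within `tolerance` bp of the deletion end, both on the deletion's
#' chromosome.  Each read pair matches at most one deletion: the smallest
#' combined gap wins, ties go to the smaller deletion start.
#'
#' @param segments aligned segments (see [read_segments()]).
#' @param dels deletion data.frame.
#' @param tolerance bp slack on breakpoint abutment (default 5; 0 demands
#'   exact abutment).
#' @param min_mapq optional minimum mapping quality, applied when the
#'   segments carry a `mapq` column.
#' @return data.frame of matches: `read_id`, `sample_id`, `del_index` (row
#'   in `dels`), `five_prime_gap`, `three_prime_gap`.
#' @export
match_junction_reads <- function(segments, dels, tolerance = 5,
                                 min_mapq = NULL) {
  if (tolerance < 0) .stopf("match_junction_reads: tolerance must be >= 0")
  empty <- data.frame(read_id = character(), sample_id = character(),
                      del_index = integer(), five_prime_gap = numeric(),
                      three_prime_gap = numeric(), stringsAsFactors = FALSE)
  if (!nrow(segments) || !nrow(dels)) return(empty)
  if (!is.null(min_mapq) && "mapq" %in% names(segments))
    segments <- segments[segments$mapq >= min_mapq, , drop = FALSE]
  key <- paste(segments$sample_id, segments$read_id, sep = "\r")
  groups <- split(seq_len(nrow(segments)), key)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) return(empty)
  dkey <- paste(dels$sample_id, dels$chrom, sep = "\r")
  dsplit <- split(seq_len(nrow(dels)), dkey)
  out <- list()
  for (g in groups) {
    off <- segments$read_offset[g]
    if (min(off) == max(off)) {
      .warnf("match_junction_reads: read '%s' has equal read offsets, skipped",
             segments$read_id[g[1]])
      next
    }
    a <- g[which.min(off)]
    b <- g[which.max(off)]
    if (segments$chrom[a] != segments$chrom[b]) next
    cand <- dsplit[[paste(segments$sample_id[a], segments$chrom[a],
                          sep = "\r")]]
    if (is.null(cand)) next
    gap5 <- abs(segments$end[a] - dels$start[cand])
    gap3 <- abs(segments$start[b] - dels$end[cand])
    ok <- gap5 <= tolerance & gap3 <= tolerance
    if (!any(ok)) next
    cand <- cand[ok]; gap5 <- gap5[ok]; gap3 <- gap3[ok]
    best <- order(gap5 + gap3, dels$start[cand])[1]
    out[[length(out) + 1L]] <- data.frame(
      read_id = segments$read_id[a], sample_id = segments$sample_id[a],
      del_index = cand[best], five_prime_gap = gap5[best],
      three_prime_gap = gap3[best], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  res
}

#' Summarize junction support per sample and hotspot region
#'
#' Matches are assigned to hotspot regions via the matched deletion's
#' overlap with the region; the summary reports, per sample and region,
#' the number of supporting reads and the number of distinct deletions
#' with at least one supporting read, plus per-region sample counts and
#' overall totals.
#'
#' @param matches output of [match_junction_reads()].
#' @param dels the deletion data.frame the matches refer to.
#' @param hotspots hotspot regions.
#' @return list with `per_sample_region` (data.frame: `sample_id`,
#'   `region`, `n_reads`, `n_dels_supported`), `per_region` (data.frame:
#'   `region`, `n_samples`), `total_reads`, `n_samples`.
#' @export
summarize_support <- function(matches, dels, hotspots) {
  region_label <- function(i)
    sprintf("%s:%s-%s", hotspots$chrom[i],
            format(hotspots$start[i], scientific = FALSE, trim = TRUE),
            format(hotspots$end[i], scientific = FALSE, trim = TRUE))
  if (!nrow(matches))
    return(list(per_sample_region = data.frame(sample_id = character(),
                                               region = character(),
                                               n_reads = integer(),
                                               n_dels_supported = integer(),
                                               stringsAsFactors = FALSE),
                per_region = data.frame(region = character(),
                                        n_samples = integer(),
                                        stringsAsFactors = FALSE),
                total_reads = 0L, n_samples = 0L))
  d <- dels[matches$del_index, , drop = FALSE]
  region <- rep(NA_character_, nrow(matches))
  for (i in seq_len(nrow(hotspots))) {
    hit <- d$chrom == hotspots$chrom[i] & d$start < hotspots$end[i] &
      d$end > hotspots$start[i]
    region[hit & is.na(region)] <- region_label(i)
  }
  df <- data.frame(sample_id = matches$sample_id, region = region,
                   del_index = matches$del_index, stringsAsFactors = FALSE)
  df <- df[!is.na(df$region), , drop = FALSE]
  agg <- if (nrow(df)) {
    sp <- split(df, paste(df$sample_id, df$region, sep = "\r"))
    do.call(rbind, lapply(sp, function(x) data.frame(
      sample_id = x$sample_id[1], region = x$region[1],
      n_reads = nrow(x), n_dels_supported = length(unique(x$del_index)),
      stringsAsFactors = FALSE)))
  } else data.frame(sample_id = character(), region = character(),
                    n_reads = integer(), n_dels_supported = integer(),
                    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  per_region <- if (nrow(agg)) {
    sp <- split(agg, agg$region)
    do.call(rbind, lapply(sp, function(x) data.frame(
      region = x$region[1], n_samples = length(unique(x$sample_id)),
      stringsAsFactors = FALSE)))
  } else data.frame(region = character(), n_samples = integer(),
                    stringsAsFactors = FALSE)
  rownames(per_region) <- NULL
  list(per_sample_region = agg, per_region = per_region,
       total_reads = nrow(df),
       n_samples = length(unique(df$sample_id)))
}
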