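# Replication-origin interval analysis: are deletions bracketed by
# consecutive Ini-seq peaks (or TAD boundaries), how strongly is that
# enriched inside hotspot regions, and where do deletions sit within the
# bracketing interval?

#' Consecutive inter-peak intervals
#'
#' For each chromosome with k peaks, emits the k-1 intervals joining
#' consecutive peak midpoints.  Peaks may be points or intervals in the
#' input; all computations use the midpoint `floor((start+end)/2)`.
#' Duplicate midpoints are dropped with a warning (a zero-width interval
#' carries no information); chromosomes with fewer than two peaks produce
#' no intervals.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @return data.frame with `chrom`, `left`, `right` (bp midpoints) and
#'   `width`.
#' @export
consecutive_interpeak_intervals <- function(peaks) {
  out <- list()
  mid <- floor((peaks$start + peaks$end) / 2)
  for (ch in sort(unique(peaks$chrom))) {
    m <- sort(mid[peaks$chrom == ch])
    dup <- duplicated(m)
    if (any(dup)) {
      .warnf("consecutive_interpeak_intervals: dropped %d duplicate peak %s",
             sum(dup), sprintf("midpoint(s) on %s", ch))
      m <- m[!dup]
    }
    if (length(m) < 2) {
      .msgf("consecutive_interpeak_intervals: %s has < 2 peaks, no intervals",
            ch)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, left = m[-length(m)], right = m[-1],
      stringsAsFactors = FALSE)
  }
  iv <- if (length(out)) do.call(rbind, out)
        else data.frame(chrom = character(), left = numeric(),
                        right = numeric(), stringsAsFactors = FALSE)
  iv$width <- iv$right - iv$left
  rownames(iv) <- NULL
  iv
}

#' Consecutive intervals from TAD annotation
#'
#' The notion of a deletion lying "between TADs" is implemented on
#' intervals derived from the TAD annotation in one of two ways:
#' `"midpoint"` joins consecutive TAD-interval midpoints (the same
#' machinery as for origin peaks), `"gap"` uses the gaps between
#' consecutive TAD annotation blocks.
#'
#' @param tads data.frame with `chrom`, `start`, `end`.
#' @param mode `"midpoint"` or `"gap"`.
#' @return data.frame with `chrom`, `left`, `right`, `width`.
#' @export
tad_intervals <- function(tads, mode = c("midpoint", "gap")) {
  mode <- match.arg(mode)
  if (mode == "midpoint") return(consecutive_interpeak_intervals(tads))
  out <- list()
  for (ch in sort(unique(tads$chrom))) {
    t <- tads[tads$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    if (nrow(t) < 2) next
    left <- t$end[-nrow(t)]
    right <- t$start[-1]
    keep <- right > left
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, left = left[keep], right = right[keep],
        stringsAsFactors = FALSE)
  }
  iv <- if (length(out)) do.call(rbind, out)
        else data.frame(chrom = character(), left = numeric(),
                        right = numeric(), stringsAsFactors = FALSE)
  iv$width <- iv$right - iv$left
  rownames(iv) <- NULL
  iv
}

# index of the interval strictly containing each interval of (chrom, start,
# end), or NA.  Containment is strict: left < start and end < right, so a
# breakpoint exactly on a peak midpoint counts as not-between.
.containing_interval <- function(chrom, start, end, intervals) {
  idx <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    iv <- which(intervals$chrom == ch)
    if (!length(iv)) next
    lefts <- intervals$left[iv]
    rights <- intervals$right[iv]
    ord <- order(lefts)
    lefts <- lefts[ord]; rights <- rights[ord]; iv <- iv[ord]
    # position of the last left endpoint strictly below each start
    k <- findInterval(start[i], lefts)
    at_edge <- k >= 1 & lefts[pmax(k, 1)] == start[i]
    k[at_edge] <- 0L  # left == start violates strict containment
    ok <- k >= 1
    ok[ok] <- end[i][ok] < rights[k[ok]]
    idx[i][ok] <- iv[k[ok]]
  }
  idx
}

#' Classify deletions as between consecutive peaks
#'
#' TRUE when both breakpoints of the deletion lie strictly inside one
#' inter-peak interval: there is an interval with `left < start` and
#' `end < right`, hence no peak midpoint inside (or on a boundary of) the
#' deletion.  The same operation is reused with TAD-derived intervals.
#'
#' @param dels deletion data.frame with `chrom`, `start`, `end`.
#' @param intervals output of [consecutive_interpeak_intervals()] or
#'   [tad_intervals()].
#' @return logical vector, one element per deletion.
#' @export
classify_containment <- function(dels, intervals) {
  !is.na(.containing_interval(dels$chrom, dels$start, dels$end, intervals))
}

#' Relative position of deletion midpoints between peaks
#'
#' For deletions strictly contained in an inter-peak interval, the
#' position of the deletion midpoint within the interval, in (0, 1).
#' Deletions not contained in any interval get `NA`.
#'
#' @inheritParams classify_containment
#' @return numeric vector of relative positions (NA where uncontained).
#' @export
relative_midpoint_position <- function(dels, intervals) {
  idx <- .containing_interval(dels$chrom, dels$start, dels$end, intervals)
  pos <- rep(NA_real_, nrow(dels))
  ok <- !is.na(idx)
  if (any(ok)) {
    left <- intervals$left[idx[ok]]
    right <- intervals$right[idx[ok]]
    pos[ok] <- ((dels$start[ok] + dels$end[ok]) / 2 - left) / (right - left)
  }
  pos
}

#' Per-deletion containment record table
#'
#' One row per deletion with the flags every enrichment analysis consumes:
#' between consecutive origin peaks, between TAD-derived intervals, and
#' inside (overlapping) a hotspot region, plus the relative midpoint
#' position within the containing inter-peak interval.
#'
#' @param dels size-filtered deletions.
#' @param peak_intervals intervals from [consecutive_interpeak_intervals()].
#' @param tad_ivs intervals from [tad_intervals()] (optional).
#' @param hotspots hotspot regions from [call_hotspots()].
#' @return data.frame: the deletion columns plus `between_peaks`,
#'   `between_tads` (NA-free logical, FALSE when `tad_ivs` is NULL),
#'   `in_hotspot`, `rel_position`.
#' @export
containment_table <- function(dels, peak_intervals, tad_ivs = NULL,
                              hotspots) {
  rec <- dels
  rec$between_peaks <- classify_containment(dels, peak_intervals)
  rec$between_tads <- if (is.null(tad_ivs)) FALSE
                      else classify_containment(dels, tad_ivs)
  rec$in_hotspot <- .overlaps_any(dels$chrom, dels$start, dels$end,
                                  hotspots$chrom, hotspots$start,
                                  hotspots$end)
  rec$rel_position <- relative_midpoint_position(dels, peak_intervals)
  rec
}

#' Cross-tabulate hotspot membership against containment
#'
#' Builds the 2x2 table `a` = in-hotspot & between, `b` = in-hotspot &
#' not-between, `c` = outside & between, `d` = outside & not-between, and
#' reports the two proportions rounded (half away from zero) to whole
#' percent.
#'
#' @param records output of [containment_table()].
#' @param flag which containment flag to tabulate: `"peaks"` or `"tads"`.
#' @return list of class `"contingency_2x2"` with `a`, `b`, `c`, `d`,
#'   `pct_inside`, `pct_outside`.
#' @export
containment_contingency <- function(records, flag = c("peaks", "tads")) {
  flag <- match.arg(flag)
  btw <- if (flag == "peaks") records$between_peaks else records$between_tads
  inh <- records$in_hotspot
  tbl <- list(a = sum(inh & btw), b = sum(inh & !btw),
              c = sum(!inh & btw), d = sum(!inh & !btw))
  tbl$pct_inside <- if (tbl$a + tbl$b > 0)
    .round_half_away(100 * tbl$a / (tbl$a + tbl$b)) else NA_real_
  tbl$pct_outside <- if (tbl$c + tbl$d > 0)
    .round_half_away(100 * tbl$c / (tbl$c + tbl$d)) else NA_real_
  class(tbl) <- "contingency_2x2"
  tbl
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 containment table\n")
  cat(sprintf("  inside hotspot : %d between / %d not (%s%%)\n",
              x$a, x$b, format(x$pct_inside)))
  cat(sprintf("  outside hotspot: %d between / %d not (%s%%)\n",
              x$c, x$d, format(x$pct_outside)))
  invisible(x)
}

.as_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2"))
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  else if (is.numeric(table) && length(table) == 4)
    setNames(as.numeric(table), c("a", "b", "c", "d"))
  else .stopf("expected a contingency_2x2 or a numeric vector (a, b, c, d)")
}

#' Odds ratio of a 2x2 table
#'
#' Point estimate `(a*d)/(b*c)` with the Wald standard error of the log
#' odds ratio and its 95% confidence interval.  When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and the
#' result is flagged; two zero cells in the same row or column leave the
#' estimate undefined (flagged, `NA`).
#'
#' @param table a `contingency_2x2` or numeric `c(a, b, c, d)`.
#' @return list with `or`, `log_or_se`, `ci95` (length-2), `haldane`,
#'   `undefined`.
#' @examples
#' odds_ratio(c(4836, 401, 6488, 3065))$or  # 5.697
#' @export
odds_ratio <- function(table) {
  x <- .as_2x2(table)
  undefined <- (x["a"] == 0 && x["b"] == 0) || (x["c"] == 0 && x["d"] == 0) ||
    (x["a"] == 0 && x["c"] == 0) || (x["b"] == 0 && x["d"] == 0)
  if (undefined)
    return(list(or = NA_real_, log_or_se = NA_real_,
                ci95 = c(NA_real_, NA_real_), haldane = FALSE,
                undefined = TRUE))
  haldane <- any(x == 0)
  xa <- if (haldane) x + 0.5 else x
  or <- unname((xa["a"] * xa["d"]) / (xa["b"] * xa["c"]))
  se <- unname(sqrt(sum(1 / xa)))
  z <- qnorm(0.975)
  list(or = or, log_or_se = se,
       ci95 = exp(log(or) + c(-1, 1) * z * se),
       haldane = haldane, undefined = FALSE)
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Pearson statistic without continuity correction, 1 degree of freedom,
#' upper-tail p-value.
#'
#' @param table a `contingency_2x2` or numeric `c(a, b, c, d)`.
#' @return list with `statistic` and `p`.
#' @export
chi_square_test <- function(table) {
  x <- .as_2x2(table)
  m <- matrix(x, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stopf("chi_square_test: zero marginal (expected count zero)")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Multivariable logistic enrichment of hotspot membership
#'
#' Maximum-likelihood logistic regression of `in_hotspot` on the
#' containment flags (with intercept), reporting Wald odds ratios, 95%
#' confidence intervals and p-values per predictor.  Complete separation
#' is flagged (infinite-OR marker) rather than raised.
#'
#' @param records output of [containment_table()].
#' @param predictors containment columns to include.
#' @return data.frame with one row per predictor: `predictor`, `or`,
#'   `ci_low`, `ci_high`, `p`, `flagged`.
#' @export
logistic_enrichment <- function(records,
                                predictors = c("between_peaks",
                                               "between_tads")) {
  predictors <- intersect(predictors, names(records))
  if (!length(predictors)) .stopf("logistic_enrichment: no predictors")
  keep <- vapply(predictors, function(p) length(unique(records[[p]])) > 1,
                 logical(1))
  if (any(!keep))
    .msgf("logistic_enrichment: dropped constant predictor(s): %s",
          paste(predictors[!keep], collapse = ", "))
  predictors <- predictors[keep]
  if (!length(predictors)) .stopf("logistic_enrichment: no varying predictors")
  if (length(unique(records$in_hotspot)) < 2)
    .stopf("logistic_enrichment: outcome does not vary")
  df <- records[, c("in_hotspot", predictors)]
  for (p in predictors) df[[p]] <- as.numeric(df[[p]])
  fit_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste("in_hotspot ~",
                                       paste(predictors, collapse = " + "))),
               family = stats::binomial(), data = df,
               control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      fit_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- stats::coef(fit)[predictors]
  se <- sqrt(diag(stats::vcov(fit)))[predictors]
  z <- qnorm(0.975)
  flagged <- fit_warn | abs(est) > 15 | !fit$converged
  data.frame(predictor = predictors,
             or = unname(exp(est)),
             ci_low = unname(exp(est - z * se)),
             ci_high = unname(exp(est + z * se)),
             p = unname(2 * pnorm(-abs(est / se))),
             flagged = unname(flagged),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Inter-peak distance statistics
#'
#' Median interval width, a distribution-free 95% confidence interval for
#' the median from binomial order statistics, and the 95th percentile
#' (linear interpolation).  An optional hotspot set restricts the
#' intervals to those overlapping a hotspot region.
#'
#' @param intervals output of [consecutive_interpeak_intervals()].
#' @param hotspots optional hotspot regions for subsetting.
#' @return list of class `"distance_stats"`: `median`, `ci_low`,
#'   `ci_high`, `p95`, `n`.
#' @export
interpeak_distance_stats <- function(intervals, hotspots = NULL) {
  iv <- intervals
  if (!is.null(hotspots)) {
    hit <- .overlaps_any(iv$chrom, iv$left, iv$right,
                         hotspots$chrom, hotspots$start, hotspots$end)
    iv <- iv[hit, , drop = FALSE]
  }
  if (!nrow(iv))
    .stopf("interpeak_distance_stats: no intervals%s",
           if (is.null(hotspots)) "" else " after hotspot subsetting")
  w <- sort(iv$width)
  n <- length(w)
  ci <- .median_ci_ranks(n)
  out <- list(median = stats::median(w),
              ci_low = w[ci[1]], ci_high = w[ci[2]],
              p95 = unname(stats::quantile(w, 0.95, type = 7)),
              n = n)
  class(out) <- "distance_stats"
  out
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("inter-peak distance: median %.1f kb (95%% CI %.1f-%.1f), p95 %.1f kb, n = %d\n",
              x$median / 1e3, x$ci_low / 1e3, x$ci_high / 1e3,
              x$p95 / 1e3, x$n))
  invisible(x)
}

# order-statistic ranks (l, u) of the distribution-free >= 95% CI for the
# median: l is the largest rank with P(Bin(n, 1/2) <= l - 1) <= 0.025,
# u = n - l + 1.
.median_ci_ranks <- function(n) {
  if (n == 1) return(c(1L, 1L))
  l <- sum(pbinom(0:(n - 1), n, 0.5) <= 0.025)
  l <- max(l, 1L)
  c(l, n - l + 1L)
}
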