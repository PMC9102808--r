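# The resolved stalled fork (RSF) score: per-sample hotspot deletion
# counts, a changepoint-derived threshold, RSF classification, and
# association with progression-free survival.

#' Per-sample hotspot deletion counts
#'
#' Counts each sample's deletions fully contained in a hotspot region
#' (`start >= region start` and `end <= region end`, the reading
#' consistent with regions being defined by their first and last deletion
#' positions); `mode = "overlap"` counts any intersection instead.
#'
#' @param dels size-filtered deletions (10 kb-1 Mb).
#' @param hotspots hotspot regions from [call_hotspots()].
#' @param samples optional character vector: samples to report (zero
#'   counts included); defaults to the samples present in `dels`.
#' @param mode `"contained"` (default) or `"overlap"`.
#' @param collapse_overlapping collapse overlapping same-sample deletions
#'   before counting (off by default; counts include all records).
#' @return named integer vector of counts.
#' @export
hotspot_del_counts <- function(dels, hotspots, samples = NULL,
                               mode = c("contained", "overlap"),
                               collapse_overlapping = FALSE) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- sort(unique(dels$sample_id))
  counts <- setNames(integer(length(samples)), samples)
  if (!nrow(dels) || !nrow(hotspots)) return(counts)
  inh <- rep(FALSE, nrow(dels))
  for (i in seq_len(nrow(hotspots))) {
    hit <- dels$chrom == hotspots$chrom[i] &
      (if (mode == "contained")
         dels$start >= hotspots$start[i] & dels$end <= hotspots$end[i]
       else
         dels$start < hotspots$end[i] & dels$end > hotspots$start[i])
    inh <- inh | hit
  }
  d <- dels[inh & dels$sample_id %in% samples, , drop = FALSE]
  if (collapse_overlapping && nrow(d)) {
    keep <- unlist(lapply(split(seq_len(nrow(d)),
                                paste(d$sample_id, d$chrom, sep = "\r")),
                          function(i) {
      red <- IRanges::reduce(.ir(d$start[i], d$end[i]), with.revmap = TRUE)
      i[vapply(S4Vectors::mcols(red)$revmap, `[`, integer(1), 1L)]
    }), use.names = FALSE)
    d <- d[sort(keep), , drop = FALSE]
  }
  tab <- table(d$sample_id)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Piecewise-linear changepoint fit of sorted deletion counts
#'
#' Fits a continuous three-segment piecewise linear model to the sorted
#' per-sample counts against rank, by exhaustive grid search over
#' changepoint pairs at data-point resolution (each segment must span at
#' least `min_segment` points), minimizing the residual sum of squares.
#' The RSF threshold is the fitted count at the rank midway between the
#' two changepoints, the point separating the flat low-count regime from
#' the steep high-count tail.
#'
#' The fit is degenerate when the three-segment model does not improve on
#' a single regression line (within 1e-6 relative); constant counts
#' additionally fall back to `fallback_threshold`.
#'
#' @param counts per-sample integer counts (order irrelevant; sorted
#'   internally).
#' @param min_segment minimum data points per segment (default 3).
#' @param fallback_threshold threshold used when the counts are constant
#'   (default 20).
#' @param threshold_on `"rank"` (default): the threshold count is the
#'   fitted value at the rank midpoint of the two changepoints;
#'   `"count"`: the midpoint of the two fitted changepoint counts.
#' @return object of class `"changepoint_fit"`: list with `cp1`, `cp2`
#'   (ranks), `coefficients` (of the hinge basis), `slopes`, `intercepts`
#'   (three linear pieces), `rss`, `threshold_count`, `degenerate`, `n`,
#'   `counts` (sorted).
#' @examples
#' y <- c(rep(2, 10), 2 + 3 * (1:5), 17 + 10 * (1:5))
#' fit <- fit_changepoints(y)
#' fit$threshold_count
#' @export
fit_changepoints <- function(counts, min_segment = 3,
                             fallback_threshold = 20,
                             threshold_on = c("rank", "count")) {
  threshold_on <- match.arg(threshold_on)
  y <- sort(as.numeric(counts))
  n <- length(y)
  if (n < 3 * min_segment)
    .stopf("fit_changepoints: need at least %d samples", 3 * min_segment)
  x <- seq_len(n)

  line_fit <- stats::.lm.fit(cbind(1, x), y)
  rss_line <- sum(line_fit$residuals^2)

  best <- list(rss = Inf)
  for (c1 in min_segment:(n - 2 * min_segment)) {
    h1 <- pmax(x - c1, 0)
    for (c2 in (c1 + min_segment):(n - min_segment)) {
      fit <- stats::.lm.fit(cbind(1, x, h1, pmax(x - c2, 0)), y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss - 1e-12) best <- list(rss = rss, c1 = c1, c2 = c2,
                                               beta = fit$coefficients)
    }
  }
  beta <- best$beta
  beta[is.na(beta)] <- 0
  slopes <- c(beta[2], beta[2] + beta[3], beta[2] + beta[3] + beta[4])
  intercepts <- c(beta[1],
                  beta[1] - beta[3] * best$c1,
                  beta[1] - beta[3] * best$c1 - beta[4] * best$c2)
  degenerate <- (rss_line - best$rss) <= 1e-6 * max(rss_line, 1)
  xm <- (best$c1 + best$c2) / 2
  threshold <- if (var(y) == 0) {
    fallback_threshold
  } else if (threshold_on == "rank") {
    beta[1] + beta[2] * xm + beta[3] * max(xm - best$c1, 0)
  } else {
    y1 <- beta[1] + beta[2] * best$c1
    y2 <- beta[1] + beta[2] * best$c2 + beta[3] * (best$c2 - best$c1)
    (y1 + y2) / 2
  }
  structure(list(cp1 = best$c1, cp2 = best$c2,
                 coefficients = unname(beta), slopes = unname(slopes),
                 intercepts = unname(intercepts), rss = best$rss,
                 threshold_count = unname(threshold),
                 degenerate = degenerate, n = n, counts = y),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("Piecewise-linear changepoint fit (n = %d)\n", x$n))
  cat(sprintf("  changepoints at ranks %.1f and %.1f; rss = %.3g%s\n",
              x$cp1, x$cp2, x$rss,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  segment slopes: %.3g / %.3g / %.3g\n",
              x$slopes[1], x$slopes[2], x$slopes[3]))
  cat(sprintf("  RSF threshold count: %.2f\n", x$threshold_count))
  invisible(x)
}

#' @export
plot.changepoint_fit <- function(x, ...) {
  plot(seq_len(x$n), x$counts, xlab = "sample rank",
       ylab = "hotspot DEL count", pch = 16, cex = 0.6, ...)
  b <- x$coefficients
  xs <- seq(1, x$n, length.out = 200)
  lines(xs, b[1] + b[2] * xs + b[3] * pmax(xs - x$cp1, 0) +
          b[4] * pmax(xs - x$cp2, 0), col = "red3", lwd = 2)
  abline(v = c(x$cp1, x$cp2), lty = 3)
  abline(h = x$threshold_count, lty = 2, col = "blue3")
  invisible(x)
}

#' Classify samples by RSF status
#'
#' A sample is RSF+ when its hotspot deletion count is strictly greater
#' than the threshold.
#'
#' @param counts named per-sample counts (see [hotspot_del_counts()]).
#' @param threshold numeric threshold, typically
#'   `fit_changepoints(counts)$threshold_count` (the motivating cohort's
#'   value is 20).
#' @return data.frame with `sample_id`, `hotspot_del_count`, `threshold`,
#'   `status` (factor `RSF-`/`RSF+`).
#' @export
classify_rsf <- function(counts, threshold) {
  status <- factor(ifelse(counts > threshold, "RSF+", "RSF-"),
                   levels = c("RSF-", "RSF+"))
  .msgf("classify_rsf: %d RSF+ / %d RSF- at threshold %.2f",
        sum(status == "RSF+"), sum(status == "RSF-"), threshold)
  data.frame(sample_id = names(counts),
             hotspot_del_count = as.integer(counts),
             threshold = threshold, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

.surv_groups <- function(clinical, groups) {
  g <- groups[clinical$sample_id]
  if (anyNA(g)) {
    .warnf("dropping %d clinical record(s) without a group", sum(is.na(g)))
    clinical <- clinical[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  list(clinical = clinical, group = as.character(g))
}

#' Kaplan-Meier estimator per group
#'
#' Product-limit estimate of progression-free survival per group; at tied
#' times, events precede censorings (the standard convention).  Empty
#' groups are omitted with a warning.
#'
#' @param clinical clinical records (see [read_clinical()]); restrict to
#'   the treated subset upstream.
#' @param groups named character vector mapping `sample_id` to group.
#' @return named list (one per group) of data.frames with `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_estimator <- function(clinical, groups) {
  sg <- .surv_groups(clinical, groups)
  lv <- unique(sg$group)
  out <- list()
  for (g in lv) {
    sel <- sg$group == g
    if (!sum(sel)) { .warnf("km_estimator: empty group '%s' omitted", g); next }
    fit <- survival::survfit(
      survival::Surv(sg$clinical$pfs_days[sel],
                     sg$clinical$progression_event[sel]) ~ 1)
    out[[g]] <- data.frame(time = fit$time, n_risk = fit$n.risk,
                           n_event = fit$n.event, surv = fit$surv)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) with hypergeometric variance and
#' upper-tail p-value.
#'
#' @inheritParams km_estimator
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(clinical, groups) {
  sg <- .surv_groups(clinical, groups)
  lv <- unique(sg$group)
  if (length(lv) != 2)
    .stopf("logrank_test: exactly two groups required (got %d)", length(lv))
  ev <- tapply(sg$clinical$progression_event, sg$group, sum)
  if (any(ev == 0))
    .stopf("logrank_test: group '%s' has no events", names(ev)[ev == 0][1])
  sd <- survival::survdiff(
    survival::Surv(pfs_days, progression_event) ~ grp,
    data = data.frame(sg$clinical, grp = sg$group))
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards model of progression-free survival
#'
#' Partial-likelihood fit with Breslow tie handling; Wald confidence
#' intervals and p-values per covariate.  Non-convergence and monotone
#' likelihood (separation) are flagged rather than raised.
#'
#' @param clinical clinical records.
#' @param covariates data.frame with `sample_id` plus numeric covariate
#'   columns (e.g. `rsf` 0/1, `prior_platinum` 0/1, `prior_lines`).
#' @return data.frame with one row per covariate: `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `flagged`.
#' @export
cox_ph <- function(clinical, covariates) {
  df <- merge(clinical[, c("sample_id", "pfs_days", "progression_event")],
              covariates, by = "sample_id")
  terms <- setdiff(names(covariates), "sample_id")
  for (tm in terms) {
    df[[tm]] <- as.numeric(df[[tm]])
    if (length(unique(df[[tm]])) < 2)
      .stopf("cox_ph: covariate '%s' is constant", tm)
  }
  if (sum(df$progression_event) < 10)
    .warnf("cox_ph: fewer than 10 events; estimates will be unstable")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste("survival::Surv(pfs_days, progression_event) ~",
                              paste(terms, collapse = " + "))),
      data = df, ties = "breslow",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  est <- stats::coef(fit)[terms]
  se <- sqrt(diag(stats::vcov(fit)))[terms]
  z <- qnorm(0.975)
  data.frame(term = terms,
             hr = unname(exp(est)),
             ci_low = unname(exp(est - z * se)),
             ci_high = unname(exp(est + z * se)),
             p = unname(2 * pnorm(-abs(est / se))),
             flagged = flagged | abs(est) > 15,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' End-to-end RSF analysis
#'
#' Convenience wrapper chaining [hotspot_del_counts()],
#' [fit_changepoints()] (unless an explicit threshold is given),
#' [classify_rsf()], and -- when clinical records are supplied -- the
#' log-rank test and multivariable Cox model (RSF status, prior platinum,
#' prior treatment lines) on the platinum-after-biopsy subset.
#'
#' @param dels size-filtered deletions.
#' @param hotspots hotspot regions.
#' @param clinical optional clinical records.
#' @param threshold optional explicit RSF threshold, overriding the
#'   changepoint fit.
#' @param samples optional full sample list (so zero-count samples are
#'   classified too).
#' @return list of class `"rsf_analysis"`: `counts`, `fit` (or NULL),
#'   `calls`, and with clinical data `km`, `logrank`, `cox`.
#' @export
rsf_analysis <- function(dels, hotspots, clinical = NULL, threshold = NULL,
                         samples = NULL) {
  counts <- hotspot_del_counts(dels, hotspots, samples = samples)
  fit <- NULL
  if (is.null(threshold)) {
    fit <- fit_changepoints(counts)
    threshold <- fit$threshold_count
  }
  calls <- classify_rsf(counts, threshold)
  out <- list(counts = counts, fit = fit, calls = calls)
  if (!is.null(clinical)) {
    cl <- clinical[clinical$platinum_after_biopsy, , drop = FALSE]
    cl <- cl[cl$sample_id %in% calls$sample_id, , drop = FALSE]
    groups <- setNames(as.character(calls$status), calls$sample_id)
    out$km <- km_estimator(cl, groups)
    out$logrank <- logrank_test(cl, groups)
    cov <- data.frame(sample_id = calls$sample_id,
                      rsf = as.numeric(calls$status == "RSF+"))
    cov <- merge(cov, cl[, c("sample_id", "prior_platinum", "prior_lines")],
                 by = "sample_id")
    cov$prior_platinum <- as.numeric(cov$prior_platinum)
    out$cox <- cox_ph(cl, cov)
  }
  class(out) <- "rsf_analysis"
  out
}

#' @export
print.rsf_analysis <- function(x, ...) {
  cat(sprintf("RSF analysis: %d samples, threshold %.2f (%s)\n",
              nrow(x$calls), x$calls$threshold[1],
              if (is.null(x$fit)) "fixed" else "changepoint fit"))
  print(table(x$calls$status))
  if (!is.null(x$logrank))
    cat(sprintf("log-rank: chi-sq %.2f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p))
  if (!is.null(x$cox)) {
    cat("Cox proportional hazards:\n")
    print(x$cox, digits = 3)
  }
  invisible(x)
}
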