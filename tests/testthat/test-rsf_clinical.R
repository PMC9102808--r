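# RSF scoring: hotspot counts, changepoint threshold, classification and
# survival association.

test_that("hotspot deletion counts require full containment by default", {
  hs <- data.frame(chrom = "chr1", start = 1e6, end = 2e6)
  dels <- make_svs(c(1.1e6, 0.95e6, 1.9e6), c(1.5e6, 1.5e6, 2.1e6),
                   sample_id = "S1")
  expect_equal(unname(hotspot_del_counts(dels, hs)), 1)
  expect_equal(unname(hotspot_del_counts(dels, hs, mode = "overlap")), 3)
  # zero-count samples are reported when the sample list is supplied
  cnt <- hotspot_del_counts(dels, hs, samples = c("S1", "S2"))
  expect_equal(unname(cnt), c(1, 0))
})

test_that("hotspot counts equal a brute-force per-sample recount", {
  set.seed(131)
  hs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(1e6, 8e6, 2e6), end = c(3e6, 9e6, 4e6))
  n <- 800
  d <- make_svs(start = (s <- runif(n, 0, 1e7)), end = s + runif(n, 1e4, 1e6),
                chrom = sample(c("chr1", "chr2"), n, TRUE),
                sample_id = sprintf("S%02d", sample(30, n, TRUE)))
  got <- hotspot_del_counts(d, hs)
  brute <- vapply(split(d, d$sample_id), function(x) {
    sum(vapply(seq_len(nrow(x)), function(i)
      any(hs$chrom == x$chrom[i] & hs$start <= x$start[i] &
            x$end[i] <= hs$end), logical(1)))
  }, numeric(1))
  expect_equal(got[names(brute)], brute[names(brute)])
})

test_that("collapsing overlapping same-sample deletions reduces counts", {
  hs <- data.frame(chrom = "chr1", start = 0, end = 1e7)
  d <- make_svs(c(1e6, 1.1e6, 5e6), c(2e6, 2.1e6, 6e6), sample_id = "S1")
  expect_equal(unname(hotspot_del_counts(d, hs)), 3)
  expect_equal(unname(hotspot_del_counts(d, hs, collapse_overlapping = TRUE)),
               2)
})

test_that("changepoint fit recovers planted breakpoints on exact data", {
  x <- 1:60
  y <- ifelse(x <= 30, 5,
              ifelse(x <= 45, 5 + 1 * (x - 30), 20 + 5 * (x - 45)))
  fit <- fit_changepoints(y)
  expect_equal(fit$cp1, 30)
  expect_equal(fit$cp2, 45)
  expect_lt(fit$rss, 1e-8)
  expect_false(fit$degenerate)
  expect_equal(fit$slopes, c(0, 1, 5), tolerance = 1e-9)
  # continuity at the changepoints
  b <- fit$coefficients
  left_of_cp2 <- b[1] + b[2] * fit$cp2 + b[3] * (fit$cp2 - fit$cp1)
  right_seg <- fit$intercepts[3] + fit$slopes[3] * fit$cp2
  expect_equal(left_of_cp2, right_seg, tolerance = 1e-9)
  # threshold sits between the low and high regimes
  expect_gt(fit$threshold_count, 5)
  expect_lt(fit$threshold_count, 95)
})

test_that("linear and constant data degenerate gracefully", {
  y_lin <- 2 + 0.5 * (1:40)
  fit <- fit_changepoints(y_lin)
  expect_true(fit$degenerate)
  lm_rss <- sum(residuals(lm(y_lin ~ seq_along(y_lin)))^2)
  expect_equal(fit$rss, lm_rss, tolerance = 1e-6)

  fit_const <- fit_changepoints(rep(7, 30))
  expect_true(fit_const$degenerate)
  expect_equal(fit_const$threshold_count, 20)
  expect_error(fit_changepoints(1:5), "at least")
})

test_that("piecewise rss never exceeds the single-line rss", {
  set.seed(137)
  for (i in 1:5) {
    y <- cumsum(rexp(50))
    fit <- fit_changepoints(y)
    x <- seq_along(y)
    lin <- sum(residuals(lm(sort(y) ~ x))^2)
    expect_lte(fit$rss, lin + 1e-9)
  }
})

test_that("RSF classification is strict and monotone in the threshold", {
  counts <- setNames(c(21, 20, 0, 35), sprintf("S%d", 1:4))
  calls <- suppressMessages(classify_rsf(counts, 20))
  expect_equal(as.character(calls$status), c("RSF+", "RSF-", "RSF-", "RSF+"))
  for (thr in c(0, 10, 20.5, 34, 35, 100)) {
    lo <- suppressMessages(classify_rsf(counts, thr))$status == "RSF+"
    hi <- suppressMessages(classify_rsf(counts, thr + 5))$status == "RSF+"
    expect_true(all(lo | !hi))  # raising the threshold never adds RSF+
  }
})

test_that("Kaplan-Meier estimates match hand product-limit computation", {
  clin <- data.frame(sample_id = c("a", "b", "c"),
                     prior_lines = 0, prior_platinum = FALSE,
                     platinum_after_biopsy = TRUE,
                     pfs_days = c(1, 2, 3),
                     progression_event = c(FALSE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  groups <- setNames(rep("g", 3), clin$sample_id)
  km <- km_estimator(clin, groups)$g
  expect_equal(km$surv[km$time == 2], 0.5)
  expect_equal(km$surv[km$time == 3], 0)

  allc <- clin; allc$progression_event <- FALSE
  km2 <- km_estimator(allc, groups)$g
  expect_true(all(km2$surv == 1))

  set.seed(139)
  n <- 80
  clin3 <- data.frame(sample_id = sprintf("P%d", 1:n), prior_lines = 0,
                      prior_platinum = FALSE, platinum_after_biopsy = TRUE,
                      pfs_days = rexp(n, 0.01),
                      progression_event = runif(n) > 0.3,
                      stringsAsFactors = FALSE)
  km3 <- km_estimator(clin3, setNames(rep("g", n), clin3$sample_id))$g
  orc <- oracle_km(clin3$pfs_days, clin3$progression_event)
  expect_equal(km3$surv[match(orc$time, km3$time)], orc$surv,
               tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 1e-12))
})

test_that("log-rank statistic matches the hand O-E computation", {
  clin <- data.frame(sample_id = sprintf("P%d", 1:4), prior_lines = 0,
                     prior_platinum = FALSE, platinum_after_biopsy = TRUE,
                     pfs_days = c(1, 2, 3, 4),
                     progression_event = TRUE, stringsAsFactors = FALSE)
  groups <- setNames(c("A", "A", "B", "B"), clin$sample_id)
  got <- logrank_test(clin, groups)
  orc <- oracle_logrank(clin$pfs_days, clin$progression_event,
                        groups[clin$sample_id])
  expect_equal(got$statistic, orc, tolerance = 1e-9)

  same <- rbind(clin, clin)
  same$sample_id <- sprintf("P%d", 1:8)
  g2 <- setNames(rep(c("A", "B"), each = 4), same$sample_id)
  same$pfs_days <- rep(c(1, 2, 3, 4), 2)
  got2 <- logrank_test(same, g2)
  expect_equal(got2$statistic, 0, tolerance = 1e-12)
  expect_equal(got2$p, 1)
  expect_error(logrank_test(clin, setNames(rep("A", 4), clin$sample_id)),
               "two groups")
})

test_that("Cox model is near the null when the covariate carries no signal", {
  set.seed(149)
  covered <- 0
  for (i in 1:10) {
    clin <- random_clinical(120, hr = 1)
    cov <- data.frame(sample_id = clin$sample_id,
                      rsf = as.numeric(clin$group == "RSF+"))
    fit <- cox_ph(clin, cov)
    if (fit$ci_low <= 1 && 1 <= fit$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 9)
})

test_that("Cox coefficients match an independent Newton solver", {
  set.seed(151)
  n <- 60
  x1 <- rbinom(n, 1, 0.4)
  x2 <- rnorm(n)
  t <- rexp(n, 0.01 * exp(0.8 * x1 + 0.3 * x2))
  clin <- data.frame(sample_id = sprintf("P%d", 1:n), prior_lines = 0,
                     prior_platinum = FALSE, platinum_after_biopsy = TRUE,
                     pfs_days = t, progression_event = runif(n) > 0.15,
                     stringsAsFactors = FALSE)
  cov <- data.frame(sample_id = clin$sample_id, xa = x1, xb = x2)
  fit <- cox_ph(clin, cov)
  beta <- oracle_cox(t, clin$progression_event, cbind(x1, x2))
  expect_equal(log(fit$hr), unname(beta), tolerance = 1e-4)
})

test_that("the end-to-end RSF wrapper classifies a planted two-mode cohort", {
  set.seed(157)
  hs <- data.frame(chrom = "chr1", start = 0, end = 5e7)
  n_lo <- 40; n_hi <- 8
  counts <- c(rpois(n_lo, 6), rpois(n_hi, 45))
  ids <- sprintf("S%02d", seq_len(n_lo + n_hi))
  d <- make_svs(start = (s <- runif(sum(counts), 1e6, 4e7)),
                end = s + runif(sum(counts), 1e4, 9e5),
                sample_id = rep(ids, counts))
  clin <- data.frame(sample_id = ids, prior_lines = rpois(48, 1) + 1,
                     prior_platinum = runif(48) < 0.4,
                     platinum_after_biopsy = TRUE,
                     pfs_days = rexp(48, 0.005 *
                                       ifelse(seq_along(ids) > n_lo, 3, 1)),
                     progression_event = TRUE, stringsAsFactors = FALSE)
  res <- suppressMessages(rsf_analysis(d, hs, clinical = clin, samples = ids))
  truth <- c(rep("RSF-", n_lo), rep("RSF+", n_hi))
  expect_gte(mean(as.character(res$calls$status) == truth), 0.95)
  expect_lt(res$logrank$p, 0.05)
  expect_true(res$cox$hr[res$cox$term == "rsf"] > 1)
  expect_output(print(res), "RSF analysis")
})
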