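# Inter-peak intervals, containment classification, enrichment statistics
# and distance summaries.

test_that("consecutive inter-peak intervals join midpoints in order", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 500, 900) - 1,
                      end = c(100, 500, 900) + 1)
  iv <- consecutive_interpeak_intervals(peaks)
  expect_equal(iv$left, c(100, 500))
  expect_equal(iv$right, c(500, 900))
  expect_equal(iv$width, c(400, 400))

  single <- data.frame(chrom = "chr2", start = 10, end = 20)
  expect_message(iv1 <- consecutive_interpeak_intervals(single), "< 2 peaks")
  expect_equal(nrow(iv1), 0)

  dup <- data.frame(chrom = "chr1", start = c(100, 100, 500) - 1,
                    end = c(100, 100, 500) + 1)
  expect_warning(iv2 <- consecutive_interpeak_intervals(dup), "duplicate")
  expect_equal(nrow(iv2), 1)
})

test_that("containment is strict: peak midpoints inside or on a breakpoint disqualify", {
  iv <- make_intervals(c(100, 500), c(500, 900))
  expect_true(classify_containment(make_svs(200, 400), iv))
  expect_false(classify_containment(make_svs(200, 600), iv))   # spans peak
  expect_false(classify_containment(make_svs(100, 400), iv))   # start == left
  expect_false(classify_containment(make_svs(200, 500), iv))   # end == right
  expect_true(classify_containment(make_svs(501, 899), iv))
})

test_that("containment agrees with a brute-force scan over peak midpoints", {
  set.seed(47)
  for (rep in 1:4) {
    mids <- sort(sample(1e6, 60))
    iv <- make_intervals(mids[-length(mids)], mids[-1])
    n <- 2500
    s <- sample(1e6, n)
    e <- s + sample(5e4, n, TRUE)
    dels <- make_svs(s, e)
    got <- classify_containment(dels, iv)
    brute <- vapply(seq_len(n), function(i)
      any(iv$left < s[i] & e[i] < iv$right), logical(1))
    expect_equal(got, brute)
  }
})

test_that("contingency tabulation handles edge cases", {
  rec <- data.frame(in_hotspot = c(TRUE, TRUE, FALSE),
                    between_peaks = c(TRUE, TRUE, TRUE),
                    between_tads = FALSE)
  tbl <- containment_contingency(rec, "peaks")
  expect_equal(c(tbl$a, tbl$b, tbl$c, tbl$d), c(2, 0, 1, 0))
  empty <- containment_contingency(rec[0, ], "peaks")
  expect_equal(c(empty$a, empty$b, empty$c, empty$d), c(0, 0, 0, 0))
  expect_true(is.na(empty$pct_inside))
})

test_that("odds ratio matches direct evaluation on random tables", {
  expect_equal(odds_ratio(c(10, 10, 10, 10))$or, 1)
  set.seed(53)
  for (i in 1:50) {
    x <- rpois(4, 40) + 1
    or <- odds_ratio(x)
    expect_equal(or$or, oracle_odds_ratio(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
    expect_false(or$haldane)
  }
  hz <- odds_ratio(c(0, 5, 8, 9))
  expect_true(hz$haldane)
  expect_equal(hz$or, (0.5 * 9.5) / (5.5 * 8.5))
  expect_true(odds_ratio(c(0, 0, 3, 4))$undefined)
})

test_that("chi-square equals the Pearson sum and degenerates correctly", {
  eq <- chi_square_test(c(10, 10, 10, 10))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  prop <- chi_square_test(c(20, 40, 10, 20))  # identical row proportions
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  set.seed(59)
  for (i in 1:50) {
    x <- rpois(4, 30) + 1
    expect_equal(chi_square_test(x)$statistic,
                 oracle_chisq(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
  }
  expect_error(chi_square_test(c(0, 0, 5, 5)), "marginal")
})

test_that("single-predictor logistic regression reproduces the 2x2 odds ratio", {
  set.seed(61)
  n <- 400
  btw <- runif(n) < 0.5
  inh <- runif(n) < ifelse(btw, 0.7, 0.3)
  rec <- data.frame(in_hotspot = inh, between_peaks = btw)
  fit <- logistic_enrichment(rec, "between_peaks")
  tbl <- containment_contingency(
    data.frame(in_hotspot = inh, between_peaks = btw, between_tads = FALSE),
    "peaks")
  expect_equal(fit$or, odds_ratio(tbl)$or, tolerance = 1e-6)
})

test_that("logistic fit matches an independent IRLS implementation", {
  set.seed(67)
  n <- 50
  btw_p <- runif(n) < 0.5
  btw_t <- runif(n) < 0.5
  y <- runif(n) < plogis(-0.5 + 1.2 * btw_p + 0.4 * btw_t)
  rec <- data.frame(in_hotspot = y, between_peaks = btw_p,
                    between_tads = btw_t)
  fit <- logistic_enrichment(rec)
  beta <- oracle_logistic(cbind(1, as.numeric(btw_p), as.numeric(btw_t)),
                          as.numeric(y))
  expect_equal(fit$or, exp(beta[2:3]), tolerance = 1e-6)
})

test_that("logistic enrichment is calibrated under the null", {
  set.seed(71)
  hits <- 0
  for (i in 1:20) {
    n <- 300
    rec <- data.frame(in_hotspot = runif(n) < 0.4,
                      between_peaks = runif(n) < 0.5,
                      between_tads = runif(n) < 0.5)
    fit <- logistic_enrichment(rec)
    if (all(fit$p > 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("complete separation is flagged, not fatal", {
  rec <- data.frame(in_hotspot = c(rep(TRUE, 20), rep(FALSE, 20)),
                    between_peaks = c(rep(TRUE, 20), rep(FALSE, 20)))
  fit <- logistic_enrichment(rec, "between_peaks")
  expect_true(fit$flagged)
})

test_that("distance statistics use order-statistic confidence bounds", {
  iv <- make_intervals(c(0, 10, 30), c(10, 30, 60))
  st <- interpeak_distance_stats(iv)
  expect_equal(st$median, 20)
  same <- make_intervals(seq(0, 900, 100), seq(100, 1000, 100))
  st2 <- interpeak_distance_stats(same)
  expect_equal(st2$ci_low, st2$median)
  expect_equal(st2$ci_high, st2$median)

  set.seed(73)
  for (n in c(15, 100, 1000)) {
    w <- rexp(n, 1 / 3e4)
    iv <- make_intervals(cumsum(c(0, w))[-(n + 1)], cumsum(w))
    st <- interpeak_distance_stats(iv)
    ranks <- oracle_median_ci_ranks(n)
    ws <- sort(w)
    expect_equal(st$ci_low, ws[ranks[1]])
    expect_equal(st$ci_high, ws[ranks[2]])
    expect_equal(st$p95, unname(quantile(w, 0.95)))
    expect_lte(st$ci_low, st$median)
    expect_gte(st$ci_high, st$median)
    expect_gte(st$p95, st$median)
  }
  expect_error(interpeak_distance_stats(iv[0, ]), "no intervals")
})

test_that("hotspot subsetting restricts distance statistics", {
  iv <- make_intervals(c(0, 1e6, 5e6), c(1e6, 5e6, 5.1e6))
  hs <- data.frame(chrom = "chr1", start = 2e6, end = 3e6)
  st <- interpeak_distance_stats(iv, hs)
  expect_equal(st$n, 1)
  expect_equal(st$median, 4e6)
})

test_that("relative midpoint positions are exact and always interior", {
  iv <- make_intervals(100, 500)
  expect_equal(relative_midpoint_position(make_svs(250, 350), iv), 0.5)
  expect_equal(relative_midpoint_position(make_svs(120, 180), iv), 0.125)
  expect_true(is.na(relative_midpoint_position(make_svs(50, 80), iv)))
  set.seed(79)
  mids <- sort(sample(1e6, 40))
  ivr <- make_intervals(mids[-40], mids[-1])
  s <- sample(1e6, 3000)
  d <- make_svs(s, s + sample(2e4, 3000, TRUE))
  pos <- relative_midpoint_position(d, ivr)
  pos <- pos[!is.na(pos)]
  expect_gt(length(pos), 0)
  expect_true(all(pos > 0 & pos < 1))
})

test_that("TAD gap mode yields the inter-block gaps", {
  tads <- data.frame(chrom = "chr1", start = c(0, 2000, 5000),
                     end = c(1000, 3000, 6000))
  iv <- tad_intervals(tads, "gap")
  expect_equal(iv$left, c(1000, 3000))
  expect_equal(iv$right, c(2000, 5000))
  ivm <- tad_intervals(tads, "midpoint")
  expect_equal(ivm$left, c(500, 2500))
})
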