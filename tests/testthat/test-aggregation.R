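fake_trace <- function(th, n_total = length(th)) {
  n_invalid <- n_total - length(th)
  data.frame(
    ascan = seq_len(n_total),
    thickness_um = c(th, rep(NA_real_, n_invalid)),
    valid = c(rep(TRUE, length(th)), rep(FALSE, n_invalid))
  )
}

test_that("B-scan summaries use sample SD over valid A-scans only", {
  s <- summarize_bscan(fake_trace(c(200, 200, 200)))
  expect_equal(s$mean_um, 200)
  expect_equal(s$sd_um, 0)
  expect_equal(s$pct_error, 0)

  s <- summarize_bscan(fake_trace(c(190, 200, 210)))
  expect_equal(s$mean_um, 200)
  expect_equal(s$sd_um, 10)
  expect_equal(s$pct_error, 5)

  # invalid A-scans are excluded from the statistics
  th <- rep(c(195, 205), 334)  # 668 valid of 768
  s <- summarize_bscan(fake_trace(th, n_total = 768))
  expect_equal(s$n_valid, 668)
  expect_equal(s$mean_um, 200)

  # too few valid A-scans -> unsummarizable
  s <- summarize_bscan(fake_trace(c(200, 201), n_total = 10))
  expect_false(s$summarizable)
  expect_true(is.na(s$mean_um))
})

summaries_of <- function(pcts) {
  do.call(rbind, lapply(seq_along(pcts), function(i) {
    m <- 200
    s <- pcts[i] * m / 100
    data.frame(index = i, n_total = 10L, n_valid = 10L, mean_um = m,
               sd_um = s, pct_error = pcts[i], summarizable = TRUE)
  }))
}

test_that("the percentage-error discard rule is strictly greater-than", {
  f <- filter_bscans(summaries_of(c(5, 10, 30)), 25)
  expect_equal(f$retained, c(TRUE, TRUE, FALSE))
  # exactly at the threshold is retained
  f <- filter_bscans(summaries_of(c(25, 25.0001)), 25)
  expect_equal(f$retained, c(TRUE, FALSE))
  # extreme thresholds
  expect_true(all(filter_bscans(summaries_of(c(0, 40, 400)), Inf)$retained))
  expect_equal(filter_bscans(summaries_of(c(0, 1)), 0)$retained, c(TRUE, FALSE))
})

vm_of <- function(means, sds, ...) {
  df <- data.frame(index = seq_along(means), n_total = 10L, n_valid = 10L,
                   mean_um = means, sd_um = sds, pct_error = 100 * sds / means,
                   summarizable = TRUE, retained = TRUE)
  volume_mean(df, ...)
}

test_that("inverse-SD weighted volume mean and SE match hand arithmetic", {
  v <- vm_of(c(200, 210), c(10, 5))
  expect_equal(v$weighted_mean, (200 / 10 + 210 / 5) / (1 / 10 + 1 / 5))
  expect_equal(v$weighted_mean, 206.6667, tolerance = 1e-4)
  expect_equal(v$se, sd(c(200, 210)) / sqrt(2))
  expect_equal(v$se, 5)

  v <- vm_of(c(200, 200), c(10, 10))
  expect_equal(v$weighted_mean, 200)
  expect_equal(v$se, 0)

  # single retained B-scan: mean passes through, SE undefined
  v <- vm_of(195, 8)
  expect_equal(v$weighted_mean, 195)
  expect_true(is.na(v$se))
  expect_equal(v$n_retained, 1L)
})

test_that("volume mean edge cases: empty input, zero SD, duplication, equal SDs", {
  empty <- filter_bscans(summaries_of(c(40, 50)), 25)
  v <- volume_mean(empty)
  expect_equal(v$n_retained, 0L)
  expect_true(is.na(v$weighted_mean))
  expect_match(v$reason, "retained")

  # zero-SD scan gets 10x the largest finite weight, staying finite
  v <- vm_of(c(100, 200), c(5, 0))
  expect_equal(v$weighted_mean, (100 * 0.2 + 200 * 2) / 2.2)

  # weighted mean within the range of retained means
  for (s in 1:20) {
    set.seed(s)
    means <- runif(5, 150, 250); sds <- runif(5, 1, 20)
    v <- vm_of(means, sds)
    expect_gte(v$weighted_mean, min(means))
    expect_lte(v$weighted_mean, max(means))
    # duplicating the list leaves the weighted mean unchanged
    v2 <- vm_of(c(means, means), c(sds, sds))
    expect_equal(v2$weighted_mean, v$weighted_mean)
  }

  # equal SDs reduce to the arithmetic mean
  v <- vm_of(c(180, 200, 230), c(7, 7, 7))
  expect_equal(v$weighted_mean, mean(c(180, 200, 230)))

  # SEM weighting uses sqrt(n)/sd
  df <- data.frame(index = 1:2, n_total = 10L, n_valid = c(4L, 16L),
                   mean_um = c(200, 210), sd_um = c(10, 10),
                   pct_error = 5, summarizable = TRUE, retained = TRUE)
  v <- volume_mean(df, weighting = "sem")
  expect_equal(v$weighted_mean, (200 * 2 + 210 * 4) / 6)
})

test_that("group comparison matches ANOVA oracles and Bonferroni arithmetic", {
  # identical groups: no between-group variance
  g <- list(a = c(200, 210, 190), b = c(200, 210, 190))
  cmp <- group_compare(g)
  expect_equal(cmp$anova$F, 0)
  expect_equal(cmp$anova$p, 1)
  expect_equal(cmp$pairwise$p_bonferroni, 1)

  # closed-form example
  cmp <- group_compare(list(x = c(1, 2, 3), y = c(2, 3, 4)))
  expect_equal(cmp$anova$F, 1.5)
  expect_equal(cmp$anova$df_between, 1)
  expect_equal(cmp$anova$df_within, 4)

  # Bonferroni multiplies by the number of pairs and caps at 1
  g3 <- list(a = c(1, 2), b = c(1.1, 2.1), c = c(0.9, 1.9))
  cmp <- group_compare(g3)
  expect_equal(nrow(cmp$pairwise), 3)
  expect_equal(cmp$pairwise$p_bonferroni, pmin(1, cmp$pairwise$p * 3))

  expect_error(group_compare(list(a = 1:3)), class = "octseg_analysis_error")
  expect_error(group_compare(list(a = 1:3, b = 2)), class = "octseg_analysis_error")

  # oracle equivalence on random small datasets
  for (s in 1:100) {
    set.seed(s)
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(2:6, 1), mean = 10 * i))
    names(groups) <- paste0("g", seq_len(k))
    cmp <- group_compare(groups)
    oracle <- brute_anova(groups)
    expect_equal(cmp$anova$F, oracle$F, tolerance = 1e-10)
    expect_equal(cmp$anova$p, oracle$p, tolerance = 1e-10)
    expect_equal(cmp$anova$df_between, oracle$df1)
    expect_equal(cmp$anova$df_within, oracle$df2)
  }
})
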