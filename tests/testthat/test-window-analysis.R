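# Window aggregation, smoothing, density summaries, correlation.

test_that("window means match direct arithmetic and honor the CpG filter", {
  calls <- cpg_calls("chr1", seq(0, 4000, by = 1000),
                     c(1, 2, 3, 4, 5), c(5, 5, 5, 5, 5))
  wt <- window_methylation(calls, window_size = 20000, min_cpgs = 5)
  expect_equal(wt$mean_meth, 0.6)
  expect_equal(wt$n_cpgs, 5L)

  # 19 covered CpGs with min_cpgs = 20 -> missing
  calls19 <- cpg_calls("chr1", seq_len(19) * 100, 1, 2)
  wt19 <- window_methylation(calls19, 20000, 20)
  expect_true(is.na(wt19$mean_meth))
  expect_equal(wt19$n_cpgs, 19L)

  # fully methylated -> 1.0
  full <- cpg_calls("chr1", seq_len(30) * 100, 4, 4)
  expect_equal(window_methylation(full, 20000, 20)$mean_meth, 1)

  # empty input -> empty track
  expect_equal(nrow(window_methylation(cpg_calls(character(0), numeric(0)),
                                       20000, 20)), 0L)
})

test_that("window and global aggregation equal brute-force recomputation", {
  for (seed in c(101, 102, 103)) {
    calls <- random_calls(500, seed = seed, span = 2e5)
    wt <- window_methylation(calls, 20000, 5)
    bf <- brute_window_means(calls, 20000, 5)
    m <- merge(as.data.frame(wt), bf, by = c("chrom", "start"))
    expect_equal(m$mean_meth, m$mean, tolerance = 1e-12)
    expect_equal(m$n_cpgs, m$n)
    covered <- calls$total_reads > 0
    expect_equal(global_methylation(calls),
                 sum(calls$meth_reads) / sum(calls$total_reads),
                 tolerance = 1e-15)
    # pooled mean bounded by site fractions
    expect_gte(global_methylation(calls),
               min(calls$fraction[covered]))
    expect_lte(global_methylation(calls),
               max(calls$fraction[covered]))
  }
})

test_that("window aggregation is invariant to input ordering", {
  calls <- random_calls(400, seed = 104, span = 1e5)
  shuf <- calls[sample(nrow(calls)), ]
  reord <- cpg_calls(shuf$chrom, shuf$pos, shuf$meth_reads,
                     shuf$total_reads)
  expect_equal(window_methylation(reord, 10000, 3),
               window_methylation(calls, 10000, 3))
})

test_that("global methylation warns and falls back for fraction tracks", {
  frac <- cpg_calls("chr1", c(10, 20), fraction = c(0.2, 0.8))
  expect_warning(g <- global_methylation(frac), "unweighted")
  expect_equal(g, 0.5)
  expect_equal(global_methylation(cpg_calls("chr1", 1, 0, 10)), 0)
})

test_that("running median matches the naive oracle and its contracts", {
  expect_error(running_median(1:10, width = 4), "odd")
  expect_equal(running_median(rep(3.5, 9), 3), rep(3.5, 9))
  x <- c(1, 9, 1, 9, 1)
  expect_equal(running_median(x, 3), brute_running_median(x, 3))
  set.seed(7)
  y <- rnorm(200)
  y[sample(200, 30)] <- NA
  expect_equal(running_median(y, 15), brute_running_median(y, 15))
  # idempotent on monotone series
  mono <- sort(rnorm(50))
  expect_equal(running_median(running_median(mono, 15), 15),
               running_median(mono, 15))
  # all-missing neighborhood stays missing
  z <- c(1, rep(NA, 9), 2)
  expect_true(any(is.na(running_median(z, 3))))
})

test_that("kernel smoothing equals a direct double-loop evaluation", {
  tr <- track_from_means(c(0.2, 0.5, NA, 0.8, 0.4))
  sm <- kernel_smooth(tr, bandwidth = 30000)
  centers <- (tr$start + tr$end) / 2
  ok <- which(!is.na(tr$mean_meth))
  direct <- vapply(centers, function(x0) {
    w <- dnorm(centers[ok] - x0, sd = 30000)
    sum(w * tr$mean_meth[ok]) / sum(w)
  }, numeric(1))
  expect_equal(sm$smooth, direct, tolerance = 1e-10)

  # constant track stays constant; tiny bandwidth reproduces the input
  ct <- track_from_means(rep(0.42, 8))
  expect_equal(kernel_smooth(ct, 5e4)$smooth, rep(0.42, 8))
  expect_equal(kernel_smooth(tr, bandwidth = 10)$smooth[ok],
               tr$mean_meth[ok])
  # no value invented where no window lies within one bandwidth
  gap <- track_from_means(c(0.5, rep(NA, 10), 0.5))
  expect_true(any(is.na(kernel_smooth(gap, bandwidth = 20000)$smooth)))
})

test_that("density summaries report median/IQR and flag planted mixtures", {
  flat <- track_from_means(rep(0.75, 10))
  d <- methylation_density(flat)
  expect_equal(d$median, 75)
  expect_equal(unname(d$iqr["upper"] - d$iqr["lower"]), 0)
  expect_false(d$bimodal)
  expect_null(d$density)

  set.seed(31)
  mix <- track_from_means(pmin(pmax(
    c(rnorm(2500, 0.35, 0.03), rnorm(2500, 0.75, 0.03)), 0), 1))
  dm <- methylation_density(mix)
  expect_true(dm$bimodal)
  expect_equal(sum((dm$density$y[-1] + dm$density$y[-nrow(dm$density)]) / 2) *
                 diff(dm$density$x[1:2]), 1, tolerance = 1e-6)

  uni <- track_from_means(pmin(pmax(rnorm(3000, 0.55, 0.05), 0), 1))
  expect_false(methylation_density(uni)$bimodal)
})

test_that("track correlation handles exact, anti and resampled replicates", {
  a <- track_from_means(c(0.1, 0.4, 0.6, 0.9, 0.5))
  expect_equal(correlate_tracks(a, a)$r, 1)
  b <- a
  b$mean_meth <- 1 - a$mean_meth
  expect_equal(correlate_tracks(a, b)$r, -1)
  short <- track_from_means(c(0.5, NA, NA, NA, 0.4))
  expect_error(correlate_tracks(a, short), "fewer than 3")

  # two binomial resamplings of one methylome at ~5X: r from the textbook
  # formula, and high at 20 kb windows
  g <- demo_small()$genome
  truth <- demo_small()$methylome$truth
  set.seed(61)
  mk <- function() {
    depth <- rnbinom(nrow(truth), mu = 5, size = 10)
    cpg_calls(truth$chrom, truth$pos, rbinom(nrow(truth), depth, truth$true),
              depth)
  }
  w1 <- window_methylation(mk(), 20000, 20, c(chr1 = 4e6))
  w2 <- window_methylation(mk(), 20000, 20, c(chr1 = 4e6))
  ct <- correlate_tracks(w1, w2)
  ok <- !is.na(w1$mean_meth) & !is.na(w2$mean_meth)
  x <- w1$mean_meth[ok]; y <- w2$mean_meth[ok]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, manual, tolerance = 1e-12)
  expect_gt(ct$r, 0.8)
})
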