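test_that("block series partitions 51 trials into 17 blocks", {
  bs <- block_series(1:51, rep(1, 51))
  expect_equal(nrow(bs), 17)
  expect_equal(bs$mean_dlight, seq(2, 50, by = 3))
  expect_equal(bs$center_trial, seq(2, 50, by = 3))
  expect_true(all(bs$hit_rate == 1))
  expect_error(block_series(1:50, rep(1, 50)), "at least 51")
  expect_error(block_series(1:52, rep(1, 52), block = 3, n_trials = 52),
               "divisible")
})

test_that("pearson correlation and p-value match the closed form", {
  x <- c(1, 2, 4, 5, 9, 11, 12)
  y <- 2 * x + 1
  expect_equal(pearson_with_p(x, y)$r, 1)
  set.seed(2)
  a <- stats::rnorm(17); b <- stats::rnorm(17)
  pw <- pearson_with_p(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_stat <- r_direct * sqrt((17 - 2) / (1 - r_direct^2))
  expect_equal(pw$r, r_direct)
  expect_equal(pw$p, 2 * stats::pt(-abs(t_stat), df = 15))
  expect_error(pearson_with_p(rep(1, 10), 1:10), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("pearson p-values are calibrated under the null", {
  set.seed(77)
  n_sim <- 2000
  rej <- mean(replicate(n_sim, {
    pearson_with_p(stats::rnorm(17), stats::rnorm(17))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("learning slope recovers linear trends", {
  bs <- block_series(rep(4, 51), rep(1, 51))
  expect_equal(learning_slope(bs), 0)
  bs2 <- block_series(0.5 * (1:51) + 3, rep(1, 51))
  expect_equal(learning_slope(bs2), 0.5)
})

test_that("learner selection flags monotone improvement and not constants", {
  hits <- c(rep(0, 25), rep(1, 26))
  expect_true(select_learners(hits))
  expect_true(is.na(select_learners(rep(1, 51))))  # constant: not evaluable
  expect_true(is.na(select_learners(rep(0, 30))))  # too few trials
  # a decreasing pattern is not a learner even if significant
  expect_false(select_learners(rev(hits)))
})

test_that("day comparisons apply the Bonferroni threshold", {
  m <- cbind(d1 = rep(1, 10), d2 = rep(1, 10), d3 = rep(1, 10))
  out <- day_comparisons(m)
  expect_equal(attr(out, "threshold"), 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(attr(out, "threshold"), 3), 0.017)
  expect_true(all(!out$significant))
  # a clear day effect across 26 mice is detected
  set.seed(12)
  base <- stats::rnorm(26)
  m2 <- cbind(base, base + 1 + stats::rnorm(26, 0, 0.3),
              base + 1.2 + stats::rnorm(26, 0, 0.3))
  out2 <- day_comparisons(m2)
  expect_true(out2$significant[out2$day_a == 1 & out2$day_b == 2])
  # missing data drops the mouse pairwise and is reported
  m3 <- m2; m3[1, 3] <- NA
  out3 <- day_comparisons(m3)
  expect_equal(out3$n_dropped[out3$day_b == 3], c(1, 1))
})

test_that("pooled block correlation is positive under generative coupling", {
  coh <- simulate_learning_cohort(6, seed = 99, couple = TRUE)
  blocks <- attr(coh, "blocks")
  pooled <- pearson_with_p(blocks$mean_dlight, blocks$hit_rate)
  expect_gt(pooled$r, 0)
  expect_true(all(coh$dlight_slope > 0))
})
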