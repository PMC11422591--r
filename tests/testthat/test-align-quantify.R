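test_that("epoch extraction aligns lag 0 to the event sample", {
  z <- numeric(5000)
  z[2001] <- 1  # impulse at t = 2.000 s
  ep <- extract_epochs(z, 2.0, pre = 0.5, post = 0.5)
  expect_equal(nrow(ep$values), 1)
  expect_equal(ep$values[1, ep$lag_ms == 0], 1)
  expect_equal(sum(ep$values), 1)
  # events too close to the recording edge are dropped and logged
  ep2 <- extract_epochs(z, c(0.2, 2.0, 4.9), pre = 0.5, post = 0.5)
  expect_equal(nrow(ep2$values), 1)
  expect_equal(ep2$dropped, 2)
  expect_error(extract_epochs(z, 0.1, pre = 1, post = 1), "no events")
})

test_that("window quantification is baseline-referenced and offset-invariant", {
  ep <- extract_epochs(numeric(5000) + 3.3, 2.0, pre = 1, post = 2)
  for (w in window_registry()$name) {
    expect_equal(window_quant(ep, w), 0)
  }
  # epoch = 1 inside the response window, 0 elsewhere -> value 1
  z <- numeric(5000)
  z[(2001 + 300):(2001 + 499)] <- 1  # lags 300..499 ms post-event
  ep2 <- extract_epochs(z, 2.0, pre = 1, post = 2)
  expect_equal(window_quant(ep2, "lick_peak"), 1)
  # adding any constant leaves the value unchanged
  ep3 <- ep2; ep3$values <- ep3$values + 17
  expect_equal(window_quant(ep3, "lick_peak"), window_quant(ep2, "lick_peak"))
})

test_that("every registry window recovers the analytic kernel mean", {
  amp <- 2; tr <- 0.2; td <- 1.0
  lag_s <- seq(-2, 3 - 1e-3, 1e-3)
  epoch <- matrix(dopamine_kernel(lag_s, amp, tr, td), nrow = 1)
  ep <- list(values = epoch, lag_ms = round(lag_s * 1000))
  class(ep) <- "photolick_epochs"
  reg <- window_registry()
  for (i in seq_len(nrow(reg))) {
    expected <- kernel_window_mean(reg$resp_start[i], reg$resp_end[i],
                                   amp, tr, td) -
      kernel_window_mean(reg$base_start[i], reg$base_end[i], amp, tr, td)
    got <- window_quant(ep, reg[i, ])
    if (abs(expected) > 1e-9) {
      expect_equal(got, expected, tolerance = 0.05,
                   label = paste("window", reg$name[i]))
    } else {
      expect_lt(abs(got), 1e-6)
    }
  }
})

test_that("first/last-k means summarize session order", {
  expect_equal(first_last_k(c(rep(1, 15), rep(0, 15))),
               c(first = 1, last = 0))
  expect_equal(first_last_k(rep(2.5, 40)), c(first = 2.5, last = 2.5))
  # short sessions truncate to disjoint halves and flag it
  out <- first_last_k(1:20, k = 15)
  expect_equal(attr(out, "truncated_k"), 10)
  expect_equal(unname(out["first"]), mean(1:10))
  expect_error(first_last_k(numeric(0)), "no trials")
})

test_that("exact signed-rank p matches full enumeration for n <= 12", {
  # all-positive differences, n = 6: p = 2/64
  r <- paired_signed_rank(1:6, rep(0, 6))
  expect_equal(r$p, 0.03125)
  expect_equal(r$method, "exact")
  # alternating symmetric differences: p = 1
  expect_equal(paired_signed_rank(c(1, -1, 1, -1, 1, -1), rep(0, 6))$p, 1)
  # random cases, with and without ties, against the 2^n oracle
  set.seed(31)
  for (n in 3:12) {
    for (rep in 1:3) {
      d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
      expect_equal(paired_signed_rank(d, numeric(n))$p,
                   enumerate_signed_rank_p(d),
                   label = paste("n =", n))
    }
  }
  # no-tie case agrees with the classic exact distribution
  set.seed(5)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  expect_equal(paired_signed_rank(x, y)$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("large-sample signed-rank uses the tie-corrected normal approximation", {
  set.seed(8)
  x <- stats::rnorm(40) + 0.5
  y <- stats::rnorm(40)
  mine <- paired_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_match(mine$method, "normal")
  expect_error(paired_signed_rank(1:5, 1:5), "zero")
})
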