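test_that("licking power is the pointwise square", {
  expect_equal(licking_power(c(0, 1, -2)), c(0, 1, 4))
  expect_equal(licking_power(numeric(10)), numeric(10))
  # sinusoid of amplitude A has mean power A^2/2
  tt <- seq(0, 10, 1e-3)
  expect_equal(mean(licking_power(3 * sin(2 * pi * 5 * tt))), 9 / 2,
               tolerance = 1e-3)
})

test_that("lick onsets are detected at true times with a refractory period", {
  expect_identical(detect_lick_onsets(numeric(1000)), numeric(0))
  # simulated 5-lick bout at 10 Hz, SNR 10
  true_licks <- 1 + (0:4) * 0.1
  ev <- manual_events(true_licks, numeric(0), numeric(0), numeric(0),
                      t_end = 3)
  set.seed(42)
  ev <- render_piezo(ev, snr = 10)
  onsets <- detect_lick_onsets(ev$piezo)
  expect_length(onsets, 5)
  expect_true(all(abs(onsets - true_licks) < 0.005))
  # two threshold crossings 20 ms apart with a 50-ms refractory -> one onset
  set.seed(7)
  p <- numeric(1000)
  p[c(100, 120)] <- 10
  p <- p + stats::rnorm(1000, 0, 0.1)
  expect_length(detect_lick_onsets(p, refractory = 0.05), 1)
})

test_that("parser labels constructed detection trials correctly", {
  cfg <- task_config("whisker_detection", n_trials = 2)
  # stim at 10, lick at 10.3 with valve -> Hit; no-stim trial with lick -> FA
  ev <- manual_events(licks = c(10.3, 10.4, 30.2),
                      stims = 10, valves = 10.3, starts = c(10, 30))
  tr <- parse_trials(ev, cfg)
  expect_equal(tr$type, c("Hit", "FA"))
  expect_equal(tr$first_report_lick_time, c(10.3, 30.2))
  expect_equal(tr$reward_time, c(10.3, NA))
  # no licks at all -> Miss and CR
  ev2 <- manual_events(numeric(0), 10, numeric(0), c(10, 30))
  expect_equal(parse_trials(ev2, cfg)$type, c("Miss", "CR"))
})

test_that("delay-period licks are not report licks in the delayed task", {
  cfg <- task_config("delayed_reward", n_trials = 1)
  # licks throughout the delay; first lick inside [11, 12) is at 11.2
  ev <- manual_events(licks = c(10.3, 10.5, 10.7, 10.9, 11.2, 11.3),
                      stims = 10, valves = 11.2, starts = 10)
  tr <- parse_trials(ev, cfg)
  expect_equal(tr$type, "Hit")
  expect_equal(tr$first_report_lick_time, 11.2)
})

test_that("report window is half-open at a 1-ms resolution", {
  cfg <- task_config("whisker_detection", n_trials = 1)
  # lick exactly at window start counts
  ev <- manual_events(10, 10, numeric(0), 10)
  expect_equal(parse_trials(ev, cfg)$type, "Hit")
  # lick exactly at window end does not
  ev2 <- manual_events(11, 10, numeric(0), 10)
  expect_equal(parse_trials(ev2, cfg)$type, "Miss")
})

test_that("orphan valve openings raise a consistency error", {
  cfg <- task_config("whisker_detection", n_trials = 1)
  ev <- manual_events(licks = numeric(0), stims = 10, valves = 10.4,
                      starts = 10)
  expect_error(parse_trials(ev, cfg), "consistency error")
})

test_that("parser reproduces simulator ground truth exactly across tasks", {
  shared <- c("onset_time", "stim", "type", "first_report_lick_time",
              "reward_time", "rewarded", "aborted_attempt_count")
  for (task in c("free_licking", "whisker_detection",
                 "delayed_reward", "reward_omission")) {
    for (sd in 1:3) {
      cfg <- task_config(task, n_trials = 40)
      beh <- simulate_behavior(cfg, behavior_params(), seed = sd)
      parsed <- parse_trials(beh$events, cfg)
      expect_equal(as.data.frame(beh$trials)[, shared],
                   as.data.frame(parsed)[, shared],
                   ignore_attr = TRUE)
    }
  }
})

test_that("d-prime uses the loglinear correction and is monotone", {
  expect_equal(dprime_loglinear(10, 20, 10, 20), 0)
  expect_equal(dprime_loglinear(7, 14, 3, 6), 0)
  d_perfect <- dprime_loglinear(20, 20, 0, 20)
  expect_true(is.finite(d_perfect))
  # independent evaluation through the inverse error function
  H <- 20.5 / 21; F <- 0.5 / 21
  d_oracle <- sqrt(2) * (pracma::erfinv(2 * H - 1) - pracma::erfinv(2 * F - 1))
  expect_equal(d_perfect, d_oracle, tolerance = 1e-9)
  # monotone: increasing in hits, decreasing in false alarms
  d_grid <- sapply(0:20, function(h) dprime_loglinear(h, 20, 5, 20))
  expect_true(all(diff(d_grid) > 0))
  f_grid <- sapply(0:20, function(f) dprime_loglinear(15, 20, f, 20))
  expect_true(all(diff(f_grid) < 0))
})

test_that("performance metrics aggregate trial types correctly", {
  tr <- data.frame(type = c(rep("Hit", 6), rep("Miss", 4),
                            rep("FA", 2), rep("CR", 8)))
  perf <- performance_metrics(tr)
  expect_equal(perf$hit_rate, 0.6)
  expect_equal(perf$fa_rate, 0.2)
  expect_equal(perf$n_stim, 10)
  expect_equal(perf$dprime,
               stats::qnorm(6.5 / 11) - stats::qnorm(2.5 / 11))
  expect_error(performance_metrics(data.frame(type = c("Hit", "Miss"))),
               "at least one")
  # omission hits count as hits
  tr2 <- data.frame(type = c("HitPlus", "HitMinus", "Miss", "CR"))
  expect_equal(performance_metrics(tr2)$hit_rate, 2 / 3)
})
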