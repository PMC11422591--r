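test_that("degenerate probabilities give deterministic outcomes", {
  cfg <- task_config("whisker_detection", n_trials = 20)
  par <- behavior_params(learning_p0 = 1, learning_pmax = 1,
                         spontaneous_bout_rate = 0)
  beh <- simulate_behavior(cfg, par, seed = 1)
  expect_true(all(beh$trials$type[beh$trials$stim] == "Hit"))
  expect_true(all(beh$trials$type[!beh$trials$stim] == "CR"))
  expect_true(all(beh$trials$aborted_attempt_count == 0))
})

test_that("reward-omission warm-up is fully rewarded, then ~50% omission", {
  par <- behavior_params(learning_p0 = 1, learning_pmax = 1,
                         satiety_tau = Inf)
  n_plus <- 0; n_late <- 0
  for (sd in 1:3) {
    cfg <- task_config("reward_omission", n_trials = 150)
    beh <- simulate_behavior(cfg, par, seed = sd)
    tr <- beh$trials
    warm <- tr[1:50, ]
    expect_equal(sum(warm$stim), 25)  # balanced 25/25 warm-up
    warm_hits <- warm[warm$type %in% c("HitPlus", "HitMinus"), ]
    expect_true(all(warm_hits$type == "HitPlus"))  # all warm-up hits rewarded
    late <- tr[51:nrow(tr), ]
    late_hits <- late$type[late$type %in% c("HitPlus", "HitMinus")]
    n_plus <- n_plus + sum(late_hits == "HitPlus")
    n_late <- n_late + length(late_hits)
  }
  # pooled rewarded fraction within a 99.7% binomial band around 0.5
  expect_gt(n_late, 100)
  expect_lt(abs(n_plus / n_late - 0.5), 3 * sqrt(0.25 / n_late))
})

test_that("stimulus sequences never exceed the maximum run length", {
  cfg <- task_config("whisker_detection", n_trials = 300)
  for (sd in 1:120) {
    set.seed(sd)
    s <- photolick:::make_stim_sequence(cfg)
    expect_lte(max(rle(s)$lengths), cfg$max_consecutive_same_type)
  }
  # exhaustive scan on one long sequence
  cfg2 <- task_config("reward_omission", n_trials = 10000)
  set.seed(1)
  s2 <- photolick:::make_stim_sequence(cfg2)
  expect_lte(max(rle(s2)$lengths), 3)
  expect_equal(sum(s2[1:50]), 25)
})

test_that("trial accounting conserves stimulus and no-stimulus counts", {
  for (sd in 1:5) {
    cfg <- task_config("whisker_detection", n_trials = 60)
    beh <- simulate_behavior(cfg, behavior_params(), seed = sd)
    tr <- beh$trials
    expect_equal(sum(tr$type %in% c("Hit", "Miss")), sum(tr$stim))
    expect_equal(sum(tr$type %in% c("FA", "CR")), sum(!tr$stim))
  }
})

test_that("satiety schedule makes late reward amplitudes smaller", {
  cfg <- task_config("free_licking", n_trials = 90)
  beh <- simulate_behavior(cfg, behavior_params(satiety_tau = 40), seed = 3)
  amps <- photolick:::latent_kernel_amps(photometry_truth(), beh$trials)
  rew <- amps$reward[!is.na(amps$reward)]
  expect_gt(length(rew), 30)
  expect_gt(mean(utils::head(rew, 15)), mean(utils::tail(rew, 15)))
  # satiety off: schedule flat
  beh2 <- simulate_behavior(cfg, behavior_params(satiety_tau = Inf), seed = 3)
  expect_true(all(beh2$trials$satiety_factor == 1))
})

test_that("infeasible parameters fail explicitly", {
  cfg <- task_config("whisker_detection", n_trials = 2)
  par <- behavior_params(spontaneous_bout_rate = 40, max_abort_attempts = 25L)
  expect_error(simulate_behavior(cfg, par, seed = 1), "infeasible")
})

test_that("rendering reduces to a pure bleach curve with everything off", {
  cfg <- task_config("whisker_detection", n_trials = 5)
  beh <- simulate_behavior(cfg, behavior_params(spontaneous_bout_rate = 0,
                                                learning_p0 = 0,
                                                learning_pmax = 0), seed = 2)
  truth <- photometry_truth(sensory_amp = 0, reward_amp = 0, dip_amp = -1e-12,
                            motion_artifact_sd = 0, noise_sd = 0,
                            bleach_tau_465 = 500, bleach_tau_405 = 800)
  tr <- render_fluorescence(beh$events, truth, beh$trials)
  n <- length(tr$f465)
  tt <- (seq_len(n) - 1) / 1000
  expect_equal(tr$f465, truth$baseline_f465 * exp(-tt / 500), tolerance = 1e-12)
  expect_equal(tr$f405, truth$baseline_f405 * exp(-tt / 800), tolerance = 1e-12)
})

test_that("reward transient peaks at the kernel latency after the second lick", {
  cfg <- task_config("free_licking", n_trials = 3)
  par <- behavior_params(spontaneous_bout_rate = 0, free_lick_prob = 1,
                         satiety_tau = Inf)
  cfg$reward_prob_on_lick <- 1
  beh <- simulate_behavior(cfg, par, seed = 4)
  truth <- photometry_truth(sensory_amp = 0, dip_amp = -1e-12,
                            motion_artifact_sd = 0, noise_sd = 0,
                            bleach_tau_465 = 1e9, bleach_tau_405 = 1e9)
  tr <- render_fluorescence(beh$events, truth, beh$trials)
  second_lick <- beh$trials$reward_sense_time[1]
  t_peak_expected <- second_lick + truth$reward_latency +
    kernel_peak_time(truth$reward_tau_rise, truth$reward_tau_decay)
  # restrict to the first trial's neighborhood
  win <- seq(floor((second_lick - 1) * 1000), floor((second_lick + 2) * 1000))
  t_peak <- (win[which.max(tr$f465[win])] - 1) / 1000
  expect_lt(abs(t_peak - t_peak_expected), 0.005)
})

test_that("shared motion artifact makes channel fluctuations highly correlated", {
  cfg <- task_config("whisker_detection", n_trials = 5)
  beh <- simulate_behavior(cfg, behavior_params(), seed = 5)
  truth <- photometry_truth(sensory_amp = 0, reward_amp = 0, dip_amp = -1e-12,
                            motion_artifact_sd = 0.02,
                            bleach_tau_465 = 1e9, bleach_tau_405 = 1e9)
  tr <- render_fluorescence(beh$events, truth, beh$trials)
  expect_gt(cor(tr$f465, tr$f405), 0.9)
})

test_that("modulation produces exact carrier products and spectral line ratios", {
  truth <- photometry_truth(fs_acquisition = 20000)
  t1k <- seq(0, 10, 1e-3)
  mk <- function(a, b) structure(list(f465 = rep(a, length(t1k)),
                                      f405 = rep(b, length(t1k)),
                                      fs = 1000, t0 = 0),
                                 class = "photolick_traces")
  # single channel: detector is exactly A * 0.5 * (1 + sin(2 pi f t))
  raw <- modulate(mk(3, 0), truth, offset = 0)
  tt <- (seq_along(raw$samples) - 1) / raw$fs
  expect_equal(raw$samples, 3 * 0.5 * (1 + sin(2 * pi * 208.616 * tt)),
               tolerance = 1e-9)
  # both zero: constant offset
  raw0 <- modulate(mk(0, 0), truth, offset = 0.7)
  expect_true(all(raw0$samples == 0.7))
  # spectral lines at the carriers with amplitude ratio 2:3
  raw23 <- modulate(mk(2, 3), truth, offset = 0)
  sp <- Mod(stats::fft(raw23$samples))
  fr <- (seq_along(sp) - 1) * raw23$fs / length(sp)
  a1 <- max(sp[abs(fr - 208.616) < 0.5])
  a2 <- max(sp[abs(fr - 500.679) < 0.5])
  expect_equal(a1 / a2, 2 / 3, tolerance = 0.02)
  # Nyquist violation
  truth_bad <- photometry_truth(fs_acquisition = 20000)
  truth_bad$fs_acquisition <- 900
  expect_error(modulate(mk(1, 1), truth_bad), "Nyquist")
})

test_that("simulation is reproducible for a fixed seed", {
  cfg <- task_config("delayed_reward", n_trials = 20)
  a <- simulate_behavior(cfg, behavior_params(), seed = 9)
  b <- simulate_behavior(cfg, behavior_params(), seed = 9)
  expect_identical(a$events$lick_times, b$events$lick_times)
  expect_identical(as.data.frame(a$trials), as.data.frame(b$trials))
})
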