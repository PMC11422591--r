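make_raw <- function(samples, fs, carriers = c(208.616, 500.679), m = 1) {
  structure(list(samples = samples, fs = fs, carrier_freqs = carriers,
                 modulation_depth = m, t0 = 0), class = "photolick_raw")
}

test_that("lock-in recovers a constant envelope from a pure carrier", {
  fs <- 12224
  tt <- (0:(3 * fs)) / fs
  raw <- make_raw(3 * 0.5 * (1 + sin(2 * pi * 208.616 * tt)), fs)
  env <- lockin_demodulate(raw, 208.616)
  keep <- tt > 0.5 & tt < max(tt) - 0.5
  expect_true(all(abs(env[keep] - 3) < 0.01 * 3))
  expect_equal(attr(env, "group_delay_s"), 0)
  # zero input -> zero output
  env0 <- lockin_demodulate(make_raw(numeric(length(tt)), fs), 208.616)
  expect_true(all(abs(env0) < 1e-9))
})

test_that("lock-in guards its preconditions", {
  raw <- make_raw(numeric(1000), 12224)
  expect_error(lockin_demodulate(raw, 333), "not one of")
  expect_error(lockin_demodulate(raw, 208.616, lowpass_cutoff = 200),
               "too high")
})

test_that("demodulation is linear in the detector signal", {
  fs <- 12224
  tt <- (0:(2 * fs)) / fs
  x <- (1 + 0.1 * sin(2 * pi * 1 * tt)) * 0.5 * (1 + sin(2 * pi * 208.616 * tt))
  y <- (2 + 0.2 * sin(2 * pi * 3 * tt)) * 0.5 * (1 + sin(2 * pi * 208.616 * tt))
  ea <- lockin_demodulate(make_raw(2 * x + 3 * y, fs), 208.616)
  ex <- lockin_demodulate(make_raw(x, fs), 208.616)
  ey <- lockin_demodulate(make_raw(y, fs), 208.616)
  keep <- tt > 0.5 & tt < max(tt) - 0.5
  expect_equal(ea[keep], (2 * ex + 3 * ey)[keep], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("lock-in agrees with the per-cycle sine-fit oracle and rejects crosstalk", {
  res <- demod_oracle_experiment(fs_acquisition = 12224, duration_s = 20)
  expect_lt(res$rms_err_oracle, 0.01)
  expect_lt(res$crosstalk, 0.01)
})

test_that("downsampling preserves constants and passband amplitude", {
  x <- rep(2.5, 5000)
  y <- downsample_1khz(x, 20000)
  expect_true(all(abs(y - 2.5) < 1e-9))
  # 10 Hz sinusoid at 20 kHz: amplitude preserved within 0.5%
  tt <- (0:(20000 * 4)) / 20000
  y10 <- downsample_1khz(sin(2 * pi * 10 * tt), 20000)
  t_out <- (seq_along(y10) - 1) / 1000
  keep <- t_out > 0.5 & t_out < max(t_out) - 0.5
  fit <- stats::lm(y10[keep] ~ sin(2 * pi * 10 * t_out[keep]) +
                     cos(2 * pi * 10 * t_out[keep]) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_lt(abs(amp - 1), 0.005)
  expect_error(downsample_1khz(x, 500), ">= 1000")
})

test_that("non-integer rate ratios land on an exact 1-ms grid", {
  x <- stats::rnorm(12224 * 2)
  y <- downsample_1khz(x, 12224)
  expect_equal(attr(y, "fs"), 1000)
  expect_equal(length(y), floor((length(x) - 1) / 12224 * 1000) + 1)
})

test_that("modulate -> demodulate round-trip recovers band-limited envelopes", {
  truth <- photometry_truth(fs_acquisition = 12224)
  t1k <- seq(0, 20, 1e-3)
  f465 <- 1 + 0.05 * sin(2 * pi * 2 * t1k) + 0.03 * sin(2 * pi * 7 * t1k)
  f405 <- 0.8 + 0.02 * sin(2 * pi * 1 * t1k)
  ideal <- structure(list(f465 = f465, f405 = f405, fs = 1000, t0 = 0),
                     class = "photolick_traces")
  rec <- demodulate_session(modulate(ideal, truth, offset = 0.3))
  keep <- t1k > 0.5 & t1k < max(t1k) - 0.5
  rms465 <- sqrt(mean((rec$f465[keep] - f465[keep])^2)) / mean(f465)
  rms405 <- sqrt(mean((rec$f405[keep] - f405[keep])^2)) / mean(f405)
  expect_lt(rms465, 0.02)
  expect_lt(rms405, 0.02)
})
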