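#' Quadrature lock-in demodulation of one carrier
#'
#' Recovers the slowly varying fluorescence envelope riding on a sinusoidal
#' excitation carrier. The detector voltage is multiplied by quadrature
#' references at the carrier frequency, both products are low-pass filtered
#' (4th-order Butterworth, applied forward-backward so the output is
#' zero-phase), and the envelope is `scale * sqrt(I^2 + Q^2)`. With the
#' non-negative excitation convention `e(t) = 0.5 (1 + m sin(2 pi f t))` the
#' carrier component of a channel with fluorescence `F` has amplitude
#' `0.5 m F`, so the scale `4 / m` returns `F` directly; the modulation
#' depth is absorbed by the scale convention.
#'
#' Because filtering is zero-phase, the group delay of the output is zero;
#' this is recorded in the `group_delay_s` attribute.
#'
#' @param raw A `photolick_raw` record (or any list with `samples`, `fs`,
#'   `carrier_freqs`, `modulation_depth`, `t0`).
#' @param carrier Carrier frequency to demodulate, Hz; must be one of
#'   `raw$carrier_freqs`.
#' @param lowpass_cutoff Low-pass cutoff, Hz. Must be below half the minimum
#'   spacing between carriers (and the carriers' distance to DC) so that
#'   cross-talk terms are rejected. Default 25 Hz: dopamine transients have
#'   sub-10 Hz content while the carriers sit at 208 Hz and above.
#' @return Numeric envelope at the raw sampling rate, attributes
#'   `group_delay_s` (0 for the offline zero-phase filter) and `fs`.
#' @export
lockin_demodulate <- function(raw, carrier, lowpass_cutoff = 25) {
  if (!any(abs(raw$carrier_freqs - carrier) < 1e-9))
    stop("carrier ", carrier, " Hz is not one of the record's carriers")
  sep <- min(abs(diff(sort(c(0, raw$carrier_freqs)))))
  if (lowpass_cutoff >= sep / 2)
    stop("lowpass_cutoff (", lowpass_cutoff, " Hz) too high: must be below ",
         "half the minimum carrier separation (", sep / 2, " Hz)")
  fs <- raw$fs
  tt <- raw$t0 + (seq_along(raw$samples) - 1) / fs
  bw <- signal::butter(4, lowpass_cutoff / (fs / 2), type = "low")
  np <- ceiling(1.0 * fs)  # reflective padding absorbs the filter transient
  i_comp <- filtfilt_padded(bw, raw$samples * sin(2 * pi * carrier * tt), np)
  q_comp <- filtfilt_padded(bw, raw$samples * cos(2 * pi * carrier * tt), np)
  m <- if (!is.null(raw$modulation_depth)) raw$modulation_depth else 1
  env <- (4 / m) * sqrt(i_comp^2 + q_comp^2)
  attr(env, "group_delay_s") <- 0
  attr(env, "fs") <- fs
  env
}

## zero-phase filtering with odd-reflection edge padding, so constants pass
## unchanged and the forward-backward filter transient never reaches the data
filtfilt_padded <- function(filt, x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  if (np < 1L) return(signal::filtfilt(filt, x))
  left <- 2 * x[1] - x[(np + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(np + 1L):(np + n)]
}

#' Per-cycle sinusoidal regression envelope (reference method)
#'
#' Independent envelope estimator used to validate the lock-in path: in
#' consecutive windows of one slow-carrier cycle the raw record is
#' regressed by least squares onto quadrature sinusoids at *both* carriers
#' plus an intercept (both carriers must be modeled jointly because they
#' are not orthogonal over a fractional-cycle window), and the envelope of
#' the requested carrier is `2/m * sqrt(a^2 + b^2)`. No filtering is
#' involved, so the two methods share no code path.
#'
#' @inheritParams lockin_demodulate
#' @return A data.frame with window-center `time_s` and `envelope`.
#' @export
envelope_sinefit <- function(raw, carrier) {
  if (!any(abs(raw$carrier_freqs - carrier) < 1e-9))
    stop("carrier ", carrier, " Hz is not one of the record's carriers")
  fs <- raw$fs
  tt <- raw$t0 + (seq_along(raw$samples) - 1) / fs
  win <- floor((tt - raw$t0) * min(raw$carrier_freqs))
  f1 <- raw$carrier_freqs[1]; f2 <- raw$carrier_freqs[2]
  X <- cbind(sin(2 * pi * f1 * tt), cos(2 * pi * f1 * tt),
             sin(2 * pi * f2 * tt), cos(2 * pi * f2 * tt), 1)
  ci <- if (abs(carrier - f1) < 1e-9) c(1L, 2L) else c(3L, 4L)
  m <- if (!is.null(raw$modulation_depth)) raw$modulation_depth else 1
  idx <- split(seq_along(win), win)
  out_t <- vapply(idx, function(i) mean(tt[i]), numeric(1))
  amp <- vapply(idx, function(i) {
    cf <- tryCatch(stats::.lm.fit(X[i, , drop = FALSE],
                                  raw$samples[i])$coefficients,
                   error = function(e) rep(NA_real_, 5))
    sqrt(cf[ci[1]]^2 + cf[ci[2]]^2)
  }, numeric(1))
  data.frame(time_s = unname(out_t), envelope = unname((2 / m) * amp))
}

#' Resample a trace to the 1 kHz analysis clock
#'
#' Applies an anti-alias low-pass (4th-order Butterworth at 400 Hz,
#' zero-phase) when the input rate exceeds 2 kHz, then interpolates linearly
#' onto an exact 1-ms grid starting at `t0`. Non-integer rate ratios (e.g.
#' 12224 Hz) are handled by the uniform-grid interpolation; output length is
#' `floor(duration * 1000) + 1` samples.
#'
#' @param x Numeric trace.
#' @param fs_in Input sampling rate, Hz; must be `>= 1000`.
#' @param t0 Time of the first sample, seconds.
#' @return Numeric trace at 1000 Hz with attributes `fs = 1000`, `t0`.
#' @export
downsample_1khz <- function(x, fs_in, t0 = 0) {
  if (fs_in < 1000) stop("fs_in must be >= 1000 Hz")
  if (fs_in > 2000) {
    bw <- signal::butter(4, 400 / (fs_in / 2), type = "low")
    x <- filtfilt_padded(bw, x, ceiling(0.05 * fs_in))
  }
  t_in <- t0 + (seq_along(x) - 1) / fs_in
  t_out <- seq(t0, t0 + floor((length(x) - 1) / fs_in * 1000) / 1000,
               by = 0.001)
  y <- stats::approx(t_in, x, t_out)$y
  attr(y, "fs") <- 1000
  attr(y, "t0") <- t0
  y
}

#' Demodulate a raw two-carrier record into 1 kHz channel traces
#'
#' Runs [lockin_demodulate()] for each carrier (465 nm first, 405 nm second,
#' following the carrier order of the record) and resamples both envelopes to
#' the shared 1 kHz analysis clock.
#'
#' @inheritParams lockin_demodulate
#' @return A `photolick_traces` object (`f465`, `f405`, `fs = 1000`, `t0`).
#' @export
demodulate_session <- function(raw, lowpass_cutoff = 25) {
  e465 <- lockin_demodulate(raw, raw$carrier_freqs[1], lowpass_cutoff)
  e405 <- lockin_demodulate(raw, raw$carrier_freqs[2], lowpass_cutoff)
  f465 <- downsample_1khz(as.numeric(e465), raw$fs, raw$t0)
  f405 <- downsample_1khz(as.numeric(e405), raw$fs, raw$t0)
  structure(list(f465 = as.numeric(f465), f405 = as.numeric(f405),
                 fs = 1000, t0 = raw$t0),
            class = "photolick_traces")
}
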