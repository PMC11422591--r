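#' Render ideal 1 kHz two-channel fluorescence for a simulated session
#'
#' Builds the dopamine-sensitive 465 nm trace and the dopamine-insensitive
#' 405 nm isosbestic trace on the 1 kHz analysis clock from the latent trial
#' table. The 465 channel receives three kernel families: a sensory transient
#' at each whisker stimulus (amplitude following the learning schedule when
#' coupling is enabled), a reward transient anchored at the second lick of
#' rewarded bouts (the lick on which the tongue meets the water), and a
#' negative dip anchored at the second lick of unrewarded report bouts.
#' Reward and dip amplitudes are scaled by the per-trial satiety factor.
#' Both channels bleach mono-exponentially and share a slow additive motion
#' artifact; the 405 channel carries no dopamine kernels.
#'
#' @param events `photolick_events` from [simulate_behavior()].
#' @param truth A [photometry_truth()] object.
#' @param trials Latent trial table from [simulate_behavior()].
#' @param fs Analysis sampling rate, Hz (default 1000).
#' @return A `photolick_traces` object: `f465`, `f405`, `fs`, `t0`, plus the
#'   injected ground-truth components as attributes `artifact` (shared
#'   fractional motion trace) and `dff_true` (noise-free fractional dopamine
#'   signal).
#' @export
render_fluorescence <- function(events, truth, trials, fs = 1000) {
  stopifnot(inherits(truth, "photolick_truth"))
  n <- ceiling(events$session_t_end * fs) + 1L
  tt <- (seq_len(n) - 1) / fs

  s <- numeric(n)  # fractional dopamine signal
  add_kernels <- function(s, times, amps, tau_r, tau_d) {
    ok <- !is.na(times)
    times <- times[ok]; amps <- amps[ok]
    if (!length(times)) return(s)
    len <- ceiling((kernel_peak_time(tau_r, tau_d) + 8 * tau_d) * fs)
    shape <- dopamine_kernel((seq_len(len) - 1) / fs, 1, tau_r, tau_d)
    for (k in seq_along(times)) {
      i0 <- floor(times[k] * fs) + 1L
      i1 <- min(i0 + len - 1L, n)
      if (i1 >= i0) s[i0:i1] <- s[i0:i1] + amps[k] * shape[seq_len(i1 - i0 + 1L)]
    }
    s
  }

  amps <- latent_kernel_amps(truth, trials)
  s <- add_kernels(s, trials$onset_time[trials$stim], amps$sensory[trials$stim],
                   truth$sensory_tau_rise, truth$sensory_tau_decay)
  ## reward/dip transients start reward_latency after the tongue meets (or
  ## misses) the water on the second lick of the bout
  s <- add_kernels(s, trials$reward_sense_time + truth$reward_latency,
                   amps$reward,
                   truth$reward_tau_rise, truth$reward_tau_decay)
  dip_anchor <- ifelse(!trials$rewarded & !is.na(trials$first_report_lick_time),
                       trials$first_report_lick_time + 0.1 +
                         truth$reward_latency, NA_real_)
  s <- add_kernels(s, dip_anchor, amps$dip,
                   truth$dip_tau_rise, truth$dip_tau_decay)

  artifact <- render_motion_artifact(n, fs, truth$motion_artifact_sd)
  B465 <- truth$baseline_f465; B405 <- truth$baseline_f405
  ## few-temporary arithmetic: these vectors are session-length
  bl465 <- exp(-tt / truth$bleach_tau_465)
  bl405 <- if (truth$bleach_tau_405 == truth$bleach_tau_465) bl465
           else exp(-tt / truth$bleach_tau_405)
  f465 <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd * B465)
          else numeric(n)
  f465 <- f465 + (B465 * bl465) * (1 + s)
  if (truth$motion_artifact_sd > 0) f465 <- f465 + B465 * artifact
  f405 <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd * B405)
          else numeric(n)
  f405 <- f405 + B405 * bl405
  if (truth$motion_artifact_sd > 0)
    f405 <- f405 + (B405 * truth$artifact_scale_405) * artifact

  structure(list(f465 = f465, f405 = f405, fs = fs, t0 = 0),
            class = "photolick_traces",
            artifact = artifact, dff_true = s)
}

## per-trial kernel amplitudes implied by the ground truth and latent table
latent_kernel_amps <- function(truth, trials) {
  sens <- rep(truth$sensory_amp, nrow(trials))
  p <- trials$hit_p
  if (isTRUE(truth$couple_sensory_to_learning) && any(!is.na(p))) {
    ## sensory amplitude proportional to the current hit probability: the
    ## sensory dopamine response grows as the stimulus-reward association
    ## is acquired
    sens <- truth$sensory_amp * ifelse(is.na(p), 1, p)
  }
  list(sensory = sens,
       reward = ifelse(trials$rewarded,
                       truth$reward_amp * trials$satiety_factor, NA_real_),
       dip = rep(truth$dip_amp, nrow(trials)) * trials$satiety_factor)
}

## slow shared motion artifact: white noise on a coarse 20 Hz grid,
## linearly interpolated to fs and scaled to the requested RMS (linear
## interpolation of unit-variance white noise has variance 2/3; the
## pre-scale compensates so the output RMS matches sd_target)
render_motion_artifact <- function(n, fs, sd_target, f_grid = 20) {
  if (sd_target <= 0) return(numeric(n))
  n_c <- ceiling((n - 1) / fs * f_grid) + 2L
  coarse <- stats::rnorm(n_c, 0, sd_target * sqrt(3 / 2))
  stats::approx(x = (seq_len(n_c) - 1) / f_grid, y = coarse,
                xout = (seq_len(n) - 1) / fs, rule = 2)$y
}

#' Render the piezo lick-sensor voltage
#'
#' Each tongue-spout contact produces a short 100 Hz damped burst on the
#' piezo film; white noise is added at the requested signal-to-noise ratio.
#'
#' @param events `photolick_events` object.
#' @param fs Sampling rate, Hz.
#' @param lick_amp Burst peak amplitude, volts.
#' @param snr Ratio of burst amplitude to noise SD.
#' @param burst_freq,burst_dur Burst carrier frequency (Hz) and duration (s).
#' @return The events object with the `piezo` slot filled.
#' @export
render_piezo <- function(events, fs = 1000, lick_amp = 1, snr = 10,
                         burst_freq = 100, burst_dur = 0.03) {
  n <- ceiling(events$session_t_end * fs) + 1L
  len <- round(burst_dur * fs)
  tb <- (seq_len(len) - 1) / fs
  shape <- lick_amp * sin(2 * pi * burst_freq * tb) * exp(-tb / (burst_dur / 2))
  piezo <- stats::rnorm(n, 0, lick_amp / snr)
  for (lt in events$lick_times) {
    i0 <- floor(lt * fs) + 1L
    i1 <- min(i0 + len - 1L, n)
    if (i1 >= i0) piezo[i0:i1] <- piezo[i0:i1] + shape[seq_len(i1 - i0 + 1L)]
  }
  events$piezo <- piezo
  events$fs_piezo <- fs
  events
}

#' Modulate two fluorescence channels onto sinusoidal excitation carriers
#'
#' Emulates the acquisition chain: each channel's fluorescence is
#' proportional to its LED excitation intensity
#' \eqn{e_i(t) = 0.5 (1 + m \sin(2\pi f_i t))} (non-negative, since LED
#' intensity cannot be negative), and the photodetector sums both channels:
#' `detector(t) = F465(t) e1(t) + F405(t) e2(t) + offset`, sampled at
#' `fs_acquisition`. The 1 kHz input traces are linearly interpolated onto
#' the acquisition clock.
#'
#' @param ideal `photolick_traces` object (1 kHz two-channel fluorescence).
#' @param truth [photometry_truth()] carrying carriers, modulation depth and
#'   acquisition rate.
#' @param offset Constant detector offset, volts.
#' @return A `photolick_raw` object: `samples`, `fs`, `carrier_freqs`,
#'   `modulation_depth`, `t0`.
#' @export
modulate <- function(ideal, truth, offset = 0.1) {
  stopifnot(inherits(ideal, "photolick_traces"))
  fs <- truth$fs_acquisition
  if (fs <= 2 * max(truth$carrier_freqs))
    stop("Nyquist violation: fs_acquisition must exceed twice the highest carrier")
  t_in <- ideal$t0 + (seq_along(ideal$f465) - 1) / ideal$fs
  t_end <- t_in[length(t_in)]
  tt <- seq(ideal$t0, t_end, by = 1 / fs)
  f465 <- stats::approx(t_in, ideal$f465, tt)$y
  f405 <- stats::approx(t_in, ideal$f405, tt)$y
  m <- truth$modulation_depth
  e1 <- 0.5 * (1 + m * sin(2 * pi * truth$carrier_freqs[1] * tt))
  e2 <- 0.5 * (1 + m * sin(2 * pi * truth$carrier_freqs[2] * tt))
  structure(list(samples = f465 * e1 + f405 * e2 + offset, fs = fs,
                 carrier_freqs = truth$carrier_freqs,
                 modulation_depth = m, t0 = ideal$t0),
            class = "photolick_raw")
}

#' Generate one complete synthetic session
#'
#' Convenience wrapper chaining [simulate_behavior()],
#' [render_fluorescence()], [render_piezo()] and optionally [modulate()].
#'
#' @inheritParams simulate_behavior
#' @param truth A [photometry_truth()] object.
#' @param include_raw If `TRUE`, also produce the carrier-modulated detector
#'   record (memory-heavy for long sessions).
#' @param include_piezo If `TRUE`, render the piezo lick-sensor voltage.
#' @return A list (`photolick_session`) with `events`, `trials`, `traces`,
#'   optionally `raw`, plus `config`, `params`, `truth`, `seed`.
#' @export
simulate_session <- function(config, params, truth, seed,
                             include_raw = FALSE, include_piezo = TRUE) {
  beh <- simulate_behavior(config, params, seed)
  traces <- render_fluorescence(beh$events, truth, beh$trials)
  events <- if (include_piezo) render_piezo(beh$events) else beh$events
  raw <- if (include_raw) modulate(traces, truth) else NULL
  structure(list(events = events, trials = beh$trials, traces = traces,
                 raw = raw, config = config, params = params, truth = truth,
                 seed = seed),
            class = "photolick_session")
}
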