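#' Task configuration
#'
#' Describes the trial structure of one behavioral session. Four task kinds
#' are supported, mirroring the standard head-fixed training sequence:
#'
#' * `free_licking`: licking within a 1-s reporting window is rewarded with
#'   probability `reward_prob_on_lick` (default 0.5); windows are separated by
#'   a 0.5-0.6 s inter-trial interval plus a 3.5-4.5 s no-lick period.
#' * `whisker_detection`: go/no-go detection. Half of trials carry a brief
#'   whisker deflection; licking within 1 s of the stimulus is a Hit
#'   (rewarded), licking in a no-stimulus trial a False alarm. Inter-trial
#'   interval 8-13 s, no-lick period 4.5-5.5 s.
#' * `delayed_reward`: as whisker detection with a 1-s delay between stimulus
#'   and reporting window; delay-period licks are neither rewarded nor punished.
#' * `reward_omission`: as delayed reward; after a 50-trial warm-up
#'   (25 stimulus / 25 no-stimulus, all correct licks rewarded) the reward
#'   probability on Hit trials drops to `1 - omission_prob`, splitting hits
#'   into rewarded (`HitPlus`) and omitted (`HitMinus`).
#'
#' @param task_kind One of `"free_licking"`, `"whisker_detection"`,
#'   `"delayed_reward"`, `"reward_omission"`.
#' @param n_trials Number of completed trials to simulate/expect.
#' @param iti_range,nolick_range Length-2 numeric vectors, seconds.
#' @param report_window Reporting-window duration, seconds.
#' @param delay Stimulus-to-reporting-window delay, seconds (0 except for the
#'   delayed tasks, where it is 1).
#' @param reward_prob_on_lick Reward probability for a reporting-window lick
#'   in the free-licking task.
#' @param omission_prob Probability that a post-warm-up Hit goes unrewarded in
#'   the reward-omission task.
#' @param warmup_trials Number of fully-rewarded warm-up trials in the
#'   reward-omission task.
#' @param stim_trial_fraction Fraction of trials carrying a stimulus.
#' @param max_consecutive_same_type Maximum run length of identical
#'   stimulus/no-stimulus trial types.
#' @param reward_volume_ul Nominal reward volume, microliters (metadata only).
#' @return An object of class `photolick_task`.
#' @export
task_config <- function(task_kind = c("free_licking", "whisker_detection",
                                      "delayed_reward", "reward_omission"),
                        n_trials = NULL,
                        iti_range = NULL,
                        nolick_range = NULL,
                        report_window = 1.0,
                        delay = NULL,
                        reward_prob_on_lick = 0.5,
                        omission_prob = 0.5,
                        warmup_trials = 50L,
                        stim_trial_fraction = 0.5,
                        max_consecutive_same_type = 3L,
                        reward_volume_ul = 5) {
  task_kind <- match.arg(task_kind)
  free <- task_kind == "free_licking"
  delayed <- task_kind %in% c("delayed_reward", "reward_omission")
  if (is.null(iti_range)) iti_range <- if (free) c(0.5, 0.6) else c(8, 13)
  if (is.null(nolick_range)) nolick_range <- if (free) c(3.5, 4.5) else c(4.5, 5.5)
  if (is.null(delay)) delay <- if (delayed) 1.0 else 0.0
  if (is.null(n_trials)) {
    n_trials <- switch(task_kind,
      free_licking = 90L, whisker_detection = 110L,
      delayed_reward = 110L, reward_omission = 150L)
  }
  cfg <- list(task_kind = task_kind, n_trials = as.integer(n_trials),
              iti_range = as.numeric(iti_range),
              nolick_range = as.numeric(nolick_range),
              report_window = report_window, delay = delay,
              reward_prob_on_lick = reward_prob_on_lick,
              omission_prob = omission_prob,
              warmup_trials = as.integer(warmup_trials),
              stim_trial_fraction = stim_trial_fraction,
              max_consecutive_same_type = as.integer(max_consecutive_same_type),
              reward_volume_ul = reward_volume_ul)
  validate_task_config(cfg)
  structure(cfg, class = "photolick_task")
}

validate_task_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(iti_range) == 2, length(nolick_range) == 2)
    if (any(c(iti_range, nolick_range, report_window) <= 0))
      stop("all durations must be positive")
    if (iti_range[1] > iti_range[2] || nolick_range[1] > nolick_range[2])
      stop("range lower bounds must not exceed upper bounds")
    fr <- c(reward_prob_on_lick, omission_prob, stim_trial_fraction)
    if (any(fr < 0 | fr > 1)) stop("probabilities must lie in [0, 1]")
    if (delay < 0) stop("delay must be non-negative")
    if (delay > 0 && !task_kind %in% c("delayed_reward", "reward_omission"))
      stop("delay > 0 is only meaningful for the delayed tasks")
    if (max_consecutive_same_type < 1) stop("max_consecutive_same_type must be >= 1")
    if (n_trials < 1) stop("n_trials must be >= 1")
  })
  invisible(cfg)
}

#' Behavioral model parameters for the session simulator
#'
#' Governs the simulated mouse: spontaneous lick bouts (a Poisson process of
#' bout onsets), rhythmic licking at ~10 Hz within bouts, longer bouts when
#' rewarded, a logistic within-session learning curve for the probability of
#' responding to the whisker stimulus, a reaction-time distribution, and an
#' exponential satiety decay of motivation driven by the cumulative number of
#' consumed rewards.
#'
#' @param spontaneous_bout_rate Spontaneous bout onsets per second. The
#'   false-alarm probability of a 1-s window is `1 - exp(-rate)`; the default
#'   0.2/s gives ~0.18, matching typical head-fixed spontaneous lick rates.
#' @param intra_bout_lick_freq Within-bout lick rate, Hz.
#' @param bout_length_rewarded_mean,bout_length_unrewarded_mean Mean number of
#'   licks per bout (Poisson, with floors of 2 and 1 licks respectively);
#'   rewarded bouts are longer because the animal consumes the droplet.
#' @param learning_p0,learning_pmax,learning_midpoint,learning_steepness
#'   Logistic hit-probability curve over the stimulus-trial index:
#'   `p(i) = p0 + (pmax - p0) / (1 + exp(-(i - midpoint)/steepness))`.
#' @param free_lick_prob Probability of initiating licking in a free-licking
#'   reporting window.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (seconds
#'   after stimulus onset); defaults put the mode near 0.3 s.
#' @param rt_min Reaction-time floor, seconds. Whisker-detection lick
#'   latencies below ~200 ms are not physiological; the floor also keeps
#'   reward responses (anchored at the second lick) causally outside the
#'   0.1-0.3 s early sensory quantification window.
#' @param post_stim_suppression Duration (s) after a whisker stimulus during
#'   which ongoing spontaneous lick-bout initiation is interrupted (orienting
#'   response to a salient stimulus). Stimulus-triggered responses and
#'   no-stimulus trials are unaffected, so false-alarm rates are preserved.
#' @param satiety_tau Satiety time constant in consumed rewards: kernel
#'   amplitudes of reward responses scale by `exp(-n_rewards/satiety_tau)`.
#'   Use `Inf` to disable satiety.
#' @param max_abort_attempts Abort-retry bound per trial before the simulator
#'   declares the parameters infeasible.
#' @return An object of class `photolick_behavior`.
#' @export
behavior_params <- function(spontaneous_bout_rate = 0.2,
                            intra_bout_lick_freq = 10,
                            bout_length_rewarded_mean = 8,
                            bout_length_unrewarded_mean = 3,
                            learning_p0 = 0.2,
                            learning_pmax = 0.8,
                            learning_midpoint = 25,
                            learning_steepness = 8,
                            free_lick_prob = 0.9,
                            rt_meanlog = log(0.3),
                            rt_sdlog = 0.35,
                            rt_min = 0.2,
                            post_stim_suppression = 0.3,
                            satiety_tau = 40,
                            max_abort_attempts = 1000L) {
  p <- as.list(environment())
  if (p$spontaneous_bout_rate < 0) stop("spontaneous_bout_rate must be >= 0")
  if (p$intra_bout_lick_freq <= 0) stop("intra_bout_lick_freq must be > 0")
  if (!(p$learning_p0 >= 0 && p$learning_p0 <= p$learning_pmax &&
        p$learning_pmax <= 1))
    stop("need 0 <= learning_p0 <= learning_pmax <= 1")
  if (p$satiety_tau <= 0) stop("satiety_tau must be > 0 (use Inf to disable)")
  structure(p, class = "photolick_behavior")
}

#' Logistic learning curve
#'
#' Per-stimulus-trial hit probability implied by a [behavior_params()] object.
#'
#' @param params A `photolick_behavior` object.
#' @param i Stimulus-trial index (1-based), vectorized.
#' @return Hit probabilities in `[p0, pmax]`.
#' @export
learning_curve <- function(params, i) {
  params$learning_p0 + (params$learning_pmax - params$learning_p0) /
    (1 + exp(-(i - params$learning_midpoint) / params$learning_steepness))
}

#' Photometry ground-truth parameters for the session simulator
#'
#' Latent parameters of the synthetic fluorescence model. The 465 nm channel
#' carries the dopamine kernels (sensory, reward, and negative "dip"
#' transients); the 405 nm isosbestic channel does not. Both channels share a
#' slow additive motion artifact and bleach mono-exponentially.
#'
#' Fluorescence model at the 1 kHz analysis clock:
#' \deqn{F465(t) = B_{465} e^{-t/\tau_{b465}} (1 + s(t)) + B_{465} m(t) + \epsilon_{465}(t)}
#' \deqn{F405(t) = B_{405} e^{-t/\tau_{b405}} + B_{405} c_{405} m(t) + \epsilon_{405}(t)}
#' where `s(t)` is the sum of dopamine kernels (fractional dF/F units),
#' `m(t)` the shared low-pass motion artifact and the noise terms are white.
#'
#' @param baseline_f465,baseline_f405 Baseline detector levels (volts).
#' @param sensory_amp Peak fractional amplitude of the stimulus-evoked kernel
#'   at full learning; with `couple_sensory_to_learning = TRUE` the per-trial
#'   amplitude follows the normalized learning curve.
#' @param sensory_tau_rise,sensory_tau_decay Sensory kernel time constants, s.
#' @param reward_amp Peak fractional amplitude of the reward kernel (anchored
#'   at the second lick of rewarded bouts, when the tongue meets the water);
#'   defaults give a peak ~0.5 s after the first tongue-spout contact and a
#'   ~1 s decay.
#' @param reward_tau_rise,reward_tau_decay Reward kernel time constants, s.
#' @param reward_latency Onset latency of the reward (and dip) transient
#'   after the tongue meets (or misses) the water, seconds: dopamine release
#'   and sensor binding delay the fluorescence rise by ~100 ms.
#' @param dip_amp Peak (negative) amplitude of the dopamine dip following
#'   unrewarded licking; slower time course.
#' @param dip_tau_rise,dip_tau_decay Dip kernel time constants, s.
#' @param couple_sensory_to_learning If `TRUE`, the per-trial sensory
#'   amplitude is `sensory_amp` scaled by the normalized learning curve;
#'   if `FALSE` the amplitude is constant at `sensory_amp`.
#' @param bleach_tau_465,bleach_tau_405 Photobleaching time constants, s.
#' @param motion_artifact_sd RMS of the shared fractional motion artifact.
#' @param artifact_scale_405 Per-channel scale of the shared artifact on the
#'   405 channel (fraction of its own baseline).
#' @param noise_sd Per-channel white-noise SD as a fraction of baseline.
#' @param carrier_freqs Excitation modulation frequencies, Hz
#'   (465 nm first, then 405 nm).
#' @param modulation_depth Sinusoidal modulation depth in `(0, 1]`.
#' @param fs_acquisition Detector sampling rate, Hz.
#' @return An object of class `photolick_truth`.
#' @export
photometry_truth <- function(baseline_f465 = 1.0,
                             baseline_f405 = 0.8,
                             sensory_amp = 0.010,
                             sensory_tau_rise = 0.02,
                             sensory_tau_decay = 0.15,
                             reward_amp = 0.050,
                             reward_tau_rise = 0.12,
                             reward_tau_decay = 1.0,
                             reward_latency = 0.1,
                             dip_amp = -0.015,
                             dip_tau_rise = 0.3,
                             dip_tau_decay = 1.5,
                             couple_sensory_to_learning = TRUE,
                             bleach_tau_465 = 3000,
                             bleach_tau_405 = 3000,
                             motion_artifact_sd = 0.005,
                             artifact_scale_405 = 1.0,
                             noise_sd = 0.003,
                             carrier_freqs = c(208.616, 500.679),
                             modulation_depth = 1.0,
                             fs_acquisition = 12224) {
  tr <- as.list(environment())
  for (k in c("sensory", "reward", "dip")) {
    if (tr[[paste0(k, "_tau_rise")]] >= tr[[paste0(k, "_tau_decay")]])
      stop(k, " kernel requires tau_rise < tau_decay")
  }
  if (length(tr$carrier_freqs) != 2 ||
      tr$carrier_freqs[1] == tr$carrier_freqs[2])
    stop("carrier_freqs must be two distinct frequencies")
  if (max(tr$carrier_freqs) >= tr$fs_acquisition / 2)
    stop("carrier frequencies must be below the acquisition Nyquist frequency")
  if (!(tr$modulation_depth > 0 && tr$modulation_depth <= 1))
    stop("modulation_depth must lie in (0, 1]")
  if (tr$reward_latency < 0) stop("reward_latency must be non-negative")
  if (any(c(tr$bleach_tau_465, tr$bleach_tau_405) <= 0))
    stop("bleach time constants must be positive")
  structure(tr, class = "photolick_truth")
}
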