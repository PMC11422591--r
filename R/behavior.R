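#' Licking power
#'
#' Pointwise square of the piezo lick-sensor voltage, the standard display
#' quantity for lick vigor.
#'
#' @param piezo Numeric voltage trace.
#' @return Numeric power trace.
#' @export
licking_power <- function(piezo) piezo^2

#' Detect lick onsets from the piezo voltage
#'
#' Threshold crossing detector: times where `|piezo|` first exceeds
#' `threshold_k` robust noise SDs (median absolute deviation), with a
#' refractory period suppressing re-triggers within one lick. Deterministic
#' for fixed input.
#'
#' @param piezo Numeric voltage trace.
#' @param fs Sampling rate, Hz.
#' @param threshold_k Threshold in robust noise-SD multiples (default 4).
#' @param refractory Minimum separation between onsets, seconds (default
#'   0.05 s; inter-lick intervals run ~100 ms at the ~10 Hz lick rhythm).
#' @param t0 Time of the first sample, seconds.
#' @return Increasing vector of onset times (possibly empty).
#' @export
detect_lick_onsets <- function(piezo, fs = 1000, threshold_k = 4,
                               refractory = 0.05, t0 = 0) {
  if (threshold_k <= 0) stop("threshold_k must be positive")
  if (refractory < 0) stop("refractory must be non-negative")
  sd_r <- stats::mad(piezo)
  if (sd_r == 0) sd_r <- stats::sd(piezo)
  if (!is.finite(sd_r) || sd_r == 0) return(numeric(0))
  above <- abs(piezo) > threshold_k * sd_r
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(cross)) return(numeric(0))
  keep <- cross[1]
  for (i in cross[-1]) {
    if ((i - keep[length(keep)]) / fs >= refractory) keep <- c(keep, i)
  }
  t0 + (keep - 1) / fs
}

#' Parse trials from event streams
#'
#' Reconstructs the completed trials of a session from the stimulus, valve,
#' lick and trial-start event streams, labelling each trial per the task
#' contingencies: Hit/Miss/FA/CR for the detection tasks, HitPlus/HitMinus
#' for reward omission, RewardedLick/UnrewardedLick for free licking
#' (free-licking windows without a lick are not trials of interest and are
#' skipped). Aborted initiation attempts (logged abort events) are counted
#' against the next completed trial. The reporting window is half-open
#' `[onset + delay, onset + delay + report_window)`: a lick exactly at the
#' window start counts, at the window end does not.
#'
#' A consistency cross-check verifies that every valve opening coincides
#' with the first reporting-window lick of a rewarded trial and raises an
#' error listing any orphan valve times.
#'
#' @param events `photolick_events` object. If `trial_start_times` is
#'   missing, only stimulus trials can be reconstructed (their onsets equal
#'   the stimulus times); this degraded mode warns.
#' @param config [task_config()] describing the session.
#' @return A `photolick_trials` data.frame (columns `trial`, `onset_time`,
#'   `stim`, `type`, `first_report_lick_time`, `reward_time`, `rewarded`,
#'   `aborted_attempt_count`).
#' @export
parse_trials <- function(events, config) {
  stopifnot(inherits(config, "photolick_task"))
  onsets <- events$trial_start_times
  if (is.null(onsets) || !length(onsets)) {
    warning("no trial-start events: reconstructing stimulus trials only")
    onsets <- sort(events$stim_times)
  }
  licks <- events$lick_times
  free <- config$task_kind == "free_licking"
  rows <- vector("list", length(onsets))
  claimed_valves <- numeric(0)
  for (j in seq_along(onsets)) {
    onset <- onsets[j]
    stim_j <- any(abs(events$stim_times - onset) < 1e-6)
    w0 <- onset + config$delay
    w1 <- w0 + config$report_window
    f <- first_lick_in_window(licks, w0, w1)
    rewarded <- FALSE; reward_time <- NA_real_
    if (!is.na(f)) {
      vmatch <- events$valve_times[abs(events$valve_times - f) < 1e-6]
      if (length(vmatch)) {
        rewarded <- TRUE
        reward_time <- vmatch[1]
        claimed_valves <- c(claimed_valves, vmatch[1])
      }
    }
    type <- classify_trial(config$task_kind, stim_j, !is.na(f), rewarded)
    if (is.na(type)) next
    rows[[j]] <- data.frame(onset_time = onset, stim = stim_j, type = type,
                            first_report_lick_time = f,
                            reward_time = reward_time, rewarded = rewarded,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no completed trials reconstructed")
  trials <- do.call(rbind, rows)
  trials <- trials[order(trials$onset_time), , drop = FALSE]
  trials$trial <- seq_len(nrow(trials))

  orphan <- events$valve_times[!vapply(events$valve_times, function(v)
    any(abs(claimed_valves - v) < 1e-6), TRUE)]
  if (length(orphan))
    stop("consistency error: valve opening(s) without a preceding ",
         "reporting-window lick at t = ",
         paste(signif(orphan, 10), collapse = ", "))

  ab <- events$abort_times
  trials$aborted_attempt_count <- count_aborts(if (is.null(ab)) numeric(0) else ab,
                                               trials$onset_time)
  rownames(trials) <- NULL
  trials <- trials[, c("trial", "onset_time", "stim", "type",
                       "first_report_lick_time", "reward_time", "rewarded",
                       "aborted_attempt_count")]
  class(trials) <- c("photolick_trials", "data.frame")
  trials
}

#' Signal-detection performance with loglinear-corrected d-prime
#'
#' Raw rates are `hit_rate = nHit / n_stim` and `fa_rate = nFA / n_nostim`
#' (hits include rewarded and omission hits). d-prime uses the loglinear
#' correction, adding 0.5 successes and 1 trial to each rate so extreme
#' rates stay finite:
#' `d' = qnorm((nHit + 0.5)/(n_stim + 1)) - qnorm((nFA + 0.5)/(n_nostim + 1))`.
#'
#' @param trials A `photolick_trials` table from a detection task.
#' @return A list (`photolick_performance`): `hit_rate`, `fa_rate`,
#'   `dprime`, `n_stim`, `n_nostim`.
#' @export
performance_metrics <- function(trials) {
  hit_types <- c("Hit", "HitPlus", "HitMinus")
  n_hit <- sum(trials$type %in% hit_types)
  n_miss <- sum(trials$type == "Miss")
  n_fa <- sum(trials$type == "FA")
  n_cr <- sum(trials$type == "CR")
  n_stim <- n_hit + n_miss
  n_nostim <- n_fa + n_cr
  if (n_stim == 0 || n_nostim == 0)
    stop("need at least one stimulus and one no-stimulus trial")
  structure(list(
    hit_rate = n_hit / n_stim,
    fa_rate = n_fa / n_nostim,
    dprime = dprime_loglinear(n_hit, n_stim, n_fa, n_nostim),
    n_stim = n_stim, n_nostim = n_nostim), class = "photolick_performance")
}

#' Loglinear-corrected d-prime from counts
#'
#' @param n_hit,n_stim Hit count and stimulus-trial count.
#' @param n_fa,n_nostim False-alarm count and no-stimulus-trial count.
#' @return d-prime in z-units (always finite).
#' @export
dprime_loglinear <- function(n_hit, n_stim, n_fa, n_nostim) {
  stats::qnorm((n_hit + 0.5) / (n_stim + 1)) -
    stats::qnorm((n_fa + 0.5) / (n_nostim + 1))
}
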