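#' Simulate session behavior: licks, stimuli, valve openings, trial truth
#'
#' Runs the task state machine forward in time. Trials are separated by an
#' inter-trial interval followed by a no-lick period; any lick inside the
#' no-lick period aborts the pending trial onset and restarts the no-lick
#' timer (each intruding bout is logged as one abort event). Stimulus /
#' no-stimulus identities are drawn randomly with at most
#' `max_consecutive_same_type` repeats; in the reward-omission task the
#' warm-up block is an exactly balanced 25/25 sequence with every correct
#' lick rewarded, after which rewards on Hit trials are delivered with
#' probability `1 - omission_prob`. The valve opens at the first lick inside
#' the (possibly delayed) reporting window of a rewarded trial; the water is
#' modeled as reaching the tongue at the second lick of the bout, which is
#' recorded as `reward_sense_time` in the latent trial table.
#'
#' @param config A [task_config()] object.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed; all randomness is local to this call.
#' @return A list with elements `events` (class `photolick_events`: sorted
#'   `lick_times`, `stim_times`, `valve_times`, `trial_start_times`,
#'   `abort_times`, `session_t_end`, and a `piezo` slot filled by
#'   [render_piezo()]) and `trials`, the latent trial table (one row per
#'   completed trial of interest) holding the generative truth:
#'   type, event times, reward outcome, abort count, stimulus-trial index,
#'   hit probability, and satiety factor.
#' @export
simulate_behavior <- function(config, params, seed) {
  stopifnot(inherits(config, "photolick_task"),
            inherits(params, "photolick_behavior"))
  set.seed(as.integer(seed))
  free <- config$task_kind == "free_licking"
  omission <- config$task_kind == "reward_omission"
  n <- config$n_trials
  stim_seq <- make_stim_sequence(config)

  rate <- params$spontaneous_bout_rate
  next_exp <- function(t) if (rate > 0) t + stats::rexp(1, rate) else Inf

  licks <- vector("list", 4L * n)
  li <- 0L
  add_licks <- function(x) {
    if (length(x)) { li <<- li + 1L; licks[[li]] <<- x }
  }

  stim_times <- numeric(0); valve_times <- numeric(0)
  trial_start <- numeric(n); abort_times <- numeric(0)
  rec <- vector("list", n)
  t_cursor <- 2.0
  t_spont <- next_exp(t_cursor)
  stim_counter <- 0L

  for (i in seq_len(n)) {
    iti <- stats::runif(1, config$iti_range[1], config$iti_range[2])
    guard_start <- t_cursor + iti
    nl <- stats::runif(1, config$nolick_range[1], config$nolick_range[2])
    n_aborts_here <- 0L

    ## --- no-lick gate: spontaneous bouts may abort and restart the timer ---
    repeat {
      onset <- guard_start + nl
      if (t_spont >= onset) break
      bout <- gen_bout(t_spont, draw_bout_len(params, rewarded = FALSE),
                       params$intra_bout_lick_freq)
      offending <- bout[bout >= guard_start]
      add_licks(bout)
      if (length(offending)) {
        n_aborts_here <- n_aborts_here + 1L
        abort_times <- c(abort_times, offending[1])
        guard_start <- bout[length(bout)]
        nl <- stats::runif(1, config$nolick_range[1], config$nolick_range[2])
      }
      t_spont <- next_exp(bout[length(bout)] + 1 / params$intra_bout_lick_freq)
      if (n_aborts_here > params$max_abort_attempts)
        stop("infeasible behavior parameters: trial ", i, " exceeded ",
             params$max_abort_attempts, " aborted initiation attempts")
    }

    trial_start[i] <- onset
    stim_i <- stim_seq[i]
    hit_p <- NA_real_
    s_idx <- NA_integer_
    if (stim_i) {
      stim_counter <- stim_counter + 1L
      s_idx <- stim_counter
      stim_times <- c(stim_times, onset)
      hit_p <- learning_curve(params, s_idx)
    }
    w0 <- onset + config$delay
    w1 <- w0 + config$report_window

    ## --- designed response licking ---
    resp <- numeric(0)
    wants_lick <- if (free) {
      stats::runif(1) < params$free_lick_prob
    } else if (stim_i) {
      stats::runif(1) < hit_p
    } else FALSE
    if (wants_lick) {
      rt <- draw_reaction_time(params, config$report_window)
      if (config$delay > 0) {
        ## anticipatory licking through the delay period into the window
        resp <- lick_train(onset + rt, w0 + 0.8 * rt,
                           params$intra_bout_lick_freq)
      } else {
        resp <- onset + rt
      }
    }

    ## --- spontaneous bouts up to the window end ---
    ## a salient whisker deflection transiently interrupts spontaneous lick
    ## initiation (orienting response); stimulus-triggered responses and
    ## no-stimulus trials are unaffected
    spont <- numeric(0)
    supp_end <- if (stim_i) onset + params$post_stim_suppression else onset
    while (t_spont < w1) {
      if (stim_i && t_spont >= onset && t_spont < supp_end) {
        t_spont <- next_exp(supp_end)
        next
      }
      bout <- gen_bout(t_spont, draw_bout_len(params, rewarded = FALSE),
                       params$intra_bout_lick_freq)
      spont <- c(spont, bout)
      t_spont <- next_exp(bout[length(bout)] + 1 / params$intra_bout_lick_freq)
    }
    pre <- dedupe_licks(sort(c(resp, spont)))
    f <- first_lick_in_window(pre, w0, w1)

    rewarded <- FALSE; reward_time <- NA_real_; sense_time <- NA_real_
    last_act <- w1
    if (!is.na(f)) {
      rewarded <- switch(config$task_kind,
        free_licking = stats::runif(1) < config$reward_prob_on_lick,
        whisker_detection = stim_i,
        delayed_reward = stim_i,
        reward_omission = stim_i &&
          (i <= config$warmup_trials ||
           stats::runif(1) >= config$omission_prob))
      len <- draw_bout_len(params, rewarded = rewarded)
      bout <- gen_bout(f, len, params$intra_bout_lick_freq)
      add_licks(c(pre[pre < f], bout))
      if (rewarded) {
        reward_time <- f
        valve_times <- c(valve_times, f)
        sense_time <- bout[2]
      }
      last_act <- bout[length(bout)]
    } else {
      add_licks(pre)
      if (length(pre)) last_act <- max(w1, pre[length(pre)])
    }

    type <- classify_trial(config$task_kind, stim_i, !is.na(f), rewarded)
    rec[[i]] <- list(onset_time = onset, stim = stim_i, type = type,
                     first_report_lick_time = f, reward_time = reward_time,
                     reward_sense_time = sense_time, rewarded = rewarded,
                     stim_index = s_idx, hit_p = hit_p)
    t_cursor <- max(w1, last_act) + 0.2
    if (t_spont < t_cursor) t_spont <- next_exp(t_cursor)
  }

  trials <- do.call(rbind, lapply(rec, function(r)
    data.frame(r[setdiff(names(r), character(0))],
               stringsAsFactors = FALSE)))
  trials$trial_all <- seq_len(n)
  keep <- !is.na(trials$type)
  trials <- trials[keep, , drop = FALSE]
  trials$trial <- seq_len(nrow(trials))

  ## satiety state: exponential in the number of rewards consumed so far
  n_rew_before <- cumsum(c(0, utils::head(as.integer(trials$rewarded), -1)))
  trials$satiety_factor <- exp(-n_rew_before / params$satiety_tau)

  lick_times <- dedupe_licks(sort(unlist(licks[seq_len(li)])))
  session_t_end <- t_cursor + 1

  events <- structure(list(
    lick_times = lick_times, stim_times = stim_times,
    valve_times = sort(valve_times), trial_start_times = trial_start,
    abort_times = abort_times, session_t_end = session_t_end,
    piezo = NULL, fs_piezo = 1000), class = "photolick_events")

  trials$aborted_attempt_count <- count_aborts(abort_times, trials$onset_time)
  rownames(trials) <- NULL
  cols <- c("trial", "onset_time", "stim", "type", "first_report_lick_time",
            "reward_time", "reward_sense_time", "rewarded",
            "aborted_attempt_count", "stim_index", "hit_p", "satiety_factor")
  trials <- trials[, cols]
  class(trials) <- c("photolick_trials", "data.frame")
  list(events = events, trials = trials)
}

## stimulus / no-stimulus sequence with bounded runs; the reward-omission
## warm-up block is exactly balanced (25/25 by default)
make_stim_sequence <- function(config) {
  n <- config$n_trials
  maxrun <- config$max_consecutive_same_type
  if (config$task_kind == "free_licking") return(rep(FALSE, n))
  draw_tail <- function(n_tail, run0, last0) {
    out <- logical(n_tail); run <- run0; last <- last0
    for (j in seq_len(n_tail)) {
      s <- if (!is.na(last) && run >= maxrun) !last
           else stats::runif(1) < config$stim_trial_fraction
      run <- if (!is.na(last) && s == last) run + 1L else 1L
      last <- s; out[j] <- s
    }
    out
  }
  if (config$task_kind == "reward_omission" && config$warmup_trials > 0) {
    nw <- min(config$warmup_trials, n)
    n_stim_w <- floor(nw / 2)
    repeat {  # rejection sampling of a balanced warm-up respecting run limit
      w <- sample(c(rep(TRUE, n_stim_w), rep(FALSE, nw - n_stim_w)))
      r <- rle(w)
      if (max(r$lengths) <= maxrun) break
    }
    r <- rle(w)
    tail_part <- draw_tail(n - nw, r$lengths[length(r$lengths)],
                           r$values[length(r$values)])
    return(c(w, tail_part))
  }
  draw_tail(n, 0L, NA)
}

draw_bout_len <- function(params, rewarded) {
  if (rewarded) max(2L, stats::rpois(1, params$bout_length_rewarded_mean))
  else max(1L, stats::rpois(1, params$bout_length_unrewarded_mean))
}

## rhythmic lick bout: n licks at ~freq Hz with jittered inter-lick intervals
gen_bout <- function(t0, n_licks, freq) {
  if (n_licks == 1L) return(t0)
  gaps <- pmax(0.06, (1 / freq) * (1 + 0.1 * stats::rnorm(n_licks - 1)))
  t0 + c(0, cumsum(gaps))
}

## regular lick train from t0 until at least t_end (used for delay-period licking)
lick_train <- function(t0, t_end, freq) {
  out <- t0
  while (out[length(out)] < t_end) {
    out <- c(out, out[length(out)] +
               max(0.06, (1 / freq) * (1 + 0.1 * stats::rnorm(1))))
  }
  out
}

## reaction times below ~200 ms are not physiological for whisker-detection
## licking; the floor also keeps the reward kernel (anchored at the second
## lick) causally outside the 0.1-0.3 s early sensory window
draw_reaction_time <- function(params, report_window) {
  rt <- stats::rlnorm(1, params$rt_meanlog, params$rt_sdlog)
  min(max(rt, params$rt_min), 0.9 * report_window)
}

## collapse near-coincident lick times (physically one tongue protrusion)
dedupe_licks <- function(x, min_gap = 0.04) {
  if (length(x) < 2) return(x)
  keep <- c(TRUE, diff(x) >= min_gap)
  while (!all(keep)) {
    x <- x[keep]
    if (length(x) < 2) break
    keep <- c(TRUE, diff(x) >= min_gap)
  }
  x
}

## first lick inside the half-open reporting window [w0, w1)
first_lick_in_window <- function(licks, w0, w1) {
  hit <- licks[licks >= w0 - 1e-9 & licks < w1 - 1e-9]
  if (length(hit)) hit[1] else NA_real_
}

## trial label; NA marks free-licking windows without a lick (not a trial of
## interest, dropped from the trial table)
classify_trial <- function(task_kind, stim, licked, rewarded) {
  if (task_kind == "free_licking") {
    if (!licked) return(NA_character_)
    return(if (rewarded) "RewardedLick" else "UnrewardedLick")
  }
  if (stim) {
    if (!licked) return("Miss")
    if (task_kind == "reward_omission")
      return(if (rewarded) "HitPlus" else "HitMinus")
    return("Hit")
  }
  if (licked) "FA" else "CR"
}

## abort events are attributed to the next completed trial onset at or after
## them; both the simulator and the parser use this partition
count_aborts <- function(abort_times, onsets) {
  if (!length(onsets)) return(integer(0))
  idx <- findInterval(abort_times, onsets, left.open = TRUE) + 1L
  idx[idx > length(onsets)] <- length(onsets)
  tabulate(idx, nbins = length(onsets))
}
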