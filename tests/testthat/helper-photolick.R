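# shared fixtures and independent oracles

# brute-force two-sided signed-rank p by enumerating all 2^n sign assignments;
# independent of the package's generating-function implementation
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# small whisker-detection session reused across tests
small_session <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- task_config("whisker_detection", n_trials = 40)
      memo <<- simulate_session(cfg, behavior_params(), photometry_truth(),
                                seed = 101, include_piezo = FALSE)
    }
    memo
  }
})

# hand-built events object for parser unit tests
manual_events <- function(licks, stims, valves, starts,
                          aborts = numeric(0), t_end = NULL) {
  if (is.null(t_end)) t_end <- max(c(licks, stims, valves, starts, 0)) + 5
  structure(list(lick_times = licks, stim_times = stims, valve_times = valves,
                 trial_start_times = starts, abort_times = aborts,
                 session_t_end = t_end, piezo = NULL, fs_piezo = 1000),
            class = "photolick_events")
}
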