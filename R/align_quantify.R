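#' Extract event-aligned epochs from a 1 kHz trace
#'
#' Builds the trials-by-lags matrix of signal values around each event on a
#' 1-ms lag grid; lag 0 is the sample at the event time. Events whose
#' `[-pre, post)` extent is not fully covered by the recording are dropped
#' and counted in the `dropped` field.
#'
#' @param z Numeric trace (z-scored dF/F0 or any 1 kHz signal).
#' @param event_times Event times, seconds.
#' @param pre,post Epoch extent before/after the event, seconds.
#' @param fs Sampling rate, Hz (must be 1000 for the 1-ms lag convention).
#' @param t0 Time of the first sample, seconds.
#' @return A `photolick_epochs` object: `values` (matrix, one row per kept
#'   event), `lag_ms` (integer lags), `event_times`, `dropped`.
#' @export
extract_epochs <- function(z, event_times, pre, post, fs = 1000, t0 = 0) {
  stopifnot(fs == 1000, pre >= 0, post > 0)
  n <- length(z)
  lag_ms <- seq.int(-round(pre * 1000), round(post * 1000) - 1L)
  idx0 <- round((event_times - t0) * 1000) + 1L
  ok <- idx0 + lag_ms[1] >= 1L & idx0 + lag_ms[length(lag_ms)] <= n
  dropped <- sum(!ok)
  if (!any(ok)) stop("no events with full epoch coverage")
  idx0 <- idx0[ok]
  mat <- matrix(z[rep(idx0, each = length(lag_ms)) + lag_ms],
                nrow = length(idx0), byrow = TRUE)
  structure(list(values = mat, lag_ms = lag_ms,
                 event_times = event_times[ok], dropped = dropped),
            class = "photolick_epochs")
}

#' Registry of quantification windows
#'
#' The named response/baseline window pairs used throughout the analyses
#' (all times in seconds relative to the align event, half-open `[start,
#' end)` on the 1-ms grid):
#'
#' * `lick_post_0_1`, `lick_post_1_2`: 0-1 s and 1-2 s after lick onset vs a
#'   baseline 1-0.5 s before (rewarded vs unrewarded licking).
#' * `lick_peak`: 0.3-0.5 s after the first tongue-spout contact vs
#'   0.2-0 s before (peak of the reward response). `lick_peak_alt` is the
#'   0.2-0.4 s variant that appears alongside it; the 0.3-0.5 s window is
#'   the default for satiety analyses.
#' * `stim_post_0_1`, `stim_post_1_2`: 0-1 s and 1-2 s after the whisker
#'   stimulus vs 0.5-0 s before.
#' * `stim_early`, `stim_late`: 0.1-0.3 s and 0.5-1.0 s post-stimulus vs
#'   0.2-0 s before (sensory response across learning).
#' * `prelick`, `lick_reward_peak`: 0.1-0 s before and 0.3-0.5 s after lick
#'   onset vs a 1.0-0.5 s pre-lick baseline.
#'
#' @return data.frame with columns `name`, `align`, `resp_start`,
#'   `resp_end`, `base_start`, `base_end`.
#' @export
window_registry <- function() {
  w <- function(name, align, rs, re, bs, be)
    data.frame(name = name, align = align, resp_start = rs, resp_end = re,
               base_start = bs, base_end = be, stringsAsFactors = FALSE)
  rbind(
    w("lick_post_0_1",   "first_report_lick", 0.0, 1.0, -1.0, -0.5),
    w("lick_post_1_2",   "first_report_lick", 1.0, 2.0, -1.0, -0.5),
    w("lick_peak",       "first_report_lick", 0.3, 0.5, -0.2,  0.0),
    w("lick_peak_alt",   "first_report_lick", 0.2, 0.4, -0.2,  0.0),
    w("stim_post_0_1",   "whisker_stim",      0.0, 1.0, -0.5,  0.0),
    w("stim_post_1_2",   "whisker_stim",      1.0, 2.0, -0.5,  0.0),
    w("stim_early",      "whisker_stim",      0.1, 0.3, -0.2,  0.0),
    w("stim_late",       "whisker_stim",      0.5, 1.0, -0.2,  0.0),
    w("prelick",         "first_report_lick", -0.1, 0.0, -1.0, -0.5),
    w("lick_reward_peak", "first_report_lick", 0.3, 0.5, -1.0, -0.5))
}

#' Baseline-referenced window quantification
#'
#' Per-trial scalar: mean of the epoch over the half-open response window
#' minus the mean over the baseline window. Adding a constant to the whole
#' epoch leaves the value unchanged.
#'
#' @param epochs `photolick_epochs` object.
#' @param spec One row of [window_registry()] (or a list with `resp_start`,
#'   `resp_end`, `base_start`, `base_end` in seconds), or a registry window
#'   name.
#' @return Numeric vector, one value per trial (epoch row).
#' @export
window_quant <- function(epochs, spec) {
  if (is.character(spec)) {
    reg <- window_registry()
    hit <- reg[reg$name == spec, ]
    if (!nrow(hit)) stop("unknown window name: ", spec)
    spec <- hit
  }
  sel <- function(a, b) {
    cols <- epochs$lag_ms >= round(a * 1000) & epochs$lag_ms < round(b * 1000)
    if (!any(cols)) stop("empty window [", a, ", ", b, ") after gridding")
    cols
  }
  rc <- sel(spec$resp_start, spec$resp_end)
  bc <- sel(spec$base_start, spec$base_end)
  rowMeans(epochs$values[, rc, drop = FALSE]) -
    rowMeans(epochs$values[, bc, drop = FALSE])
}

#' First-k versus last-k trial means
#'
#' Means over the first `k` and last `k` values in session order, used for
#' within-session satiety comparisons. With fewer than `2k` values both sets
#' are truncated to `floor(n/2)` trials (no overlap) and the result is
#' flagged via the `truncated_k` attribute.
#'
#' @param values Per-trial values in session order.
#' @param k Number of trials per end (default 15).
#' @return Named numeric vector `c(first, last)`.
#' @export
first_last_k <- function(values, k = 15) {
  n <- length(values)
  if (n == 0) stop("no trials")
  kk <- if (n >= 2 * k) k else floor(n / 2)
  if (kk == 0) stop("too few trials to form disjoint first/last sets")
  out <- c(first = mean(values[seq_len(kk)]),
           last = mean(values[seq.int(n - kk + 1L, n)]))
  if (kk < k) attr(out, "truncated_k") <- kk
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped
#' (standard convention). For `n <= exact_n` (default 25) the p-value is
#' exact, computed from the full distribution of the positive-rank sum over
#' all 2^n sign assignments via a generating-function convolution that
#' handles tied ranks exactly; for larger n a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Equal-length paired samples.
#' @param exact_n Largest n for which the exact distribution is enumerated.
#' @return A list (`photolick_signedrank`): `p`, `statistic` (positive-rank
#'   sum W+), `n` (non-zero differences), `method`.
#' @export
paired_signed_rank <- function(x, y, exact_n = 25) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_n) {
    ## exact null distribution of 2*W+ (doubling keeps tied half-ranks integer)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)  # counts[s+1] = #assignments with 2*W+ == s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    s_obs <- as.integer(round(2 * w_pos))
    p_lo <- sum(probs[seq_len(s_obs + 1)])
    p_hi <- sum(probs[seq.int(s_obs + 1, total + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w_pos - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  structure(list(p = p, statistic = w_pos, n = n, method = method),
            class = "photolick_signedrank")
}

#' Per-trial window values for one session
#'
#' Full path from a preprocessed session to per-trial quantifications:
#' selects trials, aligns epochs to the requested event and applies a
#' registry window.
#'
#' @param prep `photolick_dff` from [preprocess_session()].
#' @param trials Trial table (latent or parsed).
#' @param window Registry window name (see [window_registry()]).
#' @param types Trial types to include (default: all).
#' @param pre,post Epoch extent, seconds.
#' @return data.frame with `trial`, `type`, `value` for each quantified
#'   trial; attribute `dropped` counts events without epoch coverage.
#' @export
quantify_trials <- function(prep, trials, window, types = NULL,
                            pre = 2, post = 3) {
  reg <- window_registry()
  spec <- reg[reg$name == window, ]
  if (!nrow(spec)) stop("unknown window name: ", window)
  sub <- if (is.null(types)) trials else trials[trials$type %in% types, ]
  ev <- if (spec$align == "whisker_stim") {
    sub <- sub[sub$stim, , drop = FALSE]
    sub$onset_time
  } else {
    sub <- sub[!is.na(sub$first_report_lick_time), , drop = FALSE]
    sub$first_report_lick_time
  }
  if (!length(ev)) stop("no trials with the required align event")
  ep <- extract_epochs(prep$z, ev, pre = pre, post = post,
                       fs = prep$fs, t0 = prep$t0)
  kept <- which(ev %in% ep$event_times)
  out <- data.frame(trial = sub$trial[kept], type = sub$type[kept],
                    value = window_quant(ep, spec),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- ep$dropped
  out
}
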