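#' Block-averaged within-session learning series
#'
#' Averages per-trial values (early sensory dLight response) and the Hit
#' indicator in non-overlapping blocks of consecutive whisker-stimulus
#' trials: 51 trials in blocks of 3 give 17 blocks. The block x-coordinate
#' is the center trial index of the block (2, 5, ..., 50).
#'
#' @param values Per-whisker-trial dLight values (session order).
#' @param hits Logical/0-1 Hit indicator per whisker trial.
#' @param block Block size in trials (default 3).
#' @param n_trials Number of leading whisker trials analyzed (default 51).
#' @return A `photolick_blocks` data.frame: `block`, `center_trial`,
#'   `mean_dlight`, `hit_rate`.
#' @export
block_series <- function(values, hits, block = 3, n_trials = 51) {
  if (length(values) < n_trials || length(hits) < n_trials)
    stop("need at least ", n_trials, " whisker trials (have ",
         min(length(values), length(hits)), "); session not analyzable")
  if (n_trials %% block != 0)
    stop("n_trials (", n_trials, ") must be divisible by block (", block, ")")
  v <- values[seq_len(n_trials)]
  h <- as.numeric(hits[seq_len(n_trials)])
  if (any(!h %in% c(0, 1))) stop("hits must be a 0/1 or logical indicator")
  grp <- rep(seq_len(n_trials / block), each = block)
  out <- data.frame(
    block = seq_len(n_trials / block),
    center_trial = tapply(seq_len(n_trials), grp, mean),
    mean_dlight = as.numeric(tapply(v, grp, mean)),
    hit_rate = as.numeric(tapply(h, grp, mean)))
  class(out) <- c("photolick_blocks", "data.frame")
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, neither constant.
#' @return A list `(r, p, n)`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Learning slope from a block series
#'
#' Ordinary least-squares slope of the block means against the block-center
#' trial index, in value units per trial.
#'
#' @param blocks A `photolick_blocks` data.frame.
#' @param what Which block quantity to regress (`"mean_dlight"` or
#'   `"hit_rate"`).
#' @return Slope (numeric scalar).
#' @export
learning_slope <- function(blocks, what = c("mean_dlight", "hit_rate")) {
  what <- match.arg(what)
  if (nrow(blocks) < 2) stop("need at least 2 blocks")
  unname(stats::coef(stats::lm(blocks[[what]] ~ blocks$center_trial))[2])
}

#' Flag sessions with significant within-session learning
#'
#' A session is a "learner" when the Pearson correlation of the per-trial
#' Hit indicator against trial number over the first `n_trials` whisker
#' trials is positive with p < 0.05. A constant hit pattern has no defined
#' correlation and returns `NA` (not evaluable), as does a session with too
#' few whisker trials.
#'
#' @param hits Hit indicator per whisker trial (session order).
#' @param n_trials Number of leading whisker trials tested (default 51).
#' @param alpha Significance level (default 0.05).
#' @return `TRUE`, `FALSE`, or `NA` (not evaluable).
#' @export
select_learners <- function(hits, n_trials = 51, alpha = 0.05) {
  if (length(hits) < n_trials) return(NA)
  h <- as.numeric(hits[seq_len(n_trials)])
  if (stats::sd(h) == 0) return(NA)
  pw <- pearson_with_p(seq_len(n_trials), h)
  isTRUE(pw$p < alpha && pw$r > 0)
}

#' Pairwise across-day comparisons with Bonferroni correction
#'
#' Paired signed-rank tests between all day pairs of a per-mouse value
#' (e.g. the early sensory window amplitude), with the Bonferroni-corrected
#' significance threshold `alpha / n_pairs` (0.05 / 3 = 0.0167 for three
#' days). Mice missing a value on either day of a pair are dropped from
#' that pair and counted in `n_dropped`.
#'
#' @param day_values Matrix or data.frame, mice in rows, days in columns.
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame with one row per day pair: `day_a`, `day_b`, `p`,
#'   `n`, `n_dropped`, `significant`; attribute `threshold` holds the
#'   corrected level.
#' @export
day_comparisons <- function(day_values, alpha = 0.05) {
  m <- as.matrix(day_values)
  nd <- ncol(m)
  if (nd < 2) stop("need at least two days")
  pairs <- utils::combn(nd, 2)
  thr <- alpha / ncol(pairs)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ok <- stats::complete.cases(m[, c(a, b)])
    ## identical day values carry no evidence of a difference: p = 1
    res <- if (all(m[ok, a] == m[ok, b])) list(p = 1, n = 0L)
           else paired_signed_rank(m[ok, a], m[ok, b])
    data.frame(day_a = a, day_b = b, p = res$p, n = res$n,
               n_dropped = sum(!ok), significant = res$p < thr)
  })
  out <- do.call(rbind, out)
  attr(out, "threshold") <- thr
  out
}

#' Within-session learning analysis of one simulated session
#'
#' Runs the full path for one whisker-detection session: preprocess, align
#' to the whisker stimulus, quantify the early sensory window per whisker
#' trial, build the 3-trial block series over the first 51 whisker trials
#' and return both slopes plus the block data.
#'
#' @param session A `photolick_session` from [simulate_session()].
#' @param n_trials,block Passed to [block_series()].
#' @param window Registry window for the sensory response (default
#'   `"stim_early"`).
#' @return List: `blocks`, `dlight_slope`, `hit_slope`, `learner`,
#'   `r_dlight` (block dLight vs trial-number correlation), `r_hit`.
#' @export
session_learning_analysis <- function(session, n_trials = 51, block = 3,
                                      window = "stim_early") {
  prep <- preprocess_session(session$traces, session$trials)
  stim_trials <- session$trials[session$trials$stim, , drop = FALSE]
  q <- quantify_trials(prep, stim_trials, window, pre = 1, post = 2)
  ## align quantified values back to whisker-trial order
  vals <- q$value[match(stim_trials$trial, q$trial)]
  hits <- stim_trials$type %in% c("Hit", "HitPlus", "HitMinus")
  ok <- !is.na(vals)
  vals <- vals[ok]; hits <- hits[ok]
  blocks <- block_series(vals, hits, block = block, n_trials = n_trials)
  list(blocks = blocks,
       dlight_slope = learning_slope(blocks, "mean_dlight"),
       hit_slope = learning_slope(blocks, "hit_rate"),
       learner = select_learners(hits, n_trials),
       r_dlight = pearson_with_p(blocks$center_trial, blocks$mean_dlight)$r,
       r_hit = if (stats::sd(blocks$hit_rate) > 0)
         pearson_with_p(blocks$center_trial, blocks$hit_rate)$r else NA_real_)
}

#' Simulate a cohort of whisker-detection sessions for learning analyses
#'
#' Each session draws its own learning-curve parameters (midpoint, floor
#' and ceiling hit probabilities) to model across-mouse heterogeneity, then
#' runs [session_learning_analysis()]. With
#' `couple = TRUE` the sensory kernel amplitude follows the session's
#' learning curve (the generative coupling between sensory dopamine and
#' performance); with `couple = FALSE` the amplitude is constant, the
#' switch-off control.
#'
#' @param n_sessions Number of sessions.
#' @param seed Integer seed.
#' @param couple Couple sensory amplitude to the learning curve?
#' @param truth Baseline [photometry_truth()]; its
#'   `couple_sensory_to_learning` flag is overridden by `couple`.
#' @param n_trials_session Trials per session (default 120 gives ~60 whisker
#'   trials). Sessions that end up with fewer than 51 whisker trials are not
#'   analyzable and are replaced by a freshly seeded session (the standard
#'   exclusion rule for short sessions).
#' @return data.frame with one row per session: `session`, `dlight_slope`,
#'   `hit_slope`, `learner`, `r_dlight`, `r_hit`, plus pooled blocks in the
#'   `blocks` attribute.
#' @export
simulate_learning_cohort <- function(n_sessions, seed, couple = TRUE,
                                     truth = photometry_truth(),
                                     n_trials_session = 120) {
  set.seed(as.integer(seed))
  n_pool <- 2L * n_sessions + 10L
  session_seeds <- sample.int(2^30, n_pool)
  ## across-mouse heterogeneity: every session learns (midpoint inside the
  ## analyzed 51 trials, sizable p range) but learning speed and extent vary
  mids <- stats::runif(n_pool, 18, 32)
  p0s <- stats::runif(n_pool, 0.08, 0.2)
  pmaxs <- stats::runif(n_pool, 0.75, 0.95)
  steeps <- stats::runif(n_pool, 5, 10)
  truth$couple_sensory_to_learning <- couple
  cfg <- task_config("whisker_detection", n_trials = n_trials_session)
  rows <- vector("list", n_sessions)
  pooled <- vector("list", n_sessions)
  s <- 0L
  for (k in seq_len(n_pool)) {
    if (s >= n_sessions) break
    par <- behavior_params(learning_midpoint = mids[k], learning_p0 = p0s[k],
                           learning_pmax = pmaxs[k],
                           learning_steepness = steeps[k])
    ses <- simulate_session(cfg, par, truth, seed = session_seeds[k],
                            include_piezo = FALSE)
    if (sum(ses$trials$stim) < 51) next  # short session: excluded
    s <- s + 1L
    an <- session_learning_analysis(ses)
    rows[[s]] <- data.frame(session = s, dlight_slope = an$dlight_slope,
                            hit_slope = an$hit_slope,
                            learner = isTRUE(an$learner),
                            r_dlight = an$r_dlight, r_hit = an$r_hit)
    pooled[[s]] <- cbind(session = s, an$blocks)
  }
  if (s < n_sessions)
    stop("could not assemble ", n_sessions, " analyzable sessions")
  out <- do.call(rbind, rows)
  attr(out, "blocks") <- do.call(rbind, pooled)
  out
}
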