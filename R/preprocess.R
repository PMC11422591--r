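#' Least-squares fit of the isosbestic channel to the signal channel
#'
#' Fits `f465 ~ a * f405 + b` over the whole session by ordinary least
#' squares. The fitted 405 trace captures photobleaching and shared motion
#' artifacts while being blind to dopamine, and serves as the F0 baseline
#' for dF/F0. An intercept is included because detector offsets differ
#' between channels; the fit absorbs any common gain applied to both
#' channels.
#'
#' @param f465,f405 Equal-length numeric traces on the 1 kHz clock.
#' @return A list `(a, b, fitted405)`.
#' @export
fit_isosbestic <- function(f465, f405) {
  if (length(f465) != length(f405)) stop("traces must have equal length")
  if (length(f465) < 2) stop("need at least 2 samples")
  if (!is.finite(sum(f465)) || !is.finite(sum(f405)))
    stop("traces must be finite")
  v <- stats::var(f405)
  if (v == 0) stop("degenerate fit: f405 is constant")
  a <- stats::cov(f405, f465) / v
  b <- mean(f465) - a * mean(f405)
  fitted405 <- a * f405 + b
  if (min(fitted405) <= 0) {
    bad <- which(fitted405 <= 0)
    stop("fitted 405 baseline is non-positive at sample ", bad[1],
         " (and ", length(bad) - 1L, " more); dF/F0 undefined")
  }
  list(a = a, b = b, fitted405 = fitted405)
}

#' Fractional fluorescence change dF/F0
#'
#' `dF/F0 = (F465 - fitted405) / fitted405`, the fractional change of the
#' dopamine-sensitive channel relative to the fitted isosbestic baseline.
#'
#' @param f465 Signal-channel trace.
#' @param fitted405 Fitted isosbestic baseline from [fit_isosbestic()];
#'   must be strictly positive.
#' @return Numeric dF/F0 trace (dimensionless).
#' @export
compute_dff <- function(f465, fitted405) {
  if (length(f465) != length(fitted405)) stop("traces must have equal length")
  if (any(fitted405 <= 0)) stop("fitted405 must be strictly positive")
  (f465 - fitted405) / fitted405
}

#' Per-mouse z-normalization factor from trial-averaged traces
#'
#' One scalar per mouse: the standard deviation of all samples of the
#' concatenated trial-averaged dF/F0 traces across trial types and tasks.
#' Dividing dF/F0 by this factor yields the z-scored signal used for all
#' quantifications, putting every session of a mouse on a common scale.
#'
#' @param trial_averaged_traces Named list of numeric trial-averaged dF/F0
#'   traces (one per trial type/task combination).
#' @return A list `(sigma, provenance)` of class `photolick_norm`.
#' @export
compute_norm_factor <- function(trial_averaged_traces) {
  if (!length(trial_averaged_traces)) stop("need at least one trial-averaged trace")
  if (any(!vapply(trial_averaged_traces, length, 1L)))
    stop("trial-averaged traces must be non-empty")
  allv <- unlist(trial_averaged_traces, use.names = FALSE)
  sigma <- stats::sd(allv)
  if (!is.finite(sigma) || sigma == 0)
    stop("normalization sigma is zero or undefined")
  prov <- names(trial_averaged_traces)
  if (is.null(prov)) prov <- paste0("trace_", seq_along(trial_averaged_traces))
  structure(list(sigma = sigma, provenance = prov), class = "photolick_norm")
}

#' Apply the z-normalization factor
#'
#' @param dff Numeric dF/F0 trace.
#' @param factor A `photolick_norm` object (or positive scalar).
#' @return z-scored trace `dff / sigma`.
#' @export
apply_zscore <- function(dff, factor) {
  sigma <- if (inherits(factor, "photolick_norm")) factor$sigma else factor
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  dff / sigma
}

#' Full preprocessing of channel traces into a z-scored dF/F0 trace
#'
#' Chains [fit_isosbestic()], [compute_dff()], and (given a trial table for
#' the session) computes trial-averaged traces per trial type to derive the
#' normalization factor via [compute_norm_factor()].
#'
#' @param traces `photolick_traces` object.
#' @param trials Trial table used to build the per-type trial averages for
#'   normalization (alignment: stimulus time for stimulus trials, first
#'   report lick otherwise).
#' @param norm Optional pre-computed `photolick_norm` (e.g. the per-mouse
#'   factor from other sessions); if `NULL` it is computed from this session.
#' @param pre,post Epoch extent (s) for the normalization trial averages.
#' @return List `(dff, z, fit, norm)` of class `photolick_dff`.
#' @export
preprocess_session <- function(traces, trials, norm = NULL,
                               pre = 1, post = 2) {
  fit <- fit_isosbestic(traces$f465, traces$f405)
  dff <- compute_dff(traces$f465, fit$fitted405)
  if (is.null(norm)) {
    tavg <- list()
    for (ty in unique(trials$type)) {
      sub <- trials[trials$type == ty, ]
      ev <- ifelse(sub$stim, sub$onset_time, sub$first_report_lick_time)
      ev <- ev[!is.na(ev)]
      if (!length(ev)) next
      ep <- try(extract_epochs(dff, ev, pre = pre, post = post,
                               fs = traces$fs, t0 = traces$t0), silent = TRUE)
      if (!inherits(ep, "try-error")) tavg[[ty]] <- colMeans(ep$values)
    }
    norm <- compute_norm_factor(tavg)
  }
  structure(list(dff = dff, z = apply_zscore(dff, norm), fit = fit,
                 norm = norm, fs = traces$fs, t0 = traces$t0),
            class = "photolick_dff")
}
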