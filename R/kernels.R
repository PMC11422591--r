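#' Double-exponential dopamine transient kernel
#'
#' Canonical shape of a phasic dopamine transient as reported by fluorescent
#' dopamine sensors: a fast rise followed by a slower decay,
#' \eqn{k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}} for \eqn{t \ge 0},
#' normalized so that the peak value equals `amp`. The kernel is causal
#' (identically zero for negative times) and continuous.
#'
#' The peak occurs at
#' \eqn{t^* = \tau_r \tau_d / (\tau_d - \tau_r) \cdot \log(\tau_d/\tau_r)}.
#'
#' @param t_rel Numeric vector of times in seconds relative to the anchoring
#'   event (e.g. tongue-spout contact).
#' @param amp Peak amplitude; the sign of the output equals the sign of `amp`
#'   (negative amplitudes model dopamine dips).
#' @param tau_rise Rise time constant in seconds; must be `< tau_decay`.
#' @param tau_decay Decay time constant in seconds.
#' @return Numeric vector of kernel values, same length as `t_rel`.
#' @examples
#' dopamine_kernel(seq(0, 2, 0.001), amp = 1, tau_rise = 0.2, tau_decay = 1)
#' @export
dopamine_kernel <- function(t_rel, amp, tau_rise, tau_decay) {
  stopifnot(is.numeric(t_rel), is.numeric(amp), length(amp) == 1L)
  if (!(tau_rise > 0 && tau_decay > 0)) stop("time constants must be positive")
  if (tau_rise >= tau_decay) stop("tau_rise must be strictly less than tau_decay")
  out <- numeric(length(t_rel))
  pos <- t_rel >= 0
  tp <- t_rel[pos]
  norm <- kernel_peak_norm(tau_rise, tau_decay)
  out[pos] <- amp * (exp(-tp / tau_decay) - exp(-tp / tau_rise)) / norm
  out
}

#' Time of the kernel peak
#'
#' @inheritParams dopamine_kernel
#' @return Peak time in seconds after the anchoring event.
#' @export
kernel_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise >= tau_decay) stop("tau_rise must be strictly less than tau_decay")
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# un-normalized kernel value at the peak; divides the raw difference of
# exponentials so that the peak equals amp exactly
kernel_peak_norm <- function(tau_rise, tau_decay) {
  ts <- kernel_peak_time(tau_rise, tau_decay)
  exp(-ts / tau_decay) - exp(-ts / tau_rise)
}

#' Analytic mean of the kernel over a half-open time window
#'
#' Closed-form integral of [dopamine_kernel()] averaged over `[a, b)`,
#' used as the reference value for window quantifications on synthetic
#' epochs. Portions of the window at negative times contribute zero.
#'
#' @inheritParams dopamine_kernel
#' @param a,b Window bounds in seconds relative to the kernel anchor, `a < b`.
#' @return The exact window-averaged kernel value.
#' @export
kernel_window_mean <- function(a, b, amp, tau_rise, tau_decay) {
  stopifnot(a < b)
  norm <- kernel_peak_norm(tau_rise, tau_decay)
  lo <- max(a, 0)
  hi <- max(b, 0)
  if (hi <= lo) return(0)
  ig <- function(tau) tau * (exp(-lo / tau) - exp(-hi / tau))
  amp * (ig(tau_decay) - ig(tau_rise)) / norm / (b - a)
}
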