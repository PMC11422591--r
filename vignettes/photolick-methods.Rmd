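---
title: "Models and methods behind photolick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photolick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolick)
```

# Scope

`photolick` analyzes two-wavelength fiber-photometry recordings of a
fluorescent dopamine sensor (e.g. dLight) made while a head-fixed, water-
restricted mouse licks a reward spout under four reward contingencies:
free licking, whisker detection, delayed reward, and reward omission. The
pipeline runs from the raw carrier-modulated detector voltage to
learning-dynamics statistics. Because cohort-level effect sizes depend on
real animals, every stage is validated instead on synthetic sessions with
known ground truth, generated by the package's own simulator. This
vignette documents the models, the defaults and why they were chosen, the
numerical conventions, and what the synthetic validation does and does not
establish about real recordings.

# The acquisition model

Two LEDs excite the sensor at 465 nm (dopamine-sensitive) and 405 nm
(near the sensor's isosbestic point, dopamine-insensitive). Their
intensities are sinusoidally modulated at 208.616 Hz and 500.679 Hz and a
single photodetector records the summed emission. Because LED intensity
cannot be negative, the simulator uses the excitation waveform

$$e_i(t) = \tfrac12\,(1 + m \sin 2\pi f_i t), \qquad m \in (0, 1],$$

and the detector sees
$\mathrm{det}(t) = F_{465}(t)\,e_1(t) + F_{405}(t)\,e_2(t) + \text{offset}$,
sampled at 12,224 or 20,000 Hz (both supported acquisition rates).

**Demodulation.** `lockin_demodulate()` multiplies the record by
quadrature references at the carrier, low-passes both products with a
4th-order Butterworth filter applied forward and backward (zero phase, so
the reported group delay is 0), and returns
$\frac{4}{m}\sqrt{I^2+Q^2}$; the factor $4/m$ absorbs the $\tfrac12$ of
the excitation convention and the modulation depth. The default cutoff is
25 Hz: dopamine transients live below 10 Hz while the carriers sit at
208 Hz and above, and the cutoff must stay below half the minimum carrier
separation so cross-terms are rejected (violations are an error, not a
warning). Zero-phase filtering uses odd-reflection edge padding so that a
constant input passes through unchanged.

An independent reference estimator, `envelope_sinefit()`, fits quadrature
sinusoids at *both* carriers plus an intercept by least squares in
windows of one slow-carrier cycle. Both carriers must be modeled jointly
because they are not orthogonal over a fractional-cycle window. The two
estimators share no code path, which is what makes their agreement (to
within 1% RMS on band-limited envelopes) informative.

**Resampling.** `downsample_1khz()` applies an anti-alias low-pass
(400 Hz) when needed and interpolates onto an exact 1-ms grid, so
non-integer rate ratios such as 12,224 → 1,000 Hz land on uniform
timestamps. All downstream analysis runs on this 1 kHz clock.

# The fluorescence model

`render_fluorescence()` builds the two channels as

$$F_{465}(t) = B_{465}\,e^{-t/\tau_{b465}}\,(1 + s(t)) + B_{465}\,m(t) + \epsilon_{465}(t)$$
$$F_{405}(t) = B_{405}\,e^{-t/\tau_{b405}} + B_{405}\,c_{405}\,m(t) + \epsilon_{405}(t)$$

where $s(t)$ is the dopamine signal in fractional dF/F units, $m(t)$ a
shared low-frequency motion artifact, and $\epsilon$ white noise. This is
deliberately the simplest structure the isosbestic fit can cancel:
bleaching is mono-exponential per channel and the artifact is additive
and channel-shared up to a scale. The 405 channel carries no dopamine
kernels.

Dopamine transients are causal double exponentials,
$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, normalized so the peak
equals the amplitude parameter (`dopamine_kernel()`; the peak time
$t^* = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\ln\frac{\tau_d}{\tau_r}$ and the
analytic window mean in `kernel_window_mean()` are the closed-form
references used by the tests). Three kernel families are rendered:

* **Sensory** (default amplitude 1% dF/F, $\tau_r$ 20 ms, $\tau_d$
  150 ms), anchored at each whisker stimulus. When the learning coupling
  is on, the per-trial amplitude is proportional to the current hit
  probability — the sensory dopamine response grows as the
  stimulus–reward association is acquired.
* **Reward** (default 5% dF/F, $\tau_r$ 0.12 s, $\tau_d$ 1 s), anchored
  0.1 s (`reward_latency`) after the tongue meets the water. The valve
  opens at the first reporting-window lick, but the droplet only forms
  after the tongue retracts, so water is encountered on the *second*
  lick of the bout; with the ~10 Hz lick rhythm and the 0.1-s onset
  latency the rendered reward response peaks ≈0.5 s after the first
  tongue-spout contact and decays over ~1 s.
* **Dip** (default −1.5% dF/F, slower: $\tau_r$ 0.3 s, $\tau_d$ 1.5 s),
  anchored when an unrewarded bout discovers the absence of water.

Reward and dip amplitudes are scaled by the satiety state
$e^{-n_\text{rewards}/\tau_\text{satiety}}$ (default $\tau$ = 40 rewards),
modeling within-session devaluation as thirst is quenched.

Defaults for the baselines (1.0 and 0.8 V), bleach taus (3000 s each,
i.e. roughly half the fluorescence lost over a 40-minute session — faster
bleaching would push the late-session baseline below the noise floor,
which real usable sessions do not do), artifact RMS (0.5% of baseline),
and noise (0.3% of baseline per 1-kHz sample) were chosen once as
representative of usable head-fixed recordings and are all exposed as
parameters of `photometry_truth()`.

# The behavioral model

`simulate_behavior()` runs the task state machine forward in time:

* Trials are separated by an inter-trial interval (8–13 s; 0.5–0.6 s in
  free licking) plus a no-lick period (4.5–5.5 s; 3.5–4.5 s in free
  licking). Any lick inside the no-lick period aborts the pending onset
  and restarts the no-lick timer; each intruding bout is logged as one
  abort event. A configurable bound on abort retries turns pathological
  parameter choices (e.g. an extreme spontaneous lick rate) into an
  explicit error.
* Stimulus/no-stimulus identities are drawn with at most three
  consecutive repeats of the same type. The reward-omission warm-up is an
  exactly balanced 25/25 block (rejection-sampled to respect the run
  limit) in which every correct lick is rewarded; afterwards rewards on
  hits are delivered with probability 0.5.
* Spontaneous licking is a Poisson process of bout onsets (default
  0.2 bouts/s, giving a false-alarm probability of
  $1-e^{-0.2} \approx 0.18$ per 1-s window) with ~10 Hz jittered licks
  within a bout. Rewarded bouts are longer (mean 8 licks vs 3) because
  the animal consumes the droplet.
* The probability of responding to the whisker stimulus follows a
  logistic learning curve over the stimulus-trial index
  ($p_0 \to p_\text{max}$, midpoint and steepness configurable).
  Reaction times are log-normal with mode ≈0.3 s and a 0.2-s floor —
  whisker-detection lick latencies below ~200 ms are not physiological.
* A salient whisker deflection transiently interrupts spontaneous
  lick-bout *initiation* for 0.3 s (`post_stim_suppression`), an
  orienting response. Stimulus-triggered responses and no-stimulus
  trials are unaffected, so false-alarm rates are preserved. Without
  this, chance licks in the first ~200 ms of stimulus trials would place
  reward transients inside the 0.1–0.3 s sensory quantification window,
  coupling the measured "sensory" signal to the hit indicator even when
  the generative sensory-learning coupling is switched off — the
  synthetic ground truth would then no longer isolate the effect the
  learning analyses are designed to detect.

The simulator returns both the event streams (licks, stimuli, valve
openings, trial starts, aborts) and a latent trial table carrying the
generative truth per trial — label, event times, reward outcome, abort
count, hit probability, satiety factor — which is what the round-trip
tests compare against.

# Preprocessing and normalization

`fit_isosbestic()` regresses F465 on F405 over the whole session
(ordinary least squares with an intercept; detector offsets differ
between channels, and the fit absorbs any common gain). The session-wide
fit is deliberate: segmenting would let transients leak into the
baseline. dF/F0 is $(F_{465} - \widehat{F_{405}})/\widehat{F_{405}}$; a
non-positive fitted baseline anywhere is an error that names the first
offending sample rather than producing silent nonsense.

Each mouse gets a single normalization factor: the standard deviation of
all samples of the concatenated trial-averaged dF/F0 traces across trial
types and tasks (`compute_norm_factor()`). Dividing by it yields the
z-scored signal used by every quantification, and the factor's
provenance (which trial types and tasks entered it) is recorded. Whether
free-licking sessions should enter the per-mouse factor is left as a
choice of the provenance list the caller supplies; the session-level
helper defaults to all trial types of the session at hand.

# Trial parsing and performance

`parse_trials()` reconstructs completed trials from the event streams.
The reporting window is half-open, $[onset+\text{delay},\,
onset+\text{delay}+1\,\text{s})$ on the 1-ms grid: a lick exactly at the
window start counts, one at the end does not. Delay-period licks are
neither rewarded nor counted as report licks. Free-licking windows
without a lick are not trials of interest and are skipped; abort events
are attributed to the next completed trial. Every valve opening must
coincide with the first reporting-window lick of a rewarded trial —
anything else is a consistency error listing the orphan event times.
When trial-start events are absent the parser falls back to stimulus
trials only (no-stimulus onsets are drawn from random schedules and
cannot be reconstructed exactly from the remaining streams), with a
warning.

Performance metrics use the loglinear correction:
$d' = \Phi^{-1}\!\big(\frac{n_\text{hit}+0.5}{n_\text{stim}+1}\big) -
\Phi^{-1}\!\big(\frac{n_\text{FA}+0.5}{n_\text{nostim}+1}\big)$, which
keeps $d'$ finite at perfect or zero rates.

# Windows, satiety, and paired statistics

`window_registry()` holds the named response/baseline window pairs used
throughout (post-lick 0–1 s and 1–2 s vs −1 to −0.5 s; 0.3–0.5 s vs
−0.2–0 s; early sensory 0.1–0.3 s and late 0.5–1 s post-stimulus;
pre-lick −0.1–0 s and reward 0.3–0.5 s vs −1 to −0.5 s). All windows are
half-open on the 1-ms grid and the sample at the event time belongs to
lag 0. Two near-duplicate reward-peak windows circulate in practice
(0.3–0.5 s and 0.2–0.4 s after lick onset); the registry contains both
(`lick_peak`, `lick_peak_alt`) with 0.3–0.5 s as the default used by the
satiety analyses. `window_quant()` returns response-mean minus
baseline-mean per trial and is invariant to adding a constant to the
whole epoch. `first_last_k()` compares the first and last 15 trials of a
type; with fewer than 30 trials both sets truncate to disjoint halves
and the result is flagged.

`paired_signed_rank()` is the package's own implementation because the
contract requires exact two-sided p-values *including ties* for
$n \le 25$: the null distribution of the positive-rank sum is built by a
generating-function convolution over the (possibly tied, half-integer)
ranks, doubled to stay on an integer lattice. Zero differences are
dropped first (standard convention; all-zero input is a defined error).
Beyond $n = 25$ a normal approximation with tie and continuity
correction is used, matching `stats::wilcox.test` in that regime, while
the exact branch is validated against full $2^n$ enumeration in the
tests.

# Learning dynamics

Within-session learning uses the first 51 whisker trials in 17
non-overlapping blocks of 3 (`block_series()`); the block x-coordinate
is the center trial index (2, 5, …, 50), an explicit convention.
Slopes come from ordinary least squares of block means on that
coordinate; correlations from the Pearson $r$ with the $t$-transform
p-value. A session is a "learner" when the per-trial hit indicator
correlates positively with trial number at p < 0.05 (a constant hit
pattern has no defined correlation and is flagged not-evaluable).
Across-day comparisons run paired signed-rank tests on all day pairs at
the Bonferroni-corrected level $\alpha = 0.05/3 \approx 0.017$.
Sessions with fewer than 51 whisker trials are excluded from the
within-session analysis. Both the per-trial-indicator and block-rate
forms of the hit correlation are exposed.

`simulate_learning_cohort()` draws per-session learning parameters
(midpoint 18–32, floor 0.08–0.2, ceiling 0.75–0.95, steepness 5–10) to
model across-mouse heterogeneity — every simulated session learns, but
at different speeds and to different extents, which is what makes the
across-session slope correlation informative. With the coupling switch
off, the sensory amplitude is constant and the dLight-slope /
hit-slope correlation is centered at zero (verified over 800 switch-off
sessions during development).

# Problem sizes and numerical conventions

The validation suite runs on: 60-s two-carrier records at both
acquisition rates for demodulation; 10-minute sessions with bleach
$\tau$ = 600 s and transient amplitudes of 1, 5, and 10% dF/F for
dF/F0 recovery; 100 seeded sessions spanning all four tasks for
trial-parsing exactness; cohorts of 50 (coupled) and 4 × 100
(switch-off) sessions of ~120 trials for the learning analysis; and
100 + 100 free-licking sessions of 90 trials for the satiety contrast.
These sizes give the Monte-Carlo rates comfortable margins over their
binomial noise while keeping the whole suite inside a coffee break.

Times are double-precision seconds from session start. Epoch extraction
maps an event to its 1-ms sample by rounding; events without full
epoch coverage are dropped and counted. Event-stream comparisons use a
1 µs tolerance so that delimited-text round-trips of event tables remain
exact; the binary trace container (feather) round-trips doubles
bit-for-bit. All randomness flows through explicit integer seeds; the
simulator has no hidden global state beyond the seed it is handed, and
identical seeds give byte-identical pipeline outputs.

# What the synthetic validation does and does not show

The generator reproduces the statistical structure the analysis assumes:
carrier-modulated acquisition, shared-artifact isosbestic geometry,
task state machines with aborts and warm-ups, learning-coupled sensory
amplitudes, and satiety-scaled reward responses. Passing tests therefore
establish that the pipeline recovers known ground truth under that
structure — they do not establish that real recordings satisfy it. In
particular the simulator has no hemodynamic contamination, no
wavelength-dependent artifact shape (the artifact is exactly
channel-shared up to a scale, the most favorable case for the isosbestic
fit), mono-exponential bleaching only, no whisker-movement or body-
movement kinematics, and reaction-time and bout-length distributions
that are convenient parametric stand-ins. Real sessions that violate
these assumptions (e.g. strongly non-shared artifacts) will degrade the
isosbestic correction in ways the synthetic tests do not measure.

# Known limitations

* The parser requires trial-start events for exact reconstruction of
  no-stimulus trials; without them only stimulus trials are recovered.
* The exact signed-rank branch is $O(n \cdot W)$ in time and memory via
  the convolution lattice; it is capped at $n = 25$ by default.
* The lock-in path assumes stationary carrier frequencies; drifting
  carriers would require a phase-locked loop, which is out of scope.
* The CLI (`inst/cli/photolick.R`) is a thin convenience wrapper over
  `simulate_session()`, `run_pipeline()` and the session container; the
  exported R functions are the primary interface.
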