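---
title: "Detecting grasp events in continuous ECoG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting grasp events in continuous ECoG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspdetect)
```

# The problem

A self-paced brain-machine interface must notice *when* a discrete motor
event — here, the tightening of a grasp — happens, from a continuous
multichannel electrocorticographic (ECoG) recording, with no trial
structure to lean on. `graspdetect` implements a complete pipeline for this
asynchronous detection problem: causal feature extraction, a regularized
linear discriminant (RLDA) posterior, an online detection rule, and an
evaluation framework that treats temporal tolerance as a first-class
quantity. Because clinical ECoG cannot ship with a package, a synthetic
session generator reproduces the signal structure the method relies on, so
the entire pipeline is testable end to end.

# Preprocessing

Recordings are re-referenced to a common average (CAR: the across-channel
mean is subtracted at every sample) over all channels present, *before*
any channel subsetting for feature construction. Each channel is then
centred by its session mean and scaled by its session standard deviation,
so channels with larger raw amplitudes do not dominate multichannel feature
vectors. Normalization statistics default to the whole session; a
`span` argument provides a strict train-only mode. When only sparse task
periods of a longer recording are of interest,
`restrict_to_task_periods()` drops stretches further than four times the
median inter-event interval from every event and returns contiguous
segments; each retained segment is filtered independently (filter state is
never carried across an excised gap, since the gap's data are unknown to
the causal filters).

# Feature extraction

Two kinds of signal components feed the classifier, both strictly causal —
the output at time $t$ never depends on samples after $t$:

* **Low-pass filtered component (LFC).** A causal Savitzky–Golay filter:
  a 2nd-order polynomial is least-squares fitted to the trailing 250 ms
  window and evaluated at the window's newest point. At 256 Hz this has a
  3-dB cutoff near 6.7 Hz. During the first window the fit uses the
  growing number of available samples; those warm-up samples are flagged
  and excluded from training. Unlike the centred Savitzky–Golay smoother,
  the endpoint evaluation has a rippled stopband; its low-pass character
  holds on the coarse scale (binned response maxima decay), which is what
  the tests assert.

* **Band-amplitude envelopes.** The 0–128 Hz range is divided into 32
  consecutive 4 Hz bands. Each band is isolated with a causal elliptic
  filter of design order 4 (0.5 dB passband ripple, 50 dB stopband
  attenuation — values chosen for steep roll-off at 4 Hz bandwidths while
  remaining numerically stable), rectified by absolute value, and smoothed
  with the same causal Savitzky–Golay filter. The 0–4 Hz band cannot be a
  band-pass (zero-frequency edge) and is implemented as a low-pass at
  4 Hz; symmetrically, a band ending exactly at Nyquist (124–128 Hz at a
  256 Hz sampling rate) is implemented as a high-pass at its lower edge.
  Each band envelope is divided by its time-average over the recording, so
  bands with intrinsically weak power (high frequencies) are not drowned
  when several bands are averaged into a broad component such as 16–28 Hz
  (beta) or 56–128 Hz (high gamma). Normalization uses the envelope's own
  time-mean — the natural reading of normalizing "by the average
  amplitude" — rather than a spectral average.

Narrowband causal filtering is not free: a 4 Hz-wide elliptic band-pass
delays its envelope by roughly $1/\mathrm{bandwidth} \approx 0.2$ s. This
is physics, not a bug, and it shapes two choices documented below (the
generator's modulation window, and the interpretation of detection bias).

For recordings sampled above 256 Hz, filters are designed at the native
rate and the filtered values are causally decimated (most recent value at
each grid time) onto the 64 Hz evaluation grid; the same causal decimation
maps 256 Hz output to the grid. Per-band normalization constants are
computed on the decimated grid, which keeps averaged-band components
self-consistent between the scan and direct runs.

# Feature vectors, delay and history

The posterior is evaluated every 15.625 ms (64 times per second). The
feature vector for time $t$ contains, per channel and component, samples at
$t + \mathit{delay} - k/16$ for $k = 0, \dots, 16\,h$, i.e. a trailing
history of $h$ seconds sampled 16 times per second — sufficient because
every component is low-passed below ~8 Hz. One second of history gives 17
samples per channel per component; $N = n_{ch} \cdot n_{comp} \cdot
(16h + 1)$ features in total. The *delay* fixes where the newest sample
sits relative to the reference time: negative delay means every sample
precedes the event (prediction), positive delay admits post-event signal.
The sign convention follows the semantic definition ("negative delay
corresponds to a time prior to the event"); both the 16 Hz history grid
and the 64 Hz evaluation grid are aligned to session start.

Training sets contain one event row per event (features referenced to the
event time) and exactly 16 non-event rows per event row, drawn at evenly
spaced evaluation times after removing all times within 300 ms of any
event — near-event samples resemble event samples and would blur the class
boundary, and evenly spaced (rather than random) sampling keeps runs
reproducible. If the eligible grid over-fulfils the quota, the spacing is
rounded down and the selection truncated, so the 16:1 ratio is exact.

# The classifier

Both classes are modelled as Gaussians with a shared covariance
$\Sigma$ (pooled, maximum-likelihood $1/n$ normalization), with priors
taken from training-class frequencies (1:16 by construction). Because $N$
easily reaches a few hundred while events number ~100, $\Sigma$ is shrunk
towards a scaled identity,

$$\Sigma_{reg} = (1 - \lambda)\,\Sigma + \lambda\,\frac{\mathrm{tr}\,\Sigma}{N}\,I,$$

which preserves the trace; $\lambda = 0$ is classical LDA, $\lambda = 1$
assumes spherical classes. $\lambda$ is chosen from
$\{10^{-4}, 10^{-3}, 10^{-2}, 0.1, 0.5, 1\}$ by nested cross-validation.
The posterior $P(\mathrm{event}\mid x)$ follows from Bayes' rule; with a
shared covariance the log posterior odds is affine in $x$, so the
implementation evaluates $w^\top x + b$ (with $w$ obtained by a Cholesky
solve of $\Sigma_{reg}$, never an explicit inverse) and maps it through the
logistic function — numerically stable for arbitrarily large Mahalanobis
distances, and fast enough that a session's full posterior trace is a
single pass of weighted shifted sums.

# The detector

The 64 Hz posterior trace is turned into discrete detections online: when
the posterior exceeds 0.95 outside the refractory period, a candidate
opens; if a strictly higher value appears within the next
$t_{advance} = 3/64$ s the candidate moves there and the window restarts;
when no higher value follows, the candidate is emitted. This is a bounded,
real-time-compatible approximation of picking the posterior peak.
Emission suppresses further candidates for 1.5 s, a conservative lower
bound on the interval between successive grasps. Three tie-break rules
make the detector deterministic: equal values never trigger a shift (so
plateaus emit their earliest sample and recursion terminates), the
look-ahead window restarts fully after each shift, and the refractory
period is measured from the emitted detection time. The implementation is
a per-sample state machine, so feeding the trace in chunks of any size —
including single samples — reproduces the whole-trace result exactly.

# Evaluation

A detection counts as a true positive if it falls within a tolerance
$\tau$ of an event; each event claims its nearest detection, and a
detection claimed by two events goes to the closer one, the farther event
staying undetected. Sensitivity is $TPR = N_{TP}/N_{events}$, specificity
is expressed as $FPR = N_{FP}/N_{det}$ (the fraction of detections that
are false — a ratio, not a rate; the false positive *rate* per minute is
reported separately). Temporal precision is summarized tolerance-free by
the signed nearest-detection errors: their median (bias) and root mean
square (temporal deviation, TD).

**Random-predictor baseline.** Chance performance is defined by a renewal
process emitting detections at the true event rate $N_{events}/T$ with the
same 1.5 s refractory period. For $\tau$ below half the refractory period
at most one detection can fall in an event's $\pm\tau$ window, so the
expected number of detections there — rate times the $2\tau + \Delta t$
span covered by the window's decision grid points — equals the detection
probability:

$$TPR_{rand}(\tau) = \frac{N_{events}}{T}\,(2\tau + \Delta t), \qquad
  FPR_{rand}(\tau) = 1 - TPR_{rand}(\tau),$$

the latter because the matched rate makes the expected number of
detections equal $N_{events}$. Both are linear in $\tau$ and depend only
on the temporal density of events. The derivation is validated in the test
suite against a Monte-Carlo simulation of the refractory renewal detector
(shifted-exponential intervals, burn-in to stationarity) before the closed
form is used anywhere; `random_predictor_mc()` exposes the simulation, and
its per-session spread provides the scale for judging whether an observed
score is distinguishable from chance.

# Cross-validation

Sessions are cut into ten contiguous periods of equal length; each is held
out in turn while the other nine form the training set, so training and
test data are mutually exclusive at every moment and temporal
autocorrelation cannot leak across the boundary. Feature rows whose
history window straddles a fold boundary are excluded from both sides.
Within each training set, $\lambda$ is chosen by a second, inner blocked
cross-validation; the inner objective is $TPR - FPR$ at $\tau = 0.5$ s
(the headline metric), with ties broken towards the smaller $\lambda$.
The winning $\lambda$ retrains on the full training set. Held-out
posterior traces are concatenated in time and the detector runs once over
the whole session, so the refractory period behaves exactly as it would
online. Per-band normalization statistics are session-global — a mild,
acknowledged leakage matching how the statistics would be computed on a
full recording; `normalize_channels(span=)` provides a strict alternative.

`band_scan()` repeats the whole procedure for every contiguous band on a
4 Hz grid (528 pairs on the full grid), averaging $TPR - FPR$ over delays
and tolerances. Nested $\lambda$ selection is optional there (a fixed
$\lambda$ keeps the 528-fold scan tractable), and a coarser edge grid can
be supplied.

# The synthetic generator

`generate_session()` emulates what the method assumes about a grasping
session, not the biophysics of cortex:

* **Events** come from a renewal process with shifted-gamma intervals:
  a hard 2 s floor plus a gamma draw (shape 4), mean interval 5 s — the
  observed inter-grasp statistics of self-paced grasping (median close to
  5 s, minimum above 2 s).
* **Background** is $1/f$ noise per channel.
* **Event-locked structure**, each term placed at the event time plus a
  shared 60 ms Gaussian jitter representing behavioural labeling
  imprecision: an additive slow biphasic transient (difference of
  Gaussians spanning ~0.6 s, peak 1.5 background SDs — the LFC target); a
  40% beta (16–28 Hz) amplitude decrease; and a 100% high-gamma
  (56–128 Hz) amplitude increase. The band effects multiply *all* in-band
  background content: the background is band-stopped in both bands and
  replaced by independent band-limited carriers of matching spectral
  level, so a configured fractional effect is what the band envelope
  actually shows.
* **Modulation window**: a raised cosine of 1 s width, i.e. modulation
  building up from about half a second before the event. Two reasons: the
  empirical movement-related band-power changes this emulates extend well
  before the grasp, and the causal narrowband filters delay observable
  envelopes by ~0.2 s, so a window confined to the event's immediate
  vicinity would make the pre-event feature history carry no information
  at zero delay — an artefact of the window choice, not of the method.
* **Topography**: each channel carries fixed per-session effect gains
  (Gaussian around 1 for the slow potential, uniform 0.5–1.5 for the band
  effects). A spatially uniform event-locked signal would be annihilated
  by common-average referencing; real electrode grids see
  channel-dependent amplitudes.

All randomness derives from a single integer seed through fixed
sub-streams (events, jitter, per-channel noise), so events, noise and
jitter are independently reproducible.

What the generator does *not* model: artifacts, line noise,
non-stationarity, cross-channel correlated noise, grasp-type or load
covariates, and any realistic spatial mixing. Passing end-to-end tests on
synthetic sessions therefore demonstrates that the pipeline recovers the
structure it assumes, under honest cross-validation — not that it attains
any particular performance on clinical ECoG.

# Numerical choices and degenerate inputs

* Savitzky–Golay warm-up uses growing windows (copying the input while
  fewer than order + 1 samples exist); warm-up spans are flagged and
  excluded from training.
* Band envelopes are clamped at zero (the polynomial smoother can
  overshoot slightly below zero on steep flanks).
* Posterior evaluation times whose feature window reaches into warm-up get
  posterior 0 (no detection possible there).
* `rlda_fit()` refuses a non-positive-definite regularized covariance
  (possible at $\lambda = 0$ with fewer rows than features) rather than
  silently pseudo-inverting.
* Fold boundaries snap to the 64 Hz grid; fold lengths differ by at most
  one step when the session length is not divisible.
* Ties in the inner-CV objective and in the detector are broken
  deterministically (smaller $\lambda$, earliest sample).

# Problem sizes used in the tests

The packaged tests exercise the full pipeline at desk scale: 60–240 s
sessions with 2–3 channels for unit tests; a 10-minute, 5-channel session
with full nested ten-fold cross-validation for the end-to-end recovery
check (and a matching null session with all effects zeroed); a 180 s,
2-channel session on a 16 Hz band-edge grid for the scan experiment; and
a few hundred Monte-Carlo sessions for baseline validation. These sizes
were chosen so the complete suite runs comfortably on one CPU while every
statistical check retains enough events (~35–120 per session) to be
meaningful.

# Known limitations

* The detector's look-ahead bound means a detection is only as close to
  the true posterior peak as recursive 3-step shifts allow; broad plateaus
  keep a residual early bias.
* The random-predictor closed form assumes stationarity and
  $\tau < 0.75$ s; outside that range the report leaves baseline columns
  `NA`.
* EDF support covers continuous recordings with one common sampling rate
  (the layout the package itself writes); discontinuous EDF+D files are
  out of scope.
* With a single channel, common-average referencing yields an all-zero
  recording by definition; channel subsetting should happen after CAR.
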