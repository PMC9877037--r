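---
title: "Dissociating place, time and distance codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating place, time and distance codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

On a linear track, a CA1 pyramidal cell can appear tuned to the animal's
*position*, to the *time elapsed* since it left the reward site, or to the
*distance travelled* since that departure — and, because all three variables
evolve together as the animal shuttles back and forth, a cell genuinely tuned
to one of them inevitably carries information about the others. The package
implements a complete analysis pipeline for this problem — binarization of
calcium traces, information-theoretic tuning classification with
circular-permutation nulls, naive Bayes population decoding, optogenetic
modulation detection, and LFP analyses (oscillation strength, quiet-rest
segmentation, sharp-wave-ripple detection) — together with a synthetic-data
generator with known ground truth, so that every stage can be validated
end to end without any recorded data.

# Behavioral simulation: the generator defines the study conditions

`simulate_track_session()` builds a piecewise-constant-velocity trajectory
over a 134-cm track with end sensors, three tones advancing on successive
end crossings, and a reward at the starting end on every fourth completed
run. Elapsed time and distance travelled reset at the first frame after a
reward at which the animal is more than 5 cm from the reward end.

A minimal trajectory model (constant speed, clean turns) makes position,
elapsed time and distance *deterministic functions of each other* within a
trial; under such behavior no cell can be exclusively tuned in an
information-theoretic sense, and every tuned cell classifies as conjunctive.
Real mice dissociate the variables through behavioral variability, and the
generator models the main sources of it explicitly:

* **per-leg speed jitter** (`speed_cv = 0.4`) and a **per-trial speed
  factor** (`trial_speed_cv = 0.45`, log-normal, truncated to [0.55, 1.6]):
  some trials are run fast throughout, others slowly, spreading the
  distance-at-time relation across trials;
* **end pauses** (1–6 s, uniform) and **mid-run stops** (2 per run on
  average, 1–5 s): elapsed time advances while position and distance are
  frozen; stopped frames fall below the locomotion threshold and are
  excluded from analysis, but they desynchronize the trial clock from the
  path integrator;
* **mid-run hesitations** (1.5 per run, 5–30 cm partial retreats at
  uniform track positions) and **start-of-run sorties** (0.8 per run,
  15–110 cm aborted runs out of the end zone and back): these add random
  path length at random points, scrambling the position-to-distance map
  from trial to trial;
* **turn-around jitter** inside the 5-cm sensor zones and smooth,
  speed-scaled **tracking/micro-movement noise** (0.5 cm SD), which
  inflates path length the way real pose-tracking trajectories do;
* **full reversals** (probability 0.2 per run): the animal returns into
  the origin sensor zone and restarts.

Error scoring follows the hardware: the task's only sensors sit at the two
track ends, so a "change of running direction before the next tone" is
detectable only as a re-trigger of the origin sensor. `derive_task_variables()`
therefore scores a run as an error when the origin zone is re-entered after
the run got under way (progress beyond 25 cm); hesitations and sorties,
which never re-enter the zone, are not errors. Performance is the fraction
of four-run trials without an error run, and sessions with fewer than 12
runs are flagged for exclusion.

The defaults above, together with a 15-minute session budget
(`max_duration_s = 900`), are the package's study conditions. They were
chosen once, to emulate a moderately trained mouse whose behavior actually
dissociates the three variables, and are exposed in `track_config()`.

What the generator does **not** emulate: real tuning-curve shapes (fields
are Gaussian by construction), rate remapping, theta-phase dynamics of
spiking, slow drift of fields within a session, or any coupling between
LFP state and spiking. Passing tests therefore demonstrate that the
*analysis* behaves as specified on data whose generative structure is
known — not that real CA1 data satisfy the generator's assumptions.

# Neurons and calcium traces

Each synthetic cell activates per frame with probability
$$p(t) = p_0 + (p_1 - p_0)\prod_c \exp\!\left(-\frac{(v_c(t)-\mu_c)^2}{2\sigma_c^2}\right),$$
with baseline $p_0 = 0.02$ and in-field peak $p_1 = 0.3$ per frame at
30 Hz; exclusive cells have one tuning component, conjunctive cells
several, untuned cells none. Field widths default to 8 cm (location), 4 s
(time) and 20 cm (distance). Field centers are drawn uniformly over each
variable's *dissociable* range (location 4–130 cm, time 15–45 s, distance
164–1100 cm): immediately after the trial clock resets, small elapsed time
or path length pins the animal near the reward end by continuity, so
exclusive tuning is not even definable there (see the binning discussion
below). Activations are convolved with a single-exponential calcium kernel
(`calcium_tau = 0.5` s, no rise time — adequate for testing a rising-edge
binarizer) and corrupted with Gaussian noise.

# Binarization

`binarize_traces()` low-pass filters each trace (2 Hz, 4th-order
Butterworth, applied forward and backward for zero phase), z-scores it over
the session, and marks a frame active when the normalized amplitude exceeds
2 SD *and* the first difference of the filtered trace is positive — only
the rising phase of a transient counts. Design choices the underlying
description leaves open: the normalization is a session-wide z-score of the
filtered trace; the derivative is the first difference labeled by the later
sample. Consequences worth knowing: within a dense in-field burst the 2-Hz
filter merges successive activations into a single detected rising event,
and isolated single-activation transients on a sparsely active cell are
recovered essentially completely (the unit tests check onset recovery at
0.005 activations/frame).

# Tuning curves, mutual information and the permutation null

The activity likelihood per state bin is
$P(A\mid S_i) = \text{(active frames in bin } i) / \text{(frames in bin } i)$,
with the marginal $P(A)$ as an overall activity proxy. Binning follows the
study conventions — 3-cm location bins, 1-s time bins, 3-cm distance bins,
display smoothing with Gaussian kernels of 5, 10 and 15 bins respectively —
and analysis is restricted to locomotion frames (speed > 5 cm/s on the
track, > 2 cm/s in the open field). MI is the plug-in estimate
$$MI = \sum_{i=1}^{M}\sum_{j\in\{0,1\}} P(S_i \cap A_j)\,
\log_2\frac{P(S_i \cap A_j)}{P(S_i)\,P(A_j)},$$
computed on unsmoothed curves (smoothing is display- and decoder-side
only).

**Binning ranges.** The time range is 8–80 s and the distance range
134–1350 cm. Two considerations set these. First, under realistic
behavioral variability a four-run trial's path length is roughly twice the
nominal $4 \times 134 = 536$ cm, so a range sized to the nominal geometry
would truncate every trial midway. Second, near the reset the variables are
degenerate: distance below one track length, or elapsed time below a few
seconds, confines the animal to a neighborhood of the reward end, making
"distance tuning" there indistinguishable from place tuning. Frames outside
a range are excluded from that variable's analysis only. Both ranges are
config-exposed (`binning_spec()`).

**The null distribution.** Significance uses 1000 circular permutations:
each surrogate rotates the *full-session* binary trace by a random offset
(at least one second) and re-applies the locomotion/range mask before
recomputing MI; the p-value is the fraction of surrogate MI values strictly
greater than the actual one, so ties favor significance. Rotating the full
session rather than the masked series matters: mask gaps correlate with the
behavioral variables (stops occur at particular elapsed times), and
rotating the concatenated masked vector breaks exchangeability — measured
on 200 untuned cells, that variant inflates the elapsed-time false-positive
rate to ~11%; the full-circle construction restores ~5% per variable.
Session-conditional rates still fluctuate a few percent around the nominal
level, so calibration checks pool cells across simulated sessions, as the
experimental analyses pool neurons across animals.

**Classification.** A cell significant ($p \le 0.05$) for exactly one
variable gets that label; for two or more, `conjunctive`; none, `none`.
Stimulation modulation treats the binarized stimulation signal as a
two-state behavioral variable and reuses the same machinery, reporting
`excited`/`inhibited` from the sign of the conditional rate difference.

**What exclusive-label recovery can and cannot reach.** With strongly and
purely tuned synthetic cells under the study conditions, recovery of
exclusive labels plateaus around 0.85 for place, 0.75 for distance and 0.5
for time cells (~0.65 overall): the variables remain physically coupled on
a track, a ~25,000-frame MI test detects the residual coupling for a
minority of cells, and for elapsed time the circular null is additionally
inflated by rotations near multiples of the trial period, which partially
preserve time alignment. This mirrors the experimental finding that
exclusively tuned cells are a small minority relative to conjunctive ones.
The acceptance suite states the stronger 80% recovery target and reports
the measured value; the companion population-level checks (decoder z-scores
beyond 2 SD for all three variables, every location bootstrap beating its
shuffled surrogate) pass with wide margins.

# Naive Bayes decoding

`fit_decoder()` estimates $P(A_k \mid S_i)$ per cell and bin on the
training split, with a uniform prior over occupied bins and likelihoods
clipped to $[1/(n_i+2),\, 1 - 1/(n_i+2)]$ (add-one style, $n_i$ the bin's
occupancy) so silent cells cannot zero the posterior. The train/test split
is contiguous — the last 10% of analyzed frames, backed up to a trial
boundary — to prevent leakage through the calcium autocorrelation.

`decode()` offers two scorings:

* **exact**: the log-posterior $\sum_k \log P(A_k \mid S_i) + \log P(S_i)$
  with full binary likelihoods (inactive cells contribute the complement),
  summed over a trailing 2-s window and normalized per frame — Bayes' rule
  under independence, and the variant verified against brute-force
  enumeration to $10^{-10}$;
* **published**: the printed scoring of the original analysis
  $\sum_k \log(1 + P(A_k\mid S)P(S)/P(A_k)) - 1$, a log(1+x) compression
  of the per-neuron posterior ratios.

The two are interchangeable as decoders — mean errors agree to a fraction
of a bin — but the compression shifts flat-topped score profiles by a bin
or two once evidence accumulates, so their argmax choices coincide on ~90%
of single frames for small populations and less under long windows; tests
assert the error equivalence rather than bin-identical choices. Argmax ties
break to the lowest bin index; frames with no finite evidence fall back to
the prior and are flagged. Decoding error is
$|\text{decoded} - \text{actual}|$ at bin centers, in the variable's units.
`bootstrap_decode()` repeats fit-and-decode over 50 samples of 160 cells
drawn with replacement, with matched surrogates built by circularly
shifting each sampled cell, and `zscore_error()` reports
$z = (\bar{x} - \bar{s})/\sigma(x)$ — negative for better-than-chance
decoding, with a `display_negated` flag for the "higher is better"
presentation.

# LFP analyses

`simulate_lfp()` builds $1/f$ background noise (spectral shaping), a theta
component whose instantaneous frequency is
`theta_base_freq + theta_speed_gain * speed(t)` (defaults 6 Hz + 0.05 Hz
per cm/s — free parameters of the generator, not measured values),
stimulation epochs that replace the theta drive (8 Hz pacing with phase
reset, variance-matched white "scrambled" drive, or one random 4–12 Hz
frequency per epoch), and Gaussian-envelope ripple bursts (SD 15 ms,
180 Hz) at given times.

**Spectral machinery.** `wavelet_spectrogram()` convolves with complex
Morlet atoms (bandwidth 1, center frequency 1.5), L1-normalized so ridge
power is comparable across frequencies; `movingwin_spectrum()` is a tapered
short-time Fourier transform on 2-s windows (theta) or 5-s windows (gamma)
stepped by 10 ms.

**Oscillation strength.** OS is the fraction of 4–12 Hz power within
±1 Hz of the band's peak frequency. The estimator uses the moving-window
convention with a 4-term Blackman–Harris taper, tracks the peak per window,
and takes the ratio on power accumulated across windows. Two printed
anchors pin this convention: a pure 8 Hz sinusoid gives OS $\approx 1$
(measured 0.9997; the taper's sidelobes account for the rest) and 5-s
white-noise epochs average OS $\approx 0.5$ (measured 0.46–0.47 across
seeds). Averaging the PSD across windows *before* locating the peak — the
other natural reading — yields ~0.35 on white noise and was rejected
against the calibration anchor.

**Band powers and theta–speed coupling.** `band_power_portions()` reports
stimulation/baseline power ratios over the six canonical bands (delta 1–4,
theta 4–12, alpha/beta 12–30, slow gamma 30–60, fast gamma 60–120, HFO
120–250 Hz) from 1-s Welch windows, which resolve the delta edge;
`theta_speed_relation()` is the Pearson $R^2$ between the per-step dominant
theta frequency and running speed — high for speed-coupled theta,
undefined-or-nil under 8 Hz pacing.

**Quiet rest.** The theta/delta Hilbert-envelope ratio is z-scored on a log
scale (the raw ratio's heavy right tail would otherwise drag the mean above
the typical value and mark most of any session as rest) and rest is
$z < 0$. Very low bands are filtered on a decimated copy of the signal:
transfer-function Butterworth coefficients are unstable at normalized
cutoffs of ~$10^{-3}$.

**Ripple detection.** The 150–250 Hz band signal's Gaussian-smoothed
(10 ms) Hilbert envelope is log-transformed and z-scored; local maxima of
at least 4 SD, spaced at least 30 ms (the taller peak wins), restricted to
quiet rest, are events; width is the time above half threshold. The log
transform makes the statistic near-Gaussian, which is what turns the 4-SD
threshold into a genuine rarity level: on ripple-free noise the detector
fires essentially never (0 events in 100 simulated minutes), while
thresholding the raw z-scored band signal — the most literal reading of
the detection recipe — would fire at the Gaussian level-crossing rate of
several events per minute. Injected bursts of 8 background-SDs are
recovered completely with ~1 ms timing error.

# Degenerate inputs and numerical conventions

Constant traces binarize to all-inactive; all-silent cells get $p = 1$ and
undefined modulation direction; constant tuning curves make field stability
`NA` with a warning; zero exploration makes the recognition index `NA`;
zero actual-error variance makes the decoding z-score `NA`; empty rest
masks return an empty event table with a warning; unoccupied bins are `NA`
and excluded from MI, smoothing normalization, and confusion-matrix rows.
Every generator consumes one integer seed and reproduces its output
bit-identically; derived sub-seeds stay below $2^{31}$.

# Problem sizes

The validation analyses run at desk scale by design: 15-minute sessions at
30 Hz (~27,000 frames), populations of ~70–200 cells, 1000 circular
permutations per test, 50 decoding bootstraps of 160 cells, and LFP
segments of 1–10 minutes at 1 kHz. Calibration and recovery checks pool
cells across three independently seeded sessions.

# Known limitations

* Elapsed-time tuning is intrinsically the hardest to certify against a
  circular null in a quasi-periodic task; exclusive time-cell recovery is
  correspondingly the weakest (see above).
* The published decoder scoring is kept for comparability, but its
  argmax is not bin-identical to exact Bayes; use the exact variant for
  quantitative error analyses.
* The generator's LFP is phenomenological (additive components), so
  cross-frequency or spike-field relations are out of scope.
* Cross-day cell registration is consumed as a given mapping
  (`compare_sessions()`), never computed.
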