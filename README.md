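# thetacode

Analysis pipeline for dissociating hippocampal spatiotemporal codes —
place, elapsed-time, and distance-travelled tuning of CA1 neurons recorded
with calcium imaging on a sequential-tone linear track — and for the LFP
analyses used to study their relation to theta oscillations (oscillation
strength under optogenetic pacing or scrambling, theta-frequency/running
speed coupling, quiet-rest segmentation, sharp-wave-ripple detection).

It is written for systems-neuroscience analysts who want a tested,
self-contained R implementation of this analysis family. Everything runs
on synthetic data with known ground truth: the package ships a generator
for track/open-field behavior, Bernoulli-tuned neurons convolved with a
calcium kernel, and LFP with speed-coupled theta, stimulation epochs and
injected ripples, so every stage is validated end to end without any
recorded data.

## Methods at its core

* **Binarization** — calcium traces are low-pass filtered (2 Hz,
  zero-phase), z-scored, and a frame is active when amplitude > 2 SD and
  the first derivative is positive.
* **Tuning and classification** — activity likelihood per state bin
  $P(A\mid S_i)$ (3-cm location, 1-s time, 3-cm distance bins), mutual
  information
  $MI = \sum_i \sum_j P(S_i \cap A_j) \log_2 \frac{P(S_i\cap A_j)}{P(S_i)P(A_j)}$,
  significance from 1000 random circular permutations of the full-session
  trace ($p$ = fraction of surrogates beating the data), labels
  place/time/distance (exactly one significant variable), conjunctive
  (several) or none. The same machinery detects optogenetic
  stimulation-modulated cells.
* **Decoding** — naive Bayes with uniform prior,
  $P(S_i \mid A) \propto P(S_i)\prod_k P(A_k \mid S_i)$, 90/10 trial-wise
  split, 2-s temporal filtering, MAP readout; error
  $|\hat{y} - y|$ in the variable's units, bootstrapped (50 draws of 160
  cells) and z-scored against circularly shuffled surrogates,
  $z = (\bar{x}-\bar{s})/\sigma(x)$.
* **LFP** — complex Morlet (cmor1-1.5) and moving-window Fourier spectra
  (2-s/5-s windows, 10-ms steps); oscillation strength = theta-band power
  within ±1 Hz of the peak frequency over total 4–12 Hz power; band-power
  portions of baseline for δ/θ/α-β/γ-slow/γ-fast/HFO; quiet rest from the
  z-scored theta/delta envelope ratio; ripples as ≥4 SD peaks of the
  z-scored log-envelope of the 150–250 Hz band, ≥30 ms apart.
* **Behavior metrics** — recognition index
  $RI = t_{novel}/(t_{novel}+t_{familiar})$, track performance
  (correct trials / total, 12-run minimum), ANOVA effect sizes
  $\eta^2 = SS_{between}/SS_{total}$,
  $\eta_p^2 = SS_{effect}/(SS_{effect}+SS_{error})$.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data and write tables under `results/`. A condensed session:

```r
library(thetacode)

beh   <- simulate_track_session(track_config(), seed = 1)
specs <- make_population(n_place = 50, n_time = 30, n_distance = 20,
                         n_untuned = 50, seed = 101)
sim   <- simulate_neurons(beh, specs, seed = 201)
bin   <- binarize_traces(sim$neural$traces, sim$neural$frame_rate)

cls <- classify_session(bin, beh, n_shuffles = 1000, seed = 2)
table(cls$label)

res <- bootstrap_decode(bin, beh$x_cm, binning_spec("location"),
                        use = beh$speed_cm_s > 5, split_by = beh$trial_id,
                        seed = 11)
c(error = res$mean_error, shuffled = res$mean_shuffled_error, z = res$z)
```

Running `analysis/01` – `analysis/05` prints, among other things:

```
session: 15.3 min, 34 runs, 8 trials
performance: 38% correct trials (min-12-runs filter: included)

label composition (all cells):
conjunctive    distance        none       place        time
      0.273       0.087       0.320       0.247       0.073

location  error  17.92 cm vs shuffled  37.22 cm  (z = -13.87)
time      error  11.21 s  vs shuffled  21.19 s   (z = -5.59)
distance  error 216.67 cm vs shuffled 299.83 cm  (z = -5.43)

OS none     : 0.965   OS pace8 : 0.977
OS scrambled: 0.458   OS whitenoise: 0.470   OS 8Hz sine: 1.000
theta-frequency vs speed R2 (none): 0.781   (pace8): 0.009

quiet rest: 56% of the session
injected: 60 (36 during rest); detected: 36; recovered: 100%
```

Read: tuned cells decode their variable far below chance (negative z);
8 Hz pacing concentrates theta power (OS near 1) and abolishes the
theta–speed relation, while scrambled stimulation collapses OS to the
white-noise level; injected ripples during quiet rest are recovered
completely. The methods vignette
(`vignettes/spatiotemporal-coding.Rmd`) documents the models, parameter
choices and their rationale.

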