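---
title: "Tracking BCI user learning in the channel and Riemannian domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking BCI user learning in the channel and Riemannian domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A motor-imagery brain-computer interface (BCI) translates sensorimotor-rhythm
(SMR) modulations — event-related desynchronization of the mu (8–12 Hz) and
beta (16–26 Hz) bands during imagined movement of both hands versus both
feet — into discrete commands. Over months of mutual training the user's
neural patterns change, and the interesting question for a longitudinal study
is not only *does accuracy improve* but *where in neural space does the
learning live, and which changes survive a long pause in training*.

`bcilearn` implements a complete, testable version of such an analysis:

1. the online decoding pipeline (Laplacian spatial filter, Welch PSD
   features, canonical-variate feature ranking, Gaussian prototype classifier
   with rejection, evidence integration with an intentional non-control
   state, EOG artifact gating);
2. two run-level learning metrics, the between-class distance and the
   within-class distance, each computed in two neural domains;
3. the statistical battery used to read the resulting learning curves;
4. a Cybathlon-style race-game simulator; and
5. a synthetic-EEG generator with *programmed* learning dynamics, so every
   claim the analysis makes can be checked against a known ground truth.

## The learning metrics

For each training run and class, the artifact-free 1 s analysis windows form
a distribution of neural patterns. Two summaries are computed:

- **Between-class distance**
  `bcDist = delta(mu_bh, mu_bf) / (sigma_bh + sigma_bf)`:
  the distance between the two classes' mean patterns, normalized by the
  dispersion of each class around its mean. It quantifies discriminability.
- **Within-class distance**
  `wcDist = delta(mu_1, mu_r) / (sigma_1 + sigma_r)`:
  the shift of one class's mean pattern in run `r` relative to the first
  recorded run, reported averaged over the two classes. It quantifies
  reorganization of the activity itself, whether or not discriminability
  changes.

Both are evaluated in two domains:

- **Channels' domain.** Each window is the 14-vector of per-channel PSD
  averaged over the band's 2 Hz bins; `delta` is the Euclidean distance and
  `sigma` the mean Euclidean distance of windows to their class mean. In one
  dimension, with the standard-deviation dispersion convention, `bcDist`
  reduces *exactly* to the Fisher score
  `FS = |mu_1 - mu_2| / sqrt(s_1^2 + s_2^2)` — the package verifies this
  algebraically in its tests.
- **Riemann domain.** Each window is the sample covariance matrix
  `C = X X' / (T - 1)` of the 14 zero-mean band-pass-filtered channels, a
  symmetric positive-definite (SPD) matrix. `delta` is the affine-invariant
  geodesic distance `sqrt(sum(log^2 lambda_i))` (eigenvalues of
  `A^{-1}B`), the mean is the Karcher (geometric) mean computed by the
  tangent-space fixed-point iteration, and `sigma` is the mean geodesic
  distance of windows to the class mean.

### Two dispersion conventions

The denominator of both metrics is "the average distance around the means".
Read literally this is the mean distance to the class mean, combined by a
plain sum — the package default (`convention = "meandist"`). But the stated
equivalence of the 1-D channels'-domain `bcDist` with the Fisher score holds
only if the dispersions are standard deviations combined in quadrature;
`convention = "sd"` selects that reading. Both are exposed because the two
definitions are in mild tension; all qualitative conclusions are unchanged
by the choice, and the exact Fisher-score equivalence test uses `"sd"`.

### Choice of metric space

The channels'-domain metrics are computed on sensor-space (non-Laplacian)
PSD: per-channel band power is then a function of each electrode's signal
alone, so the domain cleanly isolates *power* reorganization, while the
Riemann domain also sees *correlation-structure* reorganization. The
decoder's feature path keeps the Laplacian filter, as in the online system.
This separation is what lets the two domains dissociate (below).

## The decoding pipeline

- **Laplacian filter**: each electrode minus the mean of its orthogonal
  grid neighbors among the 14 sensorimotor channels (Fz, FC3, FC1, FCz,
  FC2, FC4, C3, C1, Cz, C2, C4, CP1, CPz, CP2); edge channels use the
  neighbors that exist.
- **PSD**: Welch estimate on 1 s windows sliding every 62.5 ms, 256-sample
  Hamming-tapered half-overlapping sub-segments with constant detrend —
  exactly 2 Hz resolution at 512 Hz.
- **Feature ranking**: two-class canonical variate analysis; per-feature
  score = squared canonical loading times the canonical correlation;
  deterministic tie-break by channel order then band. Feature selection is
  top-k with a carryover policy: features of the previous decoder are
  force-included while they retain discriminant power, which is what keeps
  decoders stable across re-calibrations.
- **Classifier**: per-class Gaussian prototypes (diagonal covariance, equal
  weights; default 2 per class) initialized by a 1-D ring SOM over each
  class (batch updates, 200 epochs, exponentially decaying neighborhood),
  refined by batch gradient descent on the posterior cross-entropy
  (learning rate 0.01, up to 500 epochs, tolerance 1e-6). Features are
  standardized inside the model.
- **Rejection**: a sample updates the integrator only if its maximum
  posterior reaches `th_rej = 0.6` (boundary inclusive — "below threshold"
  is rejected).
- **Integrator**: exponential evidence accumulation
  `y <- y + alpha (p - y)` with clipping and renormalization. Pure convex
  averaging can never literally reach 1, so a command fires when the
  integrated probability comes within `eps_cmd` of 1 (defaults
  `alpha = 0.1`, `eps_cmd = 0.025`). On delivery the integrator resets to
  uniform and a 1 s refractory period applies. Under constant saturated
  evidence the command time has the closed form
  `n = ceiling(log(eps_cmd / 0.5) / log(1 - alpha))` = 29 frames
  (1.81 s) at the defaults; under uniform evidence no command is ever
  delivered (the intentional non-control state). Rejected and
  artifact-frozen samples leave the integrator unchanged (a decay-to-uniform
  variant was considered and not adopted: freezing is the minimal faithful
  contract).
- **EOG guard**: the two frontal electrodes are combined as
  `HEOG = Fp1 - Fp2`, `VEOG = (Fp1 + Fp2)/2`, filtered with a zero-lag
  order-2 Butterworth band-pass at 1–10 Hz (signal mirrored at the edges
  before filtering), and the absolute amplitudes are compared with a 30 uV
  threshold per 32-sample frame. A detection freezes command output for
  2 s; overlapping detections extend the freeze. Windows overlapping
  suppressed intervals are excluded from *all* downstream metrics. In
  streaming mode the filter runs on a 1 s trailing buffer and reads back
  the newest frame, so detection is causal at frame granularity.

## The synthetic-EEG generator

No public longitudinal dataset accompanies this kind of single-pilot study,
so the generator is a first-class module: it produces sessions whose
statistical structure matches what the analysis assumes, with the learning
dynamics *programmed* and logged as ground truth.

A session is: spatially correlated pink-noise background (per-channel
`1/f^1.3` noise mixed over a distance kernel on the 10-20 grid, 10 uV RMS
on EEG channels, 4 uV on the frontal EOG electrodes) plus band-limited
Gaussian-noise carriers in mu and beta (7 and 6 uV RMS) with strong
spatial coherence. Trials follow the calibration protocol: 15 cue-guided
trials per class per run, 4.5–5.5 s each, labels randomized, with windows
labeled only from 0.5 s after the cue (a fixed cue-to-task latency).
Event-related desynchronization is an amplitude modulation of the carriers
(not pure tones, so PSD features have realistic variance): hands imagery
suppresses lateral channels (FC3, C3, FC4, C4), feet imagery medial ones
(FCz, Cz, CPz), with depths 0.5 (mu) and 0.8 (beta) scaled by a run-indexed
separability gain `g(r)`.

Within-class drift has two programmed components per band:

- a **band-power shift**: per-channel log-power moves along a fixed random
  direction with run-indexed magnitude `d(r)` — visible to the channels'
  domain;
- a **correlation rotation**: the carriers' inter-channel correlation matrix
  is rotated by `expm(theta(r) A)` (unit-spectral-norm skew generator `A`)
  and renormalized to unit diagonal — visible to the Riemann domain but, by
  construction, invisible to sensor-space band power.

Zero-mean run-to-run jitter (0.08 log-units on power, 0.25 rad on rotation)
emulates day-to-day state variability; without it, run-level curves are
unrealistically smooth and any microscopic difference becomes
"statistically significant". A long training break resets the power shift
for every band and the rotation for non-retained bands; a *retained* band
keeps its rotated covariance structure. Blinks (raised-cosine bumps,
150–400 ms, same sign on both EOG electrodes, default 150 uV) and saccades
(opposite sign) arrive as Poisson events and are logged.

`study_history()` packages the three canonical conditions:

- **growth** — separability 0.2 to 1 over 25 runs with accumulating drift:
  accuracy and beta-band `bcDist` must rise, rejection must fall;
- **break** — stable skill, drift plateau before a break after run 20 with
  the beta rotation retained: the within-class distance must drop back
  toward baseline in the channels' domain (both bands) and in the Riemann
  mu band, while the Riemann beta band stays continuous — the headline
  dissociation between transient power reorganization and persistent
  covariance structure;
- **null** — flat everything: no metric may trend.

Drift magnitudes (power 1.6/0.4 log-units for mu/beta in the break
condition, rotation 2 rad with a plateau from run 12) were fixed once, by
simulation during generator design, so that programmed effects sit well
clear of the run-level sampling floor of each metric while the retained
band's residual power footprint stays inside the jitter band. They are
study conditions of the simulation, not estimates of any real pilot.

What the generator does *not* emulate: volume conduction from a biophysical
head model, non-stationary artifacts other than ocular events (EMG, cable
movement), 50 Hz interference (assumed hardware-filtered), and
reaction-time variability beyond the fixed 0.5 s latency. Passing the
recovery tests therefore shows the *analysis* is sound — that the metrics
detect exactly the structures they claim to measure — not that any
particular real dataset contains those structures.

## Numerical choices

- Welch sub-segments use a constant detrend; PSD is one-sided density in
  uV^2/Hz.
- Band-pass filters are 4th-order Butterworth applied forward-backward
  (zero phase) with mirrored edges; the EOG guard uses the 2nd order the
  detection scheme specifies.
- Window SCMs from 1 s of narrow-band data are badly conditioned; every
  SCM receives relative diagonal loading `0.01 x trace/C` before entering
  the Riemannian computations (`scm_set(shrinkage = )`), and
  `sample_covariance` itself floors only truly singular estimates
  (`1e-10 x trace/C`, logged). The geodesic uses Cholesky whitening rather
  than explicit inversion.
- The Karcher mean stops when the tangent-space mean norm falls below
  1e-8 (50 iterations) for the exported operation; the learning-metric
  path runs it at 1e-6 with a larger iteration budget, which is far below
  metric noise.
- Kruskal-Wallis is tie-corrected; the Tukey-Kramer post-hoc runs on rank
  means with the studentized-range approximation (infinite df), with a
  raw-value variant available. Degenerate (constant) series report
  non-significant rather than erroring, so batch reports never abort.
- Batch analyses keep every 3rd PSD window and every 8th SCM window by
  default (`experiment_config(psd_stride, scm_stride)`); the windows are
  heavily overlapped, so this trades negligible information for a large
  constant factor. Strides of 1 reproduce the online window rate.

## The race simulator

Tracks are seeded uniform permutations of 4 x {right, headlight, left,
noinput} over 16 sections. Both-hands maps to `left`, both-feet to
`right`; a command of the opposite type within 2 s of the previous
delivered command becomes `headlight` (the sequential strategy), and no
command is `noinput`. The true game kinematics are proprietary; the
simulator's speeds (base 1, boost 4, penalty 0.5 units/s over 16-unit
sections, 2 s penalties, 240 s cap) preserve the orderings that matter —
correct beats silent beats wrong — with a perfect pilot finishing in about
112 s and a silent pilot capped at 240 s. Race times are monotone
non-increasing in pilot accuracy by construction (common random numbers
per section).

## Reproducing the analysis

```r
library(bcilearn)

# one simulated run, decoded end to end
cfg <- simulation_config(seed = 1)
s <- simulate_session(cfg, run_index = 1)
det <- detect_eog_artifacts(s$recording)
fr <- psd_frames(s$recording)
fr <- mask_artifacts(label_windows(fr, s$trials), det$intervals)

ranked <- cva_rank_features(fr)
head(ranked)

# a full longitudinal experiment with the canonical growth condition
rep <- run_longitudinal_experiment(
  experiment_config(history = study_history("growth", seed = 1),
                    n_runs = 30))
rep$trends
```

`scripts/acceptance.R` re-runs the whole battery (Riemannian identities,
decoder contracts, guard operating point, both canonical histories, game
invariants) from a single seed and writes the resulting numbers as JSON.

## Known limitations

- Single-pilot designs give run-level statistics, not population claims;
  the package mirrors that scope.
- The CVA step implements the batch ranking + carryover policy; the
  "semi-automatic" operator-in-the-loop step of an online system is
  represented by the printed ranking, not by interaction.
- The exact dynamical system behind the original evidence integrator is
  not published; the exponential-accumulation contract implemented here
  preserves its observable behavior (accumulation, INC, reach-1 delivery,
  uniform reset, refractory) with the simplest dynamics, and `alpha` /
  `eps_cmd` are configuration.
- EDF/BDF I/O is out of scope in this build; recordings round-trip through
  a plain-text CSV + JSON container (`write_recording` / `read_recording`).
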