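---
title: "An asynchronous artifact-enhanced EEG control decoder driven by slight facial expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An asynchronous artifact-enhanced EEG control decoder driven by slight facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfebci)
```

## The paradigm

Scalp EEG recorded while a user makes a *slight* facial expression (sFE) — a
barely visible raise of the brow, smirk, pout — contains two superimposed
signals: genuine cortical activity and electromyographic (EMG) leakage from
the facial muscles. Classical pipelines scrub the EMG away; this paradigm
deliberately keeps it, because the artifact is informative: different
expressions engage different muscles, and the mixture of EEG rhythm and
EMG topography makes eight expressions separable from a single 100 ms,
30-channel window. The retained artifact also provides a cheap guard: a
*regular*-amplitude expression (the kind used in daily communication)
produces vastly more 55–95 Hz energy on the electrodes over the facial
muscles, so it can be rejected before any classifier runs, and the user can
talk, eat and emote freely while wearing the cap.

The decoder is a staged stream processor over overlapping 100 ms windows
(stride 10 ms by default):

* **Step A — screening.** Per-window temporal energy `sum(x_i^2)` on the
  six facial-muscle reference channels (Fp1, Fp2, F7, F8, T3, T4), computed
  in the 55–95 Hz band. Each channel has its own threshold, fit as 105% of
  the largest energy that channel showed over all slight-expression
  training windows; one exceedance rejects the window as an obvious
  non-sFE.
* **Step B — switch-on detection** (non-control mode only). Common spatial
  patterns (2 filter pairs) on the 5–50 Hz band; the feature of filtered
  signal `k` is `log(var(Y_k)) / sum(log(var(Y_k)))`, a four-vector summing
  to one, fed to an SVM with the *scaled Gaussian* kernel,
  `gamma = 1 / (n_feature * var(X))` pooled over all feature entries. Only
  the designated switching expression (slight raise-brow, `s-RB`) counts as
  `ON`.
* **Step C — nine-class decoding** (in-control mode only). A temporal
  Conv1D(64, k3) → max-pool(3/3) → Conv1D(128, k3) → GRU(128) →
  dense 64 → 32 → 9-softmax network over the 100 x 30 window, trained with
  categorical cross-entropy under RMSprop (lr 0.001, batch 128). The ninth
  class `NON`, sliced from resting-state data, is the hold-on command.
* **Step D — validity judgment.** A decoded label becomes an instruction
  only if, among the latest `n = 20` decoded labels, a per-class fraction
  (0.35–0.95, stricter for destructive actions) agrees with it; the
  boundary is inclusive and `NON` never triggers. A valid `s-RB` toggles
  the non-control/in-control state instead of moving the device.

Validated instructions step a device by fixed increments (a virtual
robotic arm and prosthetic hand are included, down to the Z-dependent
"Down" stepping and the 95 mm aperture clamp).

Alongside the decoder sit two analysis tracks: time-varying effective
connectivity via the generalized orthogonalized partial directed coherence
(gOPDC) of a sliding-window MVAR fit, and an artifact audit that
decomposes recordings (FastICA or per-channel EMD) and labels each
component EMG-dominated when its sample entropy (m = 2, r = 0.2 sd)
exceeds 0.45.

## The synthetic sessions

No public recordings accompany the paradigm, so `synth_config()` /
`generate_session()` produce annotated sessions with the statistical
structure the decoder assumes, and every test runs against them. A trial
is 3 s countdown, 4 s rest, 4 s expression, 4 s relax. The generator
superimposes:

* a stationary background: a stable random MVAR(6) across channels
  (innovation sd 3 uV), low-passed at 30 Hz so its rhythms live where
  resting EEG rhythms do, plus steep `1/f^2`-power noise (8 uV) — this
  gives the connectivity estimators a realistic stationary null and the
  order-selection criterion something to select;
* per class, a narrow-band oscillation (amplitude 14 uV, centre
  frequencies 9–41 Hz, a weak 1.9x harmonic) projected through a
  class-specific unit spatial pattern;
* during expressions, an EMG-like burst: noise with its spectrum dominant
  in 55–95 Hz and a 15% 20–55 Hz leak, a 150 ms raised-cosine onset, slow
  amplitude modulation, weighted onto the six reference channels with a
  class-specific tilt. Slight expressions use gain 1, regular-amplitude
  ones gain 5 (the amplitude ratio is qualitative in the source material;
  5 gives a 25x energy ratio, comfortably past the screening margin);
* during relax, occasional low-frequency frontal transients.

The oscillation amplitude was set so that the spec-level contract holds —
a linear classifier on per-channel band-power features exceeds 80%
eight-class accuracy — with margin; weaker settings (6 uV) leave the
classes insufficiently separable to exercise the decoder at all.

What the generator does *not* emulate: volume conduction and a realistic
forward model, eye blinks, electrode drift and impedance changes,
inter-subject variability, and the empirical sub-50 Hz smoothness of real
amplifier output. That last point matters for the entropy audit: sample
entropy is scale-free, and band-limited stochastic content in (5, 50) Hz
at 1000 Hz scores about 0.5 *regardless of its amplitude*, so synthetic
sub-50 components do not fall below the 0.45 threshold the way smooth real
EEG does. The audit tests therefore assert the reproducible structure —
wide-band (5, 95) regular-expression content scores above threshold and
strictly above the matching (5, 50) slight content, and sub-30 Hz resting
rhythms score below — rather than the absolute sub-threshold claim.
Passing tests show the pipeline's machinery is correct under these
conditions; they do not certify accuracy on real subjects.

## Numerical and design choices

* **Filtering.** Band edges are all the source states; the filter itself is
  a 4th-order Butterworth applied forward-backward (zero phase, so 100 ms
  windows stay aligned), with odd-reflection padding to tame start-up
  transients. Decimation low-passes at 0.45x the target rate before index
  selection.
* **gOPDC.** The spectral transform is
  `A(f) = I - sum_r A_r exp(-i 2 pi f r / rate)` on a 1 Hz grid; the
  measure multiplies the real- and imaginary-part magnitudes of `A_pq(f)`,
  each divided by the quadratic form `a_q^H Sigma_w^-1 a_q` *as printed*
  (no square root; `sqrt_denominator = TRUE` gives the classical variant),
  scaled by `1/lambda_p^2` from the innovation-covariance diagonal.
  Time variation uses sliding-window refits (0.5 s windows) rather than a
  dual-extended-Kalman estimator, which the source only cites; the window
  summaries are what is reported, and they are what sliding windows
  estimate. Baseline thresholds are order statistics (type-1 quantiles),
  and band matrices are max-normalized only at the reporting layer.
* **Sample entropy.** Self-matches are excluded (the standard convention;
  the source is silent), `r` comes from the analyzed sequence's own sd, a
  constant sequence scores 0, and a match-free sequence scores `Inf`.
* **EMD.** Cubic-spline envelope sifting with mirrored boundary extrema, a
  0.2 energy-ratio stop, at most 10 modes; the multivariate noise-assisted
  variant is realized as per-channel ensemble EMD (white-noise assist,
  10% of channel sd) since no multivariate sifting backend exists in the
  supporting stack. FastICA uses symmetric decorrelation with `tanh`
  (default) or Gauss contrast and caps components at the channel count.
* **Network.** The architecture table is silent on the convolution
  activations; ReLU is used (the community default for trainability).
  Inputs are divided by one global scale (the pooled sd of the training
  windows) so the Glorot-initialized layers start in range. Dropout masks
  (0.1 input, 0.1 recurrent) are shared across time steps. 30 epochs with
  best-validation-checkpoint selection; argmax ties break to the lowest
  one-hot index. Training data are balanced by overlap slicing: the
  per-class stride shrinks until every class yields its quota.
* **Step D / engine.** The consistency count includes the current label
  and the boundary is inclusive. The history clears on every transition
  and, by default, after each instruction (so a held expression steps the
  device once per refilled buffer rather than every 10 ms). A 3 s
  refractory period follows each state transition: without it, a switching
  expression held longer than one consistency span (about 0.3 s) would
  toggle the interface straight back off. The 3 s value mirrors the
  countdown that separates control phases in the trial timing. Step
  outcomes for a recording are computed in batch and replayed through the
  state machine — the staged logic has no feedback from state into the
  signal, so this is exactly the per-window loop, only faster.
* **Problem sizes.** The bundled tests train the network once at 400
  windows per class for 30 epochs (the benchmark condition), evaluate on
  held-out sessions generated with fresh seeds, and run the scripted
  switch-on / operate / switch-off scenario over 10 seeds. Parameter
  recovery uses 20 000-sample realizations; entropy oracles use sequences
  up to 200 samples.

## Known limitations

* The paper's subject-level numbers (96.46% switch-on accuracy, 89.48%
  validation accuracy, the online IoU and water volumes) characterize its
  participants; nothing here re-estimates them, and synthetic benchmarks
  should not be read as claims about real-subject performance.
* The exact time-varying MVAR estimator behind the reported dynamic
  connectivity is unspecified in the source; sliding-window refitting is a
  stand-in with coarser temporal resolution.
* FastICA on strongly band-limited (near-Gaussian) inputs can fail to
  converge; the error is reported with the iteration count rather than
  silently retried.
* The EDF reader covers the continuous 16-bit single-record-layout subset
  of the format used for interchange here, not EDF+ annotations.
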