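---
title: "Graph embeddings for motor-imagery EEG classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph embeddings for motor-imagery EEG classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor imagery — the mental rehearsal of a movement without executing it —
produces classifiable patterns in scalp EEG, and decoding them is the core of
non-invasive brain-computer interfacing. The canonical benchmark geometry is
a 22-channel, 250 Hz recording with 4-second task epochs and four imagery
classes (left hand, right hand, feet, tongue). Two kinds of structure in such
recordings carry class information:

* **spatial (structural) structure** — which electrodes are neighbours on the
  scalp, and how task-related power changes (event-related
  desynchronization/synchronization, ERD/ERS) distribute over the sensorimotor
  electrodes C3, Cz, C4;
* **functional structure** — phase synchronization between channels,
  irrespective of scalp distance.

`graphmi` implements one classifier for each view, plus everything needed to
evaluate them: a structural graph embedding followed by a wide-kernel CNN, and
a phase-locking-value (PLV) connectivity embedding followed by a compact 2-D
CNN.

## The structural pathway

The montage is fixed as a 2-D grid of electrode cells; two electrodes are
connected when their cells are vertical, horizontal or diagonal neighbours
(Chebyshev distance 1), so an interior electrode such as Cz has exactly eight
neighbours and boundary electrodes have fewer. With binary adjacency $A$ and
$\tilde A = A + I$, the propagation operator is the spectral normalization

$$\hat A = \tilde D^{-1/2}\, \tilde A\, \tilde D^{-1/2},
\qquad \tilde D = \mathrm{diag}(\textstyle\sum_j \tilde A_{ij}),$$

whose eigenvalues lie in $[-1, 1]$ and whose entry $(i,j)$ is
$\tilde A_{ij}/\sqrt{\tilde D_{ii}\tilde D_{jj}}$. Each trial
$X \in \mathbb{R}^{22\times 1000}$ is embedded as $G = \hat A X$: every
channel becomes the degree-weighted average of itself and its grid
neighbours, which denoises spatially smooth activity at the cost of mixing in
neighbour content.

The classifier is a single valid convolution whose kernel spans the full
channel axis (22 × 45, stride 2 × 2, 64 filters, ReLU), followed by 1 × 50
max pooling over time, dropout 0.25 and a softmax head; on a 22 × 1000 input
the feature chain is 1 × 478 × 64 → 1 × 9 × 64 → 576. Its canonical regime is
Adam at learning rate $10^{-4}$, batch 128, up to 1000 epochs with early
stopping (patience 250) on a stratified 10 % validation split carved from the
training folds.

**Input scaling.** Signals are standardized per trial before embedding, using
one mean and standard deviation pooled over all channels (`scale = "global"`).
We deliberately do not z-score per channel: ERD/ERS is a *cross-channel power
topography*, and per-channel scaling would flatten exactly the feature this
classifier exists to read. Per-channel scaling remains available
(`scale = "channel"`) for workloads where the topography should be ignored,
and `scale = "none"` supports exact-arithmetic tests. All statistics are per
trial, so nothing leaks across cross-validation folds.

## The functional pathway

Each trial is band-pass filtered (zero-phase, order-4 Butterworth applied
forward-backward) into one of the packaged bands — broadband 1–51 Hz, δ 1–4,
θ 4–8, α 8–12, μ 8–13, β 12–30, the sensorimotor 8–30 Hz range, γ 30–51 —
and each channel's instantaneous phase $\varphi_i(t)$ is taken from the
analytic signal (FFT construction of the Hilbert transform). The
phase-locking value between channels $i$ and $j$ is the time-averaged unit
phasor magnitude

$$\mathrm{PLV}_{ij} = \frac{1}{M}\left|\sum_{t=1}^{M}
  e^{\,\mathrm{i}(\varphi_i(t)-\varphi_j(t))}\right| ,$$

with $M$ the number of retained samples: 1 for perfect synchrony, about
$\sqrt{\pi}/(2\sqrt{M})$ for independent phases, symmetric, unit diagonal,
invariant to per-channel amplitude and to common phase offsets. By default
0.5 s (125 samples) is trimmed from each epoch edge before averaging to
suppress filter and Hilbert edge artifacts; `edge_trim = 0` recovers the raw
estimator for arithmetic tests. The trial is thus summarized as a dense
22 × 22 connectivity matrix — no edge thresholding; the weights are the
input. One model is trained per band.

Broadband (1–51 Hz) PLV is computed identically, but the phase of a
broadband signal is physically ambiguous; the band is retained for
completeness and its output should be read with that caveat.

The classifier is a compact 2-D CNN: conv 3 × 3 × 32 (ReLU) → max pool 2 × 2
→ conv 3 × 3 × 64 (ReLU) → dropout 0.25 → flatten (4096) → softmax; canonical
regime Adam $10^{-3}$, batch 64, 800 epochs, no early stopping.

## The CNN engine

Both architectures are expressed as data (`model_spec`) and validated by
symbolic shape propagation before any weights exist. The training and
inference engine is implemented in the package — unpadded convolutions and
max pooling as compiled im2col + BLAS kernels, with dense, dropout, softmax
cross-entropy and Adam in R. A finite-difference gradient check over every
layer kind is part of the test suite. Weight initialization is He-normal for
ReLU convolutions and Glorot-normal for the dense head, under a recorded
seed; a fixed seed reproduces weights, batch order and dropout masks exactly.

## Evaluation machinery

`make_folds()` builds class-stratified $k$-fold partitions (fold sizes per
class within ±1) for each of several runs, every run re-randomized under a
seed derived from the master seed; trials from all pseudo-subjects mix within
folds. `run_cv()` trains one model per (run, fold) cell and reports accuracy,
macro/micro F1, macro/micro precision and one-vs-rest ROC-AUC (macro =
unweighted class mean, micro = pooled), plus the standard deviation of
fold-level accuracies pooled across runs — the single SD convention used
everywhere in the package's tables. For single-label multiclass predictions
micro-F1 = micro-precision = accuracy identically; the implementation
preserves that identity exactly and the tests assert it. ROC curves come
from `pROC`; a fold missing a class yields an undefined AUC, which is
flagged rather than silently dropped. The canonical evaluation is 9-fold ×
15 runs; desk-scale work uses 3-fold × 1 run.

`hyperparameter_grid()` sweeps filter counts and kernel sizes (packaged
grids: 32/64/128/256 filters at 22 × 45; kernel widths 22/45/65/85; and the
eight-row PLV grid crossing filter pairs (8,16)…(256,512) with 2 × 2 and
3 × 3 kernels), marking failed configurations and flagging the best row by
accuracy.

## The synthetic generator

Real benchmark recordings cannot be redistributed, so the package ships a
generator that emulates the study geometry (22 channels on the same montage,
250 Hz, 4 s, four classes, 9 pseudo-subjects round-robin; 648 trials/class at
full scale) with two planted, analytically tractable mechanisms:

* **Phase coupling** (`"plv-separable"`): per class, chosen channel pairs
  share one band-limited oscillator; each member receives slow Gaussian
  phase jitter of variance $\sigma^2/2$ (AR(1), lag-1 correlation 0.95), so
  the pair's phase difference has variance $\sigma^2$ and its large-sample
  PLV tends to $e^{-\sigma^2/2}$ in the noise-free limit. The "strong"
  preset uses $\sigma = 0.3$ and distinct pair sets per class.
* **Power topography** (`"erd-separable"`): coherent scalp patches (centre
  plus grid neighbours at half amplitude) around C3, C4 and Cz, with the
  patch oscillator power scaled ±50 % by class (one damped patch per
  hand/feet class, both hand patches raised for the tongue class). Patch
  coherence mimics the spatial smoothness of scalp EEG and is what makes
  the neighbourhood-averaging embedding useful rather than harmful.

Oscillators are not pure tones: instantaneous frequency is the band centre
(default 12 Hz) plus a per-trial uniform offset (±3 Hz) and a slow AR(1)
drift (0.3 Hz marginal SD). The offset spread was chosen so that independent
oscillators decorrelate within a trial (empirical uncoupled-pair PLV ≈
0.10–0.15 at 750 retained samples); narrower spreads leave occasional
near-degenerate frequency pairs and inflate the baseline. Background noise
is an even mix of 1/f ("pink") and white noise, normalized to unit total
variance; `snr_db` sets oscillator power relative to that *total* broadband
noise power (default 0 dB), which corresponds to an in-band SNR of roughly
7 dB in the 8–30 Hz range.

`planted_oracle()` returns the closed-form expectation of the *measured*
class-mean PLV matrix: the jitter factor $e^{-\sigma^2/2}$ times, per
channel, the mean resultant length of the Rice phase distribution at that
channel's in-band SNR,
$R(\rho) = \tfrac{\sqrt{\pi\rho}}{2} e^{-\rho/2}
\left[I_0(\rho/2) + I_1(\rho/2)\right]$,
with the in-band noise power computed exactly from the generator's own
spectral weights. The parameter-recovery test requires empirical class means
to match this oracle within ±0.05 on coupled entries.

**Measurement design for the jitter closed form.** Phase jitter is a
*modulation*: its spectrum appears as sidebands around the carrier. At
$\sigma = 1$ the sidebands span roughly ±16 Hz, which cannot fit around a
12 Hz carrier inside any causal band — the filter would clip part of the
jitter and bias the measured PLV upward. The closed-form recovery test
therefore plants the coupled pair on a 25 Hz carrier and analyses the
broadband 1–51 Hz output, where the sidebands survive; the residual upward
bias from time-averaging a correlated phasor (≈ +0.03 at $\sigma = 1$, 750
samples) stays within the ±0.05 band. At the preset $\sigma = 0.3$ the
effect is negligible and recovery is tested in the 8–30 Hz band under full
noise.

**What the generator does not emulate:** volume conduction through a
realistic head model, eye/muscle artifacts, non-stationary drifts across a
session, inter-subject variability (pseudo-subjects are i.i.d.), and any
waveform asymmetry of real sensorimotor rhythms. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers the structures it is
designed to read at realistic SNR — not that the reported accuracies
transfer to any particular real recording.

## Desk-scale study conditions

The packaged end-to-end checks run the full pipeline at a reduced but fixed
scale, chosen once as the study conditions for this package:

* datasets of 200 trials/class (800 trials), the presets above, seeds fixed
  in the tests;
* 3-fold × 1-run cross-validation;
* PLV classifier: 30 epochs at the canonical learning rate $10^{-3}$,
  batch 32;
* structural classifier: 40 epochs at learning rate $10^{-3}$, batch 32 —
  the canonical $10^{-4}$/1000-epoch regime is impractical at desk scale, so
  the learning rate is scaled up by the same order the epoch budget is
  scaled down; batch 32 keeps enough optimizer steps per epoch at 533
  training trials;
* ablation baselines trained at the same scaled settings on the same folds.

Expectations under these conditions (asserted by the acceptance tests): the
PLV classifier reaches ≥ 90 % on `"plv-separable"` (observed: 100 %); the
structural classifier reaches ≥ 80 % on `"erd-separable"`; label-shuffled
controls sit at chance (25 % ± 5 %); removing the PLV graph embedding
(feeding band-passed raw trials to a matched CNN) costs ≥ 10 accuracy
points, because phase coupling is invisible to waveform-level features.

## Numerical choices and degenerate inputs

* Valid (unpadded) convolutions everywhere; pooling stride equals pool size;
  partial pooling windows are dropped (478 → 9 at pool 50).
* Filters: order-4 Butterworth, `filtfilt` for zero phase; band edges at or
  above Nyquist are rejected.
* The analytic signal of an all-zero (or constant) channel is undefined and
  raises an error rather than returning NaN phases.
* PLV entries are clipped to [0, 1] against rounding; diagonals are set to
  exactly 1.
* The adjacency normalization validates symmetry, binarity and zero
  diagonal; a single isolated node normalizes to [1].
* AUC with a class absent from the truth is NA and flagged
  (`auc_defined = FALSE`); macro-AUC averages the defined classes.
* Probabilities under the log in the cross-entropy are floored at 1e-12.

## Known limitations

* The no-PLV-graph ablation's layer list is a package adaptation (first
  convolution widened to 3 × 45, stride 1 × 2 over time) — the canonical
  source does not print one; it is flagged `non-canonical` in its spec notes.
* The container format is R-native serialization with a version tag —
  convenient and lossless for workflow artifacts, not a cross-language
  interchange format; matrices export to CSV for portability.
* GDF ingest of real recordings is optional and delegates decoding to
  python-mne when present; the package never downloads data.
* Broadband-phase PLV (the 1–51 Hz band) is retained for completeness
  despite its ambiguous interpretation.
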