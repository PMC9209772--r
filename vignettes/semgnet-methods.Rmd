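---
title: "Methods: multi-stream attention networks for sEMG gesture recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stream attention networks for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgnet)
```

## The problem

Surface electromyography (sEMG) records muscle electrical activity from
skin electrodes — here a 16-electrode forearm cuff sampling at 1000 Hz —
and a gesture-recognition system must map short multi-channel signal
windows to one of up to 52 hand gestures, fast enough for real-time
prosthetic or dexterous-hand control. The signal is weak (microvolts),
broadband (useful energy mostly between 10 and 200 Hz), and contaminated
by 50 Hz power-line interference and low-frequency motion artifact. This
package implements the full pipeline: denoising, electrode pruning,
feature extraction, a 1-D convolutional block attention module (CBAM),
and a multi-stream CNN + GRU classifier with accelerometer (ACC) fusion.

## Preprocessing

Two filters run in sequence on each sEMG channel (never on ACC):

* **Notch.** The ideal trap — unit gain everywhere, zero at ω₀ = 50 Hz —
  is unrealizable, so we use a constrained second-order IIR biquad whose
  zeros sit exactly on the unit circle at ±ω₀. With Q = 30 the −3 dB
  width is about 1.7 Hz, narrow enough to spare the neighbouring signal
  band; the magnitude is exactly 0 at 50 Hz and within a fraction of a
  percent of 1 elsewhere.
* **High-pass.** An order-3 Butterworth with −3 dB turning frequency
  20 Hz, i.e. `|H(jΩ)|² = 1/(1 + ε²(Ωc/Ω)^(2N))` with ε = 1, giving the
  maximally flat passband and an 18 dB/octave (= 6N) stopband slope. The
  digital design (bilinear transform with cutoff prewarping via
  `signal::butter`) tracks the analytic form within 0.4 % over 1–400 Hz;
  ε ≠ 1 is supported by rescaling the effective cutoff to
  `Ωc·ε^(1/N)`.

Filtering defaults to causal single-pass, because the target is a
real-time system whose decision latency budget (window plus inference
under 300 ms) leaves no room for acausal smoothing. A zero-phase
forward–backward option exists for offline analysis; note it doubles the
stopband slope, so the 18 dB/octave property is stated for the causal
path only.

Rectification (elementwise absolute value) is applied when building the
amplitude-sensitive features, not in the raw-window path fed to the
network — the filtered signal is the network's input so that phase
structure survives for the convolutions.

Per-channel standardization uses training-set mean and standard deviation
only; the fitted statistics are stored and reapplied at inference.
Zero-variance channels fall back to a unit divisor with a warning.

Decision windows default to 200 ms with a 100 ms stride. The recordings
give no canonical window length, so this is our choice: 200 ms of signal
plus small-model inference keeps the end-to-end delay under a 300 ms
real-time budget, and 100 ms overlap doubles the training set without
letting any window cross a segment boundary.

## Redundant-channel ranking

Some forearm electrodes barely modulate with gesture and only add data
volume. The pruning statistic operationalizes "variance of the signal
values of different actions against a rest benchmark" as:

1. per channel *c* and gesture *k*, the RMS of the filtered action
   segments, averaged over repetitions;
2. subtraction of the channel's rest-segment RMS (the motionless-arm
   benchmark);
3. the variance of these rest-corrected activations across gestures.

A channel whose activation is the same whatever the gesture scores near
zero and is maximally redundant. RMS is the standard sEMG activity level;
note RMS is unchanged by rectification, so the statistic can be computed
on the signed filtered signal. Channels are binned into `n_levels = 8`
ascending-score quantile grades (matching the 8-fold granularity;
channels with equal scores share a grade) and weights are the reversed
grades — simple ordinal ("sequencing") coding positively correlated with
redundancy. The whole scoring runs once per held-in portion of an 8-fold
repetition-level cross-validation, and fold weights are aggregated by
arithmetic mean. Removal takes the `n_remove = 10` highest-weight
channels (ties: lower electrode id first), leaving 6 of 16.

The exact statistic, the grade-to-weight coding, and the fold-aggregation
rule are design choices of this package — redundancy-pruning procedures
of this kind are usually described only loosely — and they are isolated
behind `compute_redundancy_scores()` / `grade_and_weight()` /
`crossval_aggregate()` so any piece can be swapped.

## Window features

Per channel and decision window (order fixed): integrated EMG
`IEMG = Σ|xᵢ|`; the second-moment variance `VAR = Σxᵢ²/(N−1)` — as
printed, without mean subtraction; on high-passed, near-zero-mean signal
the difference from the sample variance is negligible, and the raw-moment
form is kept deliberately; the median frequency MDF, the smallest
frequency at which the inclusive cumulative one-sided periodogram first
reaches half the total power (rectangular window, no taper; an exact
half-total tie resolves to the lower bin); and the frequency ratio
`FR = Σ P between LLC..LHC / Σ P between HLC..HHC`, low band over high
band as the formula states (even though this family of features is often
*named* a high-to-low ratio). Band edges are nowhere specified by the
method; the defaults LLC/LHC = 20/45 Hz and HLC/HHC = 95/450 Hz are a
common low/high sEMG split inside the 0–500 Hz bandwidth and are fully
configurable via `band_edges()`.

## One-dimensional CBAM

For a feature map `F ∈ ℝ^{T×C}` (T time frames, C feature channels):

* **Channel attention.** Average- and max-pool over time to two `1×C`
  descriptors; pass both through a *shared* two-layer perceptron with a
  `C/r` bottleneck; sum and squash: `M_C = σ(W₁W₀F_avg + W₁W₀F_max)`.
* **Temporal attention.** Average- and max-pool over channels to two
  `T×1` descriptors, stack as 2 input channels (order: average, max), and
  convolve with a length-3 kernel under same-length zero padding:
  `M_T = σ(f₃ₓ₁[F_avg; F_max])`.
* **Composition**, channel first: `F′ = M_C ⊗ F`, `F″ = M_T ⊗ F′`.

Since σ maps into (0,1) the module can only attenuate (`|F″| ≤ |F|`
elementwise), and `M_C` is invariant to permuting time frames while `M_T`
is invariant to permuting feature channels — both are tested properties.

Open details resolved as design choices: a rectifier after W₀ (standard
for this module family; the compact description omits it), biases in the
shared perceptron disabled by default (`cbam_mlp_bias` re-enables them),
compression rate r = 8 with C required to be a multiple of r. One block
adds exactly `2C²/r (+ C/r + C biases) + 7` parameters
(`cbam_param_count()`).

## The multi-stream classifier

Each retained electrode is one network branch; the 3-axis ACC window is
one extra branch joining at the aggregation layer. A branch is: Conv1D
blocks (default two: 32 then 64 filters, kernel 3, stride 1, same
padding) → batch normalization → ReLU, with the CBAM inserted after the
last ReLU, then a GRU (hidden 64) consuming the attended map as a T-step
sequence, its last hidden state becoming the stream vector. Without the
GRU the stream vector is the global time-average of the conv features —
this is how the "global average pooling" of the aggregation stage is
realized on the conv path, while GRU streams already emit a pooled
vector; the fully-connected head (dropout p = 0.5, then softmax of size
M) is identical in both cases. Decision:
`p(m|g) = exp(g_m)/Σⱼ exp(g_j)`, `m₀ = argmax p(m|g)` with the lowest
index winning ties.

No layer sizes, optimizer, or schedule are prescribed anywhere for this
architecture family, so the defaults are chosen small enough to train on
one desktop CPU core in minutes and are all configurable: Adam with
lr 10⁻³, batch 64, cross-entropy. The entire network — convolutions (via
im2col + BLAS), batch norm, CBAM, GRU (fused-gate BPTT), dropout, Adam —
is implemented in base R with hand-written backpropagation; the test
suite validates every layer's analytic gradient against central finite
differences at 10⁻⁵ relative tolerance, and the vectorized CBAM against
a pure-loop reference at 10⁻⁶.

The five ablation variants toggle exactly `use_bn`, `use_cbam`,
`use_gru`: I multi-stream conv, II +BN, III +BN+GRU, IV +BN+CBAM,
V +BN+CBAM+GRU. `param_manifest()` exposes every tensor's shape so the
structural claim — variants differ only in their stated components — is
machine-checkable. Ablations run sEMG-only (no ACC branch), matching how
such comparisons are customarily performed.

## Synthetic data: what it emulates, and what it does not

`simulate_recording()` produces, per channel, an amplitude-modulated
band-limited Gaussian carrier: white noise filtered by an order-4
10–200 Hz band-pass, multiplied by a per-class × per-channel gain under a
trapezoidal activation envelope (0.5 s rise/fall), plus a broadband noise
floor, additive 50 Hz sinusoidal interference, and sub-5 Hz drift (two
slow sinusoids with random phases). Actions alternate with rest, every
action is annotated, and the generator is a pure function of its
specification, seed included. ACC axes get class-specific smooth
low-frequency trajectories plus noise. Redundant electrodes are planted
by zeroing amplitude-matrix columns.

Defaults follow the acquisition protocol this pipeline targets: 16
channels, 1000 Hz, 10 s actions, 15 repetitions, 50 Hz line. The
*easy-mode* spec used by the fast end-to-end checks is deliberately
smaller and friendlier: 5 classes on 6 channels with nearly orthogonal
activation profiles (one dominant electrode per class), 2 s actions,
5 repetitions. With it, the default model reaches ≥ 90 % held-out window
accuracy within three epochs. That demonstrates the pipeline is wired
correctly end to end — it does **not** demonstrate real-world accuracy:
the amplitude-modulated-noise model has no motor-unit action potentials,
no electrode-shift or fatigue nonstationarity, no cross-channel
correlation (an optional mixing is not modelled; channels are
independent), and class separability is by construction far cleaner than
between, say, two thumb movements that differ only in direction.
Published headline accuracies on real 52-gesture recordings are therefore
out of reach of — and out of scope for — this synthetic harness.

Problem sizes used by the test suite (short actions, few repetitions,
4-gesture redundancy fixtures, 20-seed recovery runs) are scaled to keep
the whole suite in the low minutes on one CPU core while leaving every
statistical property testable.

## Numerical choices and degenerate inputs

* Sample indexing is 0-based with half-open event windows `[onset,
  offset)`; recordings are CSV + JSON sidecar, floats printed at 15
  significant digits so round trips are value-exact and byte-stable.
* Missing accelerometer data is represented as an all-zero ACC block plus
  a `has_acc = false` sidecar flag, keeping the fusion contract uniform.
* Windowing drops a trailing remainder shorter than the window; a window
  longer than its segment yields an empty list with a warning.
* MDF of an all-zero window and FR with a numerically empty high band
  (≤ 10⁻¹² of total power) are errors, not infinities.
* Redundancy scoring requires ≥ 2 distinct gestures and ≥ 1 rest
  segment; `k_folds` may not exceed the number of repetitions.
* Argmax ties (class decision, max-pooling backward routing) resolve to
  the lowest index / first occurrence; quantile grade bins collapse
  duplicated break points so all-equal scores share one grade.
* Training requires every class present; seeded runs are reproducible
  bit-for-bit (shuffling, dropout and initialisation all flow through
  one seed).

## Known limitations

* Pure-R training is practical for the desk-scale models it targets
  (hundreds of thousands of parameters, minutes per run), not for
  full-scale benchmark replication.
* Batch norm uses per-batch statistics with running-average inference
  estimates; very small final batches give noisy updates.
* The redundancy statistic assumes activation differences are visible in
  RMS; gestures distinguished purely by timing patterns at equal power
  would defeat it.
* The CLI reads one recording per directory for train/eval; multi-session
  merging is left to the R API.
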