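---
title: "Methods: sEMG gait-phase identification with compact sequence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG gait-phase identification with compact sequence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem

Assistive lower-limb exoskeletons need to know, online and a little ahead of
time, whether the wearer's leg is in stance (foot on the ground) or swing
(foot in the air), so that joint torques can be modulated to follow the
wearer's intent. Surface EMG is attractive for this because muscle activation
*leads* the movement it produces by roughly 100–200 ms: a classifier reading
EMG can, in principle, announce the next phase transition before the
kinematics show it.

`gaitphase` implements a complete methodology for this task: frame-wise
stance/swing sequence labeling of four-channel sEMG (Biceps Femoris,
Tibialis Anterior, Vastus Lateralis, Soleus) recorded at 1500 Hz during slow
exoskeleton-assisted walking, with hip and knee flexion angles providing the
labeling ground truth. Because clinical sEMG recordings of this kind are not
publicly redistributable, the package ships a synthetic generator with the
statistical structure the pipeline assumes, so that every stage is testable
end to end from code alone. What a passing test suite shows — and does not
show — about real data is discussed at the end.

## Synthetic gait generator

`simulate_subject()` builds one subject's recording from a configurable gait
cycle (`gait_sim_config()`):

* **Kinematics.** The knee angle follows a low stance plateau (~5°, with a
  small loading-response bump) and a ~55° swing excursion; the hip oscillates
  between +25° at heel-strike and −20° in late stance. Stance/swing
  transitions are deliberately fast (~3% of a cycle, ~50 ms at the default
  35 strides/min cadence). Angles are generated directly at 1500 Hz; the
  step-wise structure that a real 100 Hz-upsampled IMU stream would show is
  not emulated.
* **Ground-truth events.** True heel-strike and toe-off indices are defined
  as the hysteresis crossings of the noise-free knee angle (30° upward for
  toe-off, 15° downward for heel-strike). Anchoring truth to the same
  crossing rule the detector uses makes detector validation exact and, with
  the transition placement chosen here, keeps the realized stance fraction
  within ±0.5% of the configured `stance_fraction` (default 0.60, standard
  physiology for slow gait).
* **Muscle envelopes.** Each muscle gets one raised-cosine activation bump
  per cycle at its physiological phase (BF terminal swing/loading, TA around
  heel-strike, VL loading into mid-stance, SOL late-stance push-off). Every
  bump's onset precedes its kinematic event by exactly `lead_ms`
  (default 120 ms) — the anticipatory property the shifted labeling exploits.
  The recording keeps its envelopes as ground truth, because onset timing
  cannot be recovered to single-frame precision from the EMG itself (a
  raised cosine leaves zero slope at onset).
* **EMG synthesis.** Each channel is its envelope multiplying zero-mean white
  Gaussian noise at MVIC scale, plus additive baseline noise. This is the
  simplest model with the two properties the pipeline relies on — zero-mean
  carrier before rectification, amplitude structure recoverable by
  rectify-and-smooth. It makes no attempt at motor-unit realism, spectral
  shape, or electrode artifacts.
* **Heterogeneity.** `simulate_cohort()` derives per-subject seeds, ±10%
  cadence jitter and lognormal per-muscle gain jitter (sd 0.2 on the log
  scale) from one master seed. Gains are *not* reflected in the recorded
  MVIC references, so they survive normalization, giving leave-one-subject-out
  validation something real to generalize over.
* **Quiet standing.** Bouts requested in `quiet_bouts` are spliced in as
  low-variance angles with baseline-only EMG.

## Preprocessing

`preprocess_pipeline()` applies, in order: full-wave rectification; a
first-order Savitzky–Golay filter with a 39-sample window; division by the
per-muscle MVIC reference; and 3:1 decimation from 1500 Hz to 500 Hz by
keeping every third sample (no anti-aliasing filter — the smoothed envelope
is already far below the target Nyquist). Angles pass through un-rectified
and un-normalized, decimated by the same selection so frames stay aligned.

Numerical choices: smoothing delegates to `signal::sgolayfilt()`, whose edge
rule fits the first/last full window and evaluates it at the off-centre
positions; interior samples — the only ones the correctness oracles check —
equal the explicit per-window least-squares fit. Decimation starts at the
first sample. Scaling a channel together with its MVIC leaves the output
unchanged (a tested invariant).

## Labeling, anticipatory shift, and windowing

Quiet standing is removed first. `detect_quiet_standing()` flags spans where
the rolling standard deviation of both joint angles stays below 0.5° over a
1 s window. This replaces the hidden-Markov-model segmenter used on the
original recordings, whose parameters are not public; the two regimes differ
by an order of magnitude in angle variance, so a threshold rule separates
them cleanly, and the detector is pluggable for anyone wanting an HMM.

`detect_gait_events()` then emits toe-offs at upward crossings of the knee
angle through 30° and heel-strikes at downward crossings through 15°. The
hysteresis pair enforces strict alternation; a light Savitzky–Golay smoothing
(order 3, 21 frames) suppresses sensor noise before thresholding. The
thresholds are validated against the simulator's ground truth (exact on
clean input; median error ≤ 5 frames at 0.5° angle noise), not against any
external dataset.

`events_to_labels()` assigns stance to `[HS, TO)` and swing to `[TO, HS)`,
frames before the first event taking the class consistent with it.
`shift_labels()` implements the anticipatory variant: `out[t] = in[t + 60]`
(120 ms at 500 Hz), dropping the final 60 frames rather than padding —
padding would fabricate labels. `make_sequences()` cuts 500-frame (1 s)
windows every 50 frames (90% overlap, 10 Hz update rate) and one-hot encodes
labels to 2×500 arrays with class order [stance, swing]. Windows never span
a removed quiet bout: segments are windowed independently, the conservative
choice when overlap across deleted spans would mix unrelated gait context.

## Architectures and parameter accounting

`model_spec()` describes a network as an ordered layer list from which both
the exact parameter count (`count_parameters()`) and the runnable network
(`instantiate_network()`) derive — one declaration, two independently
testable consumers. The five architectures:

| builder | structure | parameters |
|---|---|---|
| `build_full_bilstm()` | BiLSTM 200/100/100/100 + dense 100/50/25 | 1,236,877 |
| `build_small_bilstm()` | BiLSTM 100/50 | 184,602 |
| `build_gru()` | GRU 100/50 | 54,252 |
| `build_res_tcn()` | 3 residual blocks, 2 dilated convs each, 64 filters, k = 37 | 768,834 |
| `build_attention()` | 16-head self-attention, 256 QKV channels, dense 128 frame | 149,890 |

Counting conventions: one bias vector per recurrent gate set (4h per LSTM
direction, 3h per GRU) — the only convention consistent with all the counts
above; dense `h(i+1)`; conv `k·c_in·c_out + c_out`; layer norm `2·channels`;
attention `3(D·i+D) + (i·D+i)` including the output projection back to the
128-channel stream. Counts are *truncated*, not rounded, when displayed in
k/M units (`format_parameter_count()`); that is the only rule consistent
with displaying 54,252 as "54.2 k" alongside 994,852 as "994 k".
`memory_footprint()` assumes 32-bit storage.

The Res-TCN kernel comes from a receptive-field design rule:
`receptive_field(c, b, N, k) = 1 + c(b^N − 1)(k − 1)` for `N` blocks of `c`
stride-1 convolutions where block `j` dilates by `(b−1)·b^(j−1)` (the
standard 1, 2, 4 schedule at basis 2). `select_kernel(500, 2, 2, 3)` returns
37, for a receptive field of 505 frames — the closest attainable to the
500-frame windows. The formula is verified against empirical dependency
tracing (perturb one input frame of an instantiated stack, count affected
outputs) over a grid of small configurations.

Ambiguities resolved as design choices: convolutions are centred
("same"-padded), not causal — classification is offline within each window,
so there is no causality constraint, and centred padding keeps residual adds
shape-compatible; the attention model mirrors its dense+ReLU+dropout(0.4)
stack on both sides of the attention block; dropout inside recurrent stacks
follows each recurrent layer with probability 0.6.

## Training engine

No deep-learning framework is attached: the package carries its own
RcppArmadillo engine (`src/nn.cpp`) implementing forward and
backpropagation-through-time for dense, sigmoid/ReLU/softmax, dropout,
spatial dropout, layer normalization, dilated 1-D convolution, residual
blocks, BiLSTM and GRU layers, with data laid out as (channels × batch ×
time) cubes so each time step is one BLAS GEMM over the whole batch. Every
layer's analytic gradient is checked against central differences in the test
suite (worst absolute error below 1e-7 on probe networks). Weights
initialize Glorot-uniform with forget-gate biases at 1; all randomness
(initialization, shuffling, dropout) flows from one engine seed, so training
is bit-reproducible.

`train_config()` carries the training recipe used throughout: Adam, up to 60
epochs, initial learning rate 4e-4 multiplied by 0.9 every 2 epochs, batch
size 128, early stopping after 10 validation checks without improvement
(interpreted as one check per epoch — the natural reading when validation is
evaluated per epoch), best-validation weights restored. The "binary
cross-entropy" loss is implemented as per-frame two-class categorical
cross-entropy under the final softmax — mathematically identical for one-hot
two-class targets.

The self-attention layer supports forward passes, parameter counting and
export, but not training: the models the optimization pipeline actually
trains are all BiLSTM-family, and training attention at 500 frames would
need O(T²·heads·batch) activation caches for no tested benefit.
`train_model()` on an attention spec raises a clear error.

Evaluation (`evaluate()`) pools per-frame argmax predictions over all test
windows into one 2×2 confusion matrix and reports percent accuracy and
per-class F-scores. `best_of_seeds()` mirrors the convention of reporting
the best of three seeded runs; selecting on test accuracy is optimistically
biased, so the API equally accepts validation-based reports.

Cross-validation: `split_kfold()` randomizes over *sequences* (the natural
contrast to subject-level splitting), `split_loso()` holds out whole
subjects, `split_cross_subject()` reproduces a fixed 23–3-style subject
split. The validation set for a cross-subject run is a seeded random 10% of
training sequences, since early stopping and the optimization objective both
need one.

## Bayesian hyperparameter optimization

`build_pruned_bilstm(M, P)` is the two-hyperparameter family: BiLSTM layers
of 2P/P/P units, dense layers of 2M/M units, 60% dropout throughout. The
search box M ∈ [15, 50], P ∈ [20, 100] caps the largest layers at the full
reference model's widths.

`bayes_optimize()` maximizes the objective with a Gaussian-process surrogate
(ARD Matérn 5/2 kernel; length scales, signal and noise variance refit by
L-BFGS-B marginal-likelihood maximization after each trial from two fixed
starts) and expected improvement evaluated *exhaustively* over the 36×81
integer grid — with at most 30 evaluations there is no reason to optimize
the acquisition approximately, and grid evaluation makes the integer
handling trivial: proposals are grid points, and a proposal colliding with
an evaluated point falls back to the nearest unevaluated one. Four
Latin-hypercube points seed the model. The "plus" safeguard: when the
acquisition maximum is negligible (the surrogate is confident everywhere),
the proposal switches to the unevaluated point of highest posterior standard
deviation. The reference acquisition this emulates is proprietary, so this
safeguard is documented and parameter-free rather than a reproduction.
Failed objective evaluations are recorded as failed trials and the search
continues. On a deterministic quadratic objective the 30-trial search lands
on the optimum for every tested seed.

`optimize_pruned()` plugs in "validation frame accuracy of the trained
pruned model" as the objective and attaches the best fitted model to the
returned trace.

## Trade-Off Score

Model selection balances accuracy against size relative to a reference
model. With candidate/reference accuracies `Ac, Ar` (%) and parameter counts
`Pc, Pr`:

* accuracy delta `Ad = Ac − Ar`;
* parameter variation `Pv = 100(Pc − Pr)/Pr`;
* logistic compression `Pvc = 2L/(1 + exp(α·Pv)) − L`, mapping any `Pv` into
  `(−L, L)` with slope α (defaults L = 1, α = 0.05);
* score `TOS = (Ad + Pvc)/(2L)`, zero for self-comparison, positive when
  shrinking the model is worth its accuracy cost.

Candidates with `Ad < −1%` are excluded outright, always — the floor is a
hard admission rule, applied identically during α-sensitivity re-ranking.
The exponent symbol differs between the defining equations in the source
material, but the worked selection values (0.49, 0.35, 0.37) confirm both
are the same α = 0.05. `TOS` is bounded in [−1, 1] only while `|Ad| ≤ 1`;
the implementation warns beyond that. Reported scores round half away from
zero to two decimals. Ranking ties break toward the smaller model, in
keeping with the metric's complexity-reduction intent.

`alpha_sensitivity()` re-ranks for α ∈ {0.001, 0.005, 0.01, 0.05}: with the
published accuracy/count surfaces, the winner flips from the TOS-preferred
compact models ([15 53] kinematics, [27 57] shifted) to the
accuracy-preferred ones ([50 100], Full-BiLSTM) exactly when α drops
below 0.01.

## Streaming simulation

`run_stream()` emulates deployment: slice 1500 raw samples (1 s), rectify,
smooth, MVIC-normalize, decimate to 500 frames, one forward pass, advance by
150 samples (0.1 s), repeat until the buffer is exhausted; wall-clock time
is recorded around each preprocessing+inference iteration, and the model's
32-bit parameter footprint is reported alongside. Latency numbers are
descriptive only — they depend on hardware and BLAS.

Smoothing is applied within each 1 s window independently, as a streaming
loop must; overlapping frames can therefore differ slightly from
whole-recording batch smoothing near window edges. The equivalence check
(`offline_online_equivalence()`) accordingly compares streamed predictions
against batch preprocessing applied per window, where agreement is exact up
to floating-point evaluation order. MVIC normalization happens inside the
loop, matching the batch pipeline's order. Models cross the
training/deployment boundary through a plain-text checkpoint
(`save_network()`/`load_network()`): a JSON architecture plus a
17-significant-digit weight table, loading back bit-identically.

## Problem sizes used by the tests

The heavy end-to-end check trains the (M = 15, P = 53) pruned BiLSTM on a
4-subject synthetic cohort of 12 strides each (≈21 s of gait per subject,
about 840 windows) for up to 5 epochs under the standard optimizer settings,
then evaluates on the held-out fourth subject; it exceeds 85% frame accuracy.
Unit-level training tests use 100-frame windows and tiny recurrent stacks.
The optimizer contract is verified on a deterministic quadratic objective
(5 seeds × 30 trials), keeping the suite's runtime in minutes.

## Known limitations

* The generator's EMG is amplitude-modulated white noise: no motor-unit
  structure, no spectral realism, no crosstalk or motion artifacts. Passing
  tests demonstrate the pipeline's *mechanics* (labeling, shifting,
  windowing, training, selection, streaming) and the separability of
  envelope-coded phases — they say nothing about classification accuracy on
  real sEMG.
* A single global `lead_ms` is exposed rather than per-muscle leads;
  reported anticipation windows in the physiology literature are ranges, not
  per-muscle measurements, and the simulator follows that simplification.
* Self-attention models train nowhere in the package (inference only).
* Event truth is anchored to knee-angle threshold crossings; detectors based
  on other conventions (foot switches, force plates) would shift both truth
  and detection together, not the evaluation of one against the other.
* The quiet-standing detector is a variance threshold, not an HMM; recordings
  whose quiet bouts contain slow postural sway near the threshold would need
  the pluggable detector interface.
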