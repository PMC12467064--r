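# gaitphase

Frame-wise stance/swing gait-phase identification from surface EMG recorded
during exoskeleton-assisted walking — for researchers in rehabilitation
robotics and biomedical signal processing who want a fully testable,
self-contained implementation of the methodology: preprocessing, anticipatory
labeling, compact sequence networks with exact parameter accounting, Bayesian
hyperparameter pruning, Trade-Off-Score model selection, and an online
streaming simulator.

Muscle activation precedes the movement it produces by 100–200 ms. The
package exploits this by advancing the kinematics-derived stance/swing labels
by 120 ms (60 frames at 500 Hz), so a classifier over four sEMG channels
(Biceps Femoris, Tibialis Anterior, Vastus Lateralis, Soleus) predicts the
*upcoming* phase — early enough to derive an exoskeleton torque command.

The core quantities:

* **Receptive-field design rule** for the residual TCN:
  `Rf(c, b, N, k) = 1 + c (b^N − 1)(k − 1)`; `select_kernel(500, 2, 2, 3)`
  returns k = 37, the kernel whose receptive field (505 frames) comes closest
  to the 1 s training sequences.
* **Exact learnable-parameter accounting** from declarative architecture
  specs, validated against the instantiated networks: Full-BiLSTM 1,236,877;
  Small-BiLSTM 184,602; GRU 54,252; Res-TCN 768,834; attention 149,890;
  pruned BiLSTM family `build_pruned_bilstm(M, P)`.
* **Trade-Off Score** for selecting a compact model against a reference:
  `TOS = (Ad + Pvc) / 2L` with `Ad = Ac − Ar` (accuracy delta, %),
  `Pvc = 2L/(1 + e^{α·Pv}) − L` the logistic compression of the parameter
  variation `Pv = 100 (Pc − Pr)/Pr`, defaults L = 1, α = 0.05, and a hard
  −1% floor on `Ad`.

Everything runs on a synthetic exoskeleton-gait generator (cyclic
kinematics, anticipatory raised-cosine muscle envelopes, EMG as
envelope-modulated noise, MVIC scaling, quiet-standing bouts), so no private
recordings are required. See `vignettes/gaitphase-methods.Rmd` for the full
model description and its limitations.

## Worked example

```r
library(gaitphase)

# 1. synthesize a 4-subject cohort and build the windowed dataset
cohort <- simulate_cohort(gait_sim_config(n_strides = 12, seed = 11), 4,
                          master_seed = 11)
ds <- prepare_dataset(cohort, shift_frames = 60)   # anticipatory labeling

# 2. train the compact pruned BiLSTM, leaving subject S04 out
split <- split_loso(ds)[["S04"]]
parts <- validation_split(subset_dataset(ds, split$train), seed = 1)
model <- train_model(build_pruned_bilstm(15, 53), parts$train, parts$val,
                     train_config(max_epochs = 5), seed = 1)

# 3. evaluate on the unseen subject
evaluate(model, subset_dataset(ds, split$test))
#> <eval_report> accuracy 92.17% | F stance 93.89% | F swing 89.08% (108500 frames)

# 4. score the compact model against the full reference
tos(Ac = 93.56, Ar = 93.53,
    Pc = count_parameters(build_pruned_bilstm(15, 53)),
    Pr = count_parameters(build_full_bilstm()))
#> <tos_result> TOS 0.495 (Ad 0.03%, Pv -77.49%, Pvc 0.959)
```

The evaluation line reports pooled per-frame accuracy and per-class F-scores
on the held-out subject, printed by this exact script (the same run with
`shift_frames = 0` scores 87.5% — the anticipatory shift helps on synthetic
data too, since the envelopes lead the events). The TOS line says:
trading the full 1.24 M-parameter reference for the 278 k-parameter pruned
model costs nothing in accuracy (+0.03%) while saving 77% of the parameters,
for a strongly positive trade-off of 0.49.

A command-line interface wraps the same functions
(`inst/exec/gaitphase simulate|preprocess|label|train|optimize|select|stream|all`),
driven by a YAML configuration with strict key checking.

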