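---
title: "Multimodal sleep staging with multisess: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal sleep staging with multisess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical sleep staging assigns one of five AASM stages — wake (W), three
non-REM depths (N1–N3) and REM — to every 30-second window of an overnight
polysomnogram. Different stages express themselves in different signals:
N2 is recognised by EEG spindles and K-complexes, N3 by high-amplitude
delta waves, while REM and N1 have nearly identical EEG and are separated
mainly by the electrooculogram. An automatic stager therefore has to solve
two problems at once: extracting frequency-structured features from each
raw signal, and fusing evidence *across* modalities.

`multisess` implements an end-to-end network for this task on two raw
100 Hz channels (one EEG, one EOG; 3000 samples each per epoch):

1. **Multi-scale convolution (MSCNN).** Each modality passes through two
   parallel filter banks: a long-kernel bank (kernel 50, stride 20, 64
   filters) and a short-kernel bank (kernel 20, stride 5, 64 filters), so
   both slow and fast rhythms get a matched temporal resolution. Each
   branch is conv → ReLU → max-pool(4) → conv → ReLU → max-pool(4).
2. **Squeeze-and-excitation (SE) attention.** Per modality, channels of
   the concatenated multi-scale feature map are rescaled by a gating
   vector `s = sigmoid(W2 relu(W1 z))`, where `z` is the temporal mean of
   each channel and the bottleneck width is `C/r` with reduction `r = 16`.
3. **State-space coupling.** The per-modality feature sequences
   (`D = 128` channels over `T = 7` steps) drive a joint recurrence. At
   each step the layer-normalised input is projected by `B`, a
   pre-activation state `h_n(t) = tanh(Σ_m h_m(t−1)·S_n + B x̃_n(t))` is
   formed from the summed previous states, scaled-dot attention
   `α_nm ∝ exp(h_n·h_m/√H)` between the fresh states is computed, and the
   update is redone with the attention-weighted mixture of previous
   states. Final states are projected by `E` and fused as
   `Y = (1/M) Σ_n W_n Y_n` with learned scalar weights `W_n`.
4. **Head.** Two fully connected layers (width 64, ReLU, dropout 0.5
   between them) and a softmax over the five stages.

Training uses Adam (learning rate 0.001), minibatches of 128 by default,
and class-weighted cross-entropy with inverse-frequency weights recomputed
on each training fold — N1 is rare (≈ 6–7 % of epochs) and would otherwise
be ignored. Evaluation is five-fold cross-validation *across subjects*:
folds partition subjects, never epochs, so test subjects are never seen
during training.

## Reading real recordings

`load_recording()` / `prepare_recording()` read EDF signal files and EDF+
hypnograms with the conventions used by Sleep-EDF style datasets:

* channels are selected by label (default `EEG Fpz-Cz` + `EOG horizontal`,
  matching the two-modality design; the second EEG channel, Pz-Oz, is not
  used by default but any channel set can be requested);
* a requested channel at a rate other than 100 Hz is an error — no silent
  resampling;
* R&K labels map to AASM: stages 3 and 4 merge into N3; MOVEMENT and
  UNKNOWN epochs are excluded;
* only 60 epochs (30 minutes) of wake on each side of the sleep period are
  kept (`trim_wake_margin()`); the margin is counted in epochs, applied on
  the mapped label sequence before excluded epochs are dropped, so
  excluded epochs inside the kept range are still removed;
* the epoch grid is anchored at annotation onsets and partial trailing
  windows are dropped.

Each epoch is z-scored per channel by default. No band-pass filtering or
artifact rejection is applied; absolute µV scale varies strongly across
subjects and electrodes and would otherwise dominate the early
convolution layers, while the stage information lives in spectral shape.

## The synthetic cohort

Real Sleep-EDF nights require a PhysioNet download, so the package ships a
generator (`synth_dataset()`) whose output has the statistical structure
the model relies on, with known ground truth:

* per-stage recipes place textbook rhythms in each channel — alpha with
  ocular deflections for W, theta with slow rolling eye movements for N1,
  theta plus 13 Hz spindle bursts and K-complexes for N2, high-amplitude
  delta for N3, low-amplitude theta with large saccadic EOG deflections
  for REM — plus white noise;
* stage proportions default to the Sleep-EDF-20 mix (19.6 / 6.6 / 42.1 /
  13.5 / 18.2 % for W / N1 / N2 / N3 / REM);
* hypnograms are generated as stage runs with geometric lengths (mean 10
  epochs), so the temporal contiguity of real hypnograms — which the
  recurrence exploits — is present;
* every subject perturbs recipe amplitudes and centre frequencies by a
  relative jitter of 0.1, so cross-subject generalisation is non-trivial;
* amplitudes only set signal-to-noise ratios: after per-epoch z-scoring
  the class is carried by spectral shape, exactly as intended for the
  preprocessing default.

What the generator does **not** emulate: 1/f background spectra,
artifacts, electrode drift, inter-scorer ambiguity, or stage-transition
grammar beyond run lengths. Synthetic results therefore demonstrate that
the implementation learns and fuses the intended structure; they do not
predict accuracy on clinical data. A leave-one-subject-out 1-nearest-
neighbour classifier on ten relative band powers reaches ≥ 95 % on default
settings, which is the separability contract the end-to-end checks build
on. The default cohort is 10 subjects × 200 epochs, generated from a
single integer seed that determines everything.

## Design decisions where the architecture was open

* **Attention score.** The score between modality states is the scaled
  dot product `h_n·h_m/√H` (bounded logits); plain dot product is
  available via `model_config(score = "dot")`.
* **Attention-weighted update.** The refined update mixes the *other*
  modalities' previous states, `Σ_m α_nm h_m(t−1)·S_n` — the cross-modal
  reading. The degenerate self-coupling variant (each modality re-weights
  only its own previous state, which collapses because attention rows sum
  to one) is kept behind `literal_update = TRUE` for comparison.
* **State matrix A.** A dedicated state-transition matrix is part of the
  parameter inventory but not of the written update; by default it is
  disabled (`use_A = FALSE`), and enabling it adds `h_n(t−1)·Aᵀ` inside
  both tanh updates.
* **Branch alignment.** The large and small branches end at different
  temporal lengths (7 vs 35 steps after both pooling stages); both are
  adaptively max-pooled to the shorter length before channel
  concatenation, preserving a sequence for the recurrence rather than
  collapsing to a single vector.
* **Second convolution.** Each branch's second layer defaults to kernel
  8, stride 1, 64 filters, pool 4; all of it is configurable in
  `mscnn_config()`.
* **Pooling shape.** On 1-D feature maps the 4×4 pooling window
  degenerates to temporal pooling of width 4, which is what is
  implemented.
* **SE placement and sharing.** SE is applied per modality, after the
  multi-scale concatenation and before fusion, with separate weights per
  modality; the two modalities also use separate convolutional weights.
* **Coupling input.** The coupling module consumes the full `B × T × D`
  feature sequences (`T = 7`), not a pooled vector; the output dimension
  of `E` equals the input feature dimension `D`.
* **Head.** Hidden width 64 with ReLU and dropout 0.5 between the two
  layers (disable with `dropout = 0`).
* **Ablations.** `mscnn_se` bypasses the coupling module (temporal mean
  pooling, concatenation, head). `ssm_only` feeds raw epochs cut into 30
  patches of 100 samples per modality directly into the coupling module —
  the patch size is a reconstruction choice, exposed as
  `ssm_only_patch`.
* **Aggregation of overall metrics.** Sensitivity, specificity and
  precision are macro-averaged (unweighted over classes), consistent with
  reporting macro-F1; cross-validation reports both per-fold metrics and
  metrics pooled over all test epochs (the pooled form is the headline).
* **Class weights** are inverse-frequency, normalised to mean one over
  the classes present, recomputed on each fold's training labels; absent
  classes get weight zero with a warning.
* **Seeding.** One master seed feeds independent derived streams (subject
  generation, fold split, initialisation, shuffling, dropout) through a
  small integer hash, so components are decoupled but the whole run is
  reproducible bit for bit; no validation split or early stopping is
  used — training runs for the configured epoch budget exactly.

## Numerical choices

* Layer normalisation uses ε = 1e-5 with learnable affine per modality.
* Cross-entropy clips probabilities at 1e-12; weighted by
  `w_y / Σ_b w_{y_b}`.
* Per-epoch z-scoring guards the denominator at 1e-8 (flat signals).
* Zero-denominator metric ratios (classes never predicted or absent)
  report 0 with a warning; chance-level agreement makes Cohen's kappa 0,
  and the degenerate `p_e = 1` case returns 0 with a warning.
* Max-pooling breaks ties by the earliest index; adaptive pooling uses
  near-equal segments `[⌊iT/S⌋, ⌈(i+1)T/S⌉)`.
* All gradients are hand-derived and verified against central finite
  differences (step 1e-5) at a relative tolerance of 1e-4 on small
  configurations of every variant, including backpropagation through the
  attention softmax and the recurrence.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` size their experiments so the
whole suite runs on one CPU core in minutes: the end-to-end checks use
the default 10 × 200-epoch cohort with minibatches of 64 and an Adam
budget of 2 training epochs per fold. On this cohort the loss saturates
within the first epoch (the synthetic classes are linearly separable in
band-power space), so longer budgets only add runtime; the 90 %
accuracy / 0.85 kappa bar is met with margin under the shorter budget,
which is the stricter direction. The ablation comparison averages three
seeds of both the full model and the coupling-only variant on the same
cohort. For real-data scale (tens of thousands of epochs), use the
full training defaults in `train_config()` (batch 128, 100 epochs).

## Known limitations

* The coupling recurrence is a plain (non-selective) state-space
  update; no hardware-aware scan is implemented or needed at `T = 7`.
* The EDF reader covers the subset of EDF/EDF+ used by Sleep-EDF style
  recordings (uniform-rate signals, annotation channels); it is not a
  general EDF+D reader.
* Only the two-modality EEG+EOG configuration is exercised end to end,
  although the coupling module itself supports any number of modalities.
* Synthetic validation bounds what the tests can claim about clinical
  performance; see the generator section above.
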