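---
title: "Predicting upcoming speech fluency from pre-speech EEG and facial action units: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting upcoming speech fluency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adults who stutter fluctuate between fluent and stuttered speech on a
timescale of seconds. In a cued speech task (cue S1, go-signal S2 always
1,500 ms later), the speech-preparation window between S1 and S2 is free of
vocalisation artifacts and should carry the neural and facial-muscle
precursors of the upcoming outcome. `ssmlr` implements a multimodal pipeline
that predicts, trial by trial, whether the upcoming utterance will be fluent
or stuttered, from two synchronised inputs per trial:

* an **AU matrix** `x_au` (17 x 87): frame-wise intensities of 17 FACS
  action units at 58 frames/s;
* an **EEG matrix** `x_eeg` (62 x 192): 62 channels of artifact-cleaned EEG,
  resampled to 128 Hz and normalized by one robust constant per session.

Four task paradigms are used (word vs. cue at S1, each with or without a
1,000 Hz tone at 600 ms), coded WG/WAG/CW/CAW = classes 0-3.

## Self-supervised pretext stage

Two compact CNN encoders `H_AU` and `H_EEG` map each modality to a
64-dimensional embedding. They are pretrained without fluency labels on four
joint objectives:

* `L_para`: cross-entropy of a linear head on `Z_EEG` predicting the
  paradigm class (experimental metadata as pseudo-label);
* `L_st`: identify which signal transformation, with which parameter, was
  applied to a 100 ms window of the AU matrix. The legal set is scaling
  (theta in 0.25, 0.5, 1.25, 1.75), additive Gaussian noise (theta in 0.1,
  0.25, 0.5, 0.75, 0.9), zero-fill, and none — one joint categorical with 11
  classes;
* `L_win`: identify the transformed window. The 100 ms window grid is 14
  non-overlapping 6-frame windows tiling frames 1-84 (at 58 frames/s,
  100 ms = 5.8 frames, rounded up; the last 3 frames are never windowed),
  plus a 15th "no-window" class used when the transformation kind is "none".
  A transformation always touches either the upper-face rows (AU 1, 2, 4, 5,
  6, 7, 45) or the lower-face rows, never both;
* `L_KLD = KL(softmax(Z_EEG/T) || softmax(Z_AU/T))`: the AU embedding is
  pulled toward the (gradient-stopped) EEG embedding, so facial
  representations inherit cognitive-state structure.

The total loss is `L = L_para + alpha * L_win + beta * L_st + L_KLD`.
Transformation sampling is uniform over the 11 joint (kind, theta) classes,
uniform over the 14 windows, and uniform over the two face regions.

### Numerical and design choices

* **Embedding batch-norm.** Each encoder ends in
  flatten -> dense(64) -> batch-norm. Without the final batch-norm the
  alignment term has a degenerate minimiser — shrink `Z_AU` toward a
  constant so its softmax matches the average EEG distribution — and we
  measured exactly this collapse (per-dimension embedding SD dropping three
  orders of magnitude). Pinning the batch scale removes the degenerate
  direction; the alignment term can then only align distributions.
* **`alpha`, `beta`, `T`.** Defaults are `alpha = beta = 1`, `T = 1`. In the
  desk-scale studies shipped with the package we use `alpha = beta = 5`,
  `T = 4`, chosen by monitoring pretext learnability and embedding health:
  the transformation tasks carry weak gradients early in training and are
  otherwise dominated by the alignment pull.
* Probabilities inside logs are clamped at `1e-12`. Losses are batch means.

## Downstream stage

The downstream task is binary (stuttered = positive class), on a set
balanced by random down-sampling of the majority class with an explicit
seed. Two protocols are provided:

* **`ssml_ensemble`** (and `fusion`, `unimodal_*`, `margin_classifier`):
  the pretrained encoders are **frozen** and a 3-dense-layer head
  (64 -> 32 -> 16 -> 1 logit) is trained per branch on the cached
  embeddings. The final prediction is
  `sigmoid(delta * y_eeg + gamma * y_au)` on the two branch logits; `delta`
  and `gamma` are selected by grid search on validation accuracy over
  `[0, 2]` in steps of 0.1, ties broken toward the smallest `delta + gamma`
  and then the smallest `delta`. The all-zero pair is excluded (it is a
  constant classifier). The fusion baseline concatenates both embeddings
  (128-dim) into a single head; the margin-classifier baseline fits an RBF
  SVM on the frozen 128-dim embeddings.
* **`fsml`**: the same two-branch architecture trained end to end from
  random initialisation (fully supervised reference).

Optimisation is SGD (momentum 0.9) at an initial learning rate of 0.01 by
default; the rate halves after 25 epochs of validation plateau and training
stops early (best-epoch weights restored). Batch norm and 50% dropout curb
overfitting. Evaluation uses one stratified holdout split plus k-fold
cross-validation over the remaining pool; metrics are rank-statistic AUC, F1
at threshold 0.5, and accuracy in percent.

## Architectures

* **Variant A** (primary): the first convolution spans the full spatial axis
  (17 AU rows, or 62 channels), later layers filter along time only
  (17-tap temporal kernels for AU; depthwise with depth factor 2 and
  separable temporal convolutions for both branches), with average pooling
  for temporal compression. Average pooling is linear, which makes the
  explanation stage exactly additive (below).
* **Variants B/C**: plain 3x3 convolution stacks (16/32/64 kernels) with max
  pooling; C adds one extra 64-kernel 3x3 convolution per branch. Parameter
  totals land at the published order of magnitude (~280k/~317k); exact
  dense widths and pooling sizes are not recoverable from the description,
  so totals are sanity bounds, not targets.

## Multimodal Shapley explanations

Each trial gets one attribution map per modality, `E(x_au)` (17 x 87) and
`E(x_eeg)` (62 x 192), computed by DeepLIFT rescale-rule multiplier
backpropagation from the post-sigmoid model output against a reference
population: k = 20 trials sampled (seeded, without replacement) from the
same subject, session, and paradigm as the explained trial, across both
fluency outcomes. Per-reference attributions are averaged — the
double-mean form of the marginal-contribution estimator — and the base
value is the mean model output over references. Properties:

* **Completeness**: `sum(E(x_au)) + sum(E(x_eeg)) = f(x) - base`. Exact (to
  float precision) for variant A ensembles: every layer is linear/affine
  (conv, batch-norm at inference, average pooling, dense) or elementwise
  with the rescale rule (ReLU, final sigmoid). Max pooling in variants B/C
  uses gradient-style routing to the argmax, the standard deep-explainer
  treatment, and is only approximately additive; `additivity_report()`
  quantifies the residual.
* Against the exact coalition-enumeration oracle
  (`exact_shapley_oracle()`, feasible to 20 features), rescale-rule
  attributions are exact for linear models; through ReLU kinks individual
  attributions deviate (median on the order of 10-20% on random
  one-hidden-layer probes) while completeness is preserved.

## Attribution statistics

Maps are aggregated to per-trial mean absolute attribution by face region
(upper/lower) or electrode group (AF, LF, C, FP1, FP2, T7, T8, other) and
time zone (0-500, 500-1,000, 1,000-1,500 ms; 29/29/29 frames and 64/64/64
samples). The fluency-by-zone analysis is a **split-plot ANOVA**: fluency is
a between-trial factor, zone a within-trial (repeated-measures) factor. The
three zone values of one trial come from the same map and are strongly
correlated; a plain two-way fixed-effects F is badly miscalibrated here
(permuted-label p-values are far from uniform), while the split-plot
within-stratum tests stay calibrated — the packaged tests verify this by
permutation. Signed means are also emitted for inspection.

## The synthetic generator

Cohort data are available only on request, so the package ships a generator
(`generate_dataset()`) whose defaults emulate the study conditions: 7
subjects, 3 sessions of 400 trials, equal paradigm mixture, equal
fluent/stuttered rates. Structure:

* AU noise: smoothed Gaussian (banded smoothing matrix, unit marginal SD)
  over a baseline intensity of 3, clipped at zero; EEG noise: 1/f-shaped
  circulant Gaussian per channel plus a per-session channel offset.
* Paradigm signatures in EEG: a stimulus-locked biphasic response at S1 for
  word-first paradigms, an S2-locked anticipation ramp for cue-first
  paradigms, and a tone-locked burst near 600 ms for WAG/CAW.
* Fluency signal: stuttered trials carry Gaussian bursts in upper-face AUs
  (1, 2, 4, 6) centred in the early zone and lower-face AUs (14, 15, 20) in
  the late zone; fluent trials the time-reversed pattern. In EEG, stuttered
  trials shift the left-temporal channel (T7) early and fluent trials the
  right-frontal channel (FP2) late. All effects scale with `effect_size`.
* **Stochastic occurrence.** Each trial expresses each of its class's three
  markers with probability `occurrence_prob = 0.75`. This reflects that
  microexpressions do not occur on every trial, and it is what makes the
  class-specific attribution *timing* recoverable: with deterministic
  same-amplitude planting and references drawn across both outcomes, the
  mean absolute attribution is provably identical for the two classes at
  every cell (each class mean is equidistant from the reference midpoint),
  so no fluency-by-zone interaction could exist.

`bayes_reference_accuracy()` is the matching oracle: the exact Gaussian-
mixture log-likelihood ratio over the planted rows/channels (mixtures over
the occurrence indicators), conditioning on the class-independent nuisance
terms (session offsets, paradigm components) and ignoring the rare AU
clipping. It upper-bounds any trained model and, for `occurrence_prob = 1`,
equals the closed form `pnorm(d'/2)` with `d'` the Mahalanobis separation.

What the generator does **not** emulate: realistic EEG spectra beyond 1/f
shaping, artifacts and their removal, non-stationarity across sessions,
label noise in fluency coding, or any nonlinear class structure. Passing
tests therefore demonstrate that the machinery recovers planted structure
under the stated assumptions — not that the method performs at any
particular level on real recordings.

## Desk-scale study sizes

The shipped tests run the pipeline end to end at reduced sizes chosen to
keep the full suite in the tens of minutes on one CPU: recovery studies use
a single session of 600 trials at `effect_size = 3` with 250 explained
trials and 1,000 label permutations; the chance-floor study uses 20
label-permutation repetitions at 160 balanced trials; the model-family
comparison uses 6 seeds, 300 unlabeled trials for pretraining, and 140
labeled trials. The acceptance script reports the embedding dimensionality
and the permuted-label chance floor at the same scale.

## Known limitations

* On this generator the planted signal is a (stochastically occurring)
  mean-shift pattern, which end-to-end supervised training learns easily.
  Self-supervised pretraining consistently *reduces* the fluency
  information in the AU embedding relative even to a random-weight encoder
  (the transformation/window/alignment objectives treat the class signal as
  nuisance variance), so the fully supervised reference outperforms the
  pretrained-frozen pipeline here, and the published self-supervised-over-
  supervised ordering does not reproduce at desk scale. The corresponding
  acceptance check is expected to fail and is left failing by design; the
  ensemble-versus-fusion and ensemble-versus-unimodal orderings do
  reproduce.
* The EDF reader/writer is minimal (16-bit EDF, one-second records, uniform
  sample rate) — sufficient for round-trip testing and interoperability,
  not a general EDF(+) implementation.
* ICA cleaning of real EEG is assumed to have happened upstream; the
  package implements only per-session robust normalization.
* The margin-classifier baseline has no gradient path and cannot be
  explained by the DeepLIFT machinery.
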