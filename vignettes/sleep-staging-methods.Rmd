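---
title: "Methods: multi-channel sleep staging with residual attention fusion and embedded stage refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-channel sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical sleep evaluation scores overnight polysomnography (PSG) — EEG,
EOG and chin EMG — in 30-second epochs, assigning each epoch one of five
stages: W (wake), N1, N2, N3 (slow-wave sleep) and REM. Manual scoring is
slow and labor-intensive; `sleepfusion` implements an automatic scorer
that treats the three classical processing steps — feature extraction,
classification, and refinement by sleep-transition structure — as a single
differentiable model, plus the traditional post-hoc refinement baselines
it is compared against.

## Model

### Per-channel feature extraction

Each signal channel gets its own CNN branch (no parameter sharing across
channels): five blocks of 1-D valid convolution -> batch normalization ->
ReLU, followed by global average pooling into a feature vector
$v_i \in \mathbb{R}^{256}$. The default geometry is kernels (5,5,3,3,3),
strides (3,3,2,1,1) and widths (64,64,128,128,256), giving temporal
lengths 999/332/165/163/161 for a 3000-sample input (30 s at 100 Hz) and
1279/425/212/210/208 for 3840 samples (30 s at 128 Hz). Convolutions carry
no bias (batch normalization immediately follows); batch-norm momentum is
interpreted as the running-statistics decay (0.99, epsilon 0.001).

### Residual attention channel fusion

With $V = \mathrm{Concat}(v_1,\dots,v_C)$, each channel is scored by

$$s_i = w_{is} \cdot \mathrm{ReLU}(W_{iv} v_i + W V + b), \qquad
\alpha = \mathrm{softmax}(s),$$

and the fused feature is

$$V_\mathrm{fusion} = v_\mathrm{avg} + \sum_{i=1}^C \alpha_i v_i .$$

The unweighted channel mean $v_\mathrm{avg}$ acts as a floor: even when
attention saturates on one channel, every channel still contributes
$1/C$ of its feature, which prevents the information loss that pure
attention exhibits. The per-channel maps $W_{iv}$, $w_{is}$ are unshared;
$W$ and $b$ are shared. Dimensionalities follow from the feature width:
$W_{iv} \in \mathbb{R}^{256\times256}$, $W \in \mathbb{R}^{256\times256C}$,
$w_{is} \in \mathbb{R}^{256}$, so $s_i$ is a scalar. The ablation variants
`average`, `concat`, `attention_only` and `data` (all channels stacked
into one branch) are available through `fuse_variant()` and the model
config; decision-level fusion (`vote` / `map` across independently
trained single-channel models) is implemented in `decision_fusion()`.

### Embedded stage refinement

Sleep is strongly autocorrelated, so the previous epoch's stage carries
real information about the current one. The previous stage vector — one-hot
ground truth during training (teacher forcing), the model's own output
probability vector at inference — is re-encoded by a single affine layer
into $v_c \in \mathbb{R}^{256}$ and concatenated with $V_\mathrm{fusion}$.
Because the classifier is affine, the logits decompose additively,

$$P = W [v_c, V_\mathrm{fusion}]^T = W_c v_c + W_f V_\mathrm{fusion},$$

i.e. the stage input contributes an additive correction to the signal
classification. The encoder is affine only (the "single-layer fully
connected" reading); a bias is included in the classifier, which the
additivity test accounts for with a $(0,0)$ correction term. The first
epoch of every sequence uses the uniform $1/5$ vector at training and
inference alike, keeping the two regimes consistent.

### Training and ensembling

Mean cross-entropy loss, Adam (framework defaults $\beta_1=0.9,
\beta_2=0.999, \epsilon=10^{-8}$, recorded here because the protocol
leaves them open), elementwise gradient clipping at 0.1, dropout 0.5 on
the classifier input, batch size 64, 70 training epochs at learning rate
$10^{-4}$ in the full-scale protocol. Teacher forcing makes epochs
conditionally independent given their predecessor's label, so batches mix
subjects freely and no sequence batching is needed. After every training
epoch the model is evaluated on the held-out validation subject by the
same sequential inference used at test time, and the parameters are
checkpointed; the top `ceiling(0.10 * n_epochs)` checkpoints by validation
macro-F1 (7 of 70; ties to the later epoch) are ensembled per epoch by
maximum likelihood — the sum of per-model log probabilities, argmax, ties
to the lowest stage index. Traces are produced per checkpoint
independently and fused afterwards; fusing inside the feedback loop is a
noted alternative that is not implemented.

### Evaluation

Leave-one-subject-out: one fold per subject as test, the cyclically next
subject as validation (the protocol fixes one validation subject but not
which; any deterministic rule serves), the rest as training. Fold results
are pooled at the epoch level before computing the report — accuracy,
macro-F1 over stages present in the truth, Cohen's kappa, per-stage
precision/recall/F1 — overall and stratified into transition epochs
(stage differs from either neighbor; boundary epochs compare only to
their existing neighbor) and nontransition epochs. The one-sentence
definition of "transition epoch" in the source protocol is circular; the
differs-from-either-neighbor rule is the fixed interpretation here and
the two masks always partition the recording.

## Refinement baselines

* **Expert rules**: rule 1 rewrites every REM epoch before the first
  appearance of N2 to N1 (when N2 never appears there is no "first
  appearance" and the rule is inert — this also preserves the canonical
  (REM, X, REM) -> (REM, REM, REM) example); rules 2–5 rewrite the triples
  (W, REM, N2) -> (W, N1, N2), (N1, REM, N2) -> (N1, N1, N2),
  (N2, X, N2) -> (N2, N2, N2), (REM, X, REM) -> (REM, REM, REM), each as
  one left-to-right stride-1 pass so rewrites can cascade. The rule order
  and single-pass semantics are a fixed design choice (the rule table
  gives no order); idempotence of rules 2–5 holds empirically on random
  corpora and is checked as a logged property, not an invariant.
* **HMM**: transition matrix $A$, emission matrix $B$ (hidden truth ->
  observed prediction) and initial law $\pi$ are frequency counts on the
  validation split with a Laplace pseudo-count of 1 (the source is silent;
  zero probabilities would break Viterbi in log space), transitions never
  counted across recording boundaries; test predictions are then decoded
  with Viterbi, ties to the lowest stage index.

## Synthetic world

The simulator generates what the model assumes: a first-order Markov
hypnogram with strong sleep continuity (all diagonal transition entries
$\geq 0.55$; stationary law roughly W .22 / N1 .08 / N2 .37 / N3 .18 /
REM .15, so the largest stage prior — the chance rate for a
majority-class guesser — is about 37%), and stage-conditioned signals
whose per-channel spectra follow the textbook AASM signatures: alpha-band
EEG with high EMG tone in W, theta EEG in N1, theta plus 12–14 Hz spindle
energy in N2, high-amplitude 0.5–4 Hz slow waves in N3, low-amplitude
mixed-frequency EEG with large slow EOG deflections and minimal EMG in
REM. Epochs are sums of unit-variance band-limited Gaussian noise
weighted by the square roots of the stage's relative band powers, plus
white noise of sd `noise_sigma` (default 0.2, a high-SNR world), scaled
per stage and per channel, with ±10% per-subject amplitude jitter
emulating inter-individual differences. Channels listed as uninformative
carry unit-variance white noise and no stage information — the probe used
for the attention ablation.

What the simulator does **not** emulate: K-complex/spindle morphology,
artifacts, apnea events, non-stationarity within a night, or realistic
inter-subject variability beyond amplitude jitter. A green learning test
therefore establishes that the pipeline can extract and fuse
stage-discriminative spectral structure end to end — not that it reaches
clinical accuracy on real PSG; the real-data numbers require the public
PhysioNet recordings and the full 20–25 fold protocol (see README).

## Numerical and design choices

* Gradients are computed by hand-written backpropagation through every
  layer and verified against central finite differences to ~1e-7
  relative error (training-mode batch statistics included).
* Softmaxes subtract the row maximum; probabilities are clipped at 1e-12
  inside logs; batch-norm variance uses the biased estimator with
  epsilon 0.001.
* Resampling is linear interpolation onto the target grid (the protocol
  says only "upsampled"); zero-order hold is available behind a flag;
  decimation is allowed but logged, without anti-alias filtering.
* Z-scoring is per recording (whether multi-night recordings should pool
  is an open question upstream; per recording is the default here).
* Stage coding is fixed package-wide: W=0, N1=1, N2=2, N3=3, REM=4; all
  ties anywhere break toward the lowest stage index.
* Weight init is fan-in-scaled Gaussian ("He"), seeded from the config;
  every stochastic step (init, batch order, dropout, simulation) derives
  from explicit seeds, so identical config + seed is bit-reproducible.
* The scaled-down reference experiment (`example_run_config()`) uses
  learning rate 1e-3 and batch 32 instead of the full-scale 1e-4/64: a
  ~190-step run needs a correspondingly larger step size, chosen once by
  step-count scaling before any acceptance measurement. Mechanism checks
  run in similarly small worlds (refinement-vs-ablation: 4 subjects,
  2 folds, 4 training epochs; attention-vs-noise-channel: 5 subjects,
  1 fold, 5 training epochs). The attention check needs the longer
  schedule: in a severely under-trained model the softmax attention
  saturates on one informative channel and the ordering among the
  remaining near-zero weights is arbitrary, so the noise-channel ranking
  is only meaningful once the attention module has minimally converged.

## Known limitations

* Pure-R training is orders of magnitude slower than a GPU framework;
  the full-scale protocol on real data is supported but slow.
* The EDF reader is out of scope; real recordings must be converted to
  the package's plain-text container (CSV signals + hypnogram text +
  JSON metadata) first.
* No recurrent context beyond the previous epoch; no learning-rate
  schedules, early stopping or class weighting (a class-weight flag
  exists in spirit but the default loss is unweighted, matching the
  protocol).
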