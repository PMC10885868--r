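---
title: "Learning from disagreeing annotators: uncertainty-gated privileged information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning from disagreeing annotators: uncertainty-gated privileged information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncertram)
```

## The problem

Radiological labels are noisy. When a panel of physicians rates chest
X-rays for ARDS on an ordinal 1–8 scale (1 = confidently negative, 8 =
confidently positive, 4/5 equivocal), inter-rater agreement is only fair
(pairwise Cohen's kappa well below 0.5), and the usual remedy — averaging
the scores and thresholding the mean at 4.5 — silently converts
disagreement into label noise. `uncertram` implements a family of models
that instead *exploit* the structure of the disagreement: the full set of
(score, reviewer) annotations is supplied to the network during training
as **privileged information** — input that exists at training time but
never at inference, when only the image is available.

## The model

The architecture is a two-branch network in the TRAM (Transfer and
Marginalize) family. The base branch is an image encoder $\phi$ producing
an embedding $z = \phi(x)$, followed by a linear class head $\xi$. The
privileged branch embeds the encoded annotation vector $x^\*$ through
$\varphi$ (a 64-unit linear layer with batch normalization and ReLU) and
predicts from the concatenation $(z^\*, z)$ through $\delta$, two 128-unit
layers with batch normalization and ReLU and a final head. The training
loss is

$$L = L_1\big(\xi(\mathrm{sg}(z)), y\big) + \beta\, L_2\big(\delta(z^\*, z), t\big), \qquad \beta = 0.5,$$

where $\mathrm{sg}$ is a stop-gradient: the base cross-entropy $L_1$
updates only $\xi$, while the encoder receives gradients exclusively
through the privileged branch. At inference the privileged branch is
discarded; the knowledge it injected survives in the encoder. The package
verifies this wiring bitwise (disabling either loss leaves exactly the
contracted parameter groups untouched).

Two refinements distinguish the full model (`variant = "proposed"`) from
plain TRAM:

1. **Uncertainty gating.** Per image, the uncertainty is
   $D = \tfrac1k \sum_i g(S_i) + \sigma(S_1,\dots,S_k)$ with
   $g(s) = -|s - 4.5| + 3.5$: the mean per-score equivocality plus the
   spread of the panel. $D = 0$ exactly for unanimous confident extremes;
   with the population standard deviation and panels of up to four
   reviewers its exhaustive maximum is about 4. The privileged vector is
   passed only when $D > \tau$ (default $\tau = 2$, the reference
   training-set median); otherwise an all-zero vector is substituted.
   Gating prevents the privileged branch from leaking the label outright
   on easy cases, which would starve the encoder of learning signal.
2. **Ordinal privileged head.** Instead of predicting the binarized
   label, the privileged head predicts the rounded mean score on the 1–8
   scale through a rank-consistent CORN head: $K-1$ conditional binary
   tasks, task $j$ trained on examples whose target exceeds $j-1$ with
   probability $\sigma(f_j)$; unconditional exceedance probabilities are
   running products of the conditional sigmoids, monotone by
   construction, and the predicted rank is one plus the count above 0.5.

Three encodings of the annotation set are provided: the score histogram
(length 8), the histogram concatenated with a reviewer-participation
indicator (length $8 + M$, i.e. 22 for a 14-reviewer panel), and
per-reviewer score slots (length $M$). Baselines cover linear probing,
fine tuning, per-annotator confusion-matrix estimation, plain TRAM, and
the two single-refinement ablations.

## Design choices and conventions

Several points are deliberately fixed here because the underlying
conventions are genuinely open:

* **Standard deviation in D.** The population form (divisor $k$) is the
  default. With the sample divisor, two reviewers scoring 1 and 8 give
  $D \approx 4.95$, outside the ~[0, 4] range within which the measure is
  interpreted and thresholds are swept; the population form keeps the
  exhaustive maximum at $\approx 4$. The sample form remains available
  via `sd_type = "sample"`.
* **Rounding of the mean score.** The ordinal target rounds half-values
  up (`ordinal_target(..., half = "up")`), so a mean of 4.5 maps to rank
  5, consistent with the 4.5-threshold rule that labels the boundary
  positive. Banker's rounding is available as a switch.
* **Gate boundary.** Privileged information passes strictly when
  $D > \tau$; $D = \tau$ is gated to zero.
* **Strata.** Evaluation strata are $[0, 2)$ (clean) and $[2, \max]$
  (equivocal); the top bin is closed so no record is dropped at the
  maximum of D.
* **Ranking metrics.** AUROC uses the mid-rank statistic; AUPRC is the
  step-wise average precision. Degenerate denominators (single-class
  samples, empty margins for MCC) yield `NA`, never 0.
* **CORN normalization.** The loss divides by the total number of
  contributing (task, example) terms; empty conditional subsets
  contribute nothing.
* **Confusion estimation.** One 2×2 column-stochastic matrix per
  annotator, parameterized by per-column softmax logits (stochasticity is
  therefore preserved after every optimizer step), identity-biased
  initialization (diagonal 0.9), and a trace regularizer (weight 0.01)
  that makes the decomposition into true-label predictor and annotator
  confusion identifiable. The matrices act on the estimated class
  distribution as annotator-label-given-true-class.
* **Batch normalization.** Training-mode statistics need at least two
  samples, so the trainer drops a trailing batch of size one.
* **Early stopping.** "No improvement" is measured against the best
  validation loss seen so far (not the previous epoch), matching
  lowest-validation-loss checkpointing; patience is 10 epochs at full
  scale.
* **Learning rates.** The loss weight $\beta$ is exclusively the loss
  weight; the two learning rates are named `lr_encoder` and `lr_rest`
  (two Adam parameter groups with default moments).
* **Base-head gradients.** The class head $\xi$ receives no gradient from
  $L_2$: $\delta$ consumes the embedding directly, not through $\xi$.

## The training protocol

Data splits are patient-wise throughout: patients are shuffled with a
seed and dealt round-robin into folds, so no patient ever spans folds or
the train/holdout boundary (asserted, not assumed). Validation sets are
filtered to records with $D \le 2$ — uncertain cases carry unreliable
mean labels and would corrupt checkpoint selection — while training
retains all records. Each fold trains up to 40 epochs (batch 64) with
early stopping, and validation always scores the *base branch* with
cross-entropy against the mean label, regardless of the variant's
training loss, so checkpoint selection is comparable across variants. A
5×5 learning-rate grid is searched under one seed by mean best validation
loss (ties break toward smaller rates); a second seed re-runs the
cross-validation at the chosen rates, and each fold's best checkpoint is
applied to the holdout set, reporting mean ± sd of eight metrics overall
and per uncertainty stratum.

## The synthetic generator

Because the motivating clinical dataset is protected, the package ships a
generator that reproduces the *statistical* structure the method assumes,
not radiology. Each patient receives a latent severity $u$ drawn from a
U-shaped distribution on $[0, 10]$ (most patients clearly positive or
negative, fewer near the boundary, as in cohorts assembled from clear
inclusion criteria); images inherit $u$ with patient-level jitter. Scores
follow $s = \mathrm{clip}(\mathrm{round}(4.5 + a(u - u_0) + b_t +
\varepsilon), 1, 8)$ with slope $a = 7/\text{range}$ so the severity range
spans the score scale and the class boundary $u_0$ lands on the scale
midpoint 4.5 — the premise that equivocal scores mark ambiguous images is
thus built in. Reviewer bias $b_t \sim N(0, 0.5)$ is drawn once per
panel; per-review noise $\varepsilon \sim N(0, 0.9)$. These defaults were
set so the generated uncertainty distribution matches the reference
cohort's reported summary (mean 1.95, Q1 1.00, median 2.00, maximum just
under 4); with them the generated median of D is 2.00 and the mean 1.95.
Images are 32×32 fields of Gaussian background noise plus two lateral
elliptical "lung" regions receiving Gaussian opacity blobs whose
intensity grows with severity and which become bilateral above $u_0$ — a
learnable visual correlate of the bilateral-opacity criterion.

What the generator does *not* emulate: real CXR texture, medical devices,
view variation, and annotator behavior beyond additive bias and noise
(no per-annotator scale compression, no image-difficulty-dependent
noise). Passing benchmarks on this generator therefore demonstrates that
the machinery — gating, ordinal transfer, stop-gradient, protocol — works
as specified under the assumed noise structure, not that the method
succeeds on clinical images.

## Desk-scale benchmark

`run_synthetic_benchmark()` is the package's scaled-down rendition of the
full protocol: roughly 600 training and 300 holdout images (120 and 60
patients), a single patient-wise train/validation split per seed, at most
10 epochs, three seeds. The learning rate is chosen per variant from
{1e-3, 1e-2} by validation loss — the reduced form of the full grid
search; at this scale a fixed 1e-3 leaves linear heads visibly underfit
within 10 epochs, and selection by validation keeps the choice
data-driven. The confusion baseline runs with its trainable-encoder
switch here, since desk scale has no pretrained encoder whose freezing
would be meaningful. The problem sizes were chosen so the whole benchmark
completes in minutes on one CPU while still showing the reference
qualitative pattern: every variant performs worse on the equivocal
stratum than on the clean one, and the gated ordinal model matches or
beats plain TRAM where labels are trustworthy.

The trainable encoder used at this scale is a 3-block strided
convolutional network (channels 8/16/32, embedding width 64). The
ResNet-50 topology behind the full-scale path is also implemented (He
initialization, single-channel stem, 2048-dim embedding, forward pass);
it serves frozen-encoder paths and the embedding contract, and externally
pretrained weights can be loaded into its parameter lists by name.
Nothing in the package downloads weights.

## Known limitations

* Gradient-through-encoder training is exercised with the small CNN;
  training the ResNet-50 path end-to-end, while structurally present,
  is outside the tested envelope (its max-pool layer is forward-only).
* The uncertainty measure is a heuristic, not an unbiased estimator of
  annotator error; it is effective in combination with the gate, which
  is exactly how it is used here.
* The generator's annotator model is additive-Gaussian on the score
  scale; systematic annotator behaviors (e.g. reviewers who never use
  extreme scores) are not simulated.
* Metrics-level reproducibility is bitwise under fixed seeds and
  single-threaded BLAS; multi-threaded BLAS reductions may differ in the
  last ulp.
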