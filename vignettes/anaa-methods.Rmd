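---
title: "Adaptive noise-augmented attention: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive noise-augmented attention: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaa)
```

## The problem

Transformer encoders fine-tuned on small labeled sets of longitudinal
medical-code sequences (ordered visits of ICD diagnosis and ATC
medication codes) tend to collapse their self-attention onto a
near-binary pattern: after fine-tuning, many heads assign each token pair
a weight close to either 0 or 1. This over-confident attention explores
few dependency paths between clinical events, which hurts generalization
exactly where labels are scarcest.

`anaa` implements a two-step fine-tuning augmentation that acts directly
on the post-softmax attention score matrix $A_h$ of every head $h$:

1. **Adaptive noise injection.** Add i.i.d. Gaussian noise
   $\mathcal N(\mu, \sigma_{GN}^2)$ to every entry of $A_h$, where $\mu$
   is the mean of the current matrix and $\sigma_{GN}$ its standard
   deviation. For a row-stochastic $n \times n$ matrix $\mu = 1/n$
   always; for a degenerate on/off matrix with "on" mass $\alpha$ the
   per-element variance scales as $\alpha(1-\alpha)$, so the noise is
   automatically calibrated to how polarized the head currently is.
2. **Gaussian smoothing.** Convolve the noisy matrix with a discrete 2D
   Gaussian kernel of width $\sigma_{eh}$ (the *event horizon*), side
   length $k = \operatorname{round}(2\pi\sigma_{eh})$, zero-padded at the
   boundary. The smoothing acts as a low-pass filter: isolated noise
   spikes are suppressed while coherent attention structure survives.

During training the noise is redrawn at every forward pass, so each
mini-batch sees a different, spatially smoothed view of the token
relations. At inference the noise is replaced by its expected value
$\mu$, making predictions deterministic: `ANAA` evaluates
$(A_h + \mu) * n_{\sigma_{eh}}$, `RNA` (raw noise injection, the ablation
without smoothing) evaluates $A_h + \mu$. Augmented rows are deliberately
**not** renormalized and scores are not clipped: the augmented matrix
multiplies the value projections directly.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sigma_eh` | 1.0 | Width (in attention-matrix cells) of the smoothing Gaussian; side length $k=\operatorname{round}(2\pi\sigma_{eh})$, so 1.0 gives a 6-cell and 0.33 a 2-cell kernel — the two settings used on the long-history and short-history corpora respectively. |
| `kernel_normalized` | TRUE | Scale kernel weights to sum 1, so the eval-path shift is mass-preserving in the interior. Raw Gaussian-density weights are available for fidelity experiments. |
| `variance_denominator` | `"elements_minus_one"` | See "The variance denominator" below. |
| `mlm_prob` | 0.15 | MLM corruption rate, BERT's 80/10/10 mask/random/keep convention. |
| `min_count` | 5 | Rare-code threshold; rarer codes tokenize to `[UNK]`. |

## The variance denominator

The printed definition of the adaptive noise standard deviation sums the
squared deviations of all $n^2$ matrix entries but divides by $n-1$.
Taken literally this inflates $\sigma_{GN}$ by a factor of about
$\sqrt{n}$, so for long sequences the noise would swamp the attention
signal entirely — and it contradicts the per-element
$\alpha(1-\alpha)$ variance rationale given for the two-point pattern,
which holds only for the per-element sample estimator. The default
therefore divides by $n^2 - 1$ (the sample variance over all entries);
`variance_denominator = "as_printed"` restores the literal formula for
comparison. This is the package's own reading of an ambiguity, recorded
here rather than silently resolved.

Two further conventions of the same kind:

* **Kernel support.** The convolution's printed index range ($1..k$)
  would shift the whole attention map down-right, contradicting the
  smoothing interpretation. The kernel is therefore centered: offsets
  $-\lfloor k/2\rfloor .. \lceil k/2\rceil - 1$, anchoring even kernels
  one cell up-left of center. The isotropic Gaussian is separable, so the
  implementation runs the convolution as two banded Toeplitz multiplies;
  it is tested to $10^{-10}$ against a literal nested-sum implementation.
* **Gradients.** The backward pass differentiates the smoothing
  convolution exactly (transposed convolution) but treats the drawn noise
  matrix — and hence the dependence of $(\mu, \sigma_{GN})$ on $A_h$ — as
  a constant. A full autograd implementation would also differentiate the
  adaptive statistics; the dropped term is a rank-one correction of order
  $1/n^2$ per entry.

## The synthetic cohort generator

Real corpora of this kind are access-restricted, so the package ships a
seeded generator that emulates their shape statistics: visit counts are
negative-binomial (burstier than Poisson, as hospital contact patterns
are), codes per visit are $1 + \text{Poisson}$, and code popularity
follows a power law (a few very common codes, a long tail). Two presets
mirror the published corpora: `mimic_like` (≈9 visits/patient, 2195+137
codes, ≈61 codes/patient) and `mdc_like` (≈19 visits/patient, 1558+111
codes, ≈257 codes/patient).

Outcome signal is planted as **motifs**: ordered code pairs
$(a, b)$ with a minimum visit offset. A motif *fires* when $a$ occurs at
least `min_offset` visits before $b$; each fired motif adds its log-odds
to the outcome logit on top of `logit(base_rate)`. The firing direction
is ordered ($a$ before $b$) so that long-offset motifs require genuinely
distant-token interaction — the stress case for the receptive-field
claim. Positives receive the target code in a visit appended *after* the
history, so the labeling module's positive-case truncation (cut strictly
before the first target visit) reproduces the generated label exactly;
this round-trip is tested on 5,000 patients.

Because the generator knows each patient's true logit, `bayesAUC()`
reports the ceiling any classifier can reach — used to verify that a
benchmark cohort actually carries signal before training on it.

What the generator does **not** emulate: disease progression dynamics,
calendar time, code ontology structure, and correlated comorbidity
patterns. A green benchmark therefore establishes that the training
pipeline can extract planted long-range signal at desk scale — not that
the method reproduces its published real-data AUC deltas.

## Training protocol

Patients are split 70/20/10 into pre-training / fine-tuning / test at
the patient level. The encoder (default 2 layers, 4 heads, learned token
+ absolute position embeddings, untied MLM head, `[CLS]` sigmoid
classification head) is pre-trained with MLM on the 70% split, then
fine-tuned five times — once per fold of the label-stratified 5-fold
partition of the 20% split, early-stopped on the held-out fold's AUC —
and each run is scored on the untouched 10% test set; reports carry the
per-fold AUCs and their mean ± sd. Optimizer settings (Adam, 1e-3
pre-train / 5e-4 fine-tune, batch 32, patience 5) are package defaults:
the source describes the protocol but defers exact hyperparameters to
unavailable supplementary material. Stratified folds and stratified
subsampling (for the 50/20/10% data-insufficiency sweep) protect the
small positive counts typical of these tasks.

Decisions taken where the protocol was genuinely open:

* The minimum-visit filter is applied **after** positive-case truncation
  (on the history the model actually sees); the source is ambiguous and
  its reported post-filter visit averages suggest the opposite order, so
  the threshold is configurable.
* Inference-time $\mu$ is recomputed from each sample's current matrix
  (the expected-value formula reads that way), not frozen from training.
* The eval path for `RNA` — stated only for `ANAA` — is $A_h + \mu$ by
  symmetry (noise replaced by its expectation, no kernel).
* "Initial 4 digits" of a code is read as the first 4 characters after
  dot removal, since ICD-10 codes mix letters and digits ("I50.1" →
  "I501").
* Visits are sets, so codes are sorted lexicographically within a visit
  for reproducible tokenization; over-long sequences keep the most
  recent whole visits (prediction conditions on recent history).
* DropAttention mask seeds are drawn per element and expanded along the
  key axis only; masking happens pre-softmax, so the original method's
  rescaling is subsumed by softmax renormalization. Rows that would be
  fully masked are restored unmasked.
* Patients whose first visit already carries the target are dropped
  (no history remains to predict from), and counted.

## The desk-scale benchmark

The acceptance benchmark runs the full pipeline on a reduced-scale
`mdc_like` world: 600 patients, 150+30 codes, 3 codes/visit (keeping the
≈19-visit histories and the 10-visit motif offset), a 2-layer,
2-head, 32-dimensional encoder, 8 pre-training epochs, and 5-fold
fine-tuning, over 5 seeds. The reduction keeps the run inside a
single-CPU budget; the motif (log-odds 3.0, plant probability 0.55, base
rate 0.2) was fixed from the requirement that the Bayes ceiling exceed
0.75, before any benchmark was run. The event horizon for this benchmark
is $\sigma_{eh} = 0.33$ (the smaller of the two published settings),
selected on validation folds of the reduced world: at ~75-token
sequences the 6-cell kernel over-smooths, which mirrors the original
per-dataset tuning of $\sigma_{eh}$ on the fine-tuning split. The
benchmark asserts a direction — both augmented and unaugmented models
clear AUC 0.6 and ANAA's mean is within 0.02 of the baseline or better —
not an effect size.

## Numerical choices and degenerate inputs

* Noise statistics require `valid_len >= 2`; smaller matrices are a
  degenerate-input error (the variance is undefined).
* A kernel wider than twice the valid region warns ("heavy smoothing")
  and proceeds.
* Padded rows/columns are sliced out before attention and re-zeroed
  after augmentation, so no mass ever leaks into padding.
* Min-max scaling of a constant attention pool (min = max) defines the
  scaled value as 0 and flags the head degenerate in the diagnostics.
* Pre-softmax masking uses a finite $-10^{30}$ stand-in for $-\infty$;
  rows that would be entirely masked are restored unmasked.
* All seeds derived from a global seed stay below $2^{31}$ (R integer
  range); one named stream per purpose (data, split, noise, subsample).

## Known limitations

* One sequence per forward/backward pass (no cross-sample batching); the
  optimizer accumulates gradients over a mini-batch of sequences. This
  is adequate at desk scale but is the main performance limit.
* No learnable kernels, no pre-softmax noise, no per-layer
  $\sigma_{eh}$ — explicitly out of scope.
* No significance testing of AUC differences; reports carry fold-level
  values so users can apply their own.
* The polarization index (fraction of per-head min-max-scaled scores
  within $\varepsilon = 0.05$ of 0 or 1) is this package's scalar summary
  of the qualitative near-binary pattern, not a published statistic.
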