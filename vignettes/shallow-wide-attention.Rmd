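---
title: "Shallow, wide, attention: the model behind swam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shallow, wide, attention: the model behind swam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swam)
```

## The problem

Clinical notes — discharge summaries in particular — are annotated with sets
of ICD-9 diagnosis and procedure codes. Assigning those codes automatically
is a multi-label text classification problem with a peculiar structure: for
most codes, almost all of the document is irrelevant, and the signal is a
handful of short *informative snippets* ("endotracheal intubation",
"hyponatremia") scattered at arbitrary positions. A snippet may be
*non-generic* (informative for one or a few codes) or *generic* (a symptom
shared by many diagnoses).

`swam` implements a network built around that structure, plus everything
needed to study it end to end: preprocessing, CBOW embedding pretraining,
training with early stopping, the standard multi-label metric suite, a
bag-of-words baseline, attention-based snippet explanations, and a synthetic
corpus generator that plants snippets so that every claim the package makes
can be tested against known ground truth without access to credentialed
clinical data.

## The model

A document is the matrix $X = [x_1, \dots, x_N]$ of $d_e$-dimensional word
embeddings. One **shallow** convolutional layer with $d_c$ filters of width
$k$ produces the base representation

$$h_n = g(W_c * x_{n:n+k-1} + b_c),$$

with zero padding on both sides so $H \in \mathbb{R}^{d_c \times N}$ keeps
the document length (for even $k$ the padding is $\lfloor (k-1)/2 \rfloor$
on the left and $\lceil (k-1)/2 \rceil$ on the right). Each filter behaves
as a detector for one snippet pattern: it fires at the positions where the
window is close to its parameters in embedding space. That is why the layer
must be **wide**: every non-generic snippet in the label set needs a filter
of its own, so $d_c$ scales with the number of distinct snippets, not with
the number of labels.

Two pooling variants turn $H$ into per-label decisions:

* **Per-label attention.** Each code $\ell$ owns a vector $u_\ell$, giving
  attention weights $\alpha_\ell = \mathrm{SoftMax}(H^\top u_\ell)$ and the
  document representation $v_\ell = \sum_n \alpha_{\ell,n} h_n$. The argmax
  of $\alpha_\ell$ locates the snippet that drove the prediction, which is
  the package's explanation mechanism.
* **Max pooling** (the textCNN form): $v_j = \max_n h_{n,j}$ shared across
  labels, with per-filter argmax positions retained so explanations remain
  possible via the most influential filter.

Either way the prediction is $\hat y_\ell = \sigma(\beta_\ell^\top v_\ell +
b_\ell)$ and training minimizes the label-summed binary cross-entropy,
averaged over documents in a mini-batch.

The backward pass is derived analytically and implemented with the same
batched BLAS products as the forward pass; `tests/testthat/test-gradients.R`
verifies every parameter tensor against central finite differences at
relative error below $10^{-4}$ (observed errors are near $10^{-8}$).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 4 | filter width in tokens; also the explanation window length |
| `d_c` | 500 | number of filters — the "width"; the tuned optimum at clinical scale sits at the top of the 50–500 range |
| `d_e` | 100 | embedding dimension |
| `dropout` | 0.2 | dropout on the embedded input |
| `lr` | 0.001 | Adam learning rate |
| `batch_size` | 16 | mini-batch size |
| `patience` | 10 | early-stopping patience on validation macro-F1 |
| `threshold` | 0.5 | decision threshold for F1-type metrics |

`swam_default_grid()` carries the full tuning ranges (learning rate
$\{10^{-4}, 3\cdot10^{-4}, 10^{-3}, 3\cdot10^{-3}\}$, $k \in 1..10$,
$d_c \in \{50, \dots, 500\}$, dropout $0.2..0.8$) for `grid_search()`, which
holds seeds fixed across grid points so cells differ only in the tuned
values.

## Design choices where the design was open

Several details are under-determined by the architecture itself; the package
fixes them as follows and treats them as part of its contract:

* **Tokenization**: lowercase, split on maximal runs of non-alphanumeric
  characters, then drop tokens with no ASCII letter — so `100ml` survives
  and `100` does not. ASCII-only keeps the pipeline locale-independent.
* **Vocabulary**: a token must appear in at least `min_doc_freq = 3`
  *training* documents; everything else becomes `<unk>`. The padding id is
  reserved, its embedding pinned at zero, and its gradient discarded.
* **Truncation** keeps the *first* `max_len = 2500` tokens.
* **Label space**: the top-`k` codes by document frequency over the full
  corpus, computed *before* splitting; ties break by code string. Documents
  with no retained code are dropped.
* **Splits** are by patient (default 0.70/0.15/0.15), so no patient
  contributes documents to two partitions; patients are shuffled under a
  seed and cut at the cumulative fractions.
* **Activation**: `tanh` by default, `relu` available.
* **Masking**: batching pads documents to a common length; padded positions
  are excluded from the softmax (weight exactly zero) and from the
  max-pool. The zero-padding in the convolution itself is the length-
  preserving contract above, a separate mechanism.
* **Early stopping** counts only strict improvements in validation
  macro-F1; the returned parameters are those of the best epoch.
* **Optimizer**: Adam without weight decay. The trainer is deterministic
  given the parameter seed, the data-order seed and single-threaded BLAS.
* **Numerical stability**: max-shifted softmax; probabilities clamped away
  from 0/1 inside the loss at machine epsilon (with a warning in the
  user-facing `bce_loss()`).
* **Initialization**: symmetric fan-in-scaled uniform ranges for filters
  and output/attention weights, zero biases, seeded.
* **Explanation window**: the $k$-token convolution window anchored at the
  attention argmax, offset to mirror the padding and clipped at document
  edges; ties in the argmax break toward the earliest position. Documents
  shorter than $k$ return whole. Merging of adjacent high-attention windows
  into longer spans is deliberately out of scope.
* **Bootstrap**: the paired comparison resamples documents; ties between
  the two models' metrics count half, so identical models yield
  $p = 0.5$ and a strictly dominated opponent drives $p$ to 0.
* **Embeddings** are fine-tuned during supervised training by default
  (`freeze_embeddings` flips this). CBOW pretraining uses window 5, 5
  epochs, negative sampling with the usual unigram$^{3/4}$ distribution,
  and per-document mini-batch updates, which keeps it deterministic under a
  seed and vectorizable; tokens the trainer never sees keep their seeded
  random initialization.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a corpus of noise tokens (Zipf-distributed,
exponent 1.1, so the document-frequency filter is exercised by a realistic
long tail) in which each true label plants one of its non-generic snippet
phrases at a uniform random position, with optional generic snippets shared
by pairs of labels. Labels are independent Bernoulli draws, resampled if
empty; documents are assigned to patients round-robin. With
`plant_prob = 1` the corpus is fully separable and the string-matching
classifier `bayes_optimal_reference()` attains macro-F1 1, the ceiling
trained models are judged against.

The generator reproduces the *statistical* structure the architecture
assumes: local low-level features at random positions in long noisy
documents. It does not mimic clinical language — no negation, no section
structure, no synonymy beyond what embeddings induce, and no codes whose
assignment depends on the *absence* of information (the "unspecified"
diagnosis pathology, which defeats presence-based models generally). A
model passing the planted-snippet tests is therefore validated as an
implementation of the method, not certified to reach any particular
performance on real clinical text.

Defaults — 10 labels, 2 snippets per label of 3 tokens, 3 generic snippets,
label probability 0.3, noise vocabulary 5 000, mean length 300 tokens,
2 000 documents over 1 000 patients — train a wide model on one CPU in a
few minutes.

## The width ablation and the shuffle study

If each non-generic snippet needs its own filter, a model that is too
narrow must abandon some labels: at the decision threshold it never
predicts them, which surfaces as per-label precision 0 (the package defines
zero-denominator precision as 0 for exactly this reason). The package's
study configuration contrasts `d_c = 80` ("wide": comfortably above the 23
distinct planted snippets) with `d_c = 4` ("narrow": far fewer filters
than snippets), both at $k = 4$, $d_e = 32$, dropout 0.2, learning rate
0.001, batch 16, patience 10, at most 25 epochs — sizes chosen so the full
study runs end to end on a single CPU. `run_width_ablation()` refuses cells
that differ in anything but `d_c`.

*Which* labels a narrow model abandons is a property of the local optimum
it falls into, which depends on the order training data is visited:
`run_shuffle_study()` retrains under several data-order seeds and tabulates
the zero-precision sets. Under the study configuration the narrow model's
set changes across seeds while the wide model's stays empty — the
capacity-starvation signature, reproduced from planted ground truth.

On the same corpus the attention explanations are audited directly: for
true-positive predictions of the wide model, the extracted $k$-token window
overlaps the planted snippet in essentially all cases (the acceptance suite
requires at least 80%).

## Known limitations

* Single filter width per model; ensembles over widths are out of scope.
* One convolutional layer by design; the architecture argues depth buys
  nothing for snippet detection.
* The bag-of-words baseline uses a small fixed ridge penalty for numerical
  stability rather than the unpenalized fit, which matters only at
  near-separable extremes.
* The CBOW trainer is a compact reimplementation intended for corpora of
  this package's scale, not a tuned replacement for dedicated word2vec
  tooling.
* Training is pure R over BLAS; it is sized for the desk-scale studies
  above, not for multi-hundred-thousand-document corpora.
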