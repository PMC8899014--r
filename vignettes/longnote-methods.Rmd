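---
title: "Predicting clinical events from long notes: models and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clinical events from long notes: models and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital discharge summaries are long free-text documents — a combined
summary for one admission averages around 2,000 tokens — and they carry
signal about downstream clinical events such as re-admission or death within
a given horizon.  `longnote` implements a ladder of binary text classifiers
for this setting, from bag-of-words logistic regression up to an
attention-based encoder, together with the piece that makes the encoder
usable at all on documents of this length: *segment-combination heads* that
merge the encodings of non-overlapping fixed-size windows into a single
document representation.

Because the clinical corpora this family of models targets are access
restricted, the package ships a synthetic discharge-summary generator whose
shape mimics the real corpus (document length, heavy-tailed vocabulary, rare
positive targets, boolean patient attributes) and whose class signal is
planted, position-controllable and analytically tractable.  Every mechanism
in the package is exercised end to end against that generator.

## Models

**Bag-of-words.**  A document is its vector of word counts over a vocabulary
of words occurring in at least `min_doc_freq` documents (default 10); no
stemming, no stopword removal, no weighting.  The classifier is logistic
regression with an L2 penalty, fitted by BFGS on the exact objective.  A
squared-error-on-probabilities mode (`loss = "squared"`) is provided as an
alternative reading of minimising "L2 loss" between predicted and actual
labels; the conventional cross-entropy reading is the default, since the
model is a logistic regression.

**Mean-pooled n-gram embeddings.**  Every word and n-gram (orders up to
`n_max`, kept when frequent enough) owns a trainable vector $v_w$; a
document is the arithmetic mean over all its in-vocabulary unit *instances*
(duplicates counted),
$v_d = \mathrm{mean}\{v_w\}$, followed by a fully-connected 2-way softmax
layer.  No subword units and no external corpus are used.  Empty documents
pool to the zero vector, which keeps scoring total.

**Convolutional and recurrent baselines.**  The CNN is the standard
multi-width architecture: embeddings, parallel convolutions (default widths
3/4/5), ReLU, max-over-time pooling restricted to real token positions,
dropout, linear softmax.  The RNN is a GRU over the embedded sequence with
the final state classified linearly.  Both are trained with the shared
protocol below.

**Simplified attention encoder.**  The encoder implements the simplified
single-head block literally: with lower-layer vectors $v_t$ and model
dimension $D$,

$$\alpha_t = \mathrm{softmax}_t\!\left(\frac{v_i^\top W' v_t}{\sqrt D}\right),
\qquad
v_i' = \tanh\!\Big(W \sum_t \alpha_t v_t\Big),$$

with per-layer trainable matrices $W$ and $W'$, learned positional
embeddings added to token embeddings at the input, and a reserved CLS token
at position 0.  Classification is $c = \arg\max(W_1 v_0^{top})$ through a
softmax, with exact ties resolved to label 0.  There is deliberately no
value projection, no residual connection, no layer normalisation and no
feed-forward sublayer on the reference path; a `block = "standard"` mode
(residual + layer norm around the same attention) exists for robustness
studies only.  The $1/\sqrt D$ scale is the conventional choice for a
"scaled" dot product; `scale = "none"` disables it.

All gradients are computed by hand-derived backpropagation and verified
against numerical differentiation (relative error below $10^{-4}$) and
against a brute-force per-position oracle (agreement within $10^{-6}$).

## Segment-combination heads

The encoder window (512 positions in the clinical preset, one taken by CLS)
is far shorter than a discharge summary, so documents are cut into
non-overlapping windows and the per-segment encodings are merged by one of
seven heads:

| strategy     | document vector $v_d$                                   | encoder |
|--------------|---------------------------------------------------------|---------|
| `lstm_cls`   | final LSTM state over the per-segment CLS vectors        | trained |
| `lstm_top`   | final LSTM state over *all* top-layer vectors            | frozen  |
| `concat_top` | all top-layer vectors concatenated (zero-padded to S)    | frozen* |
| `concat_cls` | CLS vectors concatenated (zero-padded to S)              | trained |
| `mean_cls`   | elementwise mean of CLS vectors                          | trained |
| `min_cls`    | elementwise min of CLS vectors                           | trained |
| `max_cls`    | elementwise max of CLS vectors                           | trained |

$v_d$ goes to a linear 2-way softmax classifier and the whole model trains
by backpropagation; with a frozen encoder, encoder parameters receive no
updates at all (the test suite checks they stay bitwise identical).
`lstm_top` is always frozen — backpropagating through every position of
every segment is its defining cost trade-off — and `concat_top` requires
freezing unless explicitly relaxed (`relax_freeze = TRUE`), since the
sources describing this family leave its training mode ambiguous.

Choices that were genuinely open, and what this package does:

* **Segment budget.**  `max_segments` defaults to 6, which covers a
  ~2,000-token document at the 511-content-token clinical window; longer
  documents are truncated at the tail.  Zero-vector padding fills the fixed
  dimension of the concatenation heads; padding never enters the recurrent
  heads.
* **`lstm_top` input order.**  Segments in document order, positions within
  a segment in order (flattened).
* **Recurrent unit.**  A standard LSTM cell, final-state readout, hidden
  size 256 in the clinical preset (tests use 16–32).

## Attribute fusion

Non-text attributes (age, gender, demographics, admission type, …) are
encoded as a fixed-order boolean vector by a schema of threshold/equality
rules; missing raw values encode as 0, keeping the encoding total.  The
clinical preset schema has 255 variables in the families listed above —
the exact category lists are synthetic placeholders (the real definitions
are not public), so only the dimension and family structure are meaningful
— and deliberately excludes variables describing medical treatments.  The
fused model concatenates the bits after the text representation fed to the
final classifier (text dimensions first), so zero attribute weights recover
the text-only model exactly.  An attribute-only baseline (single linear
layer + softmax) shares the training protocol.

## Evaluation protocol

* **Split**: 75% train / 10% validation / 15% test, group-atomic on the
  admission identifier so records deriving from the same admission can never
  straddle partitions.  Groups are shuffled under a seed and assigned
  greedily against the record-count quotas; with singleton groups the sizes
  are exact.
* **Oversampling**: the training partition is balanced by repeated full
  without-replacement passes through the minority pool, with a final
  without-replacement partial pass.  ("Oversampling without replacement" is
  literally contradictory; full-pass duplication is the only balancing
  procedure consistent with both words.)  Validation and test sets stay
  unbalanced.
* **Training**: 5 epochs of single-example Adam; validation AUC after every
  epoch; the best-validation snapshot is returned and the test AUC is
  computed once, on that snapshot.  Every run is an exact function of its
  seed.  The document-model step size defaults to $3\times10^{-3}$, chosen
  by validation-set pilot runs at the reference configuration (the
  convex/bag-of-words and attribute models are insensitive and use larger
  steps).
* **AUC**: Mann–Whitney pair counting with half-credit for ties — identical
  to trapezoidal ROC integration but with a trivially verifiable oracle
  (exhaustive pair enumeration).
* **Comparison**: paired stratified bootstrap (default 2,000 replicates) of
  the AUC difference, two-sided.  The underlying sources never name their
  significance test; a paired bootstrap is the conventional choice for
  paired AUCs and is exposed with configurable replicates.
* **Cross-validation**: repeated random re-splits with metric averaging
  (`split_spec` seeds), repeat count at the caller's discretion.

## The synthetic generator

For each document: a true label $y \sim \mathrm{Bernoulli}(\pi)$; background
tokens i.i.d. Zipf($\alpha = 1.1$) over `vocab_size` word types (heavy-tailed
like clinical vocabulary, but *not* a language model); document length
lognormal with mean ≈ 2,000 tokens by default; a Poisson count of dedicated
signal tokens with rate $\lambda_0$ for negatives and $\lambda_0 e^{\beta}$
for positives, overwriting background positions inside the placement region
(`uniform`, `head`, `tail`, or a specific window `segment_k`); optional
label flips with probability $\varepsilon$; and boolean attributes whose
per-attribute log-odds shift between classes, independent of the text
signal so that fusion gains are provable.

Two properties make the generator a usable oracle.  First, the signal-token
*count* is a sufficient statistic, so the best achievable AUC
(`bayes_auc()`) is computable exactly by enumerating the two Poisson
mixtures — trained models must approach it from below.  Second, signal
enters as token presence/count rather than order, so count-based models
(bag-of-words, mean-pooling) can succeed in principle, and
position-sensitive architectures differ only through placement — exactly
the axis the head/tail experiments vary.

Prevalence presets for the ten studied targets are available
(`target_prevalence("readmit7")` ≈ 0.024, etc.).  What passing tests on this
generator does *not* show: anything about real clinical language —
negation, abbreviation, section structure, temporal narrative, or
correlated signal spread through the discourse.  The generator validates
*mechanisms* (optimisation, segmentation, heads, fusion, protocol), not
clinical performance.

## Reference problem sizes

The test suite and reproduction script run everything at desk scale on one
CPU, a deliberate configuration of the package rather than a statement
about the clinical problem:

* encoder preset for experiments: $D = 32$, $L = 2$, window 64 (the 512
  window with BERT-scale dimensions is the clinical preset; nothing in the
  mechanics depends on the size);
* reference recovery corpus: 2,000 documents of ≈130 tokens (two to three
  segments at window 64), vocabulary 300, prevalence 0.3,
  $\lambda_0 = 1$, $\beta = 2$ (ceiling AUC ≈ 0.99);
* multi-segment-signal corpus (for comparing combination heads): 1,000
  documents of ≈250 tokens (four to five segments), per-document base rate
  $\lambda_0 = 2$, $\beta = 1.25$ (ceiling ≈ 0.96).  The per-segment
  evidence is deliberately weak so that it must be accumulated *across*
  segments: an extreme statistic such as elementwise min pooling discards
  most of it, while a recurrent head can integrate it.  (With strong,
  uniformly placed signal every segment separates the classes on its own
  and all heads — including min pooling — perform near ceiling, so that
  regime cannot distinguish head capacities.);
* head/tail asymmetry corpus: 800 documents of 256 tokens, placement
  `tail`;
* fusion corpus: 800 short documents with independent moderate text and
  attribute signal.

## Numerical conventions and degenerate inputs

* Exact classification ties resolve to label 0; `classify_cls` reports both
  softmax probabilities.
* Empty documents (or documents that are entirely out of vocabulary) score
  0.5 and are skipped during training; empty *inputs* to segmentation,
  head/tail extraction or admission assembly are errors, by contract.
* Documents shorter than a window are returned whole by head/tail/random
  windows rather than erroring (short notes exist in realistic corpora).
* The logistic fit declares failure on single-class training sets; AUC is
  undefined and errors when a class is absent.
* All trainable tensors initialise small-normal (sd 0.1) under the run
  seed; Adam uses the conventional moment decays (0.9 / 0.999).
* tanh bounds every encoder output coordinate to the open interval
  $(-1, 1)$; saturated values can round to ±1 in floating point, which the
  tests treat as the boundary case it is.

## Known limitations

* No subword tokenization: the default tokenizer lower-cases, splits
  punctuation and keeps digit runs.  The mechanisms under study are
  tokenizer-agnostic; a subword vocabulary can be plugged in by supplying
  pre-tokenized input.
* Importing externally pre-trained encoder weights is out of scope: the
  simplified block's shapes differ from published checkpoints, and no
  pre-training objective is included.
* Single-label binary targets only; no ICD-code modelling; no
  interpretability tooling.
* Training is plain R linear algebra: ideal for the tested scales
  (thousands of documents, $D \le 64$), not for BERT-scale replication.
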