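---
title: "Methods: shallow bag-of-n-gram classification of abstract sentences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shallow bag-of-n-gram classification of abstract sentences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Biomedical abstracts of randomized controlled trials are commonly structured:
each sentence plays one of five rhetorical roles — OBJECTIVE, BACKGROUND,
METHODS, RESULTS, CONCLUSIONS. `sectionseer` assigns these roles to
sentences. The model family is deliberately shallow: a linear classifier over
averaged n-gram embeddings (the fastText architecture), which trains in
seconds to minutes on a single CPU while staying competitive with much
heavier sequence models on this task.

## Supervised model

A sentence is represented as a normalized bag of features: its word unigrams
plus all consecutive word n-grams up to `n_max`. With feature embeddings
$v_f \in \mathbb{R}^h$ (columns of the input matrix $V$) and class weights
$U \in \mathbb{R}^{k \times h}$, the predicted distribution over the $k = 5$
labels for a sentence $S$ with feature multiset $R(S)$ is

$$ p(y \mid S) = \mathrm{softmax}\!\left( U \cdot \frac{1}{|R(S)|}
   \sum_{f \in R(S)} v_f \right). $$

Training minimizes the negative log-likelihood by plain SGD, one sentence at
a time, with a learning rate decaying linearly to zero over the full pass
budget. Updates are sparse: only the embedding columns of features present
in the current sentence are touched. $V$ is initialized uniformly on
$[-1/h, 1/h]$ and $U$ at zero (so the first step moves only $U$; the loss at
initialization is exactly $\ln k$, a closed form the tests rely on).

**Feature space.** Unigrams get exact ids $1..|\mathcal{V}|$ from the
vocabulary ( `min_count` filters rare words). Higher-order n-grams are
mapped by the hashing trick into a fixed number of `buckets`
(ids $|\mathcal{V}|+1, \dots$): FNV-1a (64-bit) is computed over the n-gram's
token *strings* joined by a non-printing separator, then reduced mod
`buckets`. Hashing strings rather than vocabulary ids makes a bucket id
independent of the vocabulary, which is what allows pre-trained n-gram
vectors to be transferred between models trained on different corpora.
Out-of-vocabulary unigrams are dropped from the bag but still occupy their
slots inside n-grams.

**Defaults** (`train_config()`): `dim = 20`, `n_max = 2`, `epochs = 5`,
`lr = 0.1`, `buckets = 2e6`, `min_count = 1`. The tests and the acceptance
experiments use `buckets = 2e5`, which is collision-negligible at the
synthetic corpora's ~3k-word vocabularies.

## Context augmentation

Bag-of-n-gram models see no sentence order, yet the rhetorical role depends
heavily on where a sentence sits. Two cheap preprocessing steps re-inject
that signal (`augment_config()`):

* a **position token** `pos_<i>` with the sentence's 1-based index;
* **context tokens**: every token of up to `window = 2` neighboring
  sentences on each side, each prefixed with its offset (`-2_`, `-1_`,
  `+1_`, `+2_`), laid out as distant-preceding … preceding, position token,
  the target sentence's own tokens unchanged, then trailing context.

The prefixes keep context vocabulary disjoint from target vocabulary, so the
classifier can weight "the word *patients* in the preceding sentence"
differently from the same word in the target sentence. Ablations in the
acceptance suite quantify both steps on synthetic corpora: context tokens
and the position token each raise weighted F1 substantially over the
single-sentence model (full − single ≈ 0.065). One caveat specific to the
simulator: because synthetic neighbor tokens come from label-specific pools,
window-2 context almost directly reveals neighbor labels and subsumes the
position token, so the position token's *additional* gain on top of context
is a null effect there (it is positive on real prose, whose neighbors are
noisier).

## Unsupervised pre-training

`pretrain_vectors()` learns embeddings from unlabeled sentences with
negative sampling. For a target word $w_t$ with context feature set $C$
(average embedding $v_C$) and negatives $N$ drawn from the noise
distribution $p(w) \propto \mathrm{freq}(w)^{0.75}$, the per-pair loss is

$$ \ell = \log\!\big(1 + e^{-u_{w_t}\cdot v_C}\big)
        + \sum_{n \in N} \log\!\big(1 + e^{+u_{n}\cdot v_C}\big), $$

the standard sign convention of the negative-sampling literature (a target
is pulled toward its context, negatives are pushed away). At zero parameters
$\ell = (1 + |N|)\ln 2$, another closed form used by the tests. Two context
definitions are available:

* **cbow** — a fixed window of unigrams around the target (default 5);
* **sent2vec** — the whole sentence minus the target, including the n-grams
  of the spliced remainder, which makes the learned sentence embedding the
  simple average of its feature vectors (`sent2vec_embed()`).

Defaults: 5 negatives, `lr = 0.05`, `min_count = 5`.

Pre-trained vectors enter the supervised model through `transfer_init()`:
unigram columns are copied for tokens shared with the new vocabulary, the
hashed n-gram block is copied wholesale (valid because bucket ids are
string-hashed), and everything unseen is freshly initialized from the same
seed. Alternatively, frozen sent2vec sentence embeddings can feed a small
softmax perceptron head (`train_mlp_head()`, `nnet`-based, 100 hidden
units, weight decay 1e-4).

## Evaluation

`confusion_matrix()` (rows = true), `per_class_metrics()` (precision,
recall, F1; any 0/0 is defined as 0) and support-weighted F1 — the headline
metric — plus `grid_search()` over (dim, n-gram order, epochs) with ties
broken toward the smaller model, and `learning_curve()`, which samples
byte-identical train/test splits for every setup so that scratch and
pre-trained runs are compared on exactly the same data.

## Synthetic corpus

Because the reference benchmark cannot be bundled, `generate_corpus()`
produces corpora with the same statistical skeleton: sections appear in
canonical order with realistic presence probabilities and lengths (methods
and results dominate, ≈2/3 of sentences), each label owns a discriminative
token pool, and objective/background share a confusable pool — the two
classes that are genuinely conflated in real abstracts. Each token is
discriminative with probability `delta = 0.3` (objective/background redirect
`epsilon = 0.5` of those draws to the confusable pool), otherwise it comes
from a shared pool; draws within a pool follow a 1/rank law.

Sentence lengths are uniform on 4–9 tokens. This was calibrated a priori:
at `delta = 0.3` an average sentence carries ≈2 discriminative tokens,
which puts the single-sentence classifier near weighted F1 0.85 — informative
but ambiguous, the regime in which position and context augmentation have
room to help and pre-training pays off at low label counts. The limits are
analytic anchors used by the tests: `delta = 1, epsilon = 0` is perfectly
separable (F1 1.0); `delta = 0` is label-independent (F1 at the
majority baseline); `epsilon = 1` makes objective/background the most
confused pair of the trained model's confusion matrix.

What passing on synthetic data shows — and what it does not: it validates
the mechanics (optimization, augmentation, transfer, evaluation) and the
qualitative phenomena (ablation ordering, low-label pre-training gains).
It does not reproduce published benchmark scores, which require the external
200k-abstract corpus.

## Problem sizes and numerics

The acceptance experiments use a medium corpus (5000 abstracts, ≈54k
sentences): the ablation trains 12 models (3 splits × 4 setups, dim 20,
bigrams, 10 epochs), and the learning curve compares scratch vs. pre-trained
initialization at 500 and 20000 labeled sentences (5 replicates, 20 epochs,
20000 test sentences). Everything runs single-threaded; training is
bit-reproducible for a fixed seed (C++ Mersenne Twister with explicit
shuffling; R-side RNG state is saved and restored around seeded routines).
Softmax is computed with max-subtraction; `log(1 + e^x)` via a
branch-stable softplus.

## Limitations

No sequence-level decoding (each sentence is classified independently given
its augmented bag); no subword features; the synthetic generator makes no
attempt at English realism — the method is lexical-statistical, so
distributional structure suffices for validating the implementation.
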