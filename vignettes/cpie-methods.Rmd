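---
title: "Extracting chemical-protein interactions with contextual embeddings and multihead attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting chemical-protein interactions with contextual embeddings and multihead attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpie)
```

## The task

Chemical-protein interaction (CPI) extraction asks, for a sentence
containing a chemical mention and a gene/protein mention, which of a fixed
set of semantic relations holds between the pair. In the ChemProt corpus
setting adopted here, gold entity mentions are given and each
within-sentence (chemical, gene) pair is a candidate instance to be
classified into one of five evaluated relation classes — CPR:3
(upregulator/activator), CPR:4 (downregulator/inhibitor), CPR:5 (agonist),
CPR:6 (antagonist), CPR:9 (substrate/product-of) — or a negative class.
Gold relations of the non-evaluated classes (CPR:1, 2, 7, 8, 10) are
treated as negatives, matching the shared-task evaluation.

`cpie` implements the full pipeline: corpus parsing and validation,
candidate generation, featurization, a trainable contextual-representation
layer, a Bi-LSTM + multihead-attention classifier, the training protocol,
micro-averaged evaluation, and a synthetic corpus generator that makes
every stage testable without any external download.

## Corpus conventions

The three-file TSV dialect (abstracts, entities, relations; headerless,
tab-separated, unquoted, UTF-8) is parsed by `read_corpus()`. Character
offsets are **0-based and half-open** over
`full_text = title <TAB> abstract`; the tab separator is configurable but
the offsets always resolve against the reconstructed `full_text`, and
every entity's stored surface string is checked against its slice at parse
time. Sentence splitting is pluggable; the default rule-based splitter
breaks at `.?!` followed by whitespace and an uppercase letter or digit,
with a small abbreviation guard. The title is always its own sentence.

Candidate generation (`generate_candidates()`) enumerates every
within-sentence (chemical, gene) pair. The chemical argument of a gold
relation is normalized into the `chem` slot whatever its Arg1/Arg2
position. A pair with several evaluated gold classes yields one instance
per (pair, class); cross-sentence gold relations are dropped and counted
(the published per-class supports themselves sum to slightly fewer
instances than the corpus-level relation count, consistent with a small
cross-sentence remainder that a sentence-level system cannot address).

## Featurization

Tokenization is mention-boundary-aware: each gold mention (possibly
multi-word) is kept as a single token, so no token boundary can fall
inside an entity; everything else is whitespace/punctuation splitting. POS
tags come from an injected tagger with a deterministic coarse rule tagger
as the default — the model only consumes a small tagset embedding, so any
tagger with a fixed tagset can be substituted.

Each token receives two **entity-relative position features**: distance 0
inside the target mention's token range, signed token distance outside it,
clipped to `[-D, D]` (default `D = 30`, shifted to non-negative indices
for embedding lookup). The two target mentions are replaced by the
placeholders `CHEM_ENT` / `GENE_ENT` by default, which prevents the
classifier from memorizing surface names; policies `"none"` and `"all"`
are available.

## Contextual representation layer

Instead of static word vectors, each token is represented by a
**bidirectional language model** (bi-LM). A forward LSTM LM factorizes the
sentence probability left-to-right, a backward LM right-to-left, and
training maximizes the summed log-likelihood of both directions — the
joint objective is exactly the forward sum plus the backward sum, and each
direction is causal (the forward log-probability of token *k* depends only
on tokens before *k*; this is enforced by perturbation tests). The
per-token representation is the ELMo-style mix

$$r_k = \gamma \sum_{j=0}^{L} s_j\, h_{k}^{(j)}, \qquad s = \mathrm{softmax}(w),$$

over the embedding layer (duplicated to `[e_k \| e_k]`) and the `L` LSTM
layers (forward‖backward states). The bi-LM is trained on the task corpus
and **frozen**; the mixing weights $w$ and scale $\gamma$ are trained with
the task loss. This keeps the interface of a large pretrained
contextualizer — `load_precomputed()` accepts externally computed
per-sentence representations through the same provider mechanism — while
remaining self-contained and CPU-sized. The package's bi-LM uses a word
embedding input (no character convolutions) and requires
`embedding_dim == hidden_dim` so all layers share one width.

## Classifier

Per token, the input vector concatenates the contextual representation,
the two position embeddings and the POS embedding. The encoder is a
**Bi-LSTM** with the standard gate equations

$$f_t, o_t, i_t = \sigma(W x_t + U h_{t-1} + b), \quad
g_t = \tanh(\cdot), \quad c_t = f_t \odot c_{t-1} + i_t \odot g_t,$$

and $h_t = o_t \odot \tanh(c_t)$. A variant with
$h_t = o_t \odot \tanh(c_{t-1})$ — the output gate applied to the
*previous* cell — is retained behind `variant = "literal"` for fidelity
experiments; it ignores the current cell update, the two variants agree
exactly whenever $c_t = c_{t-1}$, and the standard form is the default and
the only one used in training. Forward and backward hidden states are
concatenated into width $d = 2H$.

**Multihead self-attention** follows
$\mathrm{Attention}(Q,K,V) = \mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ with
per-head projections $W^Q_k, W^K_k, W^V_k \in \mathbb{R}^{d \times d/h}$,
concatenation, and an output projection $W^O \in \mathbb{R}^{d \times d}$.
Design choices where the formulation leaves room:

* **Scaling**: the per-head key width $\sqrt{d/h}$ is the default scaling
  divisor (it keeps logits unit-scale per head); `scale_mode =
  "model_width"` uses $\sqrt{d}$ literally.
* **Projections**: Q, K and V get three separate projections per head.
* **No residual connections or layer normalization** are wrapped around
  the attention block — the model is the plain composition of encoder,
  attention, pooling.
* **Masking**: padded positions receive $-\infty$ logits so they can never
  draw attention weight. In practice each instance's attention runs on its
  unpadded rows only, which the padding-invariance tests verify
  end-to-end.

**Attention pooling** maps the attention output to one sentence vector:
$u_t = v^\top \tanh(W^\top m_t)$, $\alpha = \mathrm{softmax}(u)$ over
unmasked positions, $s = \sum_t \alpha_t m_t$. The weights $\alpha$ are
exposed — they drive the keyword report. A 6-way softmax layer produces
the class distribution.

All forward and backward passes are written explicitly in vectorized R
(the LSTM is batched across instances at each time step), and every
parameterized block is verified against central finite differences at
float64 with relative error below $10^{-4}$, alongside brute-force loop
oracles for the LSTM cell, scaled dot-product attention, multihead
attention and pooling.

## Training protocol

Categorical cross-entropy, RMSProp (learning rate 0.001, decay 0.9,
epsilon $10^{-7}$ — the latter two are unstated in the reference protocol
and fixed here as the common defaults), mini-batch 64, dropout 0.5 applied
at two sites (the concatenated input embeddings and the pooled sentence
vector), a 10% uniformly sampled validation split, and early stopping.
The early-stopping metric is validation micro-F (the protocol names the
validation set but not the metric; micro-F is the task's headline number),
with patience 5 by default and the best checkpoint kept (ties to the
earliest epoch). Experiments are repeated over five seeds by default and
the micro metrics averaged arithmetically; each seed redraws its
validation split. No class re-weighting is applied by default (an optional
hook exists), since the protocol mentions none despite the heavy negative
majority. Training is bit-reproducible given (data, configuration, seed).

Initialization is uniform Glorot for all weight matrices — including the
output layer, since a zero output layer would pass no gradient to the
encoder at the start of training — zeros for biases except the LSTM
forget-gate bias (1), and uniform mixing weights.

## Synthetic corpora: what they emulate and what they do not

`generate_corpus()` builds ChemProt-format corpora from slot-filling
sentence frames (active, passive, multi-clause) around one chemical and
one gene mention, with Zipf-distributed filler tokens and synthetic entity
surfaces (`CHM####`, `GEN####`). Per class, a trigger keyword drawn from a
small disjoint lexicon (seeded from the attention-keyword vocabulary of
the five classes: *expression/increased/induced/activation/activity*,
*inhibitor/inhibition/inhibitors/inhibited*, *agonist/agonists/selective*,
*antagonist/antagonists*, *metabolism/catalyzes/metabolized/uptake/enzyme*)
is planted near the pair with probability `trigger_strength`; otherwise a
neutral verb disjoint from every lexicon is used. Consequences that the
tests rely on:

* at trigger strength 1 with no distractors, a keyword-matching rule is
  Bayes-optimal (micro-F 1), so a trained model's ceiling is known;
* at trigger strength 0 the positive classes carry no signal, so a model
  should collapse to the prior;
* micro-F should fall as trigger strength falls.

`generate_hard_corpus()` raises passive-frame and multi-clause distractor
rates and plants cross-class CPR:3/CPR:4 trigger confounds, emulating the
qualitative error structure of real corpora (passive constructions and
clause-separated pairs drive false negatives; CPR:3 vs CPR:4 is the
dominant inter-class confusion).

Default generator settings — 50% negatives and 10% per positive class,
3-6 sentences per document, 10% passive frames, vocabulary 120, one
entity pair per sentence — are one fixed, documented operating point.
Real ChemProt text differs in essentially every distributional respect:
much heavier negative skew, multiple pairs per sentence, anaphora, real
morphology, annotation noise. Passing the synthetic recovery tests
therefore demonstrates that the architecture, gradients, protocol and
reporting work as specified — not that any particular benchmark F-score
would be reproduced on the real corpus, which requires the external
corpus and GPU-scale training and is out of scope here.

The generator draws one RNG substream per sentence, with all difficulty
decisions drawn before content: a knob that extends a sentence's tail
(the distractor rate) provably leaves every other sentence, every label
and every gold relation unchanged.

## Evaluation

The scorer is a fixed-order 6×6 confusion matrix (gold × predicted) and
micro-averaged precision/recall/F pooled over the five positive classes:
NEG is excluded from the positive set, but negatives predicted as
relations count as false positives and relations predicted NEG as false
negatives. Per-class metrics use the zero convention for empty
denominators. Reports round half-even to 3 decimals. A stored confusion
matrix can be scored directly (`read_confusion_tsv()`), and the package
ships the published test-set confusion matrix of a contextualized
Bi-LSTM + multihead-attention CPI model on ChemProt
(`inst/extdata/chemprot_test_confusion.tsv`) as a worked example: scoring
it reproduces micro 0.706/0.618/0.659 and the per-class breakdown to three
decimals, which is the package's exact numeric reference surface.

The attention-keyword report ranks tokens by their **mean** pooling weight
over the instances predicted as each class, with a minimum-support
threshold (`min_count = 2`) so a token seen once with an incidentally
high weight cannot top the list. Mean rather than summed aggregation is
deliberate: summed weights are dominated by ubiquitous function words
whose many small weights outweigh rare, heavily attended class triggers,
while the mean isolates how strongly a token is attended when it occurs
(`agg = "sum"` is available). Placeholders and padding are excluded;
stopwords are not filtered. A caveat that matters at desk scale: once the
classifier separates the classes, nothing forces the pooling weights to
sit on the trigger token itself — self-attention has already mixed the
trigger's evidence into every position — so keyword-trigger alignment is
a qualitative, seed-dependent diagnostic, not a guaranteed outcome of
high accuracy. On some training seeds the report locks onto frame markers
(e.g. the passive "was"/"by") for a subset of classes.

## Problem sizes and numerical choices

The package's study sizes, used by its own end-to-end checks and chosen
once as a desk-scale operating point for a single CPU:

* easy-corpus recovery: ~2 900 instances (650 documents), full protocol
  (dropout 0.5, batch 64, RMSProp 0.001), at most 20 epochs; network
  ctx 64 (= 2×32 bi-LM), Bi-LSTM hidden 48 per direction (d = 96), 2
  heads, position/POS embeddings 16/8, bi-LM pretrained 4 epochs. Width
  matters under 0.5 dropout: substantially narrower networks need many
  more epochs at this corpus size.
* difficulty sweeps: 180-300 documents, dropout 0 and 12-15 epochs, a
  narrower network (ctx 32, hidden 24) — these runs compare conditions,
  so clear convergence at small cost is preferred over protocol fidelity.
* reference-scale settings (hidden 300 per direction, 6 heads × width
  100, embeddings 50, clip distance 30) remain the `model_config()`
  defaults and are exercised shape-wise in the tests.

Numerical details: masked softmax uses $-\infty$ logits with an error on
fully masked rows; probabilities are floored at $10^{-300}$ inside the
log-loss only; dropout is "inverted" (activations scaled by $1/(1-p)$ at
training time); ties in early stopping resolve to the earliest epoch;
`argmax` prediction ties resolve to the first class in the fixed order.
The bi-LM keeps the parameters of its best epoch, so its returned
objective never falls below the initialization's.

## Known limitations

* The bi-LM is a word-level LM trained on the task corpus; it shares the
  interface, not the capacity, of a large pretrained contextualizer.
* The scorer works at the instance level; abstract-level (pair, class)
  aggregation, as used by some official evaluation services, is left as a
  hook.
* Document-level (cross-sentence) relations are out of scope by
  construction; they are counted and dropped.
* The rule-based sentence splitter and coarse POS tagger are deliberate
  dependency-free defaults; both are injection points.
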