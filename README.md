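# cpie — chemical–protein interaction extraction

`cpie` is an R package for sentence-level **chemical–protein interaction
(CPI) extraction** from ChemProt-format corpora. Given abstracts with gold
chemical and gene/protein mentions, it classifies every within-sentence
(chemical, gene) pair into one of the five evaluated ChemProt relation
classes — CPR:3 (upregulator/activator), CPR:4 (downregulator/inhibitor),
CPR:5 (agonist), CPR:6 (antagonist), CPR:9 (substrate/product-of) — or a
negative class. It is aimed at biomedical text-mining researchers who want
a transparent, fully testable reference implementation of this model
family on a single CPU.

## The model

Each token of a candidate sentence is represented by an ELMo-style
contextual vector from a small trainable bidirectional language model,

    r_k = γ Σ_j softmax(w)_j · h_k^(j),

concatenated with two entity-relative position embeddings and a POS
embedding. The sequence is encoded by a Bi-LSTM
(`c_t = f_t ⊙ c_{t−1} + i_t ⊙ g_t`, `h_t = o_t ⊙ tanh(c_t)`, forward and
backward states concatenated), refined by multihead scaled dot-product
self-attention

    Attention(Q, K, V) = softmax(QKᵀ / √d_k) V

with per-head projections and an output projection, collapsed to one
sentence vector by attention pooling
(`α = softmax(vᵀ tanh(Wᵀ m_t))`, `s = Σ α_t m_t`), and classified by a
6-way softmax. Training follows the standard protocol for this model
family: categorical cross-entropy, RMSProp (lr 0.001), mini-batch 64,
dropout 0.5 before the encoder and the output layer, a 10% validation
split with early stopping, and averaging over repeated seeded runs.
Evaluation is micro-averaged precision/recall/F over the five positive
classes. All forward/backward passes are written explicitly and verified
against finite differences and brute-force oracles.

A synthetic ChemProt-format corpus generator with controllable difficulty
(per-class trigger keywords, trigger strength, passive frames, distractor
clauses, CPR:3/CPR:4 confounds) makes every stage runnable and testable
offline; see the methods vignette (`vignettes/cpie-methods.Rmd`).

## Worked example

Scoring a stored confusion matrix — here the published test-set confusion
matrix of a contextualized Bi-LSTM + multihead-attention CPI model on
ChemProt, shipped with the package:

```r
library(cpie)
cm <- read_confusion_tsv(system.file("extdata", "chemprot_test_confusion.tsv",
                                     package = "cpie"))
eval_report(cm)
#> Per-class performance:
#>   label   support precision  recall       F
#>   CPR:3       664     0.662   0.539   0.594
#>   CPR:4      1661     0.704   0.732   0.718
#>   CPR:5       194     0.737   0.593   0.657
#>   CPR:6       281     0.759   0.694   0.725
#>   CPR:9       643     0.735   0.379   0.501
#> Micro average: precision 0.706, recall 0.618, F 0.659
```

Micro precision is pooled true positives over pooled predicted positives
across the five relation classes (the negative class only contributes
false positives/negatives); F is the harmonic mean of micro precision and
recall.

Training end-to-end on a synthetic corpus (a reduced-size run; ~1 minute
on one CPU):

```r
gen <- generate_corpus(synth_config(n_docs = 300, seed = 41,
                                    trigger_strength = 1, distractor_rate = 0))
pipe <- cpie_train_pipeline(gen$corpus, seed = 6, ctx_dim = 16, hidden = 24,
                            heads = 2, pos_dim = 8, postag_dim = 8,
                            bilm_epochs = 2,
                            train_cfg = train_config(dropout = 0,
                                                     max_epochs = 15,
                                                     patience = 15))
pipe$run
#> <cpie_run_result> seed 6 - 15 epochs, best val micro-F 0.684 at epoch 12
cpie_evaluate(pipe, pipe$split$val)$keywords[["CPR:3"]]
#> [1] "expression" "enzyme"     "inhibitors" "activity"   "activation"
```

The planted CPR:3 trigger keywords (*expression*, *activation*, ...)
surface in the attention-keyword report; at the package's full study size
(~2 900 instances, wider network, full dropout-0.5 protocol) validation
micro-F exceeds 0.9 within 20 epochs and the top-1 keyword per class is
the planted trigger — that configuration is what the acceptance script
runs.

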