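# End-to-end convenience layer: corpus -> candidates -> features ->
# contextual representations -> trained classifier -> evaluation.

#' Prepare a corpus for training
#'
#' Generates candidates, builds the token vocabulary over the (anonymized)
#' candidate sentences, and featurizes every candidate.
#'
#' @param corpus a `cpie_corpus`.
#' @param D position clip distance.
#' @param anonymize entity anonymization policy (see [featurize()]).
#' @param min_count vocabulary minimum token count.
#' @param tagger POS tagger.
#' @return List with `candidates`, `vocab`, `feats`.
#' @export
prepare_corpus <- function(corpus, D = 30L, anonymize = "target",
                           min_count = 1L, tagger = default_pos_tagger) {
  candidates <- corpus_candidates(corpus)
  vocab <- corpus_vocab(candidates, corpus, anonymize = anonymize,
                        tagger = tagger, min_count = min_count)
  feats <- featurize_corpus(candidates, corpus, vocab, D = D,
                            anonymize = anonymize, tagger = tagger)
  list(candidates = candidates, vocab = vocab, feats = feats)
}

#' Pretrain the contextualizer and precompute representations
#'
#' Trains the small bi-LM on the distinct token sequences of the
#' featurized instances, freezes it, and precomputes the per-sentence
#' layer stacks.
#'
#' @param feats featurized instances.
#' @param vocab the token vocabulary (fixes the bi-LM vocabulary size).
#' @param embedding_dim bi-LM embedding/hidden width per direction.
#' @param layers bi-LM LSTM layers per direction.
#' @param epochs bi-LM training epochs.
#' @param seed integer seed.
#' @param lr bi-LM learning rate.
#' @return List with `bilm` (the [train_bilm()] result) and `provider`.
#' @export
pretrain_contextualizer <- function(feats, vocab, embedding_dim = 12L,
                                    layers = 1L, epochs = 2L, seed = 1L,
                                    lr = 0.01) {
  keys <- vapply(feats, function(f) f$sentence_key, "")
  seqs <- lapply(feats[!duplicated(keys)], function(f) f$token_ids)
  cfg <- bilm_config(vocab_size = vocab$size, embedding_dim = embedding_dim,
                     layers = layers)
  bl <- train_bilm(seqs, cfg, seed = seed, epochs = epochs, lr = lr)
  list(bilm = bl, provider = precompute_context(feats, bl$params))
}

#' Train the full CPI extraction pipeline on a corpus
#'
#' Runs [prepare_corpus()], [pretrain_contextualizer()], a seeded
#' validation split and [train_model()]. The network sizes default to
#' desk-scale settings (see the package vignette); the architecture is
#' unchanged at any size.
#'
#' @param corpus a `cpie_corpus`.
#' @param seed integer seed controlling every random choice.
#' @param D position clip distance.
#' @param hidden LSTM hidden units per direction.
#' @param heads attention heads (must divide `2 * hidden`).
#' @param pos_dim,postag_dim embedding widths.
#' @param ctx_dim bi-LM embedding/hidden width (context width is twice
#'   this).
#' @param bilm_epochs bi-LM pretraining epochs.
#' @param train_cfg a [train_config()].
#' @param anonymize anonymization policy.
#' @param verbose print progress.
#' @return List with `prep`, `ctx`, `model_cfg`, `run`
#'   (a `cpie_run_result`), `split`.
#' @export
cpie_train_pipeline <- function(corpus, seed = 1L, D = 15L, hidden = 48L,
                                heads = 2L, pos_dim = 16L, postag_dim = 8L,
                                ctx_dim = 32L, bilm_epochs = 4L,
                                train_cfg = train_config(max_epochs = 20L,
                                                         patience = 8L),
                                anonymize = "target", verbose = FALSE) {
  prep <- prepare_corpus(corpus, D = D, anonymize = anonymize)
  ctx <- pretrain_contextualizer(prep$feats, prep$vocab,
                                 embedding_dim = ctx_dim,
                                 epochs = bilm_epochs, seed = seed)
  model_cfg <- model_config(d_ctx = 2L * ctx_dim,
                            n_mix_layers = attr(ctx$provider, "n_layers"),
                            pos_dim = pos_dim, postag_dim = postag_dim,
                            D = D, hidden = hidden, heads = heads)
  sp <- split_validation(prep$feats, train_cfg$validation_fraction,
                         seed = seed)
  run <- train_model(sp$train, sp$val, model_cfg, train_cfg, ctx$provider,
                     seed = seed, verbose = verbose)
  list(prep = prep, ctx = ctx, model_cfg = model_cfg, run = run, split = sp)
}

#' Evaluate a trained pipeline on featurized instances
#'
#' @param pipe result of [cpie_train_pipeline()].
#' @param feats featurized instances to score (they must be featurized
#'   with the pipeline's vocabulary; their sentences are embedded on
#'   demand if not already cached).
#' @param k keywords per class for the attention report.
#' @return A `cpie_eval_report` with attention keywords attached.
#' @export
cpie_evaluate <- function(pipe, feats, k = 5L) {
  provider <- extend_provider(pipe$ctx$provider, feats, pipe$ctx$bilm$params)
  pred <- model_predict(feats, pipe$run$params, pipe$model_cfg, provider)
  gold <- vapply(feats, function(f) f$label_id, 1L)
  kw <- attention_keywords(pred$tokens, pred$pool_weights, pred$pred_labels,
                           k = k)
  eval_report(confusion_from_predictions(gold, pred$pred_ids), keywords = kw)
}

# Ensure the provider covers `feats`, embedding any unseen sentences with
# the frozen bi-LM.
extend_provider <- function(provider, feats, bilm_params) {
  cache <- attr(provider, "cache")
  for (f in feats) {
    if (!exists(f$sentence_key, envir = cache, inherits = FALSE)) {
      assign(f$sentence_key, embed_sentence(f$token_ids, bilm_params)$layers,
             envir = cache)
    }
  }
  provider
}
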