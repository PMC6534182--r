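# Hand-built corpus fixtures, written programmatically at test time.
# Entity offsets are located with gregexpr over the reconstructed
# full_text (title + tab + abstract), so the fixture cannot drift from the
# offset convention.

fixture_entity <- function(full_text, doc_id, tid, type, surface, occurrence = 1L) {
  hits <- gregexpr(surface, full_text, fixed = TRUE)[[1]]
  stopifnot(hits[1] != -1L, length(hits) >= occurrence)
  start <- hits[occurrence] - 1L
  sprintf("%s\t%s\t%s\t%d\t%d\t%s", doc_id, tid, type, start,
          start + nchar(surface), surface)
}

# A two-document corpus:
#  - doc 10480573: 14 entity mentions, 2 relation annotations (one CPR:3
#    evaluated, one CPR:2 non-evaluated); its third abstract sentence has
#    3 chemicals x 3 genes.
#  - doc 20000001: a gold relation whose arguments sit in different
#    sentences (must be dropped and counted).
write_fixture_corpus <- function(dir = tempfile("corp")) {
  dir.create(dir, showWarnings = FALSE)
  titleA <- "Ibandronate and FAS."
  absA <- paste("Ibandronate inhibits FAS.",
                "ALD2 and BCL2 respond to Estradiol via MAPK.",
                "Caffeine, Theophylline and Aspirin bind HDAC1, HDAC2 and JAK2.")
  fullA <- paste0(titleA, "\t", absA)
  titleB <- "Aspirin and ABC1."
  absB <- "Aspirin regulated XYZ2 weakly. ABC1 responded slowly."
  fullB <- paste0(titleB, "\t", absB)
  writeLines(c(paste("10480573", titleA, absA, sep = "\t"),
               paste("20000001", titleB, absB, sep = "\t")),
             file.path(dir, "abstracts.tsv"), useBytes = TRUE)
  eA <- c(
    fixture_entity(fullA, "10480573", "T1", "CHEMICAL", "Ibandronate", 1L),
    fixture_entity(fullA, "10480573", "T2", "GENE-Y", "FAS", 1L),
    fixture_entity(fullA, "10480573", "T3", "CHEMICAL", "Ibandronate", 2L),
    fixture_entity(fullA, "10480573", "T4", "GENE-Y", "FAS", 2L),
    fixture_entity(fullA, "10480573", "T5", "GENE-N", "ALD2"),
    fixture_entity(fullA, "10480573", "T6", "GENE-Y", "BCL2"),
    fixture_entity(fullA, "10480573", "T7", "CHEMICAL", "Estradiol"),
    fixture_entity(fullA, "10480573", "T8", "GENE-Y", "MAPK"),
    fixture_entity(fullA, "10480573", "T9", "CHEMICAL", "Caffeine"),
    fixture_entity(fullA, "10480573", "T10", "CHEMICAL", "Theophylline"),
    fixture_entity(fullA, "10480573", "T11", "CHEMICAL", "Aspirin"),
    fixture_entity(fullA, "10480573", "T12", "GENE-Y", "HDAC1"),
    fixture_entity(fullA, "10480573", "T13", "GENE-Y", "HDAC2"),
    fixture_entity(fullA, "10480573", "T14", "GENE-Y", "JAK2"))
  eB <- c(
    fixture_entity(fullB, "20000001", "T1", "CHEMICAL", "Aspirin", 2L),
    fixture_entity(fullB, "20000001", "T2", "GENE-N", "XYZ2"),
    fixture_entity(fullB, "20000001", "T3", "GENE-Y", "ABC1", 2L))
  writeLines(c(eA, eB), file.path(dir, "entities.tsv"), useBytes = TRUE)
  writeLines(c(
    "10480573\tCPR:3\tY\tUPREGULATOR\tArg1:T3\tArg2:T4",
    "10480573\tCPR:2\tN\tREGULATOR\tArg1:T7\tArg2:T6",
    "20000001\tCPR:4\tY\tDOWNREGULATOR\tArg1:T1\tArg2:T3"),
    file.path(dir, "relations.tsv"), useBytes = TRUE)
  dir
}

read_fixture_corpus <- function() {
  dir <- write_fixture_corpus()
  read_corpus(file.path(dir, "abstracts.tsv"), file.path(dir, "entities.tsv"),
              file.path(dir, "relations.tsv"))
}

# Small featurized batch straight from the synthetic generator.
fixture_feats <- function(n_docs = 6L, seed = 5L, D = 6L, ...) {
  gen <- generate_corpus(synth_config(n_docs = n_docs, seed = seed, ...))
  prep <- prepare_corpus(gen$corpus, D = D)
  list(gen = gen, prep = prep)
}

# Tiny deterministic model setup for forward/backward tests.
fixture_model <- function(feats_n = 5L, seed = 7L, heads = 2L, hidden = 4L) {
  fx <- fixture_feats(n_docs = 4L, seed = seed, distractor_rate = 0.3,
                      passive_rate = 0.3)
  ctx <- pretrain_contextualizer(fx$prep$feats, fx$prep$vocab,
                                 embedding_dim = 5L, epochs = 1L, seed = 3L)
  cfg <- model_config(d_ctx = 10L, n_mix_layers = 2L, pos_dim = 3L,
                      postag_dim = 3L, D = 6L, hidden = hidden, heads = heads,
                      dropout_input = 0, dropout_output = 0)
  set.seed(11L)
  params <- model_init(cfg)
  feats <- fx$prep$feats[seq_len(feats_n)]
  list(fx = fx, ctx = ctx, cfg = cfg, params = params, feats = feats,
       batch = pad_batch(feats),
       stacks = lapply(feats, function(f) ctx$provider(f$sentence_key)))
}
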