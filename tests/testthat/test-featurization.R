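test_that("tokenization covers the sentence and never splits a mention", {
  toks <- tokenize_and_tag("Ibandronate inhibits FAS.")
  expect_equal(toks$text, c("Ibandronate", "inhibits", "FAS", "."))
  # spans reconstruct the string
  rebuilt <- vapply(seq_len(nrow(toks)), function(i)
    substr("Ibandronate inhibits FAS.", toks$start[i] + 1L, toks$end[i]), "")
  expect_identical(rebuilt, toks$text)

  # a multi-word, non-ASCII mention stays one token
  s <- "Binding of ERÎ± beta subunit was strong."
  span <- regexpr("ERÎ± beta subunit", s)
  prot <- matrix(c(span - 1L, span - 1L + attr(span, "match.length")), ncol = 2L)
  toks2 <- tokenize_and_tag(s, prot)
  expect_true("ERÎ± beta subunit" %in% toks2$text)

  # property: over synthetic corpora no token boundary falls inside a mention
  gen <- generate_corpus(synth_config(n_docs = 6L, seed = 13L,
                                      distractor_rate = 0.4))
  cand <- corpus_candidates(gen$corpus)
  for (i in seq_len(min(nrow(cand), 25L))) {
    cd <- cand[i, ]
    doc <- gen$corpus$documents[[cd$doc_id]]
    ct <- cpie:::candidate_tokens(cd, doc, gen$corpus$entities,
                                  anonymize = "none")
    ent <- gen$corpus$entities
    ent <- ent[ent$doc_id == cd$doc_id & ent$start >= cd$sent_start &
                 ent$end <= cd$sent_end, ]
    for (j in seq_len(nrow(ent))) {
      a <- ent$start[j] - cd$sent_start; b <- ent$end[j] - cd$sent_start
      inside <- ct$tokens$start > a & ct$tokens$start < b
      expect_false(any(inside))
    }
  }

  expect_error(tokenize_and_tag(""), "empty")
  one <- tokenize_and_tag("kinase")
  expect_equal(nrow(one), 1L)
  expect_true(one$pos_tag %in% cpie:::POS_TAGS)
})

test_that("entity-relative positions follow the span/clip definition", {
  toks3 <- tokenize_and_tag("A inhibits B")
  expect_equal(relative_positions(toks3, c(0L, 1L), D = 30L), c(0L, 1L, 2L))
  expect_equal(relative_positions(toks3, c(11L, 12L), D = 30L), c(-2L, -1L, 0L))
  # clipping oracle: raw arithmetic then min/max
  n <- 50L; D <- 30L
  got <- relative_positions(n, c(1L, 1L), D = D)
  raw <- pmin(pmax(seq_len(n) - 1L, -D), D)
  expect_equal(got, raw)
  expect_true(all(got[32:50] == 30L))
  # weak monotonicity outside the entity span
  set.seed(3)
  for (r in 1:20) {
    n <- sample(3:40, 1); s <- sample(seq_len(n), 1); e <- min(n, s + sample(0:2, 1))
    v <- relative_positions(n, c(s, e), D = 7L)
    expect_true(all(diff(v) >= 0L))
    expect_true(all(v >= -7L & v <= 7L))
  }
  expect_error(relative_positions(toks3, c(200L, 210L)), "no token")
})

test_that("vocabulary reserves PAD/OOV and freezes lookups", {
  v <- build_vocab(list(c("Alpha", "beta"), c("beta", "gamma")))
  expect_equal(v$pad_index, 0L)
  expect_equal(v$oov_index, 1L)
  expect_equal(vocab_lookup(v, c("alpha", "BETA", "unseen")),
               c(2L, 3L, 1L))
  expect_identical(vocab_tokens(v, c(0L, 1L, 2L)), c("<PAD>", "<OOV>", "alpha"))
  p <- tempfile(fileext = ".json")
  save_vocab(v, p)
  v2 <- load_vocab(p)
  expect_identical(v2$token_to_index, v$token_to_index)
})

test_that("featurization is deterministic and uses the fixed class order", {
  fx <- fixture_feats(n_docs = 5L, seed = 8L)
  cand <- fx$prep$candidates
  corpus <- fx$gen$corpus
  i <- which(cand$label != "NEG")[1]
  f1 <- featurize(cand[i, ], corpus$documents[[cand$doc_id[i]]],
                  corpus$entities, fx$prep$vocab, D = 6L)
  f2 <- featurize(cand[i, ], corpus$documents[[cand$doc_id[i]]],
                  corpus$entities, fx$prep$vocab, D = 6L)
  expect_identical(f1, f2)
  n <- length(f1$token_ids)
  expect_true(all(lengths(list(f1$pos_ids, f1$dist_chem, f1$dist_gene)) == n))
  # label ids follow the documented order (explicit lookup table)
  lut <- c("NEG" = 0L, "CPR:3" = 1L, "CPR:4" = 2L, "CPR:5" = 3L,
           "CPR:6" = 4L, "CPR:9" = 5L)
  for (lab in names(lut)) expect_equal(class_to_id(lab), unname(lut[[lab]]))
  expect_equal(f1$label_id, unname(lut[[cand$label[i]]]))
  # anonymization replaces the two target mentions with placeholders
  expect_true(all(c("chem_ent", "gene_ent") %in% f1$tokens))
  # unseen token under a frozen vocabulary maps to OOV
  tiny <- build_vocab(list("solitary"))
  f3 <- featurize(cand[i, ], corpus$documents[[cand$doc_id[i]]],
                  corpus$entities, tiny, D = 6L)
  expect_true(all(f3$token_ids == tiny$oov_index))
  bad <- cand[i, ]; bad$label <- "CPR:7"
  expect_error(featurize(bad, corpus$documents[[bad$doc_id]],
                         corpus$entities, fx$prep$vocab), "6-class")
})

test_that("pad_batch pads with PAD, masks real tokens, and counts lengths", {
  fx <- fixture_feats(n_docs = 4L, seed = 10L)
  feats <- fx$prep$feats
  lens <- vapply(feats, function(f) length(f$token_ids), 1L)
  b <- pad_batch(feats)
  expect_equal(dim(b$token_ids), c(length(feats), max(lens)))
  expect_equal(rowSums(b$mask), as.numeric(lens))
  for (i in seq_along(feats)) {
    if (lens[i] < max(lens)) {
      expect_true(all(b$token_ids[i, (lens[i] + 1):max(lens)] == 0L))
      expect_true(all(b$mask[i, (lens[i] + 1):max(lens)] == 0))
    }
  }
  single <- pad_batch(feats[1])
  expect_equal(dim(single$token_ids), c(1L, lens[1]))
  expect_true(all(single$mask == 1))
})
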