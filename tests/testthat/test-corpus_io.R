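test_that("the three-file dialect parses with validated offsets and counts", {
  corpus <- read_fixture_corpus()
  expect_length(corpus$documents, 2L)
  expect_equal(sum(corpus$entities$doc_id == "10480573"), 14L)
  expect_equal(sum(corpus$relations$doc_id == "10480573"), 2L)
  # offsets resolve against full_text under the 0-based half-open convention
  for (i in seq_len(nrow(corpus$entities))) {
    e <- corpus$entities[i, ]
    ft <- corpus$documents[[e$doc_id]]$full_text
    expect_identical(substr(ft, e$start + 1L, e$end), e$text)
  }
})

test_that("empty relations file yields documents and entities but no relations", {
  dir <- write_fixture_corpus()
  writeLines(character(0), file.path(dir, "relations.tsv"))
  corpus <- read_corpus(file.path(dir, "abstracts.tsv"),
                        file.path(dir, "entities.tsv"),
                        file.path(dir, "relations.tsv"))
  expect_length(corpus$documents, 2L)
  expect_gt(nrow(corpus$entities), 0L)
  expect_equal(nrow(corpus$relations), 0L)
})

test_that("corrupted records are rejected with informative errors", {
  dir <- write_fixture_corpus()
  ents <- readLines(file.path(dir, "entities.tsv"))
  bad <- sub("Ibandronate$", "Ibandronatx", ents[1])
  writeLines(c(bad, ents[-1]), file.path(dir, "entities.tsv"))
  expect_error(read_corpus(file.path(dir, "abstracts.tsv"),
                           file.path(dir, "entities.tsv"),
                           file.path(dir, "relations.tsv")),
               "T1.*mismatch|mismatch.*T1")

  dir2 <- write_fixture_corpus()
  rels <- readLines(file.path(dir2, "relations.tsv"))
  writeLines(c(rels, "10480573\tCPR:77\tY\tX\tArg1:T1\tArg2:T2"),
             file.path(dir2, "relations.tsv"))
  expect_error(read_corpus(file.path(dir2, "abstracts.tsv"),
                           file.path(dir2, "entities.tsv"),
                           file.path(dir2, "relations.tsv")),
               "CPR:77")

  dir3 <- write_fixture_corpus()
  writeLines("onlyonefield", file.path(dir3, "entities.tsv"))
  expect_error(read_corpus(file.path(dir3, "abstracts.tsv"),
                           file.path(dir3, "entities.tsv"),
                           file.path(dir3, "relations.tsv")),
               "line 1")
})

test_that("candidate generation enumerates within-sentence pairs with gold labels", {
  corpus <- read_fixture_corpus()
  docA <- corpus$documents[["10480573"]]
  cand <- generate_candidates(docA, corpus$entities, corpus$relations)
  # brute-force pairing oracle
  expect_equal(nrow(cand), oracle_pair_count(docA, corpus$entities))
  expect_equal(nrow(cand), 14L)
  # the 3 chemicals x 3 genes sentence contributes 9 pairs
  last_sent <- max(cand$sentence_index)
  expect_equal(sum(cand$sentence_index == last_sent), 9L)
  # evaluated gold relation labels its pair; CPR:2 (non-evaluated) -> NEG
  expect_equal(sum(cand$label == "CPR:3"), 1L)
  lab_est <- cand$label[cand$chem_id == "T7" & cand$gene_id == "T6"]
  expect_equal(lab_est, "NEG")
  # 1 chem + 1 gene, no relation -> single NEG instance
  docB <- corpus$documents[["20000001"]]
  candB <- generate_candidates(docB, corpus$entities, corpus$relations)
  expect_equal(nrow(candB), 1L)
  expect_equal(candB$label, "NEG")
  expect_equal(attr(candB, "dropped_cross_sentence"), 1L)
})

test_that("label distribution equals within-sentence evaluated gold relations", {
  gen <- generate_corpus(synth_config(n_docs = 25L, seed = 9L,
                                      distractor_rate = 0.4,
                                      passive_rate = 0.3))
  cand <- corpus_candidates(gen$corpus)
  for (cl in setdiff(cpi_classes(), "NEG")) {
    expect_equal(sum(cand$label == cl),
                 sum(gen$corpus$relations$cpr_class == cl),
                 info = cl)
  }
  # candidate count per sentence equals #chem x #gene (pairing oracle)
  expect_equal(nrow(cand),
               sum(vapply(gen$corpus$documents, oracle_pair_count, 0L,
                          entities = gen$corpus$entities)))
})

test_that("write_corpus round-trips byte-identically", {
  for (seed in c(1L, 4L)) {
    gen <- generate_corpus(synth_config(n_docs = 8L, seed = seed,
                                        distractor_rate = 0.3),
                           out_dir = d1 <- tempfile())
    corpus <- read_corpus(file.path(d1, "abstracts.tsv"),
                          file.path(d1, "entities.tsv"),
                          file.path(d1, "relations.tsv"))
    write_corpus(corpus, d2 <- tempfile())
    for (f in c("abstracts.tsv", "entities.tsv", "relations.tsv")) {
      expect_identical(readLines(file.path(d2, f)),
                       readLines(file.path(d1, f)), info = f)
    }
  }
  # empty corpus -> three empty headerless files
  empty <- structure(list(documents = list(),
                          entities = generate_corpus(synth_config(n_docs = 1L))$corpus$entities[0, ],
                          relations = generate_corpus(synth_config(n_docs = 1L))$corpus$relations[0, ]),
                     class = "cpie_corpus")
  paths <- write_corpus(empty, tempfile())
  expect_true(all(vapply(paths, function(p) length(readLines(p)) == 0L, TRUE)))
})

test_that("instances serialize to JSON lines and back", {
  gen <- generate_corpus(synth_config(n_docs = 5L, seed = 2L))
  cand <- corpus_candidates(gen$corpus)
  path <- tempfile(fileext = ".jsonl")
  write_instances(cand, path)
  expect_equal(length(readLines(path)), nrow(cand))
  back <- read_instances(path)
  expect_equal(back$label, cand$label)
  expect_equal(back$chem_id, cand$chem_id)
})
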