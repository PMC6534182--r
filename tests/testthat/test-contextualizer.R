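# Builds a zeroed bi-LM (all weights and embeddings 0) whose softmax is
# uniform at every position.
zeroed_bilm <- function(V = 7L, e = 4L) {
  cfg <- bilm_config(vocab_size = V, embedding_dim = e)
  set.seed(1)
  p <- bilm_init(cfg)
  p$E[] <- 0; p$out_b[] <- 0
  for (d in c("fwd", "bwd")) {
    for (j in seq_along(p[[d]])) {
      for (nm in names(p[[d]][[j]])) {
        if (is.numeric(p[[d]][[j]][[nm]]) && !nm %in% c("hidden", "input_dim"))
          p[[d]][[j]][[nm]][] <- 0
      }
    }
  }
  p
}

test_that("a uniform language model assigns -log(V) to every token", {
  p <- zeroed_bilm(V = 7L)
  ids <- c(0L, 3L, 6L, 2L)
  for (dir in c("forward", "backward")) {
    ll <- bilm_log_likelihood(ids, p, dir)
    expect_equal(ll, rep(-log(7), 4L), tolerance = 1e-12)
  }
  expect_error(bilm_log_likelihood(c(0L, 9L), p), "vocab_size")
})

test_that("the joint objective is exactly the forward plus backward sums", {
  set.seed(5)
  cfg <- bilm_config(vocab_size = 12L, embedding_dim = 6L)
  p <- bilm_init(cfg)
  for (r in 1:10) {
    ids <- sample(0:11, sample(1:12, 1), replace = TRUE)
    expect_identical(bilm_joint_objective(ids, p),
                     sum(bilm_log_likelihood(ids, p, "forward")) +
                       sum(bilm_log_likelihood(ids, p, "backward")))
    expect_true(all(bilm_log_likelihood(ids, p, "forward") <= 0))
  }
})

test_that("causality holds: each direction conditions only on its own context", {
  set.seed(6)
  cfg <- bilm_config(vocab_size = 10L, embedding_dim = 5L)
  p <- bilm_init(cfg)
  for (r in 1:25) {
    n <- sample(3:10, 1)
    ids <- sample(0:9, n, replace = TRUE)
    k <- sample(2:n, 1)
    # forward: perturbing any w_j with j >= k leaves log p(w_k) unchanged
    ids2 <- ids
    ids2[k:n] <- sample(0:9, n - k + 1L, replace = TRUE)
    llf <- bilm_log_likelihood(ids, p, "forward")
    llf2 <- bilm_log_likelihood(ids2, p, "forward")
    if (k > 1L) expect_equal(llf[seq_len(k - 1L)], llf2[seq_len(k - 1L)],
                             tolerance = 1e-12)
    # backward: perturbing any w_j with j <= k leaves log p of later tokens
    ids3 <- ids
    ids3[1:k] <- sample(0:9, k, replace = TRUE)
    llb <- bilm_log_likelihood(ids, p, "backward")
    llb3 <- bilm_log_likelihood(ids3, p, "backward")
    if (k < n) expect_equal(llb[(k + 1L):n], llb3[(k + 1L):n],
                            tolerance = 1e-12)
  }
})

test_that("training on Markov text beats the uniform baseline and is seeded", {
  # 3-state Markov chain over a 6-word vocabulary
  set.seed(77)
  trans <- matrix(c(0.8, 0.1, 0.1,
                    0.1, 0.8, 0.1,
                    0.1, 0.1, 0.8), 3, 3, byrow = TRUE)
  gen_seq <- function() {
    s <- sample(1:3, 1)
    out <- integer(8)
    for (t in 1:8) {
      out[t] <- s - 1L
      s <- sample(1:3, 1, prob = trans[s, ])
    }
    out
  }
  seqs <- replicate(200, gen_seq(), simplify = FALSE)
  held <- replicate(40, gen_seq(), simplify = FALSE)
  cfg <- bilm_config(vocab_size = 6L, embedding_dim = 6L)
  bl <- train_bilm(seqs, cfg, seed = 4L, epochs = 3L)
  expect_lt(bilm_perplexity(held, bl$params), 6)
  # objective never ends below its starting point
  expect_gte(max(bl$objective[-1]), bl$objective[1])
  expect_true(all(diff(bl$objective) > -abs(0.02 * bl$objective[1])))
  # bit-identical trajectory under the same seed
  bl2 <- train_bilm(seqs, cfg, seed = 4L, epochs = 3L)
  expect_identical(bl$objective, bl2$objective)
  expect_error(train_bilm(list(), cfg), "empty")
})

test_that("a memorizable corpus is driven to near-zero per-token entropy", {
  seqs <- rep(list(c(1L, 4L, 2L, 0L, 3L)), 40L)
  cfg <- bilm_config(vocab_size = 5L, embedding_dim = 8L)
  bl <- train_bilm(seqs, cfg, seed = 2L, epochs = 12L, lr = 0.02)
  nll <- -bilm_joint_objective(seqs[[1]], bl$params) / (2 * 5)
  expect_lt(nll, 0.2)
})

test_that("layer mixing selects, combines and contextualizes", {
  set.seed(9)
  cfg <- bilm_config(vocab_size = 9L, embedding_dim = 4L)
  p <- bilm_init(cfg)
  ids <- c(2L, 5L, 7L)
  emb <- embed_sentence(ids, p)
  expect_length(emb$layers, 2L)
  expect_equal(dim(emb$layers[[1]]), c(3L, 8L))
  # one-hot weight on the embedding layer reproduces the static embedding
  m0 <- embed_sentence(ids, p, mix = list(w = c(50, -50), gamma = 1))
  expect_equal(m0$rep, cbind(p$E[ids + 1L, ], p$E[ids + 1L, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # one-hot weight on layer 1 reproduces the LSTM layer
  m1 <- embed_sentence(ids, p, mix = list(w = c(-50, 50), gamma = 2))
  expect_equal(m1$rep, 2 * emb$layers[[2]], tolerance = 1e-10)
  # same token in different contexts gets different vectors...
  a <- embed_sentence(c(3L, 1L, 4L), p)$layers[[2]]
  b <- embed_sentence(c(8L, 6L, 4L), p)$layers[[2]]
  expect_gt(max(abs(a[3, ] - b[3, ])), 1e-8)
  # ...but identical sentences give identical matrices
  expect_identical(a, embed_sentence(c(3L, 1L, 4L), p)$layers[[2]])
})

test_that("precomputed representations round-trip and feed the model identically", {
  fm <- fixture_model()
  path <- tempfile(fileext = ".rds")
  save_precomputed(fm$ctx$provider, path)
  loaded <- load_precomputed(path)
  keys <- vapply(fm$feats, function(f) f$sentence_key, "")
  for (k in keys) expect_identical(loaded(k), fm$ctx$provider(k))
  expect_error(loaded("9999,9999"), "no precomputed")
  stacks2 <- lapply(keys, loaded)
  out1 <- model_forward(fm$batch, fm$stacks, fm$params, fm$cfg)
  out2 <- model_forward(fm$batch, stacks2, fm$params, fm$cfg)
  expect_identical(out1$probs, out2$probs)
})
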