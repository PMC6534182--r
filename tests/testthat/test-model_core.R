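test_that("the LSTM cell matches its definition at anchor points", {
  p <- lstm_init(3L, 4L)
  for (nm in names(p)) {
    if (is.numeric(p[[nm]]) && !nm %in% c("hidden", "input_dim")) p[[nm]][] <- 0
  }
  st <- lstm_step(c(1, -2, 3), NULL, p, variant = "standard")
  expect_equal(st$f, rep(0.5, 4)); expect_equal(st$o, rep(0.5, 4))
  expect_equal(st$i, rep(0.5, 4)); expect_equal(st$g, rep(0, 4))
  expect_equal(st$c, rep(0, 4)); expect_equal(st$h, rep(0, 4))
  st_lit <- lstm_step(c(1, -2, 3), NULL, p, variant = "literal")
  expect_equal(st_lit$h, rep(0, 4))

  # 1-dim hand arithmetic: zero weights, large positive input/forget biases
  p1 <- lstm_init(1L, 1L)
  for (nm in c("W_f", "W_o", "W_g", "W_i", "U_f", "U_o", "U_g", "U_i"))
    p1[[nm]][] <- 0
  p1$b_f <- 10; p1$b_i <- 10; p1$b_o <- 0; p1$b_g <- 0.5
  prev <- list(h = 0.3, c = 2)
  st1 <- lstm_step(0.7, prev, p1)
  f <- 1 / (1 + exp(-10)); i <- f; g <- tanh(0.5); o <- 0.5
  c_exp <- f * 2 + i * g
  expect_equal(st1$c, c_exp, tolerance = 1e-12)
  expect_equal(st1$h, o * tanh(c_exp), tolerance = 1e-12)
  st1_lit <- lstm_step(0.7, prev, p1, variant = "literal")
  expect_equal(st1_lit$h, o * tanh(2), tolerance = 1e-12)

  # reference widths: 300 hidden units per direction, 600 concatenated
  p300 <- lstm_init(8L, 300L)
  st300 <- lstm_step(rnorm(8), NULL, p300)
  expect_length(st300$h, 300L)
  enc <- bilstm_encode(matrix(rnorm(3 * 8), 3, 8), p300, lstm_init(8L, 300L))
  expect_equal(dim(enc), c(3L, 600L))
})

test_that("lstm_step matches a scalar-loop oracle on 100 random instances", {
  set.seed(21)
  for (r in 1:100) {
    I <- sample(1:5, 1); H <- sample(1:5, 1)
    p <- rand_lstm_params(I, H)
    x <- rnorm(I); prev <- list(h = rnorm(H), c = rnorm(H))
    variant <- sample(c("standard", "literal"), 1)
    got <- lstm_step(x, prev, p, variant)
    want <- oracle_lstm_step(x, prev$h, prev$c, p, variant)
    for (fld in c("h", "c", "f", "o", "i", "g")) {
      expect_equal(got[[fld]], want[[fld]], tolerance = 1e-6)
    }
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$g > -1 & got$g < 1))
  }
})

test_that("literal and standard gate variants agree whenever c_t equals c_{t-1}", {
  set.seed(22)
  for (r in 1:20) {
    I <- sample(1:4, 1); H <- sample(1:4, 1)
    p <- rand_lstm_params(I, H)
    p$b_i[] <- -1e9        # input gate shut: c_t = f * c_{t-1}
    prev <- list(h = rnorm(H), c = rep(0, H))  # and c_{t-1} = 0 -> c_t = 0
    x <- rnorm(I)
    expect_identical(lstm_step(x, prev, p, "standard")$h,
                     lstm_step(x, prev, p, "literal")$h)
  }
})

test_that("the Bi-LSTM encoder concatenates directions and respects masks", {
  set.seed(23)
  I <- 3L; H <- 4L
  pf <- rand_lstm_params(I, H); pb <- rand_lstm_params(I, H)
  # n = 1: both directions see the same single token
  x1 <- matrix(rnorm(I), 1, I)
  enc1 <- bilstm_encode(x1, pf, pb)
  sf <- lstm_step(drop(x1), NULL, pf); sb <- lstm_step(drop(x1), NULL, pb)
  expect_equal(drop(enc1), c(sf$h, sb$h), tolerance = 1e-12)

  # palindrome with shared parameters: mirror symmetry with halves swapped
  xp <- matrix(rnorm(2 * I), 2, I)
  Xpal <- rbind(xp, xp[1, ])
  Xpal[2, ] <- Xpal[2, ]  # rows: a b a
  encp <- bilstm_encode(Xpal, pf, pf)
  n <- nrow(Xpal)
  for (t in seq_len(n)) {
    expect_equal(encp[t, 1:H], encp[n + 1L - t, H + 1:H], tolerance = 1e-10)
  }

  # appending masked padding leaves the real rows unchanged
  X <- matrix(rnorm(4 * I), 4, I)
  enc <- bilstm_encode(X, pf, pb)
  Xpad <- rbind(X, matrix(rnorm(2 * I), 2, I))
  encpad <- bilstm_encode(Xpad, pf, pb, mask = c(1, 1, 1, 1, 0, 0))
  expect_equal(encpad[1:4, ], enc, tolerance = 1e-12)
  expect_true(all(encpad[5:6, ] == 0))
  expect_error(bilstm_encode(X, pf, pb, mask = rep(1, 9)), "mask")
})

test_that("scaled dot-product attention matches the explicit loop oracle", {
  set.seed(24)
  # degenerate anchors
  V1 <- matrix(rnorm(4), 1, 4)
  a1 <- scaled_dot_attention(matrix(rnorm(3), 1, 3), matrix(rnorm(3), 1, 3), V1)
  expect_equal(a1$output, V1)
  expect_equal(a1$weights[1, 1], 1)
  Q0 <- matrix(0, 3, 2); K <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(12), 4, 3)
  a0 <- scaled_dot_attention(Q0, K, V)
  for (r in 1:3) expect_equal(a0$output[r, ], colMeans(V), tolerance = 1e-12)
  expect_error(scaled_dot_attention(matrix(0, 2, 3), K, V), "share width")

  for (r in 1:100) {
    n <- sample(1:6, 1); m <- sample(1:6, 1); dk <- sample(1:5, 1); dv <- sample(1:5, 1)
    Q <- matrix(rnorm(n * dk), n, dk); K <- matrix(rnorm(m * dk), m, dk)
    V <- matrix(rnorm(m * dv), m, dv)
    got <- scaled_dot_attention(Q, K, V)
    want <- oracle_sdp_attention(Q, K, V, sqrt(dk))
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(rowSums(got$weights), rep(1, n), tolerance = 1e-9)
    expect_true(all(got$weights >= 0))
  }
  # masked keys receive zero weight
  am <- scaled_dot_attention(matrix(rnorm(6), 2, 3), matrix(rnorm(9), 3, 3),
                             matrix(rnorm(6), 3, 2), key_mask = c(1, 0, 1))
  expect_true(all(am$weights[, 2] == 0))
  expect_equal(rowSums(am$weights), c(1, 1), tolerance = 1e-12)
})

test_that("multihead attention reduces, splits heads, and matches its oracle", {
  set.seed(25)
  # h = 1 with identity projections reduces to scaled_dot_attention
  d <- 4L
  prm <- attention_init(d, 1L)
  prm$Wq[[1]] <- diag(d); prm$Wk[[1]] <- diag(d); prm$Wv[[1]] <- diag(d)
  prm$Wo <- diag(d)
  X <- matrix(rnorm(3 * d), 3, d)
  expect_equal(multihead_attention(X, prm)$output,
               scaled_dot_attention(X, X, X)$output, tolerance = 1e-12)

  # reference geometry: 6 heads over width 600 -> 100 per head
  prm600 <- attention_init(600L, 6L)
  expect_equal(ncol(prm600$Wq[[1]]), 100L)
  X600 <- matrix(rnorm(2 * 600), 2, 600)
  expect_equal(dim(multihead_attention(X600, prm600)$output), c(2L, 600L))
  expect_error(attention_init(600L, 7L), "divisible")

  for (r in 1:100) {
    h <- sample(c(1L, 2L, 3L), 1); d <- h * sample(1:3, 1)
    n <- sample(1:5, 1)
    prm <- attention_init(d, h)
    X <- matrix(rnorm(n * d), n, d)
    got <- multihead_attention(X, prm)
    expect_equal(got$output, oracle_multihead(X, prm), tolerance = 1e-6)
  }

  # permutation equivariance (no positional terms inside attention)
  prm <- attention_init(6L, 2L)
  X <- matrix(rnorm(5 * 6), 5, 6)
  perm <- sample(5)
  expect_equal(multihead_attention(X[perm, ], prm)$output,
               multihead_attention(X, prm)$output[perm, ], tolerance = 1e-9)
})

test_that("attention pooling is a convex combination matching its oracle", {
  set.seed(26)
  prm <- attention_pool_init(4L, 3L)
  H1 <- matrix(rnorm(4), 1, 4)
  p1 <- attention_pool(H1, prm)
  expect_equal(p1$output, drop(H1)); expect_equal(p1$weights, 1)
  prm0 <- prm; prm0$v[] <- 0
  H <- matrix(rnorm(20), 5, 4)
  pu <- attention_pool(H, prm0)
  expect_equal(pu$weights, rep(0.2, 5))
  expect_equal(pu$output, colMeans(H), tolerance = 1e-12)
  for (r in 1:100) {
    n <- sample(1:7, 1); d <- sample(2:5, 1)
    prm <- attention_pool_init(d, sample(2:4, 1))
    H <- matrix(rnorm(n * d), n, d)
    got <- attention_pool(H, prm)
    want <- oracle_pool(H, prm)
    expect_equal(got$output, want$output, tolerance = 1e-6)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
  }
  expect_error(attention_pool(H, prm, mask = rep(0, nrow(H))), "masked")
})

test_that("model forward produces proper probabilities deterministically", {
  fm <- fixture_model()
  fw <- model_forward(fm$batch, fm$stacks, fm$params, fm$cfg)
  expect_equal(rowSums(fw$probs), rep(1, nrow(fw$probs)), tolerance = 1e-6)
  # zeroed output layer -> exactly uniform class probabilities
  pz <- fm$params; pz$out_W[] <- 0; pz$out_b[] <- 0
  fwz <- model_forward(fm$batch, fm$stacks, pz, fm$cfg)
  expect_equal(fwz$probs, matrix(1 / 6, nrow(fwz$probs), 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical instances in one batch get identical rows (eval mode)
  dup <- pad_batch(fm$feats[c(1, 1)])
  fwd <- model_forward(dup, fm$stacks[c(1, 1)], fm$params, fm$cfg)
  expect_identical(fwd$probs[1, ], fwd$probs[2, ])
})

test_that("padding and batch composition do not change model outputs", {
  fm <- fixture_model(feats_n = 5L)
  # batch-of-1 vs the same instance inside a larger (longer-padded) batch
  full <- model_forward(fm$batch, fm$stacks, fm$params, fm$cfg)
  for (i in seq_along(fm$feats)) {
    solo <- model_forward(pad_batch(fm$feats[i]), fm$stacks[i], fm$params, fm$cfg)
    expect_equal(drop(solo$probs), full$probs[i, ], tolerance = 1e-10)
  }
  # perturbing token ids at masked positions leaves logits unchanged
  b2 <- fm$batch
  pads <- b2$mask == 0
  if (any(pads)) {
    b2$token_ids[pads] <- 3L
    b2$pos_ids[pads] <- 2L
    fw2 <- model_forward(b2, fm$stacks, fm$params, fm$cfg)
    expect_identical(fw2$probs, full$probs)
  }
})

test_that("analytic gradients match central finite differences", {
  fm <- fixture_model(feats_n = 4L)
  params <- fm$params
  set.seed(12)
  params$out_W[] <- rnorm(length(params$out_W), sd = 0.2)
  lg <- model_loss_and_grads(fm$batch, fm$stacks, params, fm$cfg,
                             dropout = FALSE)
  flat <- cpie:::flatten_params(params)
  ana <- cpie:::flatten_params(lg$grads)
  expect_length(ana, length(flat))
  loss_at <- function(v) {
    model_loss_and_grads(fm$batch, fm$stacks,
                         cpie:::unflatten_params(params, v), fm$cfg,
                         dropout = FALSE)$loss
  }
  set.seed(13)
  idx <- sample(length(flat), 220L)
  eps <- 1e-5
  for (i in idx) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    num <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
    denom <- max(1e-6, abs(num) + abs(ana[i]))
    expect_lt(abs(num - ana[i]) / denom, 1e-4)
  }
})

test_that("bi-LM gradients match finite differences", {
  set.seed(31)
  cfg <- bilm_config(vocab_size = 7L, embedding_dim = 4L, tie = FALSE)
  params <- bilm_init(cfg)
  ids1 <- c(2L, 5L, 1L, 6L) + 1L
  gf <- cpie:::lm_sentence_grads(ids1, params, params$fwd)
  sub <- params[c("E", "fwd", "out_W", "out_b")]
  grads <- list(E = gf$dE, fwd = gf$layers, out_W = gf$dW, out_b = gf$db)
  flat <- cpie:::flatten_params(sub)
  ana <- cpie:::flatten_params(grads)
  loss_at <- function(v) {
    s2 <- cpie:::unflatten_params(sub, v)
    p2 <- params; p2[names(s2)] <- s2
    cpie:::lm_sentence_grads(ids1, p2, p2$fwd)$loss
  }
  set.seed(32)
  idx <- sample(length(flat), 120L)
  eps <- 1e-6
  for (i in idx) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    num <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
    denom <- max(1e-6, abs(num) + abs(ana[i]))
    expect_lt(abs(num - ana[i]) / denom, 1e-4)
  }
})

test_that("model construction rejects inconsistent dimensions early", {
  expect_error(model_config(d_ctx = 10L, hidden = 10L, heads = 3L), "divisible")
  fm <- fixture_model()
  bad_stacks <- lapply(fm$stacks, function(s) s[1])
  expect_error(model_forward(fm$batch, bad_stacks, fm$params, fm$cfg),
               "layers")
})
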