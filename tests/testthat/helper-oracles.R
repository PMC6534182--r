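# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit loops, scalar arithmetic, no shared
# helpers beyond base R.

oracle_lstm_step <- function(x, h_prev, c_prev, p, variant = "standard") {
  H <- p$hidden
  sig <- function(z) 1 / (1 + exp(-z))
  f <- o <- i <- g <- numeric(H)
  for (j in seq_len(H)) {
    af <- sum(x * p$W_f[, j]) + sum(h_prev * p$U_f[, j]) + p$b_f[j]
    ao <- sum(x * p$W_o[, j]) + sum(h_prev * p$U_o[, j]) + p$b_o[j]
    ag <- sum(x * p$W_g[, j]) + sum(h_prev * p$U_g[, j]) + p$b_g[j]
    ai <- sum(x * p$W_i[, j]) + sum(h_prev * p$U_i[, j]) + p$b_i[j]
    f[j] <- sig(af); o[j] <- sig(ao); g[j] <- tanh(ag); i[j] <- sig(ai)
  }
  c_t <- f * c_prev + i * g
  h_t <- if (variant == "standard") o * tanh(c_t) else o * tanh(c_prev)
  list(h = h_t, c = c_t, f = f, o = o, i = i, g = g)
}

oracle_sdp_attention <- function(Q, K, V, scale) {
  n <- nrow(Q); m <- nrow(K)
  out <- matrix(0, n, ncol(V))
  W <- matrix(0, n, m)
  for (a in seq_len(n)) {
    logits <- numeric(m)
    for (b in seq_len(m)) logits[b] <- sum(Q[a, ] * K[b, ]) / scale
    e <- exp(logits - max(logits))
    w <- e / sum(e)
    W[a, ] <- w
    for (b in seq_len(m)) out[a, ] <- out[a, ] + w[b] * V[b, ]
  }
  list(output = out, weights = W)
}

oracle_multihead <- function(X, prm, scale_mode = "per_head") {
  h <- prm$h; d <- prm$d; p <- d / h
  scale <- if (scale_mode == "per_head") sqrt(p) else sqrt(d)
  pieces <- vector("list", h)
  for (k in seq_len(h)) {
    Q <- X %*% prm$Wq[[k]]; K <- X %*% prm$Wk[[k]]; V <- X %*% prm$Wv[[k]]
    pieces[[k]] <- oracle_sdp_attention(Q, K, V, scale)$output
  }
  do.call(cbind, pieces) %*% prm$Wo
}

oracle_pool <- function(H, prm) {
  n <- nrow(H)
  u <- numeric(n)
  for (t in seq_len(n)) u[t] <- sum(prm$v * tanh(drop(H[t, ] %*% prm$W)))
  e <- exp(u - max(u)); a <- e / sum(e)
  out <- numeric(ncol(H))
  for (t in seq_len(n)) out <- out + a[t] * H[t, ]
  list(output = out, weights = a)
}

# Independent micro-averaged scorer working from label vectors: 6-way task,
# NEG excluded from the positive set.
oracle_micro_from_labels <- function(gold, pred) {
  pos <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")
  tp <- fp <- fn <- 0
  for (cl in pos) {
    tp <- tp + sum(gold == cl & pred == cl)
    fp <- fp + sum(gold != cl & pred == cl)
    fn <- fn + sum(gold == cl & pred != cl)
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

# Brute-force within-sentence pairing: every (chemical, gene) pair whose
# spans both fall inside the same sentence span.
oracle_pair_count <- function(doc, entities) {
  ent <- entities[entities$doc_id == doc$doc_id, , drop = FALSE]
  total <- 0L
  for (s in seq_len(nrow(doc$sentence_spans))) {
    lo <- doc$sentence_spans[s, "start"]; hi <- doc$sentence_spans[s, "end"]
    inside <- ent$start >= lo & ent$end <= hi
    nc <- sum(inside & ent$type == "CHEMICAL")
    ng <- sum(inside & ent$type %in% c("GENE-Y", "GENE-N"))
    for (a in seq_len(nc)) for (b in seq_len(ng)) total <- total + 1L
  }
  total
}

rand_lstm_params <- function(I, H) {
  p <- lstm_init(I, H)
  for (nm in names(p)) {
    if (is.numeric(p[[nm]]) && !nm %in% c("hidden", "input_dim")) {
      p[[nm]][] <- rnorm(length(p[[nm]]), sd = 0.5)
    }
  }
  p
}
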