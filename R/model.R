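# The CPI classifier network.
#
# Per token, the input is the contextual representation (ELMo-style layer
# mix, gradient flows into the mixing weights but not the frozen bi-LM)
# concatenated with two entity-relative position embeddings (distance to
# the chemical and to the gene mention) and a POS-tag embedding. The
# sequence is encoded by a Bi-LSTM, passed through multihead
# self-attention, collapsed to a sentence vector by attention pooling, and
# classified by a 6-way softmax layer. Dropout is applied to the
# concatenated input embeddings and to the pooled sentence vector
# (training mode only). No residual connections or layer normalization are
# used around the attention block; the architecture is the plain
# composition of the three stages.

#' Model configuration
#'
#' @param d_ctx width of the contextual representation vectors.
#' @param n_mix_layers number of mixable bi-LM layers (LSTM layers + 1).
#' @param pos_dim width of each of the two position embedding channels.
#' @param postag_dim width of the POS-tag embedding.
#' @param D position clip distance (distances live in `[-D, D]`).
#' @param hidden LSTM hidden size per direction; the attention operates on
#'   width `d = 2 * hidden`.
#' @param heads number of attention heads; must divide `2 * hidden`.
#' @param pool_dim attention-pooling score-space width.
#' @param dropout_input,dropout_output dropout rates on the concatenated
#'   input embeddings and on the pooled sentence vector.
#' @param variant LSTM output-gate variant, see [lstm_step()].
#' @param scale_mode attention logit scaling, see [multihead_attention()].
#' @param n_classes number of output classes (6: NEG + five CPR classes).
#' @return A `cpie_model_config` list (validated: `2 * hidden` divisible
#'   by `heads`).
#' @export
model_config <- function(d_ctx, n_mix_layers = 2L, pos_dim = 50L,
                         postag_dim = 50L, D = 30L, hidden = 300L,
                         heads = 6L, pool_dim = NULL,
                         dropout_input = 0.5, dropout_output = 0.5,
                         variant = "standard", scale_mode = "per_head",
                         n_classes = 6L) {
  d <- 2L * hidden
  if (d %% heads != 0L) {
    stop("2 * hidden (", d, ") must be divisible by the head count (", heads, ")")
  }
  structure(list(d_ctx = as.integer(d_ctx),
                 n_mix_layers = as.integer(n_mix_layers),
                 pos_dim = as.integer(pos_dim),
                 postag_dim = as.integer(postag_dim), D = as.integer(D),
                 hidden = as.integer(hidden), heads = as.integer(heads),
                 d = d, pool_dim = as.integer(pool_dim %||% d),
                 input_dim = as.integer(d_ctx + 2L * pos_dim + postag_dim),
                 dropout_input = dropout_input,
                 dropout_output = dropout_output, variant = variant,
                 scale_mode = scale_mode, n_classes = as.integer(n_classes),
                 n_postags = length(POS_TAGS) + 1L),
            class = "cpie_model_config")
}

#' Initialize classifier parameters
#'
#' All weight matrices use uniform Glorot-style initialization; biases
#' start at zero. Layer-mixing weights start uniform (`w = 0`) with scale
#' `gamma = 1`.
#'
#' @param config a [model_config()].
#' @return Parameter list covering every trainable block.
#' @export
model_init <- function(config) {
  ndist <- 2L * config$D + 1L
  list(
    mix_w = rep(0, config$n_mix_layers),
    mix_gamma = 1,
    P_chem = init_matrix(ndist, config$pos_dim),
    P_gene = init_matrix(ndist, config$pos_dim),
    T_pos = init_matrix(config$n_postags, config$postag_dim),
    lstm_fwd = lstm_init(config$input_dim, config$hidden),
    lstm_bwd = lstm_init(config$input_dim, config$hidden),
    att = attention_init(config$d, config$heads),
    pool = attention_pool_init(config$d, config$pool_dim),
    out_W = init_matrix(config$d, config$n_classes),
    out_b = rep(0, config$n_classes)
  )
}

# Assemble the (B, T, input_dim) input array from a padded batch and the
# per-instance contextual layer stacks. Returns the array plus the
# per-instance mixed/unscaled-layer matrices needed for mixing gradients.
build_inputs <- function(batch, ctx_stacks, params, config) {
  B <- nrow(batch$token_ids); Tm <- ncol(batch$token_ids)
  X <- array(0, c(B, Tm, config$input_dim))
  s <- softmax(params$mix_w)
  mixbar <- vector("list", B)  # sum_j s_j L_j, pre-gamma, per instance
  c1 <- seq_len(config$d_ctx)
  c2 <- config$d_ctx + seq_len(config$pos_dim)
  c3 <- config$d_ctx + config$pos_dim + seq_len(config$pos_dim)
  c4 <- config$d_ctx + 2L * config$pos_dim + seq_len(config$postag_dim)
  for (b in seq_len(B)) {
    n <- batch$lengths[b]
    layers <- ctx_stacks[[b]]
    if (length(layers) != config$n_mix_layers) {
      stop("contextual stack has ", length(layers), " layers; config expects ",
           config$n_mix_layers)
    }
    mb <- layers[[1]] * s[1]
    for (j in seq_along(layers)[-1]) mb <- mb + layers[[j]] * s[j]
    mixbar[[b]] <- mb
    X[b, 1:n, c1] <- params$mix_gamma * mb
    X[b, 1:n, c2] <- params$P_chem[batch$dist_chem[b, 1:n] + 1L, , drop = FALSE]
    X[b, 1:n, c3] <- params$P_gene[batch$dist_gene[b, 1:n] + 1L, , drop = FALSE]
    X[b, 1:n, c4] <- params$T_pos[batch$pos_ids[b, 1:n], , drop = FALSE]
  }
  list(X = X, mixbar = mixbar, s = s,
       cols = list(ctx = c1, chem = c2, gene = c3, postag = c4))
}

#' Forward pass of the classifier
#'
#' @param batch a padded batch from [pad_batch()].
#' @param ctx_stacks list (one element per instance) of contextual layer
#'   stacks, e.g. from a [precompute_context()] provider.
#' @param params from [model_init()].
#' @param config the [model_config()].
#' @param train logical; when TRUE, dropout is sampled (stochastic) and a
#'   backward cache is kept. Evaluation mode is deterministic.
#' @return List with `probs` (B x n_classes, rows summing to 1),
#'   `pool_weights` (per-instance attention-pooling weight vectors),
#'   `att_weights` (per-instance lists of per-head attention matrices) and
#'   (in training mode) a `cache`.
#' @export
model_forward <- function(batch, ctx_stacks, params, config, train = FALSE) {
  B <- nrow(batch$token_ids)
  inp <- build_inputs(batch, ctx_stacks, params, config)
  X <- inp$X
  drop_in <- NULL
  if (train && config$dropout_input > 0) {
    keep <- 1 - config$dropout_input
    drop_in <- array(stats::rbinom(length(X), 1L, keep) / keep, dim(X))
    X <- X * drop_in
  }
  enc <- bilstm_forward_batch(X, batch$mask, params$lstm_fwd,
                              params$lstm_bwd, variant = config$variant)
  d <- config$d
  S <- matrix(0, B, d)
  pool_weights <- vector("list", B)
  att_weights <- vector("list", B)
  att_caches <- vector("list", B); pool_caches <- vector("list", B)
  for (b in seq_len(B)) {
    n <- batch$lengths[b]
    Hb <- matrix(enc$H[b, 1:n, ], n, d)
    att <- multihead_attention(Hb, params$att, scale_mode = config$scale_mode)
    pl <- attention_pool(att$output, params$pool)
    S[b, ] <- pl$output
    pool_weights[[b]] <- pl$weights
    att_weights[[b]] <- att$weights
    att_caches[[b]] <- att$cache
    pool_caches[[b]] <- pl$cache
  }
  drop_out <- NULL
  Sd <- S
  if (train && config$dropout_output > 0) {
    keep <- 1 - config$dropout_output
    drop_out <- matrix(stats::rbinom(length(S), 1L, keep) / keep, B, d)
    Sd <- S * drop_out
  }
  logits <- Sd %*% params$out_W +
    matrix(params$out_b, B, config$n_classes, byrow = TRUE)
  probs <- softmax(logits)
  out <- list(probs = probs, pool_weights = pool_weights,
              att_weights = att_weights)
  if (train) {
    out$cache <- list(inp = inp, Xdrop = X, drop_in = drop_in,
                      drop_out = drop_out, enc = enc, S = S, Sd = Sd,
                      att_caches = att_caches, pool_caches = pool_caches,
                      batch = batch, ctx_stacks = ctx_stacks)
  }
  out
}

#' Mean cross-entropy loss and gradients for one batch
#'
#' Runs [model_forward()] and backpropagates the mean categorical
#' cross-entropy over the batch through every block, including the
#' layer-mixing weights (the frozen bi-LM itself receives no gradient).
#'
#' @inheritParams model_forward
#' @param dropout logical: sample dropout (training) or run the
#'   deterministic network (used by gradient checks).
#' @param class_weights optional length-`n_classes` vector of per-class
#'   loss weights (weighted mean cross-entropy).
#' @return List with `loss`, `probs` and `grads` (mirroring
#'   [model_init()]).
#' @export
model_loss_and_grads <- function(batch, ctx_stacks, params, config,
                                 dropout = TRUE, class_weights = NULL) {
  if (!dropout) {
    config$dropout_input <- 0
    config$dropout_output <- 0
  }
  fw <- model_forward(batch, ctx_stacks, params, config, train = TRUE)
  cache <- fw$cache
  B <- nrow(fw$probs)
  y <- batch$labels + 1L
  w <- if (is.null(class_weights)) rep(1, B) else class_weights[y]
  loss <- -sum(w * log(pmax(fw$probs[cbind(seq_len(B), y)], 1e-300))) / sum(w)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits * (w / sum(w))

  d <- config$d
  g_out_W <- crossprod(cache$Sd, dlogits)
  g_out_b <- colSums(dlogits)
  dSd <- dlogits %*% t(params$out_W)
  dS <- if (is.null(cache$drop_out)) dSd else dSd * cache$drop_out

  dH_enc <- array(0, dim(cache$enc$H))
  g_att <- NULL; g_pool <- NULL
  for (b in seq_len(B)) {
    n <- cache$batch$lengths[b]
    pb <- attention_pool_backward(cache$pool_caches[[b]], dS[b, ])
    ab <- multihead_attention_backward(cache$att_caches[[b]], pb$dH)
    dH_enc[b, 1:n, ] <- ab$dX
    g_att <- if (is.null(g_att)) ab$grads else add_trees(g_att, ab$grads)
    g_pool <- if (is.null(g_pool)) pb$grads else add_trees(g_pool, pb$grads)
  }
  bk <- bilstm_backward_batch(cache$enc, dH_enc)
  dX <- bk$dX
  if (!is.null(cache$drop_in)) dX <- dX * cache$drop_in

  # embedding + mixing gradients from the input array gradient
  cols <- cache$inp$cols
  ndist <- 2L * config$D + 1L
  g_P_chem <- matrix(0, ndist, config$pos_dim)
  g_P_gene <- matrix(0, ndist, config$pos_dim)
  g_T_pos <- matrix(0, config$n_postags, config$postag_dim)
  s <- cache$inp$s
  ds <- rep(0, length(s))
  g_gamma <- 0
  for (b in seq_len(B)) {
    n <- cache$batch$lengths[b]
    dXb <- matrix(dX[b, 1:n, ], n, config$input_dim)
    dRep <- dXb[, cols$ctx, drop = FALSE]
    g_gamma <- g_gamma + sum(dRep * cache$inp$mixbar[[b]])
    layers <- cache$ctx_stacks[[b]]
    for (j in seq_along(layers)) {
      ds[j] <- ds[j] + params$mix_gamma * sum(dRep * layers[[j]])
    }
    acc <- function(G, idx, block) {
      agg <- rowsum(block, group = idx)
      rows <- as.integer(rownames(agg))
      G[rows, ] <- G[rows, , drop = FALSE] + agg
      G
    }
    g_P_chem <- acc(g_P_chem, cache$batch$dist_chem[b, 1:n] + 1L,
                    dXb[, cols$chem, drop = FALSE])
    g_P_gene <- acc(g_P_gene, cache$batch$dist_gene[b, 1:n] + 1L,
                    dXb[, cols$gene, drop = FALSE])
    g_T_pos <- acc(g_T_pos, cache$batch$pos_ids[b, 1:n],
                   dXb[, cols$postag, drop = FALSE])
  }
  g_mix_w <- s * (ds - sum(s * ds))

  grads <- list(mix_w = g_mix_w, mix_gamma = g_gamma,
                P_chem = g_P_chem, P_gene = g_P_gene, T_pos = g_T_pos,
                lstm_fwd = bk$grads_fwd, lstm_bwd = bk$grads_bwd,
                att = g_att, pool = g_pool,
                out_W = g_out_W, out_b = g_out_b)
  list(loss = loss, probs = fw$probs, grads = grads)
}

# Elementwise sum of two parameter trees with identical skeletons.
add_trees <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- add_trees(a[[i]], b[[i]])
    a
  } else a + b
}

#' Predict class probabilities for featurized instances
#'
#' Deterministic evaluation-mode forward pass in mini-batches.
#'
#' @param feats list of featurized instances.
#' @param params,config model parameters and configuration.
#' @param provider contextual-representation provider
#'   (see [precompute_context()]).
#' @param batch_size mini-batch size.
#' @return List with `pred_ids` (0-based), `pred_labels`, `probs`
#'   (matrix), `pool_weights` and `tokens` (per instance).
#' @export
model_predict <- function(feats, params, config, provider, batch_size = 64L) {
  n <- length(feats)
  probs <- matrix(0, n, config$n_classes)
  pw <- vector("list", n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (ii in idx) {
    batch <- pad_batch(feats[ii])
    stacks <- lapply(feats[ii], function(f) provider(f$sentence_key))
    fw <- model_forward(batch, stacks, params, config, train = FALSE)
    probs[ii, ] <- fw$probs
    pw[ii] <- fw$pool_weights
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  list(pred_ids = pred, pred_labels = id_to_class(pred), probs = probs,
       pool_weights = pw, tokens = lapply(feats, function(f) f$tokens))
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles parameters, configuration and the class order.
#'
#' @param params,config model parameters and configuration.
#' @param path file path.
#' @export
save_model <- function(params, config, path) {
  saveRDS(list(params = params, config = config, classes = cpi_classes()), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$classes, cpi_classes())) stop("checkpoint class order mismatch")
  obj
}
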