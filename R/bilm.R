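# Small trainable bidirectional language model used as the contextual
# representation layer.
#
# A forward LSTM LM factorizes P(w_1..w_n) = prod_k p(w_k | w_1..w_{k-1});
# a backward LSTM LM factorizes it as prod_k p(w_k | w_{k+1}..w_n). Both are
# trained jointly by maximizing the summed log likelihood. Per-token
# contextual representations are a learned softmax-weighted combination of
# the intermediate layers (the static embedding layer plus each LSTM
# layer's forward||backward hidden states), scaled by a global factor --
# the standard ELMo mixing scheme. Layer widths are kept equal
# (embedding_dim == hidden_dim) so the layers can be mixed; precomputed
# representations from a larger external bi-LM can be supplied through the
# same provider interface (see [load_precomputed()]).

#' Bi-LM configuration
#'
#' @param vocab_size vocabulary size (0-based token ids in
#'   `[0, vocab_size)`).
#' @param embedding_dim static embedding width.
#' @param layers number of LSTM layers per direction (L >= 1).
#' @param hidden_dim hidden size per direction; must equal `embedding_dim`
#'   so all mixable layers share width `2 * hidden_dim`.
#' @param tie tie the output softmax weights to the input embedding table.
#' @return A `bilm_config` list.
#' @export
bilm_config <- function(vocab_size, embedding_dim = 16L, layers = 1L,
                        hidden_dim = embedding_dim, tie = TRUE) {
  stopifnot(vocab_size > 1L, embedding_dim > 0L, layers >= 1L, hidden_dim > 0L)
  if (embedding_dim != hidden_dim) {
    stop("embedding_dim must equal hidden_dim so layer widths match for mixing")
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 layers = as.integer(layers),
                 hidden_dim = as.integer(hidden_dim), tie = isTRUE(tie)),
            class = "bilm_config")
}

#' Initialize bi-LM parameters
#'
#' @param config a [bilm_config()].
#' @return Parameter list: embedding table `E` (vocab x dim), per-direction
#'   LSTM layer stacks `fwd`/`bwd`, output projection (`out_W`, `out_b`;
#'   `out_W` absent when tied) and the config.
#' @export
bilm_init <- function(config) {
  V <- config$vocab_size; e <- config$embedding_dim; H <- config$hidden_dim
  mk_dir <- function() {
    lapply(seq_len(config$layers), function(j) {
      lstm_init(if (j == 1L) e else H, H)
    })
  }
  p <- list(E = init_matrix(V, e), fwd = mk_dir(), bwd = mk_dir(),
            out_b = rep(0, V), config = config)
  if (!config$tie) p$out_W <- init_matrix(H, V)
  p
}

bilm_out_W <- function(params) {
  if (params$config$tie) t(params$E) else params$out_W
}

check_ids <- function(token_ids, V) {
  if (length(token_ids) < 1L) stop("sequence must have length >= 1")
  if (any(token_ids < 0L) || any(token_ids >= V)) {
    stop("token id outside [0, vocab_size)")
  }
}

# Run the stacked LSTM of one direction over a 1-based-id sequence given in
# reading order for that direction. Returns per-layer hidden matrices
# (n x H) and caches.
run_lm_stack <- function(ids1, params, dir_params) {
  X <- params$E[ids1, , drop = FALSE]
  n <- length(ids1)
  layers <- list(); caches <- list()
  inp <- X
  for (j in seq_along(dir_params)) {
    cc <- lstm_forward_batch(array(inp, c(1L, n, ncol(inp))),
                             matrix(1, 1L, n), dir_params[[j]])
    Hj <- matrix(cc$H[1L, , ], n, dir_params[[j]]$hidden)
    layers[[j]] <- Hj
    caches[[j]] <- cc
    inp <- Hj
  }
  list(X = X, layers = layers, caches = caches)
}

# Per-position next-token log-probabilities for one direction's run: the
# prediction for position k uses the state after k-1 observed tokens
# (a zero state for k = 1).
lm_position_logliks <- function(Htop, ids1, params) {
  n <- length(ids1)
  W <- bilm_out_W(params)
  Hprev <- rbind(matrix(0, 1L, ncol(Htop)),
                 Htop[seq_len(n - 1L), , drop = FALSE])
  logits <- Hprev %*% W + matrix(params$out_b, n, length(params$out_b),
                                 byrow = TRUE)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logits[cbind(seq_len(n), ids1)] - lse
}

#' Per-token log-probabilities under one direction of the bi-LM
#'
#' Forward direction: position k is conditioned only on tokens 1..k-1.
#' Backward direction: position k is conditioned only on tokens k+1..n.
#'
#' @param token_ids integer vector of 0-based vocabulary ids.
#' @param params from [bilm_init()] or [train_bilm()].
#' @param direction `"forward"` or `"backward"`.
#' @return Numeric vector of per-token log-probabilities (<= 0), in the
#'   original token order.
#' @export
bilm_log_likelihood <- function(token_ids, params,
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  check_ids(token_ids, params$config$vocab_size)
  ids1 <- as.integer(token_ids) + 1L
  if (direction == "backward") ids1 <- rev(ids1)
  run <- run_lm_stack(ids1, params, params[[if (direction == "forward") "fwd" else "bwd"]])
  ll <- lm_position_logliks(run$layers[[length(run$layers)]], ids1, params)
  if (direction == "backward") ll <- rev(ll)
  ll
}

#' Joint bi-LM log-likelihood objective
#'
#' The sum over tokens of the forward log-probability plus the backward
#' log-probability -- exactly the forward-direction sum plus the
#' backward-direction sum.
#'
#' @inheritParams bilm_log_likelihood
#' @return A single number (<= 0).
#' @export
bilm_joint_objective <- function(token_ids, params) {
  sum(bilm_log_likelihood(token_ids, params, "forward")) +
    sum(bilm_log_likelihood(token_ids, params, "backward"))
}

bilm_corpus_objective <- function(sequences, params) {
  sum(vapply(sequences, bilm_joint_objective, 0, params = params))
}

#' Bi-LM perplexity on a set of sequences
#'
#' `exp(-joint / (2 N))` where `joint` is the summed two-direction
#' objective and `N` the total token count: the geometric-mean inverse
#' per-token probability, averaged over both directions.
#'
#' @param sequences list of 0-based id vectors.
#' @param params bi-LM parameters.
#' @return A single positive number.
#' @export
bilm_perplexity <- function(sequences, params) {
  N <- sum(lengths(sequences))
  exp(-bilm_corpus_objective(sequences, params) / (2 * N))
}

# Loss and gradients of one direction's negative log-likelihood for one
# sentence. Returns grads for E, the direction's LSTM stack, out_W/out_b.
lm_sentence_grads <- function(ids1, params, dir_params) {
  n <- length(ids1)
  run <- run_lm_stack(ids1, params, dir_params)
  Htop <- run$layers[[length(run$layers)]]
  Hd <- ncol(Htop)
  W <- bilm_out_W(params)
  V <- params$config$vocab_size
  Hprev <- rbind(matrix(0, 1L, Hd), Htop[seq_len(n - 1L), , drop = FALSE])
  logits <- Hprev %*% W + matrix(params$out_b, n, V, byrow = TRUE)
  P <- softmax(logits)
  loss <- -sum(log(pmax(P[cbind(seq_len(n), ids1)], 1e-300)))
  dlogits <- P
  dlogits[cbind(seq_len(n), ids1)] <- dlogits[cbind(seq_len(n), ids1)] - 1
  dW <- crossprod(Hprev, dlogits)
  db <- colSums(dlogits)
  dHprev <- dlogits %*% t(W)
  dHtop <- matrix(0, n, Hd)
  if (n > 1L) dHtop[seq_len(n - 1L), ] <- dHprev[2:n, , drop = FALSE]
  # backprop through the LSTM stack
  layer_grads <- vector("list", length(dir_params))
  dh <- dHtop
  for (j in rev(seq_along(dir_params))) {
    bk <- lstm_backward_batch(run$caches[[j]],
                              array(dh, c(1L, n, Hd)))
    layer_grads[[j]] <- bk$grads
    dh <- matrix(bk$dX[1L, , ], n, dim(bk$dX)[3])
  }
  dE <- matrix(0, V, params$config$embedding_dim)
  dX <- dh  # gradient wrt the embedded inputs
  agg <- rowsum(dX, group = ids1)
  dE[as.integer(rownames(agg)), ] <- dE[as.integer(rownames(agg)), ] + agg
  if (params$config$tie) dE <- dE + t(dW)
  list(loss = loss, dE = dE, layers = layer_grads, dW = dW, db = db)
}

#' Train the bidirectional language model
#'
#' Per-sentence RMSProp on the joint negative log-likelihood, with seeded
#' shuffling. Keeps the parameters of the epoch with the best training
#' objective, so the returned model is never worse on the training data
#' than the initialization.
#'
#' @param sequences list of 0-based id vectors (each length >= 1).
#' @param config a [bilm_config()].
#' @param seed integer seed (initialization + shuffling).
#' @param epochs training epochs.
#' @param lr,rho,eps RMSProp hyperparameters.
#' @param verbose print per-epoch objective.
#' @return List with `params`, `objective` (per-epoch joint log-likelihood
#'   on the training data, starting with the initial value).
#' @export
train_bilm <- function(sequences, config, seed = 1L, epochs = 3L,
                       lr = 0.01, rho = 0.9, eps = 1e-7, verbose = FALSE) {
  if (length(sequences) == 0L) stop("empty training corpus")
  lapply(sequences, check_ids, V = config$vocab_size)
  set.seed(seed)
  params <- bilm_init(config)
  state <- NULL
  obj <- bilm_corpus_objective(sequences, params)
  best <- list(params = params, obj = obj)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(sequences))
    for (si in ord) {
      ids1 <- as.integer(sequences[[si]]) + 1L
      gf <- lm_sentence_grads(ids1, params, params$fwd)
      gb <- lm_sentence_grads(rev(ids1), params, params$bwd)
      grads <- list(E = gf$dE + gb$dE, fwd = gf$layers, bwd = gb$layers,
                    out_b = gf$db + gb$db)
      if (!config$tie) grads$out_W <- gf$dW + gb$dW
      upd <- rmsprop_step(params[names(grads)], grads, state, lr, rho, eps)
      params[names(grads)] <- upd$params
      state <- upd$state
    }
    ep_obj <- bilm_corpus_objective(sequences, params)
    obj <- c(obj, ep_obj)
    if (verbose) message(sprintf("bilm epoch %d: objective %.3f", ep, ep_obj))
    if (ep_obj >= best$obj) best <- list(params = params, obj = ep_obj)
  }
  list(params = best$params, objective = obj)
}

#' ELMo-style contextual representation of a sentence
#'
#' Computes the layer stack -- layer 0 is the static embedding duplicated
#' to `[emb || emb]`, layer j >= 1 is `[h^fwd_j || h^bwd_j]` -- and, if
#' mixing weights are given, the combined representation
#' `gamma * sum_j softmax(w)_j layer_j`. The same token id can receive
#' different vectors in different sentences (through the LSTM layers),
#' while identical sentences always yield identical matrices.
#'
#' @param token_ids integer vector of 0-based vocabulary ids.
#' @param params bi-LM parameters.
#' @param mix optional list with raw weights `w` (length layers + 1) and
#'   scale `gamma`.
#' @return List with `layers` (list of n x d_ctx matrices), `d_ctx`, and
#'   `rep` (n x d_ctx combined matrix) when `mix` is given.
#' @export
embed_sentence <- function(token_ids, params, mix = NULL) {
  check_ids(token_ids, params$config$vocab_size)
  ids1 <- as.integer(token_ids) + 1L
  n <- length(ids1)
  runf <- run_lm_stack(ids1, params, params$fwd)
  runb <- run_lm_stack(rev(ids1), params, params$bwd)
  L <- params$config$layers
  layers <- vector("list", L + 1L)
  layers[[1]] <- cbind(runf$X, runf$X)
  for (j in seq_len(L)) {
    Hb <- runb$layers[[j]][n:1, , drop = FALSE]
    layers[[j + 1L]] <- cbind(runf$layers[[j]], Hb)
  }
  out <- list(layers = layers, d_ctx = 2L * params$config$hidden_dim)
  if (!is.null(mix)) out$rep <- mix_layers(layers, mix)
  out
}

# Combine a layer stack with softmax-normalized weights and a global scale.
mix_layers <- function(layers, mix) {
  s <- softmax(mix$w)
  acc <- layers[[1]] * s[1]
  for (j in seq_along(layers)[-1]) acc <- acc + layers[[j]] * s[j]
  mix$gamma * acc
}

#' Precompute contextual layer stacks for featurized instances
#'
#' The bi-LM is frozen during task training, so each distinct token
#' sequence is embedded once and served from a cache keyed by the
#' instance's `sentence_key`.
#'
#' @param feats list of featurized instances (see [featurize()]).
#' @param params bi-LM parameters.
#' @return A provider: `function(sentence_key)` returning the layer-stack
#'   list, with attributes `d_ctx` and `n_layers`.
#' @export
precompute_context <- function(feats, params) {
  cache <- new.env(parent = emptyenv())
  d_ctx <- 2L * params$config$hidden_dim
  for (f in feats) {
    if (!exists(f$sentence_key, envir = cache, inherits = FALSE)) {
      assign(f$sentence_key, embed_sentence(f$token_ids, params)$layers,
             envir = cache)
    }
  }
  make_context_provider(cache, d_ctx, params$config$layers + 1L)
}

make_context_provider <- function(cache, d_ctx, n_layers) {
  provider <- function(sentence_key) {
    if (!exists(sentence_key, envir = cache, inherits = FALSE)) {
      stop("no precomputed representation for sentence key: ", sentence_key)
    }
    get(sentence_key, envir = cache, inherits = FALSE)
  }
  attr(provider, "d_ctx") <- d_ctx
  attr(provider, "n_layers") <- n_layers
  attr(provider, "cache") <- cache
  provider
}

#' Save / load precomputed contextual representations
#'
#' The container stores one layer stack per sentence key. Loading
#' validates that every stack has a consistent width and layer count; a
#' lookup of an unknown key raises an error.
#'
#' @param provider a provider from [precompute_context()].
#' @param path file path.
#' @return `load_precomputed` returns a provider like
#'   [precompute_context()]'s.
#' @export
save_precomputed <- function(provider, path) {
  cache <- attr(provider, "cache")
  keys <- ls(cache)
  saveRDS(list(keys = keys,
               stacks = lapply(keys, get, envir = cache),
               d_ctx = attr(provider, "d_ctx"),
               n_layers = attr(provider, "n_layers")), path)
  invisible(path)
}

#' @rdname save_precomputed
#' @export
load_precomputed <- function(path) {
  obj <- readRDS(path)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(obj$keys)) {
    st <- obj$stacks[[i]]
    if (length(st) != obj$n_layers ||
        any(vapply(st, ncol, 1L) != obj$d_ctx)) {
      stop("dimension mismatch in precomputed representations for key ",
           obj$keys[i])
    }
    assign(obj$keys[i], st, envir = cache)
  }
  make_context_provider(cache, obj$d_ctx, obj$n_layers)
}
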