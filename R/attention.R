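# Scaled dot-product attention, multihead self-attention and attention
# pooling, with explicit backward passes.

# Row-wise softmax with optional key-side mask (masked logits -> -Inf).
masked_row_softmax <- function(S, key_mask = NULL) {
  if (!is.null(key_mask)) S[, key_mask == 0] <- -Inf
  mx <- apply(S, 1L, max)
  if (any(!is.finite(mx))) stop("attention row with all keys masked")
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / scale) V`. Each output row is a
#' convex combination of the rows of `V`; the weight rows are non-negative
#' and sum to 1, with masked key positions receiving weight 0 (their
#' logits are set to `-Inf` before the softmax).
#'
#' @param Q,K,V numeric matrices; `Q` and `K` share width, `K` and `V`
#'   share row count.
#' @param key_mask optional 0/1 vector over rows of `K`/`V`.
#' @param scale scaling divisor for the logits; defaults to
#'   `sqrt(ncol(K))`, the key width.
#' @return List with `output` (nrow(Q) x ncol(V)) and `weights`
#'   (nrow(Q) x nrow(K)).
#' @export
scaled_dot_attention <- function(Q, K, V, key_mask = NULL,
                                 scale = sqrt(ncol(K))) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share width")
  if (nrow(K) != nrow(V)) stop("K and V must share row count")
  A <- masked_row_softmax(Q %*% t(K) / scale, key_mask)
  list(output = A %*% V, weights = A)
}

# Backward through softmax rows: dS_ij = A_ij * (dA_ij - sum_j A_ij dA_ij).
softmax_rows_backward <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

scaled_dot_attention_backward <- function(Q, K, V, A, dOut, scale) {
  dA <- dOut %*% t(V)
  dV <- t(A) %*% dOut
  dS <- softmax_rows_backward(A, dA)
  list(dQ = dS %*% K / scale, dK = t(dS) %*% Q / scale, dV = dV)
}

#' Initialize multihead self-attention parameters
#'
#' `h` heads over model width `d` (`d` must be divisible by `h`); each head
#' projects queries, keys and values to width `d/h` with its own three
#' matrices, and the concatenated head outputs pass through a `d x d`
#' output projection.
#'
#' @param d model width.
#' @param h number of heads.
#' @return Parameter list (`Wq`, `Wk`, `Wv`: lists of d x d/h matrices;
#'   `Wo`: d x d; plus `h`, `d`).
#' @export
attention_init <- function(d, h) {
  if (d %% h != 0L) stop("model width d must be divisible by the head count h")
  p <- d %/% h
  list(Wq = lapply(seq_len(h), function(k) init_matrix(d, p)),
       Wk = lapply(seq_len(h), function(k) init_matrix(d, p)),
       Wv = lapply(seq_len(h), function(k) init_matrix(d, p)),
       Wo = init_matrix(d, d), h = h, d = d)
}

#' Multihead self-attention
#'
#' Head k computes `Attention(X Wq_k, X Wk_k, X Wv_k)`; the heads are
#' concatenated and projected with `Wo`, giving an n x d output.
#'
#' @param X input matrix n x d (queries = keys = values).
#' @param params from [attention_init()].
#' @param key_mask optional 0/1 vector over rows of `X`.
#' @param scale_mode `"per_head"` (default) scales logits by
#'   `sqrt(d/h)`, the projected key width; `"model_width"` uses `sqrt(d)`.
#' @return List with `output` (n x d), `weights` (list of n x n per-head
#'   weight matrices) and a `cache` for the backward pass.
#' @export
multihead_attention <- function(X, params, key_mask = NULL,
                                scale_mode = c("per_head", "model_width")) {
  scale_mode <- match.arg(scale_mode)
  h <- params$h; d <- params$d
  if (ncol(X) != d) stop("input width does not match attention params")
  p <- d %/% h
  scale <- if (scale_mode == "per_head") sqrt(p) else sqrt(d)
  heads <- vector("list", h); Qs <- Ks <- Vs <- As <- vector("list", h)
  for (k in seq_len(h)) {
    Qs[[k]] <- X %*% params$Wq[[k]]
    Ks[[k]] <- X %*% params$Wk[[k]]
    Vs[[k]] <- X %*% params$Wv[[k]]
    att <- scaled_dot_attention(Qs[[k]], Ks[[k]], Vs[[k]],
                                key_mask = key_mask, scale = scale)
    heads[[k]] <- att$output
    As[[k]] <- att$weights
  }
  C <- do.call(cbind, heads)
  list(output = C %*% params$Wo, weights = As,
       cache = list(X = X, Q = Qs, K = Ks, V = Vs, A = As, C = C,
                    scale = scale, params = params))
}

multihead_attention_backward <- function(cache, dOut) {
  prm <- cache$params
  h <- prm$h; d <- prm$d; p <- d %/% h
  dWo <- crossprod(cache$C, dOut)
  dC <- dOut %*% t(prm$Wo)
  dX <- matrix(0, nrow(cache$X), d)
  dWq <- dWk <- dWv <- vector("list", h)
  for (k in seq_len(h)) {
    dHk <- dC[, ((k - 1L) * p + 1L):(k * p), drop = FALSE]
    bk <- scaled_dot_attention_backward(cache$Q[[k]], cache$K[[k]],
                                        cache$V[[k]], cache$A[[k]], dHk,
                                        cache$scale)
    dWq[[k]] <- crossprod(cache$X, bk$dQ)
    dWk[[k]] <- crossprod(cache$X, bk$dK)
    dWv[[k]] <- crossprod(cache$X, bk$dV)
    dX <- dX + bk$dQ %*% t(prm$Wq[[k]]) + bk$dK %*% t(prm$Wk[[k]]) +
      bk$dV %*% t(prm$Wv[[k]])
  }
  list(dX = dX, grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

#' Initialize attention-pooling parameters
#'
#' @param d input row width.
#' @param p score-space width (defaults to `d`).
#' @return List with projection `W` (d x p) and query vector `v` (p).
#' @export
attention_pool_init <- function(d, p = d) {
  list(W = init_matrix(d, p), v = stats::runif(p, -sqrt(6 / (p + 1)), sqrt(6 / (p + 1))))
}

#' Attention pooling of a sequence matrix to one vector
#'
#' Scores each row as `u_t = v' tanh(W' h_t)`, softmax-normalizes the
#' scores over unmasked positions into weights `a_t`, and returns
#' `sum_t a_t h_t`: a convex combination of the input rows. The weights
#' are returned for keyword reporting.
#'
#' @param H numeric matrix n x d.
#' @param params from [attention_pool_init()].
#' @param mask optional 0/1 vector of length n; at least one position must
#'   be unmasked.
#' @return List with `output` (length-d vector), `weights` (length n,
#'   summing to 1, zero at masked positions) and a backward `cache`.
#' @export
attention_pool <- function(H, params, mask = NULL) {
  n <- nrow(H)
  if (is.null(mask)) mask <- rep(1, n)
  if (sum(mask) == 0) stop("attention pooling over fully masked input")
  Z <- tanh(H %*% params$W)           # n x p
  u <- drop(Z %*% params$v)           # n
  u[mask == 0] <- -Inf
  a <- exp(u - max(u)); a <- a / sum(a)
  list(output = drop(t(H) %*% a), weights = a,
       cache = list(H = H, Z = Z, a = a, params = params))
}

attention_pool_backward <- function(cache, dOut) {
  H <- cache$H; Z <- cache$Z; a <- cache$a; prm <- cache$params
  da <- drop(H %*% dOut)
  dH <- outer(a, dOut)
  du <- a * (da - sum(a * da))
  dv <- drop(t(Z) %*% du)
  dZpre <- outer(du, prm$v) * (1 - Z^2)  # n x p
  dW <- crossprod(H, dZpre)
  dH <- dH + dZpre %*% t(prm$W)
  list(dH = dH, grads = list(W = dW, v = dv))
}
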