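# LSTM cell and batched sequence encoder with explicit backpropagation
# through time.
#
# Gate equations (time step t, input x_t, previous hidden h_{t-1}, previous
# cell c_{t-1}):
#   f_t = sigmoid(W_f x_t + U_f h_{t-1} + b_f)      (forget gate)
#   o_t = sigmoid(W_o x_t + U_o h_{t-1} + b_o)      (output gate)
#   g_t = tanh   (W_g x_t + U_g h_{t-1} + b_g)      (candidate)
#   i_t = sigmoid(W_i x_t + U_i h_{t-1} + b_i)      (input gate)
#   c_t = f_t * c_{t-1} + i_t * g_t
#   h_t = o_t * tanh(c_t)                            variant = "standard"
#   h_t = o_t * tanh(c_{t-1})                        variant = "literal"
#
# The "literal" variant reads the output gate against the *previous* cell;
# it is kept behind a flag for fidelity experiments (the two variants agree
# exactly whenever c_t == c_{t-1}) and is not used for training.

#' Initialize LSTM parameters
#'
#' Weights use uniform Glorot-style initialization; biases are zero except
#' the forget-gate bias, initialized to 1 (a standard recipe that keeps
#' early memory retention high).
#'
#' @param input_dim,hidden input and hidden sizes.
#' @return List of gate matrices `W_f,W_o,W_g,W_i` (input_dim x hidden),
#'   recurrent matrices `U_*` (hidden x hidden) and biases `b_*`.
#' @export
lstm_init <- function(input_dim, hidden) {
  p <- list()
  for (g in c("f", "o", "g", "i")) {
    p[[paste0("W_", g)]] <- init_matrix(input_dim, hidden)
    p[[paste0("U_", g)]] <- init_matrix(hidden, hidden)
    p[[paste0("b_", g)]] <- if (g == "f") rep(1, hidden) else rep(0, hidden)
  }
  p$hidden <- hidden
  p$input_dim <- input_dim
  p
}

# Assemble per-gate matrices into single blocks (order f, o, g, i) so each
# time step is two matrix products instead of eight.
lstm_blocks <- function(p) {
  list(W = cbind(p$W_f, p$W_o, p$W_g, p$W_i),
       U = cbind(p$U_f, p$U_o, p$U_g, p$U_i),
       b = c(p$b_f, p$b_o, p$b_g, p$b_i))
}

#' One LSTM cell step
#'
#' @param x_t input vector.
#' @param prev previous state: list with `h` and `c` vectors (defaults to
#'   zeros).
#' @param params from [lstm_init()].
#' @param variant `"standard"` (h from the updated cell) or `"literal"`
#'   (h from the previous cell).
#' @return `LSTMState` list with `h`, `c` and the gate activations
#'   `f`, `o`, `i`, `g`.
#' @export
lstm_step <- function(x_t, prev = NULL, params,
                      variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  H <- params$hidden
  if (length(x_t) != params$input_dim) stop("x_t has wrong length")
  if (is.null(prev)) prev <- list(h = rep(0, H), c = rep(0, H))
  if (length(prev$h) != H || length(prev$c) != H) stop("state has wrong length")
  f <- sigmoid(drop(x_t %*% params$W_f) + drop(prev$h %*% params$U_f) + params$b_f)
  o <- sigmoid(drop(x_t %*% params$W_o) + drop(prev$h %*% params$U_o) + params$b_o)
  g <- tanh(drop(x_t %*% params$W_g) + drop(prev$h %*% params$U_g) + params$b_g)
  i <- sigmoid(drop(x_t %*% params$W_i) + drop(prev$h %*% params$U_i) + params$b_i)
  c_t <- f * prev$c + i * g
  h_t <- if (variant == "standard") o * tanh(c_t) else o * tanh(prev$c)
  list(h = h_t, c = c_t, f = f, o = o, i = i, g = g)
}

# Batched forward over time. X: array (B, T, I); mask: (B, T) of 0/1 with
# all real positions left-aligned. Returns hidden states (B, T, H) with
# padded rows zero, plus caches for BPTT.
lstm_forward_batch <- function(X, mask, params, variant = "standard") {
  dims <- dim(X)
  B <- dims[1]; Tm <- dims[2]; I <- dims[3]
  H <- params$hidden
  blk <- lstm_blocks(params)
  Hs <- array(0, c(B, Tm, H)); Cs <- array(0, c(B, Tm, H))
  Fs <- array(0, c(B, Tm, H)); Os <- array(0, c(B, Tm, H))
  Is <- array(0, c(B, Tm, H)); Gs <- array(0, c(B, Tm, H))
  TC <- array(0, c(B, Tm, H))  # tanh(c_t) (or tanh(c_{t-1}) for literal)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  for (t in seq_len(Tm)) {
    Xt <- matrix(X[, t, ], B, I)
    A <- Xt %*% blk$W + h %*% blk$U +
      matrix(blk$b, B, 4L * H, byrow = TRUE)
    f <- sigmoid(A[, 1:H, drop = FALSE])
    o <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    i <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- if (variant == "standard") tanh(c_new) else tanh(cc)
    h_new <- o * tc
    m <- mask[, t]
    h <- h_new * m
    c_prev_store <- cc
    cc <- c_new * m
    Hs[, t, ] <- h; Cs[, t, ] <- cc
    Fs[, t, ] <- f; Os[, t, ] <- o; Is[, t, ] <- i; Gs[, t, ] <- g
    TC[, t, ] <- tc
  }
  list(H = Hs, C = Cs, F = Fs, O = Os, I = Is, G = Gs, TC = TC,
       X = X, mask = mask, params = params, variant = variant)
}

# BPTT for the standard variant. dH: gradient wrt the stored (masked)
# hidden states, (B, T, H). Returns dX (B, T, I) and parameter gradients.
lstm_backward_batch <- function(cache, dH) {
  if (cache$variant != "standard") stop("backward implemented for the standard variant")
  p <- cache$params
  H <- p$hidden; dims <- dim(cache$X)
  B <- dims[1]; Tm <- dims[2]; I <- dims[3]
  blk <- lstm_blocks(p)
  dX <- array(0, c(B, Tm, I))
  dW <- matrix(0, I, 4L * H); dU <- matrix(0, H, 4L * H); db <- rep(0, 4L * H)
  dh_next <- matrix(0, B, H)  # from step t+1 via U
  dc_next <- matrix(0, B, H)  # f_{t+1} * dc_raw_{t+1}
  for (t in rev(seq_len(Tm))) {
    m <- cache$mask[, t]
    f <- matrix(cache$F[, t, ], B, H); o <- matrix(cache$O[, t, ], B, H)
    i <- matrix(cache$I[, t, ], B, H); g <- matrix(cache$G[, t, ], B, H)
    tc <- matrix(cache$TC[, t, ], B, H)
    c_prev <- if (t > 1L) matrix(cache$C[, t - 1L, ], B, H) else matrix(0, B, H)
    h_prev <- if (t > 1L) matrix(cache$H[, t - 1L, ], B, H) else matrix(0, B, H)
    draw_h <- (matrix(dH[, t, ], B, H) + dh_next) * m
    dc_raw <- dc_next * m + draw_h * o * (1 - tc^2)
    do_ <- draw_h * tc
    df <- dc_raw * c_prev
    di <- dc_raw * g
    dg <- dc_raw * i
    dA <- cbind(df * f * (1 - f), do_ * o * (1 - o),
                dg * (1 - g^2), di * i * (1 - i))
    Xt <- matrix(cache$X[, t, ], B, I)
    dX[, t, ] <- dA %*% t(blk$W)
    dW <- dW + crossprod(Xt, dA)
    dU <- dU + crossprod(h_prev, dA)
    db <- db + colSums(dA)
    dh_next <- dA %*% t(blk$U)
    dc_next <- dc_raw * f
  }
  split_block <- function(M) {
    if (is.matrix(M)) list(f = M[, 1:H, drop = FALSE],
                           o = M[, (H + 1):(2 * H), drop = FALSE],
                           g = M[, (2 * H + 1):(3 * H), drop = FALSE],
                           i = M[, (3 * H + 1):(4 * H), drop = FALSE])
    else list(f = M[1:H], o = M[(H + 1):(2 * H)],
              g = M[(2 * H + 1):(3 * H)], i = M[(3 * H + 1):(4 * H)])
  }
  sw <- split_block(dW); su <- split_block(dU); sb <- split_block(db)
  # same leaf order as lstm_init so parameter and gradient trees align
  grads <- list(W_f = sw$f, U_f = su$f, b_f = sb$f,
                W_o = sw$o, U_o = su$o, b_o = sb$o,
                W_g = sw$g, U_g = su$g, b_g = sb$g,
                W_i = sw$i, U_i = su$i, b_i = sb$i)
  list(dX = dX, grads = grads)
}

# Reverse each row's valid prefix of a (B, T, K) array in time.
reverse_batch <- function(A, lengths) {
  out <- A
  for (b in seq_along(lengths)) {
    n <- lengths[b]
    if (n > 1L) out[b, 1:n, ] <- A[b, n:1, ]
  }
  out
}

#' Bidirectional LSTM encoding of one sequence
#'
#' Runs a forward LSTM over the sequence and a backward LSTM over its
#' reversal (only the unpadded prefix is reversed) and concatenates the
#' per-token hidden states: row t is `h_t^fwd || h_t^bwd`. Padded rows are
#' zero.
#'
#' @param X numeric matrix (n x input_dim) of per-token input vectors.
#' @param params_fwd,params_bwd forward/backward [lstm_init()] parameters.
#' @param mask optional 0/1 vector of length n marking real tokens
#'   (left-aligned); defaults to all ones.
#' @param variant see [lstm_step()].
#' @return Matrix n x (2 * hidden).
#' @export
bilstm_encode <- function(X, params_fwd, params_bwd, mask = NULL,
                          variant = "standard") {
  n <- nrow(X)
  if (is.null(mask)) mask <- rep(1, n)
  if (length(mask) != n) stop("mask length must equal the sequence length")
  enc <- bilstm_forward_batch(array(X, c(1L, n, ncol(X))),
                              matrix(mask, 1L, n),
                              params_fwd, params_bwd, variant = variant)
  matrix(enc$H[1L, , ], n, 2L * params_fwd$hidden)
}

# Batched Bi-LSTM. Returns concatenated hidden states (B, T, 2H) and the
# two direction caches.
bilstm_forward_batch <- function(X, mask, params_fwd, params_bwd,
                                 variant = "standard") {
  lengths <- as.integer(rowSums(mask))
  fwd <- lstm_forward_batch(X, mask, params_fwd, variant)
  Xr <- reverse_batch(X, lengths)
  bwd <- lstm_forward_batch(Xr, mask, params_bwd, variant)
  Hb <- reverse_batch(bwd$H, lengths)
  B <- dim(X)[1]; Tm <- dim(X)[2]; H <- params_fwd$hidden
  Hall <- array(0, c(B, Tm, 2L * H))
  Hall[, , 1:H] <- fwd$H
  Hall[, , (H + 1):(2 * H)] <- Hb
  list(H = Hall, fwd = fwd, bwd = bwd, lengths = lengths)
}

bilstm_backward_batch <- function(enc, dH) {
  H <- enc$fwd$params$hidden
  dHf <- dH[, , 1:H, drop = FALSE]
  dHb <- reverse_batch(dH[, , (H + 1):(2 * H), drop = FALSE], enc$lengths)
  bf <- lstm_backward_batch(enc$fwd, dHf)
  bb <- lstm_backward_batch(enc$bwd, dHb)
  dX <- bf$dX + reverse_batch(bb$dX, enc$lengths)
  list(dX = dX, grads_fwd = bf$grads, grads_bwd = bb$grads)
}
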