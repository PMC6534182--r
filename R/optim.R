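# Generic parameter-tree utilities: RMSProp updates and flatten/unflatten
# for finite-difference gradient checks. Parameter trees are nested lists
# whose numeric leaves are trainable; structural fields (dims, counts,
# configs) are skipped by name.

STRUCT_FIELDS <- c("hidden", "input_dim", "h", "d", "config")

# Walk grads (the authoritative skeleton), updating matching numeric
# leaves of params with RMSProp: v <- rho v + (1 - rho) g^2;
# theta <- theta - lr g / (sqrt(v) + eps).
rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-7) {
  walk <- function(p, g, s) {
    if (is.list(g)) {
      if (is.null(s)) s <- vector("list", length(g))
      for (nm in seq_along(g)) {
        key <- if (!is.null(names(g))) names(g)[nm] else nm
        if (is.character(key) && key %in% STRUCT_FIELDS) next
        r <- walk(p[[key]], g[[key]], if (length(s) >= nm) s[[if (is.character(key)) key else nm]] else NULL)
        p[[key]] <- r$p
        s[[key]] <- r$s
      }
      list(p = p, s = s)
    } else {
      if (is.null(s)) s <- g * 0
      s <- rho * s + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(s) + eps), s = s)
    }
  }
  r <- walk(params, grads, state)
  list(params = r$p, state = r$s)
}

# Flatten all trainable numeric leaves into one vector (stable order).
flatten_params <- function(x) {
  acc <- list()
  walk <- function(v, path) {
    if (is.list(v)) {
      for (i in seq_along(v)) {
        key <- if (!is.null(names(v)) && nzchar(names(v)[i])) names(v)[i] else i
        if (is.character(key) && key %in% STRUCT_FIELDS) next
        walk(v[[i]], c(path, key))
      }
    } else if (is.numeric(v)) {
      acc[[length(acc) + 1L]] <<- as.numeric(v)
    }
  }
  walk(x, character(0))
  unlist(acc)
}

# Write a flat vector back into the tree (inverse of flatten_params).
unflatten_params <- function(x, vec) {
  pos <- 0L
  walk <- function(v) {
    if (is.list(v)) {
      for (i in seq_along(v)) {
        key <- if (!is.null(names(v)) && nzchar(names(v)[i])) names(v)[i] else i
        if (is.character(key) && key %in% STRUCT_FIELDS) next
        v[[i]] <- walk(v[[i]])
      }
      v
    } else if (is.numeric(v)) {
      k <- length(v)
      out <- vec[(pos + 1L):(pos + k)]
      pos <<- pos + k
      if (is.matrix(v)) out <- matrix(out, nrow(v), ncol(v))
      if (is.array(v) && !is.matrix(v)) out <- array(out, dim(v))
      out
    } else v
  }
  out <- walk(x)
  stopifnot(pos == length(vec))
  out
}
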