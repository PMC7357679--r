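# Internal neural-network primitives: valid convolution via im2col + GEMM,
# rectifier MLP heads, exact backpropagation, and Adam updates.  Everything
# operates on plain numeric matrices/arrays so parameter containers stay
# serializable as named lists.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# bias add without sweep()'s overhead
add_bias <- function(m, v) m + rep(v, each = nrow(m))

# Column map for a valid (no padding, stride 1) convolution on a P x P x B
# input with a k x k kernel.  Row p = oi + (oj-1)*O indexes output position,
# column q = ki + (kj-1)*k + (b-1)*k^2 indexes kernel entry; the value is the
# flat column index into the N x (P*P*B) input matrix.
im2col_map <- function(p_in, bands, kernel) {
  o <- p_in - kernel + 1L
  stopifnot(o >= 1L)
  oi <- rep.int(seq_len(o), o)
  oj <- rep(seq_len(o), each = o)
  ki <- rep.int(seq_len(kernel), kernel * bands)
  kj <- rep(rep(seq_len(kernel), each = kernel), bands)
  kb <- rep(seq_len(bands), each = kernel * kernel)
  # flat input index (i, j, b) -> i + (j-1)*P + (b-1)*P^2
  outer(oi, ki, "+") - 1L +
    p_in * (outer(oj, kj, "+") - 2L) +
    p_in * p_in * matrix(kb - 1L, length(oi), length(ki), byrow = TRUE)
}

# X: N x (P*P*B) matrix; returns (N*O^2) x (k^2*B) matrix with row n + (p-1)*N.
im2col_apply <- function(x, colmap) {
  n <- nrow(x)
  xc <- x[, as.vector(colmap), drop = FALSE]
  dim(xc) <- c(n * nrow(colmap), ncol(colmap))
  xc
}

# Inverse scatter of im2col_apply: accumulates gradients back onto the
# N x (P*P*B) layout.  With a 1 x 1 output extent the map is a pure column
# permutation; otherwise columns of the same q never collide, so loop over q.
col2im_apply <- function(dxc, colmap, n, ncol_out) {
  if (nrow(colmap) == 1L && ncol(colmap) == ncol_out) {
    dx <- dxc
    dx[, colmap[1L, ]] <- dxc
    return(dx)
  }
  o2 <- nrow(colmap)
  dx <- matrix(0, n, ncol_out)
  for (q in seq_len(ncol(colmap))) {
    dx[, colmap[, q]] <- dx[, colmap[, q]] + matrix(dxc[, q], n, o2)
  }
  dx
}

uniform_init <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- optimizers -------------------------------------------------------------
# Moment buffers live in an environment and the compiled kernels update the
# parameter tensors in place; trainers take ownership of their parameter
# buffers (own_params) before mutating them.

own_params <- function(m) {
  for (nm in param_names(m)) m[[nm]] <- m[[nm]] + 0
  m
}

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

# Mutates the tensors of `params` (and the moment buffers) in place.
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  a <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (nm in names(grads)) {
    adam_step_(params[[nm]], state$m[[nm]], state$v[[nm]], grads[[nm]],
               a, beta1, beta2, eps)
  }
  invisible(NULL)
}

# ---- softmax / sigmoid ------------------------------------------------------

softmax_rows <- function(logits) {
  n <- nrow(logits)
  rowmax <- logits[cbind(seq_len(n), max.col(logits, ties.method = "first"))]
  e <- exp(logits - rowmax)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Plain momentum SGD (used where Adam's per-coordinate normalization would
# amplify equilibrium noise, e.g. the adversarial generator); in-place like
# adam_update.
sgd_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$v <- lapply(params, function(p) p * 0)
  st
}

sgd_update <- function(params, grads, state, lr, momentum = 0.9) {
  for (nm in names(grads)) {
    sgd_step_(params[[nm]], state$v[[nm]], grads[[nm]], lr, momentum)
  }
  invisible(NULL)
}

# Shuffled index stream recycled to nb * bs entries, sliced per batch.
epoch_index <- function(n, n_batches, batch_size) {
  idx <- sample.int(n)
  rep_len(idx, n_batches * batch_size)
}
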