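# The three network families: convolutional embedding G, softmax classifier
# C, and the binary domain discriminator D.  Architectures follow the compact
# patch model used for multispectral habitat classification: two valid
# convolutions (20 filters of 2x2xB, then 100 filters of 4x4x20, rectifier
# activations) flattened to the embedding; the classifier is one hidden layer
# of 84 rectifier units with a softmax output; the discriminator one hidden
# layer of 100 rectifier units with a logistic output.

#' Build a convolutional embedding function
#'
#' Two valid (no padding, stride 1) convolutional layers with rectifier
#' activations, flattened to a vector.  With `patch_size = 5`, `bands = 8`
#' and the default filter geometry the spatial extent collapses to 1 x 1 and
#' the embedding dimension is 100.  Initialization is uniform fan-scaled and
#' reproducible under `seed`.
#'
#' @param bands number of input bands B.
#' @param patch_size input window side P; must satisfy
#'   `P >= kernel1 + kernel2 - 1` for the valid-convolution geometry.
#' @param seed integer seed for initialization.
#' @param filters1,kernel1 first layer: 20 filters of kernel 2 by default.
#' @param filters2,kernel2 second layer: 100 filters of kernel 4 by default.
#' @return an object of class `embedding_params` with fields `W1, b1, W2, b2`
#'   and geometry metadata (including `embed_dim`).
#' @export
build_embedding <- function(bands, patch_size = 5L, seed = 1L,
                            filters1 = 20L, kernel1 = 2L,
                            filters2 = 100L, kernel2 = 4L) {
  stopifnot(bands >= 1L)
  o1 <- patch_size - kernel1 + 1L
  o2 <- o1 - kernel2 + 1L
  if (o2 < 1L) {
    stop(sprintf(
      "patch_size %d too small for kernels %d then %d under valid convolution",
      patch_size, kernel1, kernel2), call. = FALSE)
  }
  set.seed(seed)
  k1 <- kernel1 * kernel1 * bands
  k2 <- kernel2 * kernel2 * filters1
  g <- list(
    W1 = uniform_init(k1, filters1, k1, filters1),
    b1 = numeric(filters1),
    W2 = uniform_init(k2, filters2, k2, filters2),
    b2 = numeric(filters2))
  g$bands <- as.integer(bands)
  g$patch_size <- as.integer(patch_size)
  g$kernel1 <- as.integer(kernel1)
  g$kernel2 <- as.integer(kernel2)
  g$filters1 <- as.integer(filters1)
  g$filters2 <- as.integer(filters2)
  g$o1 <- as.integer(o1)
  g$o2 <- as.integer(o2)
  g$embed_dim <- as.integer(o2 * o2 * filters2)
  g$norm <- NULL  # optional per-band standardization (mean, sd)
  g$colmap1 <- im2col_map(patch_size, bands, kernel1)
  g$colmap2 <- im2col_map(o1, filters1, kernel2)
  class(g) <- "embedding_params"
  g
}

#' Embedding dimension of an embedding function
#' @param g an `embedding_params`.
#' @export
embed_dim <- function(g) g$embed_dim

# Per-band standardization applied to the flattened N x (P^2 B) layout.
apply_norm <- function(g, xm) {
  if (is.null(g$norm)) return(xm)
  p2 <- g$patch_size^2
  n <- nrow(xm)
  mu <- rep(rep(g$norm$mean, each = p2), each = n)
  si <- rep(rep(1 / g$norm$sd, each = p2), each = n)
  (xm - mu) * si
}

# Forward pass.  `x` is a patch_set, an N x P x P x B array, or an already
# flattened N x (P^2 B) matrix.  Returns the N x E embedding matrix, or with
# cache = TRUE a list(out, cache) for backpropagation.
embed_forward <- function(g, x, cache = FALSE, normalized = FALSE) {
  if (inherits(x, "patch_set")) x <- ps_matrix(x)
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x)[1], prod(dim(x)[2:4]))
  n <- nrow(x)
  if (ncol(x) != g$patch_size^2 * g$bands) {
    stop("patch shape does not match the embedding's input spec",
         call. = FALSE)
  }
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, g$embed_dim)
    return(if (cache) list(out = out, cache = NULL) else out)
  }
  xm <- if (normalized) x else apply_norm(g, x)
  xc1 <- im2col_apply(xm, g$colmap1)
  z1 <- xc1 %*% g$W1
  m1 <- bias_relu_(z1, g$b1)       # z1 becomes the activation, in place
  a1m <- z1
  dim(a1m) <- c(n, g$o1^2 * g$filters1)
  xc2 <- im2col_apply(a1m, g$colmap2)
  z2 <- xc2 %*% g$W2
  m2 <- bias_relu_(z2, g$b2)
  out <- z2
  dim(out) <- c(n, g$embed_dim)
  if (!cache) return(out)
  list(out = out, cache = list(n = n, xc1 = xc1, m1 = m1, xc2 = xc2, m2 = m2))
}

# Backward pass from dE (N x E); returns gradients for W1, b1, W2, b2.
embed_backward <- function(g, cache, de) {
  n <- cache$n
  dim(de) <- c(n * g$o2^2, g$filters2)
  dz2 <- de * cache$m2
  gw2 <- crossprod(cache$xc2, dz2)
  gb2 <- colSums(dz2)
  dxc2 <- tcrossprod(dz2, g$W2)
  da1m <- col2im_apply(dxc2, g$colmap2, n, g$o1^2 * g$filters1)
  dim(da1m) <- c(n * g$o1^2, g$filters1)
  dz1 <- da1m * cache$m1
  list(W1 = crossprod(cache$xc1, dz1), b1 = colSums(dz1),
       W2 = gw2, b2 = gb2)
}

#' Build a softmax patch classifier head
#'
#' One fully connected rectifier layer of `hidden` units and a softmax output
#' over `n_classes` units, operating on embeddings.
#'
#' @param embed_dim input embedding dimension E.
#' @param n_classes number of classes N_c.
#' @param seed integer seed for initialization.
#' @param hidden hidden layer width (default 84).
#' @return an object of class `classifier_params`.
#' @export
build_classifier <- function(embed_dim, n_classes, seed = 1L, hidden = 84L) {
  if (embed_dim < 1L || n_classes < 1L || hidden < 1L) {
    stop("dimensions must be positive", call. = FALSE)
  }
  set.seed(seed)
  structure(list(
    Wh = uniform_init(embed_dim, hidden, embed_dim, hidden),
    bh = numeric(hidden),
    Wo = uniform_init(hidden, n_classes, hidden, n_classes),
    bo = numeric(n_classes),
    n_classes = as.integer(n_classes)), class = "classifier_params")
}

#' Build the domain discriminator head
#'
#' One fully connected rectifier layer on the embedding and a single logistic
#' output unit: the probability that a sample comes from the source domain.
#'
#' @param embed_dim input embedding dimension E.
#' @param seed integer seed for initialization.
#' @param hidden hidden layer width (default 100).
#' @return an object of class `discriminator_params`.
#' @export
build_discriminator <- function(embed_dim, seed = 1L, hidden = 100L) {
  if (embed_dim < 1L || hidden < 1L) {
    stop("dimensions must be positive", call. = FALSE)
  }
  set.seed(seed)
  structure(list(
    Wh = uniform_init(embed_dim, hidden, embed_dim, hidden),
    bh = numeric(hidden),
    Wo = uniform_init(hidden, 1L, hidden, 1L),
    bo = numeric(1L)), class = "discriminator_params")
}

# MLP head forward; out_fun transforms logits (softmax rows or sigmoid).
head_forward <- function(m, e, cache = FALSE) {
  z <- e %*% m$Wh
  msk <- bias_relu_(z, m$bh)       # z becomes the hidden activation
  logits <- z %*% m$Wo
  bias_add_(logits, m$bo)
  if (!cache) return(logits)
  list(logits = logits, cache = list(e = e, h = z, m1 = msk))
}

classifier_forward <- function(c_params, e, cache = FALSE) {
  f <- head_forward(c_params, e, cache = cache)
  if (!is.list(f)) return(softmax_rows(f))
  list(prob = softmax_rows(f$logits), cache = f$cache)
}

discriminator_forward <- function(d_params, e, cache = FALSE) {
  f <- head_forward(d_params, e, cache = cache)
  if (!is.list(f)) return(as.vector(sigmoid(f)))
  list(prob = as.vector(sigmoid(f$logits)), cache = f$cache)
}

# Backward through an MLP head from dlogits; returns grads and dE.
head_backward <- function(m, cache, dlogits) {
  gwo <- crossprod(cache$h, dlogits)
  gbo <- colSums(dlogits)
  dh <- tcrossprod(dlogits, m$Wo) * cache$m1
  list(grads = list(Wh = crossprod(cache$e, dh), bh = colSums(dh),
                    Wo = gwo, bo = gbo),
       de = tcrossprod(dh, m$Wh))
}

#' Predict class labels for a patch set
#'
#' Label = argmax of the classifier's probability vector; ties broken by the
#' lowest class index.  Deterministic given parameters.
#'
#' @param g an `embedding_params`.
#' @param c_params a `classifier_params`.
#' @param patches a `patch_set` (or N x P x P x B array).
#' @return list with `labels` (0-based integer vector) and `probabilities`
#'   (N x N_c matrix).
#' @export
predict_labels <- function(g, c_params, patches) {
  e <- embed_forward(g, patches)
  if (nrow(e) == 0L) {
    return(list(labels = integer(0),
                probabilities = matrix(numeric(0), 0L, c_params$n_classes)))
  }
  prob <- classifier_forward(c_params, e)
  list(labels = max.col(prob, ties.method = "first") - 1L,
       probabilities = prob)
}

#' Number of trainable parameters in a model component
#' @param m an `embedding_params`, `classifier_params` or
#'   `discriminator_params`.
#' @export
n_params <- function(m) {
  nms <- intersect(names(m), c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo"))
  sum(vapply(m[nms], length, integer(1)))
}

# Trainable tensors of a component, for Adam and checkpointing.
param_names <- function(m) {
  intersect(names(m), c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo"))
}

#' Bundle the five model components of the two-step procedure
#'
#' @param g_s,g_t source/target embedding functions (structurally identical).
#' @param c_s,c_t source/target classifier heads.
#' @param d domain discriminator (or NULL before adversarial training).
#' @return an object of class `model_suite`.
#' @export
model_suite <- function(g_s, g_t, c_s, c_t, d = NULL) {
  stopifnot(inherits(g_s, "embedding_params"),
            inherits(g_t, "embedding_params"))
  if (!identical(lapply(g_s[c("W1", "W2")], dim),
                 lapply(g_t[c("W1", "W2")], dim))) {
    stop("G_s and G_t must be structurally identical", call. = FALSE)
  }
  structure(list(G_s = g_s, G_t = g_t, C_s = c_s, C_t = c_t, D = d),
            class = "model_suite")
}
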