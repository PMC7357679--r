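# Shared fixtures, built in code.

# Deterministic H x W x B scene with values on the storable grid (k/255).
grid_scene <- function(h = 10, w = 10, b = 8, seed = 1) {
  set.seed(seed)
  multispectral_scene(array(sample(0:255, h * w * b, TRUE) / 255, c(h, w, b)))
}

# Labeled patch set with well-separated Gaussian classes (no scene needed):
# class k has mean level mu[k] in every pixel of every band.
toy_patches <- function(n_per_class = 60, n_classes = 5, p = 5, b = 8,
                        sep = 0.08, noise = 0.01, seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  mu <- 0.1 + sep * (labels)
  x <- array(stats::rnorm(n * p * p * b, mean = mu, sd = noise), c(n, p, p, b))
  patch_set(pmin(pmax(x, 0), 1), labels = labels,
            centers = matrix(1L, n, 2),
            class_names = paste0("class", seq_len(n_classes)))
}

# Small quick training configuration for unit tests.
quick_config <- function(...) {
  train_config(source_epochs = 6L, adversarial_epochs = 4L,
               ccsa_epochs = 4L, batch_size = 64L, pairs_per_class = 20L,
               ...)
}

# Numeric gradient of f at x (central differences).
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Bind two N x P x P x B arrays along the first axis.
abind_rows <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, c(da[1] + db[1], da[-1]))
  if (da[1]) out[seq_len(da[1]), , , ] <- a
  if (db[1]) out[da[1] + seq_len(db[1]), , , ] <- b
  out
}
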