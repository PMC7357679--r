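test_that("classification loss matches closed forms", {
  onehot <- diag(5)[c(1, 3, 5), ]
  expect_equal(classification_loss(onehot, c(0L, 2L, 4L)), 0,
               tolerance = 1e-9)
  unif <- matrix(0.2, 4, 5)
  expect_equal(classification_loss(unif, c(0L, 1L, 2L, 3L)), log(5),
               tolerance = 1e-9)
  mixed <- rbind(diag(5)[1, , drop = FALSE], matrix(0.2, 1, 5))
  expect_equal(classification_loss(mixed, c(0L, 0L)), log(5) / 2,
               tolerance = 1e-9)
  # a zero probability at the true label is floored, never NaN
  bad <- matrix(c(0, 1, 0, 0, 0), 1)
  expect_true(is.finite(classification_loss(bad, 0L)))
  expect_error(classification_loss(matrix(c(0.9, 0.3), 1), 0L), "normalized")
  expect_error(classification_loss(unif, c(0L, 1L, 2L, 5L)), "range")
})

test_that("adversarial losses match closed forms", {
  expect_equal(discriminator_loss(rep(1, 3), rep(0, 4)), 0, tolerance = 1e-9)
  expect_equal(discriminator_loss(rep(0.5, 7), rep(0.5, 2)), 2 * log(2),
               tolerance = 1e-9)
  expect_equal(discriminator_loss(exp(-2), numeric(0)), 2, tolerance = 1e-9)
  expect_error(discriminator_loss(1.2, 0.5), "\\[0, 1\\]")

  expect_equal(generator_loss(rep(1, 5)), 0, tolerance = 1e-9)
  expect_equal(generator_loss(rep(0.5, 3)), log(2), tolerance = 1e-9)
  expect_equal(generator_loss(rep(exp(-3), 2)), 3, tolerance = 1e-9)
  expect_error(generator_loss(-0.1), "\\[0, 1\\]")
})

test_that("pair distance and similarity match their definitions", {
  expect_equal(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0, tolerance = 1e-12)
  expect_equal(pair_distance(c(3, 4), c(0, 0)), 2.5, tolerance = 1e-12)
  expect_equal(pair_distance(c(3, 4), c(0, 0), squared = TRUE), 12.5,
               tolerance = 1e-12)
  expect_error(pair_distance(1:3, 1:2), "mismatch")

  expect_equal(pair_similarity(c(1, 0), c(0, 0), margin = 1), 0,
               tolerance = 1e-12)  # at the margin boundary
  expect_equal(pair_similarity(c(0.3, 0.7), c(0.3, 0.7), margin = 1), 0.5,
               tolerance = 1e-12)
  expect_equal(pair_similarity(c(0.5, 0), c(0, 0), margin = 1), 0.125,
               tolerance = 1e-12)
  expect_error(pair_similarity(1, 1, margin = -1), "non-negative")

  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(pair_distance(u, v), pair_distance(v, u))
    # monotone non-increasing in the distance, zero beyond the margin
    r <- sqrt(sum((u - v)^2))
    shrink <- u + 0.5 * (v - u)
    expect_gte(pair_similarity(shrink, v, margin = 2),
               pair_similarity(u, v, margin = 2) - 1e-12)
    expect_identical(pair_similarity(u, v, margin = r * 0.99), 0)
  }
})

loop_sa <- function(es, ls, et, lt, squared = FALSE) {
  total <- 0
  for (i in seq_along(ls)) for (j in seq_along(lt)) {
    if (ls[i] == lt[j]) {
      total <- total + pair_distance(es[i, ], et[j, ], squared = squared)
    }
  }
  total
}

loop_cs <- function(es, ls, et, lt, m) {
  total <- 0
  for (i in seq_along(ls)) for (j in seq_along(lt)) {
    if (ls[i] != lt[j]) {
      total <- total + pair_similarity(es[i, ], et[j, ], margin = m)
    }
  }
  total
}

test_that("pairwise alignment losses equal the double-loop oracle", {
  # explicit two-pair case: distances 1 and 2 sum to 3
  es <- rbind(c(2, 0), c(4, 0))
  et <- rbind(c(0, 0))
  expect_equal(semantic_alignment_loss(es, c(0L, 0L), et, 0L), 3,
               tolerance = 1e-12)
  # identical same-class embeddings across domains
  expect_equal(semantic_alignment_loss(es, c(0L, 1L), es, c(0L, 1L)), 0 +
                 pair_distance(es[1, ], es[1, ]), tolerance = 1e-12)
  # single overlapping cross-class pair
  expect_equal(class_separation_loss(rbind(c(1, 1)), 0L, rbind(c(1, 1)), 1L,
                                     margin = 1), 0.5, tolerance = 1e-12)
  # all cross-class pairs farther than the margin contribute nothing
  far <- rbind(c(10, 0), c(0, 10))
  expect_identical(class_separation_loss(far, c(0L, 1L), -far, c(1L, 0L),
                                         margin = 1), 0)

  set.seed(31)
  for (i in 1:10) {
    ns <- sample(3:12, 1); nt <- sample(3:12, 1); d <- sample(2:6, 1)
    es <- matrix(rnorm(ns * d), ns, d)
    et <- matrix(rnorm(nt * d), nt, d)
    ls <- sample(0:2, ns, TRUE); lt <- sample(0:2, nt, TRUE)
    expect_equal(semantic_alignment_loss(es, ls, et, lt),
                 loop_sa(es, ls, et, lt), tolerance = 1e-9)
    expect_equal(semantic_alignment_loss(es, ls, et, lt, squared = TRUE),
                 loop_sa(es, ls, et, lt, squared = TRUE), tolerance = 1e-9)
    expect_equal(class_separation_loss(es, ls, et, lt, margin = 1.5),
                 loop_cs(es, ls, et, lt, 1.5), tolerance = 1e-9)
  }
})

test_that("the combined objective is additive in its components", {
  expect_identical(ccsa_loss(0, 0, 0), 0)
  expect_equal(ccsa_loss(log(5), 3, 0.5), log(5) + 3.5, tolerance = 1e-12)
  expect_equal(ccsa_loss(1, 2, 3, weights = c(1, 0.5, 2)), 8,
               tolerance = 1e-12)
  set.seed(8)
  es <- matrix(rnorm(12), 4, 3); et <- matrix(rnorm(9), 3, 3)
  ls <- c(0L, 0L, 1L, 1L); lt <- c(0L, 1L, 1L)
  lc <- classification_loss(matrix(1 / 3, 3, 3), lt)
  lsa <- semantic_alignment_loss(es, ls, et, lt)
  lcs <- class_separation_loss(es, ls, et, lt, margin = 1)
  expect_equal(ccsa_loss(lc, lsa, lcs), lc + lsa + lcs, tolerance = 1e-12)
})

test_that("pair-loss gradients used in training match numeric gradients", {
  set.seed(41)
  u <- rnorm(6); v <- rnorm(6)
  # semantic alignment gradient: d/du of 0.5 * ||u - v||
  r <- sqrt(sum((u - v)^2))
  expect_equal(num_grad(function(x) pair_distance(x, v), u),
               (u - v) / (2 * r), tolerance = 1e-6)
  # separation gradient inside the margin
  m <- r + 0.7
  expect_equal(num_grad(function(x) pair_similarity(x, v, margin = m), u),
               -(m - r) * (u - v) / r, tolerance = 1e-6)
})
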