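# Loss terms of the two-step adaptation objective, as pure functions.
#
# Conventions: expectations are realized as sample means over the batch;
# logs are floored at eps = 1e-12 so a zero probability never produces NaN;
# the pair distance is the half Euclidean (Frobenius) norm as used by the
# contrastive semantic alignment objective, with an optional squared variant.

LOG_EPS <- 1e-12

safe_log <- function(x) log(pmax(x, LOG_EPS))

#' Contrastive-alignment configuration
#'
#' @param margin non-negative separation margin m (default 1).
#' @param squared_distance use the squared half-distance for the semantic
#'   alignment term instead of the plain half Euclidean norm.
#' @return an object of class `csa_config`.
#' @export
csa_config <- function(margin = 1, squared_distance = FALSE) {
  if (margin < 0) stop("`margin` must be non-negative", call. = FALSE)
  structure(list(margin = margin, squared_distance = squared_distance),
            class = "csa_config")
}

#' Mean cross-entropy classification loss
#'
#' Mean negative log-probability of the true class over the batch.
#'
#' @param probabilities N x N_c matrix of row-normalized class probabilities.
#' @param labels integer vector of length N, 0-based class indices.
#' @return non-negative scalar.
#' @export
classification_loss <- function(probabilities, labels) {
  probabilities <- rbind(probabilities)
  n <- nrow(probabilities)
  if (length(labels) != n) stop("labels/probabilities mismatch", call. = FALSE)
  if (n == 0L) return(0)
  if (any(labels < 0L | labels >= ncol(probabilities))) {
    stop("labels out of range", call. = FALSE)
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-4)) {
    stop("probability rows must be normalized", call. = FALSE)
  }
  -mean(safe_log(probabilities[cbind(seq_len(n), labels + 1L)]))
}

#' Discriminator (binary cross-entropy) loss
#'
#' Source samples are labeled 1, target samples 0; the loss is
#' `-mean(log D(source)) - mean(log(1 - D(target)))`.  An empty side
#' contributes 0.
#'
#' @param d_source discriminator outputs on source embeddings, in \[0, 1\].
#' @param d_target discriminator outputs on target embeddings, in \[0, 1\].
#' @return non-negative scalar.
#' @export
discriminator_loss <- function(d_source, d_target) {
  check_unit_interval(d_source)
  check_unit_interval(d_target)
  ls <- if (length(d_source)) -mean(safe_log(d_source)) else 0
  lt <- if (length(d_target)) -mean(safe_log(1 - d_target)) else 0
  ls + lt
}

#' Generator (embedding-adaptation) loss
#'
#' `-mean(log D(target))`: decreases as the target embedding fools the
#' discriminator into scoring target samples as source.
#'
#' @param d_target discriminator outputs on target embeddings, in \[0, 1\].
#' @return non-negative scalar.
#' @export
generator_loss <- function(d_target) {
  check_unit_interval(d_target)
  if (!length(d_target)) return(0)
  -mean(safe_log(d_target))
}

check_unit_interval <- function(x) {
  if (length(x) && (any(!is.finite(x)) || any(x < 0 | x > 1))) {
    stop("discriminator outputs must lie in [0, 1]", call. = FALSE)
  }
}

#' Half Euclidean distance between two embeddings
#'
#' `0.5 * ||u - v||` (or `0.5 * ||u - v||^2` with `squared = TRUE`).
#'
#' @param u,v numeric vectors of equal length.
#' @param squared use the squared variant.
#' @return non-negative scalar.
#' @export
pair_distance <- function(u, v, squared = FALSE) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  r <- sqrt(sum((u - v)^2))
  if (squared) r^2 / 2 else r / 2
}

#' Margin similarity penalty between two embeddings
#'
#' `0.5 * max(0, m - ||u - v||)^2`: zero whenever the pair is at least the
#' margin apart, growing quadratically as it approaches.
#'
#' @param u,v numeric vectors of equal length.
#' @param margin non-negative margin m.
#' @return non-negative scalar.
#' @export
pair_similarity <- function(u, v, margin = 1) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  if (margin < 0) stop("`margin` must be non-negative", call. = FALSE)
  max(0, margin - sqrt(sum((u - v)^2)))^2 / 2
}

# Cross-domain Euclidean distance matrix (n_s x n_t).
cross_distance <- function(u, v) {
  d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * tcrossprod(u, v)
  sqrt(pmax(d2, 0))
}

#' Semantic alignment loss over same-class cross-domain pairs
#'
#' Every target sample is paired with every source sample of its class; the
#' loss is the sum (or mean) of `pair_distance` over those pairs.  Classes
#' absent from either side contribute 0.
#'
#' @param src_embeddings,tgt_embeddings numeric matrices (rows = samples).
#' @param src_labels,tgt_labels integer class labels (0-based).
#' @param squared use the squared half-distance.
#' @param reduce "sum" (as defined) or "mean" (batch-size invariant form
#'   used in the optimizer path).
#' @return non-negative scalar.
#' @export
semantic_alignment_loss <- function(src_embeddings, src_labels,
                                    tgt_embeddings, tgt_labels,
                                    squared = FALSE, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  same <- outer(src_labels, tgt_labels, "==")
  if (!any(same)) return(0)
  d <- cross_distance(rbind(src_embeddings), rbind(tgt_embeddings))[same]
  d <- if (squared) d^2 / 2 else d / 2
  if (reduce == "sum") sum(d) else mean(d)
}

#' Class separation loss over different-class cross-domain pairs
#'
#' Every target sample is paired with every source sample of a different
#' class; the loss sums `pair_similarity` with margin `margin` over those
#' pairs, so it is 0 when every cross-class pair is at least the margin
#' apart.
#'
#' @inheritParams semantic_alignment_loss
#' @param margin non-negative margin m.
#' @return non-negative scalar.
#' @export
class_separation_loss <- function(src_embeddings, src_labels,
                                  tgt_embeddings, tgt_labels, margin = 1,
                                  reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (margin < 0) stop("`margin` must be non-negative", call. = FALSE)
  diff <- outer(src_labels, tgt_labels, "!=")
  if (!any(diff)) return(0)
  d <- cross_distance(rbind(src_embeddings), rbind(tgt_embeddings))[diff]
  k <- pmax(0, margin - d)^2 / 2
  if (reduce == "sum") sum(k) else mean(k)
}

#' Combined classification and contrastive semantic alignment loss
#'
#' The unweighted sum `L_C + L_SA + L_CS` of the three components computed on
#' the same pairing state; optional weights default to 1.
#'
#' @param classification,alignment,separation the three component scalars.
#' @param weights length-3 numeric weights.
#' @return scalar.
#' @export
ccsa_loss <- function(classification, alignment, separation,
                      weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L)
  sum(weights * c(classification, alignment, separation))
}
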