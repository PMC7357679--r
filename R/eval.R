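# Evaluation: stratified k-fold cross-validation, labeled-region accuracy,
# scene-wide classification maps, and t-SNE embedding export.

#' Stratified k-fold split
#'
#' Disjoint, exhaustive folds; with `stratify_labels` the per-class fold
#' sizes differ by at most 1, so class proportions are preserved.  Each
#' sample is tested exactly once across folds.
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param stratify_labels optional label vector of length `n`.
#' @return list of `k` integer index vectors.
#' @export
kfold_split <- function(n, k, seed = 1L, stratify_labels = NULL) {
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("`n` must be >= `k`", call. = FALSE)
  set.seed(seed)
  folds <- vector("list", k)
  if (is.null(stratify_labels)) {
    idx <- sample.int(n)
    fold_of <- rep_len(seq_len(k), n)
    for (f in seq_len(k)) folds[[f]] <- sort(idx[fold_of == f])
  } else {
    stopifnot(length(stratify_labels) == n)
    for (lab in sort(unique(stratify_labels))) {
      idx <- which(stratify_labels == lab)
      if (length(idx) < k) {
        stop(sprintf("class %s has %d sample(s), fewer than k = %d",
                     as.character(lab), length(idx), k), call. = FALSE)
      }
      idx <- sample(idx)
      fold_of <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    }
    folds <- lapply(folds, sort)
  }
  folds
}

#' k-fold cross-validation of the source patch classifier
#'
#' Trains a fresh model per fold on the remaining folds and evaluates on the
#' held-out part, reporting per-fold accuracies, their mean and standard
#' deviation, and the aggregated confusion matrix.  Folds are stratified by
#' class.
#'
#' @param patches labeled `patch_set`.
#' @param k number of folds (default 3).
#' @param config a `train_config`.
#' @return an object of class `eval_report`.
#' @export
kfold_cv <- function(patches, k = 3L, config = train_config()) {
  stopifnot(!is.null(patches$labels))
  n <- n_patches(patches)
  nc <- length(patches$class_names)
  folds <- kfold_split(n, k, seed = config$seed,
                       stratify_labels = patches$labels)
  acc <- numeric(k)
  conf <- matrix(0L, nc, nc,
                 dimnames = list(truth = patches$class_names,
                                 predicted = patches$class_names))
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_source(ps_take(patches, setdiff(seq_len(n), test_idx)), cfg)
    test <- ps_take(patches, test_idx)
    pred <- predict_labels(fit$G, fit$C, test)$labels
    acc[f] <- mean(pred == test$labels)
    for (i in seq_along(pred)) {
      conf[test$labels[i] + 1L, pred[i] + 1L] <-
        conf[test$labels[i] + 1L, pred[i] + 1L] + 1L
    }
  }
  eval_report(data.frame(fold = seq_len(k), accuracy = acc,
                         n_test = lengths(folds)),
              conf, patches$class_names,
              scenario = list(k = k, seed = config$seed))
}

#' Construct an evaluation report
#'
#' @param folds data.frame with columns `fold`, `accuracy`, `n_test`.
#' @param confusion aggregated N_c x N_c confusion matrix (rows = truth).
#' @param class_names class names.
#' @param scenario free-form scenario metadata list.
#' @return an object of class `eval_report` with `mean` and `sd` fields.
#' @export
eval_report <- function(folds, confusion, class_names, scenario = list()) {
  structure(list(folds = folds, mean = mean(folds$accuracy),
                 sd = stats::sd(folds$accuracy), confusion = confusion,
                 class_names = class_names, scenario = scenario),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validation report (%d fold(s))\n", nrow(x$folds)))
  print(x$folds, row.names = FALSE, digits = 4)
  cat(sprintf("  mean %.4f +/- %.4f\n", x$mean, x$sd))
  invisible(x)
}

#' Overall accuracy from a confusion matrix
#' @param confusion square confusion matrix, rows = truth.
#' @export
confusion_accuracy <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' Classify every eligible pixel of a scene
#'
#' Every pixel with a full nodata-free window receives the predicted class
#' 1..N_c of its centered patch; ineligible pixels (borders, nodata
#' windows) are 0.  Evaluation is batched and deterministic.
#'
#' @param scene an `msscene`.
#' @param g an `embedding_params`.
#' @param c_params a `classifier_params`.
#' @param patch_size patch window side.
#' @param class_names class names for the output mask.
#' @param batch_size patches per forward batch.
#' @return a predicted `label_mask`.
#' @export
classify_scene <- function(scene, g, c_params, patch_size = 5L,
                           class_names = NULL, batch_size = 8192L) {
  stopifnot(inherits(scene, "msscene"))
  if (is.null(class_names)) {
    class_names <- if (c_params$n_classes == 5L) DEFAULT_CLASSES else
      paste0("class", seq_len(c_params$n_classes))
  }
  ps <- extract_patches(scene, mask = NULL, patch_size = patch_size)
  d <- dim(scene$pixels)
  out <- matrix(0L, d[1], d[2])
  n <- n_patches(ps)
  if (n > 0L) {
    x <- ps_matrix(ps)
    for (start in seq(1L, n, by = batch_size)) {
      take <- start:min(start + batch_size - 1L, n)
      pred <- predict_labels(g, c_params, ps$patches[take, , , , drop = FALSE])
      out[ps$centers[take, , drop = FALSE]] <- pred$labels + 1L
    }
  }
  label_mask(out, class_names = class_names)
}

#' Pixelwise agreement between two label masks over labeled pixels
#'
#' @param predicted,truth `label_mask` objects of equal size.
#' @return fraction of pixels labeled in both masks that agree.
#' @export
map_accuracy <- function(predicted, truth) {
  both <- predicted$labels > 0L & truth$labels > 0L
  mean(predicted$labels[both] == truth$labels[both])
}

#' Export 2-D t-SNE coordinates of raw and embedded samples
#'
#' Draws up to `per_class` samples per class from each domain and computes
#' two t-SNE maps: one on the flattened raw patches (P*P*B dimensions, 200
#' for 5x5x8) and one on the embedded representations (source samples
#' through G_s, target samples through G_t).  The dimensionality reduction
#' itself is delegated to an existing t-SNE implementation
#' (scikit-learn's, invoked through the `python` on PATH).
#'
#' @param g_s,g_t the two embedding functions.
#' @param source_samples,target_samples labeled `patch_set`s.
#' @param per_class samples per class and domain (default 400).
#' @param seed integer seed (sampling and t-SNE random state).
#' @param perplexity t-SNE perplexity; reduced automatically for small n.
#' @return data.frame with columns `x`, `y`, `class`, `domain`, `stage`
#'   (stage is "raw" or "embedded").
#' @export
tsne_export <- function(g_s, g_t, source_samples, target_samples,
                        per_class = 400L, seed = 1L, perplexity = 30) {
  stopifnot(!is.null(source_samples$labels), !is.null(target_samples$labels))
  set.seed(seed)
  pick <- function(ps) {
    idx <- integer(0)
    for (k in sort(unique(ps$labels))) {
      avail <- which(ps$labels == k)
      idx <- c(idx, sample(avail, min(per_class, length(avail))))
    }
    sort(idx)
  }
  si <- pick(source_samples); ti <- pick(target_samples)
  src <- ps_take(source_samples, si); tgt <- ps_take(target_samples, ti)
  raw <- rbind(ps_matrix(src), ps_matrix(tgt))
  emb <- rbind(embed_forward(g_s, src), embed_forward(g_t, tgt))
  tags <- data.frame(
    class = c(src$class_names[src$labels + 1L],
              tgt$class_names[tgt$labels + 1L]),
    domain = rep(c("source", "target"), c(n_patches(src), n_patches(tgt))))
  out <- list()
  for (stage in c("raw", "embedded")) {
    xy <- run_tsne(if (stage == "raw") raw else emb, seed, perplexity)
    out[[stage]] <- data.frame(x = xy[, 1], y = xy[, 2], tags,
                               stage = stage)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Delegate t-SNE to scikit-learn via a CSV handoff.
run_tsne <- function(x, seed, perplexity) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") {
    stop("t-SNE export requires a `python` with scikit-learn on PATH",
         call. = FALSE)
  }
  inp <- tempfile(fileext = ".csv")
  outp <- tempfile(fileext = ".csv")
  scr <- tempfile(fileext = ".py")
  on.exit(unlink(c(inp, outp, scr)))
  utils::write.table(x, inp, sep = ",", row.names = FALSE, col.names = FALSE)
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from sklearn.manifold import TSNE",
    "x = np.atleast_2d(np.loadtxt(sys.argv[1], delimiter=','))",
    "perp = min(float(sys.argv[4]), (x.shape[0] - 1) / 3.0)",
    "emb = TSNE(n_components=2, random_state=int(sys.argv[3]),",
    "           perplexity=perp, init='pca').fit_transform(x)",
    "np.savetxt(sys.argv[2], emb, delimiter=',')"), scr)
  res <- suppressWarnings(system2(python, c(scr, inp, outp, seed, perplexity),
                                  stdout = TRUE, stderr = TRUE))
  code <- attr(res, "status")
  if ((!is.null(code) && code != 0L) || !file.exists(outp)) {
    stop("t-SNE backend failed: ", paste(res, collapse = "\n"),
         call. = FALSE)
  }
  as.matrix(utils::read.csv(outp, header = FALSE))
}
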