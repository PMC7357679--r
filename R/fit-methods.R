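# S3 methods for fitted two-step adaptation objects.

#' @export
print.seadapt_fit <- function(x, ...) {
  cat("Two-step semi-supervised domain adaptation fit\n")
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  shots per class: %s   seed: %d\n",
              if (is.null(x$shot_indices)) "-" else x$shots,
              x$config$seed))
  cat(sprintf("  source training accuracy: %.4f\n", x$train_accuracy))
  if (nrow(x$results)) {
    cat("  target-domain accuracy:\n")
    for (i in seq_len(nrow(x$results))) {
      cat(sprintf("    %-12s %.4f\n", x$results$method[i],
                  x$results$accuracy[i]))
    }
  }
  invisible(x)
}

#' @export
summary.seadapt_fit <- function(object, ...) {
  structure(list(results = object$results,
                 config = object$config,
                 class_names = object$class_names,
                 train_accuracy = object$train_accuracy,
                 epochs = vapply(object$histories, nrow, integer(1))),
            class = "summary.seadapt_fit")
}

#' @export
print.summary.seadapt_fit <- function(x, ...) {
  cat("Two-step domain adaptation summary\n")
  cat(sprintf("  source train accuracy: %.4f\n", x$train_accuracy))
  cat(sprintf("  stage epochs: %s\n",
              paste(sprintf("%s=%d", names(x$epochs), x$epochs),
                    collapse = ", ")))
  if (nrow(x$results)) {
    print(x$results, row.names = FALSE)
  }
  invisible(x)
}

#' Predict habitat classes with a fitted adaptation model
#'
#' @param object a `seadapt_fit`.
#' @param newdata a `patch_set` or an `msscene` (the latter yields a
#'   predicted `label_mask` via [classify_scene()]).
#' @param model which embedding/classifier to apply: the adapted target
#'   model (default), the frozen source model, or any fitted variant name.
#' @param ... unused.
#' @return for a `patch_set`: list(labels, probabilities) with 0-based
#'   labels; for an `msscene`: a predicted `label_mask`.
#' @export
predict.seadapt_fit <- function(object, newdata, model = "target", ...) {
  pair <- switch(model,
    target = list(G = object$suite$G_t, C = object$suite$C_t),
    source = object$source_model,
    {
      if (is.null(object$models[[model]])) {
        stop("unknown model variant: ", model, call. = FALSE)
      }
      object$models[[model]]
    })
  if (inherits(newdata, "msscene")) {
    return(classify_scene(newdata, pair$G, pair$C,
                          patch_size = pair$G$patch_size))
  }
  predict_labels(pair$G, pair$C, newdata)
}

#' Plot training loss traces of a fitted adaptation model
#'
#' One panel per training stage (source, adversarial, contrastive).
#'
#' @param x a `seadapt_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.seadapt_fit <- function(x, ...) {
  hs <- x$histories
  old <- graphics::par(mfrow = c(1, length(hs)))
  on.exit(graphics::par(old))
  for (nm in names(hs)) {
    h <- hs[[nm]]
    if (!nrow(h)) next
    graphics::matplot(h$epoch, h[, -1, drop = FALSE], type = "l", lty = 1,
                      xlab = "epoch", ylab = "loss", main = nm, ...)
    if (ncol(h) > 2) {
      graphics::legend("topright", legend = colnames(h)[-1], lty = 1,
                       col = seq_len(ncol(h) - 1), bty = "n", cex = 0.8)
    }
  }
  invisible(x)
}
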