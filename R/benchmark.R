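# Driver for the synthetic domain-shift benchmark: runs the model variants
# over replicated scene realizations and reports target accuracies in a tidy
# table.  Stages are shared where valid (one source model and one
# adversarial run per seed; pairing and contrastive alignment re-done per
# shot count).

#' Run the domain-shift benchmark for one regime
#'
#' For each seed: generates the regime's scene pair, trains the source
#' model, runs the adversarial step once, then for every requested shot
#' count draws shots, builds pairs and runs the contrastive step for the
#' "ccsa" and "proposed" variants.  Accuracies are measured on the held-out
#' labeled target patches.
#'
#' @param regime one of "none", "mild", "strong" (see [benchmark_suite()]).
#' @param seeds integer vector of replicate seeds.
#' @param shots integer vector of shot counts for the few-shot variants.
#' @param methods model variants to evaluate.
#' @param config base `train_config`; its seed field is replaced per
#'   replicate.
#' @param n_train_per_class,n_test_per_class benchmark split sizes.
#' @param scene_size scene dimensions.
#' @return data.frame with columns seed, method, shots, accuracy.
#' @export
run_shift_benchmark <- function(regime = "strong", seeds = 1:3,
                                shots = c(1L, 5L),
                                methods = c("source-only", "adda", "ccsa",
                                            "proposed"),
                                config = train_config(),
                                n_train_per_class = 500L,
                                n_test_per_class = 200L,
                                scene_size = c(128L, 128L)) {
  rows <- list()
  add <- function(seed, method, n_shots, acc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      seed = seed, method = method, shots = n_shots, accuracy = acc)
  }
  for (sd_ in seeds) {
    suite <- benchmark_suite(sd_, scene_size = scene_size)
    if (is.null(suite[[regime]])) stop("unknown regime: ", regime)
    bd <- benchmark_data(suite[[regime]], n_train_per_class,
                         n_test_per_class)
    cfg <- config
    cfg$seed <- as.integer(sd_)
    acc <- function(g, cp) {
      pr <- predict_labels(g, cp, bd$target_test)
      mean(pr$labels == bd$target_test$labels)
    }
    src <- train_source(bd$source_train, cfg)
    if ("source-only" %in% methods) add(sd_, "source-only", NA, acc(src$G, src$C))
    adv <- NULL
    if (any(c("adda", "proposed") %in% methods)) {
      adv <- adapt_marginal(src$G, strip_labels(bd$source_train),
                            strip_labels(bd$target_pool), cfg)
      if ("adda" %in% methods) add(sd_, "adda", NA, acc(adv$G_t, src$C))
    }
    for (n_shots in shots) {
      if (!any(c("ccsa", "proposed", "finetune") %in% methods)) break
      shot_idx <- select_shots(bd$target_pool, n_shots, cfg$seed + 7L)
      shots_ps <- ps_take(bd$target_pool, shot_idx)
      if ("finetune" %in% methods) {
        ft <- finetune_model(src$G, src$C, shots_ps, cfg)
        add(sd_, "finetune", n_shots, acc(ft$G, ft$C))
      }
      if (any(c("ccsa", "proposed") %in% methods)) {
        pairs <- sample_pairs(bd$source_train, shots_ps,
                              pairs_per_class = cfg$pairs_per_class,
                              seed = cfg$seed + 8L)
        if ("ccsa" %in% methods) {
          cc <- adapt_conditional(src$G, src$G, src$C, bd$source_train,
                                  shots_ps, pairs, cfg)
          add(sd_, "ccsa", n_shots, acc(cc$G_t, cc$C_t))
        }
        if ("proposed" %in% methods) {
          cc <- adapt_conditional(src$G, adv$G_t, src$C, bd$source_train,
                                  shots_ps, pairs, cfg)
          add(sd_, "proposed", n_shots, acc(cc$G_t, cc$C_t))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark table as mean and sd per method and shot count
#'
#' @param results data.frame from [run_shift_benchmark()].
#' @return data.frame with method, shots, mean, sd, n.
#' @export
summarize_benchmark <- function(results) {
  key <- paste(results$method,
               ifelse(is.na(results$shots), "-", results$shots))
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(method = d$method[1], shots = d$shots[1],
               mean = mean(d$accuracy), sd = stats::sd(d$accuracy),
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$method, out$shots), ]
}
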