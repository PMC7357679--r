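# The two-step semi-supervised domain adaptation procedures:
#   1. supervised source training (cross-entropy),
#   2. unsupervised adversarial alignment of the marginal embedding
#      distributions (discriminator vs. target embedding, source frozen),
#   3. few-shot contrastive semantic alignment (CCSA) jointly re-optimizing
#      both embeddings plus the target classifier from n labeled target
#      samples per class, paired against drawn source pools.
# All optimizers are Adam at the configured learning rate; every source of
# randomness is seeded through the config.

#' Training configuration for the two-step procedure
#'
#' Defaults follow the published protocol for this model family: 50 source
#' epochs at batch size 128, 300 adversarial epochs, 240 CCSA epochs,
#' learning rate 2e-4, margin 1, and 400 drawn source samples per class for
#' pairing.
#'
#' @param source_epochs supervised source training epochs.
#' @param batch_size mini-batch size (patches, or pairs in the CCSA step).
#' @param adversarial_epochs adversarial alignment epochs.
#' @param ccsa_epochs contrastive alignment epochs.
#' @param learning_rate Adam learning rate for every stage.
#' @param margin separation margin m of the class separation loss.
#' @param pairs_per_class source samples drawn per class for pairing.
#' @param shots labeled target samples per class (n-shot).
#' @param seed master integer seed.
#' @param loss_weights length-3 weights for (classification, alignment,
#'   separation); default all 1.
#' @param normalize standardize bands using source training statistics.
#' @param squared_distance squared variant of the alignment distance.
#' @param joint let gradients flow into the source embedding during CCSA
#'   (FALSE reproduces the no-joint-optimization ablation).
#' @param freeze_source_classifier keep the source classifier fixed during
#'   CCSA (default TRUE): the frozen C_s anchors the embedding geometry the
#'   alignment pulls toward, preventing representation collapse; set FALSE
#'   to let C_s re-train alongside.
#' @param replications repetitions for scenario tables (mean +/- sd).
#' @return an object of class `train_config`.
#' @export
train_config <- function(source_epochs = 50L, batch_size = 128L,
                         adversarial_epochs = 300L, ccsa_epochs = 240L,
                         learning_rate = 2e-4, margin = 1,
                         pairs_per_class = 400L, shots = 1L, seed = 1L,
                         loss_weights = c(1, 1, 1), normalize = TRUE,
                         squared_distance = FALSE, joint = TRUE,
                         freeze_source_classifier = TRUE,
                         replications = 3L) {
  stopifnot(source_epochs >= 0L, batch_size >= 1L, adversarial_epochs >= 0L,
            ccsa_epochs >= 0L, pairs_per_class >= 1L, shots >= 1L,
            replications >= 1L, length(loss_weights) == 3L)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  structure(list(source_epochs = as.integer(source_epochs),
                 batch_size = as.integer(batch_size),
                 adversarial_epochs = as.integer(adversarial_epochs),
                 ccsa_epochs = as.integer(ccsa_epochs),
                 learning_rate = learning_rate, margin = margin,
                 pairs_per_class = as.integer(pairs_per_class),
                 shots = as.integer(shots), seed = as.integer(seed),
                 loss_weights = loss_weights, normalize = normalize,
                 squared_distance = squared_distance, joint = joint,
                 freeze_source_classifier = freeze_source_classifier,
                 replications = as.integer(replications)),
            class = "train_config")
}

check_labeled <- function(ps, n_classes) {
  if (is.null(ps$labels)) stop("patch set must be labeled", call. = FALSE)
  missing <- setdiff(seq_len(n_classes) - 1L, unique(ps$labels))
  if (length(missing)) {
    stop("no samples for class(es): ",
         paste(ps$class_names[missing + 1L], collapse = ", "), call. = FALSE)
  }
}

#' Train the source-domain patch classifier
#'
#' Minimizes the mean cross-entropy classification loss by seeded mini-batch
#' Adam for `config$source_epochs` epochs.  Band standardization constants
#' are estimated from these training patches and stored on the embedding.
#'
#' @param patches labeled `patch_set` with at least one sample per class.
#' @param config a `train_config`.
#' @return list with `G` (embedding), `C` (classifier), `history`
#'   (per-epoch mean loss) and `train_accuracy`.
#' @export
train_source <- function(patches, config = train_config()) {
  nc <- length(patches$class_names)
  check_labeled(patches, nc)
  g <- build_embedding(patches$n_bands, patches$patch_size,
                       seed = config$seed)
  if (config$normalize) {
    xm <- ps_matrix(patches)
    p2 <- patches$patch_size^2
    bands <- patches$n_bands
    bm <- numeric(bands); bs <- numeric(bands)
    for (b in seq_len(bands)) {
      v <- xm[, (b - 1L) * p2 + seq_len(p2)]
      bm[b] <- mean(v)
      bs[b] <- max(stats::sd(v), 1e-8)
    }
    g$norm <- list(mean = bm, sd = bs)
  }
  c_params <- build_classifier(g$embed_dim, nc, seed = config$seed + 1L)
  set.seed(config$seed + 2L)
  x <- apply_norm(g, ps_matrix(patches))  # normalization is fixed before training
  y <- patches$labels
  n <- nrow(x)
  bs <- min(config$batch_size, n)
  nb <- ceiling(n / bs)
  st_g <- adam_state(g[param_names(g)])
  st_c <- adam_state(c_params[param_names(c_params)])
  history <- numeric(config$source_epochs)
  for (ep in seq_len(max(0L, config$source_epochs))) {
    idx <- epoch_index(n, nb, bs)
    ep_loss <- 0
    for (ib in seq_len(nb)) {
      take <- idx[((ib - 1L) * bs + 1L):(ib * bs)]
      fe <- embed_forward(g, x[take, , drop = FALSE], cache = TRUE,
                          normalized = TRUE)
      fc <- classifier_forward(c_params, fe$out, cache = TRUE)
      yb <- y[take]
      ep_loss <- ep_loss + classification_loss(fc$prob, yb)
      dlogits <- fc$prob
      dlogits[cbind(seq_along(take), yb + 1L)] <-
        dlogits[cbind(seq_along(take), yb + 1L)] - 1
      dlogits <- dlogits / length(take)
      bk <- head_backward(c_params, fc$cache, dlogits)
      ge <- embed_backward(g, fe$cache, bk$de)
      adam_update(c_params[param_names(c_params)], bk$grads, st_c,
                  config$learning_rate)
      adam_update(g[param_names(g)], ge, st_g, config$learning_rate)
    }
    history[ep] <- ep_loss / nb
  }
  pred <- predict_labels(g, c_params, patches)
  list(G = g, C = c_params,
       history = data.frame(epoch = seq_len(config$source_epochs),
                            loss = history),
       train_accuracy = if (n) mean(pred$labels == y) else NA_real_)
}

#' Adversarial alignment of the marginal embedding distributions
#'
#' Initializes the target embedding as a copy of the (frozen) source
#' embedding, then alternates one discriminator step (binary cross-entropy,
#' source = 1, target = 0) and one generator step (`generator_loss`) per
#' mini-batch for `config$adversarial_epochs` epochs.  Only unlabeled pixels
#' are used.
#'
#' @param g_s trained source `embedding_params` (never modified).
#' @param source_patches,target_patches (unlabeled) `patch_set`s.
#' @param config a `train_config`.
#' @return list with `G_t`, `D` and `history` (per-epoch discriminator and
#'   generator losses).
#' @export
adapt_marginal <- function(g_s, source_patches, target_patches,
                           config = train_config()) {
  if (n_patches(source_patches) == 0L || n_patches(target_patches) == 0L) {
    stop("both domains must be non-empty", call. = FALSE)
  }
  g_t <- own_params(g_s)
  d <- build_discriminator(g_s$embed_dim, seed = config$seed + 3L)
  ne <- max(0L, config$adversarial_epochs)
  hist_d <- numeric(ne); hist_g <- numeric(ne)
  if (ne == 0L) {
    return(list(G_t = g_t, D = d,
                history = data.frame(epoch = integer(0), d_loss = numeric(0),
                                     g_loss = numeric(0))))
  }
  set.seed(config$seed + 4L)
  xs <- apply_norm(g_s, ps_matrix(source_patches))
  xt <- apply_norm(g_s, ps_matrix(target_patches))  # same constants both domains
  ns <- nrow(xs); nt <- nrow(xt)
  bs <- min(config$batch_size, ns, nt)
  nb <- ceiling(max(ns, nt) / bs)  # one epoch covers the larger domain
  st_d <- adam_state(d[param_names(d)])
  st_g <- sgd_state(g_t[param_names(g_t)])
  for (ep in seq_len(ne)) {
    is_ <- epoch_index(ns, nb, bs)
    it_ <- epoch_index(nt, nb, bs)
    ld <- 0; lg <- 0
    for (ib in seq_len(nb)) {
      sl <- ((ib - 1L) * bs + 1L):(ib * bs)
      es <- embed_forward(g_s, xs[is_[sl], , drop = FALSE], normalized = TRUE)
      # --- discriminator step (G_t fixed) ---
      et <- embed_forward(g_t, xt[it_[sl], , drop = FALSE], normalized = TRUE)
      fd <- discriminator_forward(d, rbind(es, et), cache = TRUE)
      yb <- c(rep(1, bs), rep(0, bs))
      ld <- ld + discriminator_loss(fd$prob[seq_len(bs)],
                                    fd$prob[bs + seq_len(bs)])
      dlogit <- matrix((fd$prob - yb) / bs, ncol = 1L)  # per-side mean
      bk <- head_backward(d, fd$cache, dlogit)
      adam_update(d[param_names(d)], bk$grads, st_d,
                  config$learning_rate, beta1 = 0.5)
      # --- generator step (D fixed) ---
      fe <- embed_forward(g_t, xt[it_[sl], , drop = FALSE], cache = TRUE,
                          normalized = TRUE)
      fd <- discriminator_forward(d, fe$out, cache = TRUE)
      lg <- lg + generator_loss(fd$prob)
      dlogit <- matrix(-(1 - fd$prob) / bs, ncol = 1L)
      bk <- head_backward(d, fd$cache, dlogit)
      ge <- embed_backward(g_t, fe$cache, bk$de)
      sgd_update(g_t[param_names(g_t)], ge, st_g, config$learning_rate)
    }
    hist_d[ep] <- ld / nb
    hist_g[ep] <- lg / nb
  }
  list(G_t = g_t, D = d,
       history = data.frame(epoch = seq_len(ne), d_loss = hist_d,
                            g_loss = hist_g))
}

#' Held-out discriminator accuracy on balanced batches
#'
#' Fraction of samples whose domain the discriminator identifies correctly
#' (threshold 0.5) on equally many source and target patches.
#'
#' @param d a `discriminator_params`.
#' @param g_s,g_t the two embedding functions.
#' @param source_patches,target_patches held-out `patch_set`s.
#' @return accuracy in \[0, 1\].
#' @export
discriminator_accuracy <- function(d, g_s, g_t, source_patches,
                                   target_patches) {
  n <- min(n_patches(source_patches), n_patches(target_patches))
  ps <- discriminator_forward(d, embed_forward(g_s, ps_take(source_patches,
                                                            seq_len(n))))
  pt <- discriminator_forward(d, embed_forward(g_t, ps_take(target_patches,
                                                            seq_len(n))))
  mean(c(ps > 0.5, pt <= 0.5))
}

#' Build cross-domain sample pairs for contrastive alignment
#'
#' For each class present in the target shots, `pairs_per_class` source
#' samples of that class are drawn (without replacement where the pool
#' allows, otherwise with replacement and a warning).  Every target shot is
#' then paired positively with all drawn source samples of its class and
#' negatively with all drawn source samples of every other class.
#'
#' @param source labeled source `patch_set`.
#' @param target_shots labeled few-shot target `patch_set`.
#' @param pairs_per_class source samples drawn per class (default 400).
#' @param seed integer seed.
#' @return an object of class `pair_set`: `positives` and `negatives` are
#'   two-column (source index, target index) matrices into the given sets,
#'   `pools` the per-class drawn source indices.
#' @export
sample_pairs <- function(source, target_shots, pairs_per_class = 400L,
                         seed = 1L) {
  stopifnot(!is.null(source$labels), !is.null(target_shots$labels))
  set.seed(seed)
  tgt_classes <- sort(unique(target_shots$labels))
  miss <- setdiff(tgt_classes, unique(source$labels))
  if (length(miss)) {
    stop("class(es) present in target but absent in source: ",
         paste(source$class_names[miss + 1L], collapse = ", "),
         call. = FALSE)
  }
  pools <- list()
  for (k in tgt_classes) {
    pool <- which(source$labels == k)
    if (length(pool) < pairs_per_class) {
      warning(sprintf(
        "source pool for class %s has %d < %d samples; drawing with replacement",
        source$class_names[k + 1L], length(pool), pairs_per_class))
      pools[[as.character(k)]] <- sample(pool, pairs_per_class, replace = TRUE)
    } else {
      pools[[as.character(k)]] <- sample(pool, pairs_per_class)
    }
  }
  pos <- list(); neg <- list()
  for (j in seq_along(target_shots$labels)) {
    a <- target_shots$labels[j]
    for (k in tgt_classes) {
      drawn <- pools[[as.character(k)]]
      m <- cbind(drawn, rep.int(j, length(drawn)))
      if (k == a) pos[[length(pos) + 1L]] <- m
      else neg[[length(neg) + 1L]] <- m
    }
  }
  cm <- function(l) {
    if (length(l)) do.call(rbind, l) else matrix(integer(0), 0L, 2L)
  }
  structure(list(positives = unname(cm(pos)), negatives = unname(cm(neg)),
                 pools = pools,
                 n_source = n_patches(source),
                 n_target = n_patches(target_shots)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d positive / %d negative cross-domain pair(s)\n",
              nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

#' Few-shot joint contrastive semantic alignment
#'
#' Minimizes, by mini-batch Adam over shuffled pairs, the combined objective:
#' classification loss of the target classifier on the target shots, the
#' classification loss of the source classifier on the drawn source samples,
#' plus the semantic alignment loss over positive pairs and the class
#' separation loss over negative pairs (batch means of each term).
#' Gradients flow into both embeddings when `config$joint` is TRUE; the
#' target classifier is initialized from the source classifier.
#'
#' @param g_s,g_t source/target `embedding_params`.
#' @param c_s source `classifier_params`.
#' @param source labeled source `patch_set` (the sets the pairs were built
#'   from).
#' @param target_shots labeled few-shot target `patch_set`.
#' @param pairs a `pair_set` from [sample_pairs()].
#' @param config a `train_config`.
#' @return list with updated `G_s`, `G_t`, `C_s`, `C_t` and `history`
#'   (per-epoch classification, alignment and separation losses).
#' @export
adapt_conditional <- function(g_s, g_t, c_s, source, target_shots, pairs,
                              config = train_config()) {
  if (nrow(pairs$positives) + nrow(pairs$negatives) == 0L) {
    stop("empty pair set", call. = FALSE)
  }
  g_s <- own_params(g_s)
  g_t <- own_params(g_t)
  c_t <- own_params(c_s)
  c_s <- own_params(c_s)
  set.seed(config$seed + 5L)
  xs <- apply_norm(g_s, ps_matrix(source))
  xt <- apply_norm(g_s, ps_matrix(target_shots))
  ys <- source$labels
  yt <- target_shots$labels
  all_pairs <- rbind(cbind(pairs$positives, 1L), cbind(pairs$negatives, 0L))
  np <- nrow(all_pairs)
  bs <- min(config$batch_size, np)
  nb <- ceiling(np / bs)
  w <- config$loss_weights
  m <- config$margin
  sq <- config$squared_distance
  joint <- isTRUE(config$joint)
  st_gs <- adam_state(g_s[param_names(g_s)])
  st_gt <- adam_state(g_t[param_names(g_t)])
  st_cs <- adam_state(c_s[param_names(c_s)])
  st_ct <- adam_state(c_t[param_names(c_t)])
  ne <- max(0L, config$ccsa_epochs)
  hist <- matrix(0, ne, 5L,
                 dimnames = list(NULL, c("ce_source", "ce_target",
                                         "alignment", "separation", "total")))
  for (ep in seq_len(ne)) {
    ord <- epoch_index(np, nb, bs)
    acc <- numeric(5L)
    for (ib in seq_len(nb)) {
      pb <- all_pairs[ord[((ib - 1L) * bs + 1L):(ib * bs)], , drop = FALSE]
      is_ <- pb[, 1L]; it_ <- pb[, 2L]; is_pos <- pb[, 3L] == 1L
      nbp <- nrow(pb)
      fs <- embed_forward(g_s, xs[is_, , drop = FALSE], cache = joint,
                          normalized = TRUE)
      # the target side repeats the few shots heavily: embed unique rows
      # once and scatter, accumulating gradients back by group
      ut <- unique(it_)
      grp <- match(it_, ut)
      ft <- embed_forward(g_t, xt[ut, , drop = FALSE], cache = TRUE,
                          normalized = TRUE)
      es <- if (joint) fs$out else fs
      et <- ft$out[grp, , drop = FALSE]
      # classification terms
      fcs <- classifier_forward(c_s, es, cache = TRUE)
      fct <- classifier_forward(c_t, et, cache = TRUE)
      ysb <- ys[is_]; ytb <- yt[it_]
      ce_s <- classification_loss(fcs$prob, ysb)
      ce_t <- classification_loss(fct$prob, ytb)
      dls <- fcs$prob
      dls[cbind(seq_len(nbp), ysb + 1L)] <- dls[cbind(seq_len(nbp), ysb + 1L)] - 1
      dls <- dls * (w[1] / nbp)
      dlt <- fct$prob
      dlt[cbind(seq_len(nbp), ytb + 1L)] <- dlt[cbind(seq_len(nbp), ytb + 1L)] - 1
      dlt <- dlt * (w[1] / nbp)
      bks <- head_backward(c_s, fcs$cache, dls)
      bkt <- head_backward(c_t, fct$cache, dlt)
      des <- bks$de
      det <- bkt$de
      # contrastive terms on embedding difference
      diff <- es - et
      r <- sqrt(rowSums(diff^2))
      rsafe <- pmax(r, 1e-12)
      npos <- sum(is_pos); nneg <- nbp - npos
      sa <- 0; cs_l <- 0
      dd <- matrix(0, nbp, ncol(diff))
      if (npos) {
        rp <- r[is_pos]
        sa <- if (sq) mean(rp^2) / 2 else mean(rp) / 2
        coef <- if (sq) rep(1, npos) else 1 / (2 * rsafe[is_pos])
        dd[is_pos, ] <- diff[is_pos, , drop = FALSE] *
          (coef * w[2] / npos)
      }
      if (nneg) {
        rn <- r[!is_pos]
        gap <- pmax(0, m - rn)
        cs_l <- mean(gap^2) / 2
        dd[!is_pos, ] <- diff[!is_pos, , drop = FALSE] *
          (-(gap / rsafe[!is_pos]) * w[3] / nneg)
      }
      des <- des + dd
      det <- det - dd
      # updates
      det_u <- rowsum(det, grp, reorder = TRUE)
      gt_grads <- embed_backward(g_t, ft$cache, det_u)
      adam_update(g_t[param_names(g_t)], gt_grads, st_gt,
                  config$learning_rate)
      adam_update(c_t[param_names(c_t)], bkt$grads, st_ct,
                  config$learning_rate)
      if (joint) {
        gs_grads <- embed_backward(g_s, fs$cache, des)
        adam_update(g_s[param_names(g_s)], gs_grads, st_gs,
                    config$learning_rate)
        if (!config$freeze_source_classifier) {
          adam_update(c_s[param_names(c_s)], bks$grads, st_cs,
                      config$learning_rate)
        }
      }
      acc <- acc + c(ce_s, ce_t, sa, cs_l,
                     w[1] * (ce_s + ce_t) + w[2] * sa + w[3] * cs_l)
    }
    hist[ep, ] <- acc / nb
  }
  list(G_s = g_s, G_t = g_t, C_s = c_s, C_t = c_t,
       history = as.data.frame(cbind(epoch = seq_len(ne), hist)))
}

# Fine-tune baseline: continue supervised training of a copy of the source
# model on the target shots only.
finetune_model <- function(g, c_params, shots_ps, config) {
  g <- own_params(g)
  c_params <- own_params(c_params)
  cfg <- config
  cfg$source_epochs <- config$ccsa_epochs
  set.seed(config$seed + 6L)
  x <- apply_norm(g, ps_matrix(shots_ps))
  y <- shots_ps$labels
  n <- nrow(x)
  bs <- min(config$batch_size, n)
  nb <- ceiling(n / bs)
  st_g <- adam_state(g[param_names(g)])
  st_c <- adam_state(c_params[param_names(c_params)])
  for (ep in seq_len(max(0L, cfg$source_epochs))) {
    idx <- epoch_index(n, nb, bs)
    for (ib in seq_len(nb)) {
      take <- idx[((ib - 1L) * bs + 1L):(ib * bs)]
      fe <- embed_forward(g, x[take, , drop = FALSE], cache = TRUE,
                          normalized = TRUE)
      fc <- classifier_forward(c_params, fe$out, cache = TRUE)
      dl <- fc$prob
      dl[cbind(seq_along(take), y[take] + 1L)] <-
        dl[cbind(seq_along(take), y[take] + 1L)] - 1
      dl <- dl / length(take)
      bk <- head_backward(c_params, fc$cache, dl)
      ge <- embed_backward(g, fe$cache, bk$de)
      adam_update(c_params[param_names(c_params)], bk$grads, st_c,
                  config$learning_rate)
      adam_update(g[param_names(g)], ge, st_g, config$learning_rate)
    }
  }
  list(G = g, C = c_params)
}

# Draw n labeled target samples per class, seeded.  Errors naming the class
# when a class cannot supply n samples.
select_shots <- function(target_pool, n, seed) {
  stopifnot(!is.null(target_pool$labels))
  set.seed(seed)
  idx <- integer(0)
  for (k in sort(unique(target_pool$labels))) {
    avail <- which(target_pool$labels == k)
    if (length(avail) < n) {
      stop(sprintf("class %s has only %d labeled target sample(s), need %d",
                   target_pool$class_names[k + 1L], length(avail), n),
           call. = FALSE)
    }
    idx <- c(idx, sample(avail, n))
  }
  sort(idx)
}

ADAPT_METHODS <- c("source-only", "adda", "finetune", "ccsa", "proposed")

#' Run the adaptation protocol on prepared patch sets
#'
#' Executes the requested model variants from a single configuration,
#' sharing prerequisite stages (the trained source model; the adversarial
#' step between "adda" and "proposed").  Exactly `shots` labeled target
#' samples per class are drawn from `target_pool` and those are the only
#' target labels any adaptation stage sees; `target_test` is used solely for
#' evaluation.
#'
#' @param source_train labeled source `patch_set`.
#' @param target_pool labeled target `patch_set` the shots are drawn from.
#' @param target_test labeled target `patch_set` for evaluation.
#' @param config a `train_config`.
#' @param methods subset of "source-only", "adda", "finetune", "ccsa",
#'   "proposed".
#' @param shots labeled target samples per class (defaults to
#'   `config$shots`).
#' @return an object of class `seadapt_fit`.
#' @export
run_adaptation <- function(source_train, target_pool, target_test = NULL,
                           config = train_config(),
                           methods = "proposed", shots = config$shots) {
  methods <- match.arg(methods, ADAPT_METHODS, several.ok = TRUE)
  nc <- length(source_train$class_names)
  src <- train_source(source_train, config)
  g_s0 <- src$G; c_s0 <- src$C
  histories <- list(source = src$history)
  shot_idx <- NULL; shots_ps <- NULL; adv <- NULL
  need_shots <- any(methods %in% c("finetune", "ccsa", "proposed"))
  need_adv <- any(methods %in% c("adda", "proposed"))
  if (need_shots) {
    shot_idx <- select_shots(target_pool, shots, config$seed + 7L)
    shots_ps <- ps_take(target_pool, shot_idx)
  }
  if (need_adv) {
    adv <- adapt_marginal(g_s0, strip_labels(source_train),
                          strip_labels(target_pool), config)
    histories$adversarial <- adv$history
  }
  models <- list()
  for (mth in methods) {
    models[[mth]] <- switch(mth,
      "source-only" = list(G = g_s0, C = c_s0),
      "adda" = list(G = adv$G_t, C = c_s0),
      "finetune" = finetune_model(g_s0, c_s0, shots_ps, config),
      "ccsa" = ,
      "proposed" = {
        g_init <- if (mth == "proposed") adv$G_t else g_s0
        pairs <- sample_pairs(source_train, shots_ps,
                              pairs_per_class = config$pairs_per_class,
                              seed = config$seed + 8L)
        res <- adapt_conditional(g_s0, g_init, c_s0, source_train, shots_ps,
                                 pairs, config)
        histories[[paste0("ccsa_", mth)]] <- res$history
        list(G = res$G_t, C = res$C_t, G_s = res$G_s, C_s = res$C_s)
      })
  }
  results <- data.frame(method = character(0), shots = integer(0),
                        accuracy = numeric(0))
  predictions <- list()
  if (!is.null(target_test) && n_patches(target_test) > 0L) {
    for (mth in methods) {
      pr <- predict_labels(models[[mth]]$G, models[[mth]]$C, target_test)
      predictions[[mth]] <- pr$labels
      results <- rbind(results, data.frame(
        method = mth,
        shots = if (mth %in% c("source-only", "adda")) NA_integer_ else shots,
        accuracy = mean(pr$labels == target_test$labels)))
    }
  }
  suite <- if ("proposed" %in% methods) {
    model_suite(models$proposed$G_s, models$proposed$G,
                models$proposed$C_s, models$proposed$C,
                d = adv$D)
  } else {
    model_suite(g_s0, if (!is.null(adv)) adv$G_t else g_s0, c_s0,
                if ("ccsa" %in% methods) models$ccsa$C else c_s0,
                d = if (!is.null(adv)) adv$D else NULL)
  }
  structure(list(suite = suite, models = models, results = results,
                 predictions = predictions, histories = histories,
                 config = config, shots = shots, shot_indices = shot_idx,
                 class_names = source_train$class_names,
                 source_model = list(G = g_s0, C = c_s0),
                 train_accuracy = src$train_accuracy),
            class = "seadapt_fit")
}

strip_labels <- function(ps) {
  patch_set(ps$patches, labels = NULL, centers = ps$centers,
            class_names = ps$class_names)
}

#' Fit the full two-step domain adaptation from scenes
#'
#' End-to-end entry point: extracts labeled patches from the source and
#' target scenes, splits the target labels into a few-shot pool and a
#' held-out evaluation set, then runs supervised source training,
#' adversarial marginal alignment, seeded shot selection and pairing, and
#' joint contrastive semantic alignment.  Baseline variants (source-only,
#' ADDA-only, fine-tuning, CCSA-only) can be requested alongside.
#'
#' @param source_scene,source_mask source `msscene` + `label_mask`.
#' @param target_scene,target_mask target `msscene` + `label_mask`.
#' @param shots labeled target samples per class.
#' @param config a `train_config`.
#' @param methods model variants to fit (see [run_adaptation()]).
#' @param patch_size patch window side.
#' @param test_fraction fraction of labeled target pixels held out for
#'   evaluation.
#' @return an object of class `seadapt_fit`; see [run_adaptation()].
#' @export
run_two_step <- function(source_scene, source_mask, target_scene, target_mask,
                         shots = config$shots, config = train_config(),
                         methods = "proposed", patch_size = 5L,
                         test_fraction = 1 / 3) {
  src <- extract_patches(source_scene, source_mask, patch_size, TRUE)
  tgt <- extract_patches(target_scene, target_mask, patch_size, TRUE)
  set.seed(config$seed + 9L)
  nt <- n_patches(tgt)
  test_idx <- sort(sample.int(nt, round(test_fraction * nt)))
  pool_idx <- setdiff(seq_len(nt), test_idx)
  cfg <- config; cfg$shots <- as.integer(shots)
  fit <- run_adaptation(src, ps_take(tgt, pool_idx), ps_take(tgt, test_idx),
                        cfg, methods = methods, shots = shots)
  fit$patch_size <- patch_size
  fit
}
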