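test_that("training configuration validates its fields", {
  cfg <- train_config()
  expect_identical(cfg$source_epochs, 50L)
  expect_identical(cfg$batch_size, 128L)
  expect_identical(cfg$adversarial_epochs, 300L)
  expect_identical(cfg$ccsa_epochs, 240L)
  expect_equal(cfg$learning_rate, 2e-4)
  expect_identical(cfg$pairs_per_class, 400L)
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(margin = -1), "margin")
  expect_error(train_config(shots = 0))
})

test_that("pair sampling follows the combinatorial pairing rule", {
  src <- toy_patches(450, 5, b = 2, seed = 2)
  tgt <- toy_patches(1, 5, b = 2, seed = 3)     # 1-shot
  pairs <- sample_pairs(src, tgt, pairs_per_class = 400, seed = 4)
  expect_identical(nrow(pairs$positives), 5L * 400L)
  expect_identical(nrow(pairs$negatives), 5L * 4L * 400L)
  # label relation holds for every listed pair
  expect_true(all(src$labels[pairs$positives[, 1]] ==
                    tgt$labels[pairs$positives[, 2]]))
  expect_true(all(src$labels[pairs$negatives[, 1]] !=
                    tgt$labels[pairs$negatives[, 2]]))
  # every shot appears in at least one positive and one negative pair
  expect_setequal(unique(pairs$positives[, 2]), 1:5)
  expect_setequal(unique(pairs$negatives[, 2]), 1:5)
  # determinism
  pairs2 <- sample_pairs(src, tgt, pairs_per_class = 400, seed = 4)
  expect_identical(pairs, pairs2)

  # tiny exhaustive case: 2 classes, single-sample pools, 1 pair per class
  s2 <- toy_patches(1, 2, b = 2)
  t2 <- toy_patches(1, 2, b = 2, seed = 9)
  tiny <- sample_pairs(s2, t2, pairs_per_class = 1, seed = 1)
  expect_identical(nrow(tiny$positives), 2L)
  expect_identical(nrow(tiny$negatives), 2L)

  # undersized pools draw with replacement, with a warning per class
  w <- capture_warnings(sample_pairs(s2, t2, pairs_per_class = 3, seed = 1))
  expect_true(all(grepl("replacement", w)))
  expect_length(w, 2)
  # class present in target but missing in source
  t3 <- toy_patches(1, 3, b = 2)
  expect_error(sample_pairs(s2, t3, pairs_per_class = 1, seed = 1),
               "absent in source")
})

test_that("source training learns separable classes and is deterministic", {
  ps <- toy_patches(120, 5, b = 4, seed = 7)
  cfg <- train_config(source_epochs = 50L, batch_size = 64L, seed = 7L)
  fit <- train_source(ps, cfg)
  expect_gte(fit$train_accuracy, 0.99)
  expect_identical(nrow(fit$history), 50L)
  fit2 <- train_source(ps, cfg)
  expect_identical(fit$G$W2, fit2$G$W2)
  expect_identical(fit$C$Wo, fit2$C$Wo)

  # degenerate constant input: loss can do no better than the class prior
  const <- patch_set(array(0.5, c(100, 5, 5, 2)),
                     labels = rep(0:4, 20), centers = matrix(1L, 100, 2),
                     class_names = paste0("c", 1:5))
  dfit <- train_source(const, train_config(source_epochs = 8L, seed = 1L))
  expect_equal(tail(dfit$history$loss, 1), log(5), tolerance = 0.02)

  missing <- ps_take(ps, which(ps$labels != 2L))
  expect_error(train_source(missing, cfg), "class3")
})

test_that("the adversarial step freezes the source embedding", {
  ps <- toy_patches(80, 3, b = 2, seed = 5)
  cfg <- quick_config(seed = 5L)
  src <- train_source(ps, cfg)
  g_before <- src$G
  tgt <- toy_patches(80, 3, b = 2, seed = 6)
  adv <- adapt_marginal(src$G, ps, tgt, cfg)
  # bit-identical source parameters
  expect_identical(src$G$W1, g_before$W1)
  expect_identical(src$G$W2, g_before$W2)
  expect_identical(nrow(adv$history), cfg$adversarial_epochs)
  # zero epochs: the target embedding is an exact copy
  cfg0 <- quick_config(seed = 5L)
  cfg0$adversarial_epochs <- 0L
  adv0 <- adapt_marginal(src$G, ps, tgt, cfg0)
  expect_identical(adv0$G_t$W1, src$G$W1)
  expect_identical(adv0$G_t$W2, src$G$W2)
  expect_error(adapt_marginal(src$G, ps,
                              patch_set(array(numeric(0), c(0, 5, 5, 2)),
                                        class_names = paste0("c", 1:3)),
                              cfg), "non-empty")
})

test_that("adversarial alignment loosens the discriminator's grip on shifted domains", {
  # On a gain-shifted pair, a discriminator trained against a frozen target
  # embedding separates the domains; after adversarial adaptation of G_t a
  # discriminator trained under the same budget separates them less.
  suite <- benchmark_suite(7L, scene_size = c(96L, 96L))
  bd <- benchmark_data(suite$mild, n_train_per_class = 400L,
                       n_test_per_class = 150L)
  cfg <- train_config(source_epochs = 8L, adversarial_epochs = 20L,
                      seed = 7L)
  src <- train_source(bd$source_train, cfg)
  # discriminator against the frozen embedding (G_t = G_s throughout)
  d <- build_discriminator(embed_dim(src$G), seed = 100L)
  set.seed(101)
  xs <- seadapt:::apply_norm(src$G, seadapt:::ps_matrix(bd$source_train))
  xt <- seadapt:::apply_norm(src$G, seadapt:::ps_matrix(bd$target_pool))
  st <- seadapt:::adam_state(d[seadapt:::param_names(d)])
  for (it in 1:400) {
    is_ <- sample(nrow(xs), 128)
    it_ <- sample(nrow(xt), 128)
    es <- seadapt:::embed_forward(src$G, xs[is_, ], normalized = TRUE)
    et <- seadapt:::embed_forward(src$G, xt[it_, ], normalized = TRUE)
    fd <- seadapt:::discriminator_forward(d, rbind(es, et), cache = TRUE)
    dl <- matrix((fd$prob - rep(c(1, 0), each = 128)) / 128, ncol = 1)
    bk <- seadapt:::head_backward(d, fd$cache, dl)
    seadapt:::adam_update(d[seadapt:::param_names(d)], bk$grads, st,
                          2e-4, beta1 = 0.5)
  }
  frozen_acc <- discriminator_accuracy(d, src$G, src$G,
                                       bd$source_test, bd$target_test)
  adv <- adapt_marginal(src$G, bd$source_train, bd$target_pool, cfg)
  adapted_acc <- discriminator_accuracy(adv$D, src$G, adv$G_t,
                                        bd$source_test, bd$target_test)
  expect_lt(adapted_acc, frozen_acc)
})

test_that("joint contrastive alignment obeys its gradient-flow contract", {
  src_ps <- toy_patches(60, 3, b = 2, seed = 11)
  cfg <- quick_config(seed = 11L, shots = 2L)
  src <- train_source(src_ps, cfg)
  shots <- ps_take(toy_patches(2, 3, b = 2, seed = 12), 1:6)
  pairs <- sample_pairs(src_ps, shots, pairs_per_class = 10, seed = 13)
  res <- adapt_conditional(src$G, src$G, src$C, src_ps, shots, pairs, cfg)
  # joint = TRUE moves the source embedding
  expect_false(identical(res$G_s$W2, src$G$W2))
  # default keeps the source classifier frozen
  expect_identical(res$C_s$Wo, src$C$Wo)
  # the target classifier starts from C_s but trains
  expect_false(identical(res$C_t$Wo, src$C$Wo))
  expect_identical(nrow(res$history), cfg$ccsa_epochs)

  cfg_nj <- cfg; cfg_nj$joint <- FALSE
  res_nj <- adapt_conditional(src$G, src$G, src$C, src_ps, shots, pairs,
                              cfg_nj)
  expect_identical(res_nj$G_s$W2, src$G$W2)

  cfg_cs <- cfg; cfg_cs$freeze_source_classifier <- FALSE
  res_cs <- adapt_conditional(src$G, src$G, src$C, src_ps, shots, pairs,
                              cfg_cs)
  expect_false(identical(res_cs$C_s$Wo, src$C$Wo))

  empty <- pairs; empty$positives <- empty$positives[0, , drop = FALSE]
  empty$negatives <- empty$negatives[0, , drop = FALSE]
  expect_error(adapt_conditional(src$G, src$G, src$C, src_ps, shots, empty,
                                 cfg), "empty pair set")
})

test_that("alignment loss decreases on matched domains", {
  src_ps <- toy_patches(80, 3, b = 2, seed = 15)
  tgt_ps <- toy_patches(4, 3, b = 2, seed = 16)   # same distribution, 4-shot
  cfg <- train_config(source_epochs = 8L, ccsa_epochs = 10L,
                      pairs_per_class = 30L, seed = 15L, shots = 4L)
  src <- train_source(src_ps, cfg)
  pairs <- sample_pairs(src_ps, tgt_ps, pairs_per_class = 30, seed = 17)
  res <- adapt_conditional(src$G, src$G, src$C, src_ps, tgt_ps, pairs, cfg)
  sa <- res$history$alignment
  early <- mean(sa[1:3])
  late <- mean(sa[(length(sa) - 2):length(sa)])
  expect_lt(late, early)
})

test_that("exactly n labeled target samples per class are touched", {
  src_ps <- toy_patches(60, 3, b = 2, seed = 18)
  pool <- toy_patches(40, 3, b = 2, seed = 19)
  log <- new.env(); log$idx <- integer(0)
  attr(pool, "access_log") <- log
  cfg <- quick_config(seed = 18L, shots = 2L)
  fit <- run_adaptation(src_ps, pool, target_test = NULL, config = cfg,
                        methods = c("ccsa", "proposed", "finetune"),
                        shots = 2L)
  touched <- sort(unique(log$idx))
  expect_identical(touched, fit$shot_indices)
  expect_identical(length(fit$shot_indices), 2L * 3L)
  expect_identical(as.integer(table(pool$labels[fit$shot_indices])),
                   rep(2L, 3L))
  expect_error(run_adaptation(src_ps, pool, NULL, cfg, methods = "ccsa",
                              shots = 100L), "only")
})

test_that("the scenario lattice runs end-to-end, deterministically", {
  cfg <- quick_config(seed = 23L, shots = 1L)
  suite <- benchmark_suite(23L, scene_size = c(48L, 48L))
  cfgS <- suite$mild; cfgS$blob_scale <- 6
  bd <- benchmark_data(cfgS, n_train_per_class = 100L,
                       n_test_per_class = 60L)
  fit <- run_adaptation(bd$source_train, bd$target_pool, bd$target_test,
                        cfg, methods = c("source-only", "adda", "finetune",
                                         "ccsa", "proposed"))
  expect_setequal(fit$results$method,
                  c("source-only", "adda", "finetune", "ccsa", "proposed"))
  expect_true(all(fit$results$accuracy >= 0 & fit$results$accuracy <= 1))
  fit2 <- run_adaptation(bd$source_train, bd$target_pool, bd$target_test,
                         cfg, methods = c("source-only", "adda", "finetune",
                                          "ccsa", "proposed"))
  expect_identical(fit$results, fit2$results)
  expect_output(print(fit), "target-domain accuracy")
  expect_output(print(summary(fit)), "stage epochs")
})

test_that("scene-level fits predict on new scenes and patch sets", {
  suite <- benchmark_suite(31L, scene_size = c(64L, 64L))
  cfgS <- suite$none; cfgS$blob_scale <- 6
  pair <- generate_scene_pair(cfgS)
  cfg <- quick_config(seed = 31L)
  fit <- run_two_step(pair$source$scene, pair$source$mask,
                      pair$target$scene, pair$target$mask,
                      shots = 1L, config = cfg, methods = "proposed")
  expect_s3_class(fit, "seadapt_fit")
  mask <- predict(fit, pair$target$scene)
  expect_s3_class(mask, "label_mask")
  expect_true(all(mask$labels[3:62, 3:62] >= 1L))
  ps <- extract_patches(pair$target$scene, pair$target$mask,
                        labeled_only = TRUE)
  pr <- predict(fit, ps_take(ps, 1:10), model = "source")
  expect_identical(length(pr$labels), 10L)
})
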