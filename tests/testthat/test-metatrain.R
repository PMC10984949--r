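test_that("rank-based AUC matches closed cases and brute-force counting", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L)), 1.0)
  expect_equal(auc_score(rep(0.5, 6), c(1L, 0L, 1L, 0L, 1L, 0L)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.1), c(1L, 1L, 0L, 0L)), 0.75)
  expect_warning(a <- auc_score(c(0.4, 0.6), c(1L, 1L)), "one class")
  expect_true(is.na(a))

  set.seed(123)
  for (rep in 1:100) {
    n <- sample(4:25, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    expect_identical(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(40)
  labels <- sample(c(0L, 1L), 40, replace = TRUE)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("ablation variants wire the loss switches as documented", {
  full <- ablation_variant("full")
  wc <- ablation_variant("wc")
  wd <- ablation_variant("wd")
  expect_true(full$dynamic_enabled && full$contrastive_enabled)
  expect_false(wc$contrastive_enabled)
  expect_true(wd$contrastive_enabled && !wd$dynamic_enabled)
  expect_error(ablation_variant("nope"))

  # "wd": the selection fraction is forced to 1, so the contrastive value is
  # independent of the training clock
  set.seed(2)
  emb <- matrix(rnorm(12), 6, 2)
  labels <- c(1L, 0L, 1L, 0L, 1L, 0L)
  v_early <- molfewshot:::contrastive_pass(emb, labels, wd,
                                           hard_fraction(0L, wd)$fraction)
  v_late <- molfewshot:::contrastive_pass(emb, labels, wd,
                                          hard_fraction(500L, wd)$fraction)
  expect_identical(v_early$value, v_late$value)
  # "full": late-clock selection drops distant negative pairs
  v_full_late <- molfewshot:::contrastive_pass(
    emb, labels, full, hard_fraction(500L, full)$fraction)
  expect_lt(v_full_late$battery$hard_pair_count,
            v_full_late$battery$negative_pair_count)
})

# one small family and config shared by the training-loop tests
.toy_setup <- function() {
  fam <- dev_family()
  enc <- encoder_config(n_layers = 2L, hidden_dim = 8L)
  list(fam = fam, enc = enc,
       params = init_encoder_params(enc, 1),
       stream = episode_stream(fam$table, fam$split, "meta_train",
                               k_shot = 3, seed = 2, n_episodes = 50,
                               query_size = 16L))
}

test_that("plain episodic supervised training reduces the query loss", {
  s <- .toy_setup()
  lc <- loss_config(weight_w = 0)
  mc <- meta_config(inner_steps = 0L, meta_train_iterations = 50L)
  clock <- training_clock()
  fit <- meta_train(s$params, s$stream, lc, mc, clock, s$enc)
  expect_equal(clock$t, 50L)
  expect_equal(fit$metrics$step, 1:50)
  first <- mean(fit$metrics$loss_supervised[1:10])
  last <- mean(fit$metrics$loss_supervised[41:50])
  expect_lt(last, first)
  # w = 0: combined equals supervised exactly
  expect_equal(fit$metrics$loss_total, fit$metrics$loss_supervised)
})

test_that("the clock drives the logged schedule and training is
          deterministic under a fixed seed", {
  s <- .toy_setup()
  lc <- loss_config(weight_w = 1e-5)
  mc <- meta_config(meta_train_iterations = 10L)
  fit1 <- meta_train(s$params, s$stream, lc, mc, training_clock(), s$enc)
  fit2 <- meta_train(s$params, s$stream, lc, mc, training_clock(), s$enc)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$metrics, fit2$metrics)
  # logged f values follow the closed form at the pre-update clock
  expect_equal(fit1$metrics$f_raw,
               vapply(0:9, function(t) hard_fraction(t, lc)$raw, numeric(1)))
  expect_true(all(fit1$metrics$f_clipped <= 1))
  expect_true(all(fit1$metrics$hard_pairs <= fit1$metrics$negative_pairs))

  # a short stream is rejected up front
  expect_error(meta_train(s$params, s$stream[1:3], lc,
                          meta_config(meta_train_iterations = 10L),
                          training_clock(), s$enc), "3 episodes; 10 required")
})

test_that("meta_test never mutates the base parameters and is reproducible", {
  s <- .toy_setup()
  lc <- loss_config(weight_w = 1e-5)
  mc <- meta_config(meta_train_iterations = 15L, runs = 2L,
                    finetune_steps_at_test = 5L)
  fit <- meta_train(s$params, s$stream, lc, mc, training_clock(), s$enc)
  before <- fit$params
  rep1 <- meta_test(fit$params, s$fam$table, s$fam$split, 3L, lc, mc, s$enc,
                    fit$state, seed = 9)
  expect_identical(fit$params, before)
  expect_s3_class(rep1, "eval_report")
  expect_named(rep1$per_task_auc, s$fam$split$test_tasks)
  expect_true(all(vapply(rep1$per_task_auc, length, integer(1)) == 2L))
  aucs <- unlist(rep1$per_task_auc)
  expect_true(all(aucs >= 0 & aucs <= 1, na.rm = TRUE))
  expect_equal(rep1$mean_auc, mean(aucs, na.rm = TRUE))

  rep2 <- meta_test(fit$params, s$fam$table, s$fam$split, 3L, lc, mc, s$enc,
                    fit$state, seed = 9)
  expect_identical(rep1$per_task_auc, rep2$per_task_auc)
  rep3 <- meta_test(fit$params, s$fam$table, s$fam$split, 3L, lc, mc, s$enc,
                    fit$state, seed = 10)
  expect_false(identical(rep1$per_task_auc, rep3$per_task_auc))
})

test_that("metrics can be streamed as JSON lines", {
  s <- .toy_setup()
  path <- withr::local_tempfile(fileext = ".jsonl")
  mc <- meta_config(meta_train_iterations = 5L)
  meta_train(s$params, s$stream, loss_config(weight_w = 0), mc,
             training_clock(), s$enc, metrics_path = path)
  lines <- readLines(path)
  expect_length(lines, 5L)
  row <- jsonlite::fromJSON(lines[3])
  expect_equal(row$step, 3L)
  expect_true(all(c("loss_total", "loss_supervised", "loss_contrastive",
                    "f_raw", "f_clipped") %in% names(row)))
})
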