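# Episodic meta-training and meta-test evaluation.
#
# Outer loop: for each step, sample a batch of episodes; per episode, clone
# the parameters, adapt them on the support set with a few plain gradient
# steps on the combined loss, then compute the query-set combined loss under
# the adapted parameters. The averaged query gradient (first-order
# approximation: taken with respect to the adapted parameters) drives an
# adaptive-moment (Adam) outer update. The training clock counts completed
# outer steps and drives the hard-negative fraction.
#
# During meta-training the contrastive pairs are taken over the union of
# support and query embeddings (both are labelled in that phase); at
# meta-test time adaptation uses the support set only — query labels are
# never touched before scoring.

#' Meta-learning configuration
#'
#' @param inner_steps Support-set adaptation steps per episode during
#'   meta-training (0 disables inner adaptation).
#' @param inner_lr Learning rate of the plain-gradient inner/fine-tuning
#'   steps.
#' @param outer_lr Learning rate of the Adam outer update (the tuning grid of
#'   interest is 0.001 / 0.0001 / 0.00005).
#' @param meta_batch_tasks Episodes averaged per outer step.
#' @param meta_train_iterations Number of outer steps.
#' @param first_order If `TRUE` (default), first-order inner/outer
#'   adaptation; if `FALSE`, inner adaptation is skipped during meta-training
#'   and adaptation happens only at test time (plain fine-tuning).
#' @param runs Number of seeded evaluation runs in [meta_test()].
#' @param finetune_steps_at_test Fine-tuning steps on the support set at
#'   meta-test time.
#' @param grad_clip Global-norm gradient clipping threshold (`Inf` disables).
#' @return A validated `meta_config`.
#' @export
meta_config <- function(inner_steps = 1L, inner_lr = 0.01, outer_lr = 0.001,
                        meta_batch_tasks = 1L, meta_train_iterations = 300L,
                        first_order = TRUE, runs = 10L,
                        finetune_steps_at_test = 20L, grad_clip = 5) {
  stopifnot(inner_steps >= 0L, inner_lr > 0, outer_lr > 0,
            meta_batch_tasks >= 1L, meta_train_iterations >= 1L,
            runs >= 1L, finetune_steps_at_test >= 1L, grad_clip > 0)
  structure(list(inner_steps = as.integer(inner_steps), inner_lr = inner_lr,
                 outer_lr = outer_lr,
                 meta_batch_tasks = as.integer(meta_batch_tasks),
                 meta_train_iterations = as.integer(meta_train_iterations),
                 first_order = isTRUE(first_order), runs = as.integer(runs),
                 finetune_steps_at_test = as.integer(finetune_steps_at_test),
                 grad_clip = grad_clip),
            class = "meta_config")
}

# ---- parameter-list arithmetic ---------------------------------------------

params_axpy <- function(params, grads, alpha) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] + alpha * grads[[nm]]
  params
}

grads_zero_like <- function(params) lapply(params, function(p) p * 0)

grads_accumulate <- function(acc, grads) {
  for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
  acc
}

grads_scale <- function(grads, s) lapply(grads, function(g) g * s)

grads_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

grads_clip <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- grads_global_norm(grads)
  if (nrm > max_norm) grads <- grads_scale(grads, max_norm / nrm)
  grads
}

adam_init <- function(params) {
  list(m = grads_zero_like(params), v = grads_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- one combined-loss forward/backward pass -------------------------------

# graphs/labels: the full batch entering the encoder; ce_idx: rows on which
# the supervised term is computed (the contrastive term always uses all rows)
combined_loss_pass <- function(enc_cfg, params, state, graphs, labels, ce_idx,
                               loss_cfg, fraction, training = TRUE) {
  fw <- encoder_forward(enc_cfg, params, state, pack_graphs(graphs),
                        training = training)
  sup <- supervised_loss(fw$logits[ce_idx, , drop = FALSE], labels[ce_idx])
  d_logits <- matrix(0, nrow(fw$logits), 2)
  d_logits[ce_idx, ] <- supervised_loss_grad(fw$logits[ce_idx, , drop = FALSE],
                                             labels[ce_idx])
  contra <- 0
  n_neg <- NA_integer_; n_hard <- NA_integer_
  d_emb <- matrix(0, nrow(fw$embeddings), ncol(fw$embeddings))
  if (loss_cfg$contrastive_enabled && length(labels) >= 2L) {
    cp <- contrastive_pass(fw$embeddings, labels, loss_cfg, fraction)
    contra <- cp$value
    d_emb <- loss_cfg$weight_w * cp$grad
    n_neg <- cp$battery$negative_pair_count
    n_hard <- cp$battery$hard_pair_count
  }
  total <- combined_loss(sup, contra, loss_cfg)
  grads <- encoder_backward(enc_cfg, params, fw$cache, d_emb, d_logits)
  list(total = total, supervised = sup, contrastive = contra, grads = grads,
       state = fw$state, negative_pairs = n_neg, hard_pairs = n_hard)
}

# fine-tune a parameter clone on a support set with plain gradient steps
finetune_on_support <- function(enc_cfg, params, state, support, loss_cfg,
                                fraction, steps, lr, grad_clip) {
  idx <- seq_along(support$labels)
  for (s in seq_len(steps)) {
    pass <- combined_loss_pass(enc_cfg, params, state, support$graphs,
                               support$labels, idx, loss_cfg, fraction,
                               training = TRUE)
    if (!is.finite(pass$total)) {
      stop(sprintf("non-finite support loss at fine-tuning step %d", s))
    }
    params <- params_axpy(params, grads_clip(pass$grads, grad_clip), -lr)
    state <- pass$state
  }
  list(params = params, state = state)
}

#' Episodic meta-training
#'
#' Runs the outer optimization loop described above. Aborts with a
#' diagnostic (step, task, component losses) if any loss goes non-finite.
#'
#' @param encoder_params Initial parameter list.
#' @param stream List of episodes from [episode_stream()]; must contain at
#'   least `meta_train_iterations * meta_batch_tasks` episodes.
#' @param loss_cfg A [loss_config()].
#' @param meta_cfg A [meta_config()].
#' @param clock A [training_clock()]; advanced once per outer step.
#' @param enc_cfg The [encoder_config()] the parameters belong to.
#' @param state Batch-norm state (fresh if `NULL`).
#' @param metrics_path Optional path; one JSON line is appended per outer
#'   step (step, component losses, raw and clipped f(t), pair counts).
#' @return List with `params`, `state` and `metrics` (one data-frame row per
#'   outer step).
#' @export
meta_train <- function(encoder_params, stream, loss_cfg, meta_cfg, clock,
                       enc_cfg, state = NULL, metrics_path = NULL) {
  stopifnot(inherits(loss_cfg, "loss_config"), inherits(meta_cfg, "meta_config"),
            inherits(clock, "training_clock"))
  need <- meta_cfg$meta_train_iterations * meta_cfg$meta_batch_tasks
  if (length(stream) < need) {
    stop(sprintf("episode stream has %d episodes; %d required", length(stream),
                 need))
  }
  if (is.null(state)) state <- init_encoder_state(enc_cfg)
  params <- encoder_params
  opt <- adam_init(params)
  inner_steps <- if (meta_cfg$first_order) meta_cfg$inner_steps else 0L
  ptr <- 1L
  metrics <- vector("list", meta_cfg$meta_train_iterations)
  con <- if (!is.null(metrics_path)) file(metrics_path, "w") else NULL
  on.exit(if (!is.null(con)) close(con))

  for (step in seq_len(meta_cfg$meta_train_iterations)) {
    sched <- hard_fraction(clock, loss_cfg)
    acc <- grads_zero_like(params)
    sup_sum <- 0; contra_sum <- 0; total_sum <- 0
    n_neg <- 0L; n_hard <- 0L
    for (b in seq_len(meta_cfg$meta_batch_tasks)) {
      ep <- stream[[ptr]]; ptr <- ptr + 1L
      theta <- params
      if (inner_steps > 0L) {
        ft <- finetune_on_support(enc_cfg, theta, state, ep$support, loss_cfg,
                                  sched$fraction, inner_steps,
                                  meta_cfg$inner_lr, meta_cfg$grad_clip)
        theta <- ft$params; state <- ft$state
      }
      graphs <- c(ep$support$graphs, ep$query$graphs)
      labels <- c(ep$support$labels, ep$query$labels)
      ce_idx <- length(ep$support$labels) + seq_along(ep$query$labels)
      pass <- combined_loss_pass(enc_cfg, theta, state, graphs, labels, ce_idx,
                                 loss_cfg, sched$fraction, training = TRUE)
      if (!is.finite(pass$total)) {
        stop(sprintf(
          "non-finite loss at outer step %d (task '%s'): supervised=%g contrastive=%g",
          step, ep$task_name, pass$supervised, pass$contrastive))
      }
      state <- pass$state
      acc <- grads_accumulate(acc, pass$grads)
      sup_sum <- sup_sum + pass$supervised
      contra_sum <- contra_sum + pass$contrastive
      total_sum <- total_sum + pass$total
      if (!is.na(pass$negative_pairs)) {
        n_neg <- n_neg + pass$negative_pairs
        n_hard <- n_hard + pass$hard_pairs
      }
    }
    acc <- grads_clip(grads_scale(acc, 1 / meta_cfg$meta_batch_tasks),
                      meta_cfg$grad_clip)
    upd <- adam_step(params, acc, opt, meta_cfg$outer_lr)
    params <- upd$params; opt <- upd$opt
    clock_tick(clock)
    row <- list(step = clock$t,
                loss_total = total_sum / meta_cfg$meta_batch_tasks,
                loss_supervised = sup_sum / meta_cfg$meta_batch_tasks,
                loss_contrastive = contra_sum / meta_cfg$meta_batch_tasks,
                f_raw = sched$raw, f_clipped = sched$fraction,
                negative_pairs = n_neg, hard_pairs = n_hard)
    metrics[[step]] <- row
    if (!is.null(con)) {
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  list(params = params, state = state,
       metrics = do.call(rbind, lapply(metrics, as.data.frame)))
}

#' Rank-based ROC AUC with half-credit ties
#'
#' Mann-Whitney formulation: the probability that a random positive is scored
#' above a random negative, ties counting one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Integer 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class is
#'   present.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warning("auc_score(): only one class present; AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Meta-test evaluation over repeated seeded runs
#'
#' For each run (distinct derived seed) and each test task: sample a support
#' set, fine-tune a clone of the parameters on it, score the query set in
#' evaluation mode and compute the AUC from the predicted positive-class
#' probability. The base parameters are never mutated. Query sets containing
#' a single class yield a missing AUC (with a warning) and are excluded from
#' aggregation rather than imputed.
#'
#' @param encoder_params Trained parameter list (left untouched).
#' @param table A [task_table()].
#' @param split A [task_split()] with non-empty `test_tasks`.
#' @param k_shot Support molecules per class.
#' @param loss_cfg A [loss_config()]; at test time the hard-negative fraction
#'   is the schedule's terminal value (clipped `alpha_end`).
#' @param meta_cfg A [meta_config()] (`runs`, `finetune_steps_at_test`,
#'   `inner_lr`, `grad_clip` are used).
#' @param enc_cfg The [encoder_config()].
#' @param state Batch-norm state accompanying the parameters.
#' @param seed Base seed; run r uses a seed derived from `(seed, r, task)`.
#' @return An `eval_report`: list with `per_task_auc` (task -> one AUC per
#'   run), `mean_auc` and `std_auc` over all (task, run) AUCs, and `runs`.
#' @export
meta_test <- function(encoder_params, table, split, k_shot, loss_cfg, meta_cfg,
                      enc_cfg, state = NULL, seed = 1L) {
  validate_split(split, table)
  if (length(split$test_tasks) == 0L) stop("task split has no test tasks")
  if (is.null(state)) state <- init_encoder_state(enc_cfg)
  frac_test <- min(1, max(0, loss_cfg$alpha_end))
  pools <- lapply(split$test_tasks, function(tk) task_dataset(table, tk))
  names(pools) <- split$test_tasks

  per_task <- lapply(split$test_tasks, function(tk) rep(NA_real_, meta_cfg$runs))
  names(per_task) <- split$test_tasks
  for (r in seq_len(meta_cfg$runs)) {
    for (tk in split$test_tasks) {
      ep <- sample_episode(pools[[tk]], k_shot, "rest",
                           rng_seed = derive_seed(seed, "meta_test", r, tk))
      ft <- finetune_on_support(enc_cfg, encoder_params, state, ep$support,
                                loss_cfg, frac_test,
                                meta_cfg$finetune_steps_at_test,
                                meta_cfg$inner_lr, meta_cfg$grad_clip)
      fw <- encoder_forward(enc_cfg, ft$params, ft$state,
                            pack_graphs(ep$query$graphs), training = FALSE)
      p1 <- 1 / (1 + exp(fw$logits[, 1] - fw$logits[, 2]))
      per_task[[tk]][r] <- auc_score(p1, ep$query$labels)
    }
  }
  all_aucs <- unlist(per_task)
  n_missing <- sum(is.na(all_aucs))
  structure(list(per_task_auc = per_task,
                 mean_auc = mean(all_aucs, na.rm = TRUE),
                 std_auc = if (sum(!is.na(all_aucs)) > 1L)
                   stats::sd(all_aucs, na.rm = TRUE) else 0,
                 runs = meta_cfg$runs, n_missing = n_missing),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d run(s): AUC %.4f +/- %.4f\n", x$runs,
              x$mean_auc, x$std_auc))
  for (tk in names(x$per_task_auc)) {
    v <- x$per_task_auc[[tk]]
    cat(sprintf("  %s: %.4f (%d run(s), %d missing)\n", tk,
                mean(v, na.rm = TRUE), length(v), sum(is.na(v))))
  }
  if (x$n_missing > 0L) {
    cat(sprintf("  %d single-class query AUC(s) excluded\n", x$n_missing))
  }
  invisible(x)
}

#' Ablation variants of the loss configuration
#'
#' `"full"` keeps the dynamic contrastive loss; `"wc"` drops the contrastive
#' term entirely (supervised loss alone); `"wd"` keeps the contrastive term
#' but disables the dynamic hard-negative schedule (static all-pairs form,
#' independent of the training clock).
#'
#' @param name One of `"full"`, `"wc"`, `"wd"`.
#' @param base A [loss_config()] providing the remaining settings.
#' @return A [loss_config()].
#' @export
ablation_variant <- function(name = c("full", "wc", "wd"),
                             base = loss_config()) {
  name <- match.arg(name)
  cfg <- unclass(base)
  if (name == "full") {
    cfg$contrastive_enabled <- TRUE; cfg$dynamic_enabled <- TRUE
  } else if (name == "wc") {
    cfg$contrastive_enabled <- FALSE; cfg$dynamic_enabled <- FALSE
  } else {
    cfg$contrastive_enabled <- TRUE; cfg$dynamic_enabled <- FALSE
  }
  do.call(loss_config, cfg)
}
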