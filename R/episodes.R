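# Few-shot episode construction.
#
# An episode is one task instance: a class-balanced support set (exactly k
# molecules per class, regardless of pool imbalance — the sampler, not the
# pool, controls support balance) and a disjoint query set in which the
# pool's imbalance expresses itself. "10-shot" means k = 10 per class.

#' Sample one few-shot episode from a task pool
#'
#' Support molecules are drawn uniformly without replacement, `k_shot` per
#' class; the query set is drawn from the remainder — all of it when
#' `query_size = "rest"`, otherwise a stratified sample of the requested size
#' (at least one molecule of each class whenever the remainder allows).
#' Deterministic for a fixed seed.
#'
#' @param pool A `task_dataset` (or list with `graphs`, `labels`, `task`).
#' @param k_shot Support molecules per class (positive integer).
#' @param query_size `"rest"` or a positive integer.
#' @param rng_seed Integer seed.
#' @return An `episode`: list with `task_name`, `support`/`query` (each a
#'   list with `graphs`, `labels`, `index` into the pool) and `k_shot`.
#' @export
sample_episode <- function(pool, k_shot, query_size = "rest", rng_seed = 1L) {
  k_shot <- as.integer(k_shot)
  stopifnot(k_shot >= 1L)
  labels <- pool$labels
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  need <- k_shot + 1L
  if (length(pos) < need || length(neg) < need) {
    stop(sprintf(
      "cannot sample a %d-shot episode for task '%s': need >= %d of each class, have %d positive / %d negative",
      k_shot, pool$task %||% "?", need, length(pos), length(neg)))
  }
  run_seeded(rng_seed, {
    sup_pos <- sample_vec(pos, k_shot)
    sup_neg <- sample_vec(neg, k_shot)
    support_idx <- c(sup_pos, sup_neg)
    rest_pos <- setdiff(pos, sup_pos)
    rest_neg <- setdiff(neg, sup_neg)
    if (identical(query_size, "rest")) {
      query_idx <- c(rest_pos, rest_neg)
    } else {
      q <- as.integer(query_size)
      stopifnot(q >= 1L)
      n_rest <- length(rest_pos) + length(rest_neg)
      q <- min(q, n_rest)
      # stratified: keep the remainder's class ratio, >= 1 per class
      q_pos <- round(q * length(rest_pos) / n_rest)
      q_pos <- max(min(q_pos, length(rest_pos), q - 1L), 1L)
      q_pos <- min(q_pos, length(rest_pos))
      q_neg <- min(q - q_pos, length(rest_neg))
      query_idx <- c(sample_vec(rest_pos, q_pos), sample_vec(rest_neg, q_neg))
    }
    structure(list(
      task_name = pool$task %||% "task",
      support = list(graphs = pool$graphs[support_idx],
                     labels = labels[support_idx], index = support_idx),
      query = list(graphs = pool$graphs[query_idx],
                   labels = labels[query_idx], index = query_idx),
      k_shot = k_shot
    ), class = "episode")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:x; always index explicitly
sample_vec <- function(x, size) x[sample.int(length(x), size)]

#' Generate a reproducible sequence of episodes
#'
#' Meta-training draws tasks uniformly with replacement from the split's
#' training tasks; meta-testing enumerates each test task exactly once. The
#' sequence is reproducible per `(seed, phase)`.
#'
#' @param table A [task_table()].
#' @param split A [task_split()].
#' @param phase `"meta_train"` or `"meta_test"`.
#' @param k_shot Support molecules per class.
#' @param seed Integer seed.
#' @param n_episodes Number of episodes for `meta_train` (ignored for
#'   `meta_test`).
#' @param query_size Query-set size; default 32 (stratified) for
#'   `meta_train`, `"rest"` for `meta_test`.
#' @return List of [sample_episode()] episodes.
#' @export
episode_stream <- function(table, split, phase = c("meta_train", "meta_test"),
                           k_shot, seed = 1L, n_episodes = 100L,
                           query_size = NULL) {
  phase <- match.arg(phase)
  validate_split(split, table)
  tasks <- if (phase == "meta_train") split$train_tasks else split$test_tasks
  if (length(tasks) == 0L) {
    stop(sprintf("task split has no tasks for phase '%s'", phase))
  }
  if (is.null(query_size)) {
    query_size <- if (phase == "meta_train") 32L else "rest"
  }
  pools <- lapply(tasks, function(tk) task_dataset(table, tk))
  names(pools) <- tasks
  if (phase == "meta_train") {
    picks <- run_seeded(derive_seed(seed, phase, "tasks"),
                        tasks[sample.int(length(tasks), n_episodes, replace = TRUE)])
  } else {
    picks <- tasks
  }
  lapply(seq_along(picks), function(i) {
    sample_episode(pools[[picks[[i]]]], k_shot, query_size,
                   rng_seed = derive_seed(seed, phase, i))
  })
}
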