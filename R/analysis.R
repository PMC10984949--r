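# Embedding diagnostics: 2-component PCA projection and a quantitative
# class-separation score (mean silhouette) standing in for the visual
# "well separated clusters" claim.

#' Project embeddings onto their top two principal components
#'
#' Mean-centres the embeddings and projects onto the two leading
#' eigenvectors of the covariance matrix. The result is deterministic: each
#' component's sign is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param embeddings Real matrix `n x d`, `n >= 3`, `d >= 2`.
#' @param labels Integer 0/1 class labels (carried into the result).
#' @return A `projection_result`: list with `coordinates` (`n x 2`),
#'   `explained_variance_ratio` (length 2, non-increasing), `rotation`
#'   (`d x 2`) and `labels`.
#' @export
pca_project <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings); d <- ncol(embeddings)
  if (n < 3L || d < 2L) stop("pca_project(): need n >= 3 and d >= 2")
  if (length(labels) != n) stop("pca_project(): label length mismatch")
  if (any(!is.finite(embeddings))) stop("pca_project(): non-finite embeddings")
  centred <- sweep(embeddings, 2, colMeans(embeddings))
  cv <- stats::cov(centred)
  total_var <- sum(diag(cv))
  if (total_var <= .Machine$double.eps) {
    stop("pca_project(): zero-variance embeddings")
  }
  eg <- eigen(cv, symmetric = TRUE)
  rot <- eg$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(coordinates = centred %*% rot,
                 explained_variance_ratio = pmax(eg$values[1:2], 0) / total_var,
                 rotation = rot,
                 labels = labels),
            class = "projection_result")
}

#' Class-separation score of a 2-D projection
#'
#' Mean silhouette width of the projected coordinates under the true class
#' labels: near 1 for tight well-separated classes, near 0 for overlapping
#' clouds, negative when points sit nearer the other class.
#'
#' @param result A [pca_project()] result.
#' @return Scalar in `[-1, 1]`.
#' @export
separation_score <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  labs <- result$labels
  if (length(unique(labs)) < 2L) {
    stop("separation_score(): both classes must be present")
  }
  sil <- cluster::silhouette(as.integer(factor(labs)),
                             stats::dist(result$coordinates))
  mean(sil[, "sil_width"])
}

#' Plot a 2-D embedding projection
#'
#' Base-graphics scatter of the projected coordinates coloured by class.
#'
#' @param x A [pca_project()] result.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.projection_result <- function(x, main = "embedding projection", ...) {
  cols <- ifelse(x$labels == 1L, "#D55E00", "#0072B2")
  graphics::plot(x$coordinates, col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.0f%%)",
                                100 * x$explained_variance_ratio[1]),
                 ylab = sprintf("PC2 (%.0f%%)",
                                100 * x$explained_variance_ratio[2]),
                 main = main, ...)
  graphics::legend("topright", legend = c("class 1", "class 0"),
                   col = c("#D55E00", "#0072B2"), pch = 19, bty = "n")
  invisible(x)
}

#' Trained-vs-random separation contrast on a held-out task
#'
#' Quantifies what the embedding-projection figure of a few-shot study shows
#' qualitatively: per seed, a k-shot support set of the held-out task is
#' sampled and the identical fine-tuning procedure is applied to (a) the
#' meta-trained parameters and (b) a freshly initialized encoder; the query
#' set is then embedded, projected with [pca_project()] and scored with
#' [separation_score()]. Applying the same adaptation to both arms isolates
#' the contribution of meta-training.
#'
#' @param enc_cfg An [encoder_config()].
#' @param trained_params,trained_state Meta-trained parameters and batch-norm
#'   state.
#' @param pool A `task_dataset` of the held-out task.
#' @param loss_cfg A [loss_config()] used during fine-tuning.
#' @param k_shot Support molecules per class.
#' @param n_seeds Number of repetitions.
#' @param finetune_steps,finetune_lr,grad_clip Fine-tuning settings (defaults
#'   match [meta_config()]).
#' @param seed Base seed.
#' @return Data frame with one row per seed (`trained`, `random` silhouette
#'   scores) plus attribute `wins` (seeds where trained > random).
#' @export
separation_contrast <- function(enc_cfg, trained_params, trained_state, pool,
                                loss_cfg, k_shot = 10L, n_seeds = 10L,
                                finetune_steps = 20L, finetune_lr = 0.01,
                                grad_clip = 5, seed = 1L) {
  frac <- min(1, max(0, loss_cfg$alpha_end))
  score_one <- function(params, state, ep) {
    ft <- finetune_on_support(enc_cfg, params,
                              state %||% init_encoder_state(enc_cfg),
                              ep$support, loss_cfg, frac, finetune_steps,
                              finetune_lr, grad_clip)
    fw <- encoder_forward(enc_cfg, ft$params, ft$state,
                          pack_graphs(ep$query$graphs), training = FALSE)
    separation_score(pca_project(fw$embeddings, ep$query$labels))
  }
  rows <- lapply(seq_len(n_seeds), function(s) {
    ep <- sample_episode(pool, k_shot, "rest",
                         rng_seed = derive_seed(seed, "sep", s))
    rd_params <- init_encoder_params(enc_cfg, seed = derive_seed(seed, "init", s))
    data.frame(seed = s,
               trained = score_one(trained_params, trained_state, ep),
               random = score_one(rd_params, NULL, ep))
  })
  out <- do.call(rbind, rows)
  attr(out, "wins") <- sum(out$trained > out$random)
  out
}
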