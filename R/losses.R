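# The bifurcated training objective: supervised cross-entropy plus a
# contrastive term over pairwise embedding distances, where the fraction of
# different-class ("negative") pairs entering the loss decays exponentially
# over training, keeping only the hardest (closest) pairs.
#
# Conventions, fixed here and relied on everywhere else:
#  * pairs are unordered (i < j), self-pairs excluded;
#  * the indicator is 1 on ALL same-class pairs — hard-negative selection
#    acts only on different-class pairs, so the attraction component is
#    never suppressed;
#  * contrastive sums are not divided by the pair count; the weight w
#    absorbs the scale.

#' Configuration of the combined loss
#'
#' @param margin_m Margin enforced between different-class pairs (on squared
#'   distance under the default hinge). Must be positive.
#' @param weight_w Weight of the contrastive term in the combined loss.
#' @param alpha_start,alpha_end Initial and terminal hard-negative ratios of
#'   the decay schedule `f(t) = alpha_start * exp(-beta * t) + alpha_end`.
#' @param beta Decay rate of the schedule (per outer optimization step).
#' @param dynamic_enabled If `FALSE`, the static contrastive loss (all
#'   negative pairs) is used regardless of the clock.
#' @param contrastive_enabled If `FALSE`, the combined loss is the supervised
#'   loss alone.
#' @param hinge Repulsion hinge form: `"squared_distance"` (default) uses
#'   `max(0, m - D^2)`; `"distance"` uses the classical `max(0, m - D)^2`.
#' @return A validated `loss_config` list.
#' @export
loss_config <- function(margin_m = 1.0, weight_w = 1.0,
                        alpha_start = 1.0, alpha_end = 0.2, beta = 0.01,
                        dynamic_enabled = TRUE, contrastive_enabled = TRUE,
                        hinge = c("squared_distance", "distance")) {
  hinge <- match.arg(hinge)
  if (!is.numeric(margin_m) || margin_m <= 0) stop("margin_m must be > 0")
  if (!is.numeric(weight_w) || weight_w < 0) stop("weight_w must be >= 0")
  if (alpha_start < 0 || alpha_end < 0) stop("alpha_start/alpha_end must be >= 0")
  if (beta < 0) stop("beta must be >= 0")
  if (dynamic_enabled && !contrastive_enabled) {
    stop("dynamic_enabled requires contrastive_enabled")
  }
  structure(list(margin_m = margin_m, weight_w = weight_w,
                 alpha_start = alpha_start, alpha_end = alpha_end, beta = beta,
                 dynamic_enabled = dynamic_enabled,
                 contrastive_enabled = contrastive_enabled, hinge = hinge),
            class = "loss_config")
}

#' Training clock
#'
#' A mutable counter of completed outer optimization steps; its value `t`
#' drives the hard-negative decay schedule. Steps — not epochs or episodes —
#' are counted, mirroring learning-rate-schedule convention.
#'
#' @param t Initial step count (non-negative integer).
#' @return An environment of class `training_clock` with field `t`.
#' @export
training_clock <- function(t = 0L) {
  stopifnot(is.numeric(t), t >= 0)
  env <- new.env(parent = emptyenv())
  env$t <- as.integer(t)
  class(env) <- "training_clock"
  env
}

#' Advance the training clock by one completed outer step
#' @param clock A [training_clock()].
#' @return The clock, invisibly.
#' @export
clock_tick <- function(clock) {
  stopifnot(inherits(clock, "training_clock"))
  clock$t <- clock$t + 1L
  invisible(clock)
}

#' Hard-negative fraction schedule
#'
#' Evaluates `f(t) = alpha_start * exp(-beta * t) + alpha_end`. The raw value
#' can exceed 1 early in training (e.g. 1.2 at t = 0 under the default
#' alpha_start = 1, alpha_end = 0.2); for use as a selection fraction it is
#' clipped to `[0, 1]`, and both values are returned.
#'
#' @param clock A [training_clock()] or a non-negative step count.
#' @param config A [loss_config()].
#' @return List with `raw` (unclipped f(t)) and `fraction` (clipped to
#'   `[0, 1]`).
#' @export
hard_fraction <- function(clock, config) {
  t <- if (inherits(clock, "training_clock")) clock$t else clock
  stopifnot(is.numeric(t), t >= 0)
  raw <- config$alpha_start * exp(-config$beta * t) + config$alpha_end
  list(raw = raw, fraction = min(1, max(0, raw)))
}

#' Mean cross-entropy of binary logits
#'
#' Mean (1/k-normalised) cross-entropy over samples, computed from raw
#' two-class logits through a numerically stable log-softmax.
#'
#' @param logits Real matrix `k x 2` (columns: class 0, class 1).
#' @param labels Integer vector of length `k` with values in \{0, 1\}.
#' @return Non-negative scalar loss.
#' @export
supervised_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  if (ncol(logits) != 2L) stop("supervised_loss(): logits must have 2 columns")
  if (nrow(logits) != length(labels)) stop("supervised_loss(): size mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("supervised_loss(): labels must be 0/1")
  if (any(!is.finite(logits))) stop("supervised_loss(): non-finite logits")
  mx <- pmax(logits[, 1], logits[, 2])
  lse <- mx + log(exp(logits[, 1] - mx) + exp(logits[, 2] - mx))
  true_logit <- ifelse(labels == 1L, logits[, 2], logits[, 1])
  mean(lse - true_logit)
}

# d supervised_loss / d logits: (softmax - onehot) / k
supervised_loss_grad <- function(logits, labels) {
  k <- nrow(logits)
  mx <- pmax(logits[, 1], logits[, 2])
  e0 <- exp(logits[, 1] - mx); e1 <- exp(logits[, 2] - mx)
  p1 <- e1 / (e0 + e1)
  cbind((1 - p1) - (labels == 0L), p1 - (labels == 1L)) / k
}

#' Pairwise Euclidean distances between embedding rows
#'
#' @param embeddings Real matrix `n x d`, `n >= 2`.
#' @return Symmetric `n x n` matrix with zero diagonal,
#'   `D[i, j] = ||e_i - e_j||_2`.
#' @export
pairwise_distances <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("pairwise_distances(): need at least 2 rows")
  if (any(!is.finite(embeddings))) {
    stop("pairwise_distances(): non-finite embeddings")
  }
  sq <- rowSums(embeddings^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(embeddings)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  d
}

#' Select hard negative pairs and assemble a pairwise battery
#'
#' Among the unordered different-class pairs, the `ceiling(fraction * |K|)`
#' pairs with the smallest distance ("hardest" — violating or nearly
#' violating the margin) receive indicator 1; all other different-class pairs
#' receive 0. All same-class pairs always receive indicator 1, so attraction
#' terms are never dropped. Ties are broken by lexicographic pair index.
#'
#' @param distances Symmetric `n x n` distance matrix (zero diagonal).
#' @param pair_labels Binary `n x n` matrix, 1 where the two samples share a
#'   class.
#' @param fraction Selection fraction in `[0, 1]` (typically the clipped
#'   value from [hard_fraction()]).
#' @return A `pairwise_battery`: list with `distances`, `pair_labels`,
#'   `indicator` (binary `n x n`, symmetric), `negative_pair_count` (|K|,
#'   unordered) and `hard_pair_count` (|H|).
#' @export
select_hard_negatives <- function(distances, pair_labels, fraction) {
  distances <- as.matrix(distances); pair_labels <- as.matrix(pair_labels)
  n <- nrow(distances)
  stopifnot(ncol(distances) == n, all(dim(pair_labels) == c(n, n)))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")

  ut <- which(upper.tri(distances), arr.ind = TRUE)   # unordered pairs i < j
  neg <- ut[pair_labels[ut] == 0, , drop = FALSE]
  n_neg <- nrow(neg)

  indicator <- matrix(0, n, n)
  indicator[pair_labels == 1] <- 1
  diag(indicator) <- 0

  n_hard <- 0L
  if (n_neg == 0L) {
    warning("select_hard_negatives(): no different-class pairs in batch")
  } else if (fraction > 0) {
    n_hard <- as.integer(ceiling(fraction * n_neg))
    d <- distances[neg]
    ord <- order(d, neg[, 1], neg[, 2])[seq_len(n_hard)]
    sel <- neg[ord, , drop = FALSE]
    indicator[sel] <- 1
    indicator[sel[, c(2, 1), drop = FALSE]] <- 1
  }

  structure(list(distances = distances, pair_labels = pair_labels,
                 indicator = indicator,
                 negative_pair_count = n_neg, hard_pair_count = n_hard),
            class = "pairwise_battery")
}

# shared pair-term kernel; indicator = NULL means all-ones
.contrastive_sum <- function(distances, pair_labels, margin_m, hinge,
                             indicator = NULL) {
  if (margin_m <= 0) stop("margin m must be > 0")
  n <- nrow(distances)
  if (n < 2L) stop("contrastive loss needs at least 2 samples")
  d2 <- distances^2
  rep_term <- if (hinge == "squared_distance") {
    pmax(0, margin_m - d2)
  } else {
    pmax(0, margin_m - distances)^2
  }
  terms <- pair_labels * d2 + (1 - pair_labels) * rep_term
  if (!is.null(indicator)) terms <- terms * indicator
  sum(terms[upper.tri(terms)])
}

#' Static (all-pairs) contrastive loss
#'
#' Sum over unordered pairs of `y_ij * D^2 + (1 - y_ij) * max(0, m - D^2)`:
#' same-class pairs are attracted, different-class pairs are repelled until
#' their squared distance exceeds the margin.
#'
#' @param battery A `pairwise_battery` (its indicator is ignored) or any list
#'   with `distances` and `pair_labels`.
#' @param margin_m Positive margin.
#' @param hinge See [loss_config()].
#' @return Non-negative scalar loss.
#' @export
contrastive_static <- function(battery, margin_m,
                               hinge = c("squared_distance", "distance")) {
  hinge <- match.arg(hinge)
  .contrastive_sum(battery$distances, battery$pair_labels, margin_m, hinge)
}

#' Dynamic contrastive loss over selected hard negatives
#'
#' As [contrastive_static()], but each pair term is multiplied by the
#' indicator produced by [select_hard_negatives()]: only the scheduled
#' fraction of hardest different-class pairs is repelled, while every
#' same-class pair keeps its attraction term.
#'
#' @param battery A `pairwise_battery` from [select_hard_negatives()].
#' @param margin_m Positive margin.
#' @param hinge See [loss_config()].
#' @return Non-negative scalar loss.
#' @export
contrastive_dynamic <- function(battery, margin_m,
                                hinge = c("squared_distance", "distance")) {
  hinge <- match.arg(hinge)
  if (is.null(battery$indicator)) {
    stop("contrastive_dynamic(): battery has no indicator; run select_hard_negatives() first")
  }
  .contrastive_sum(battery$distances, battery$pair_labels, margin_m, hinge,
                   battery$indicator)
}

# Gradient of the (dynamic or static) contrastive loss wrt the embeddings,
# with the indicator treated as a constant of the forward pass. Returns n x d.
contrastive_grad <- function(embeddings, pair_labels, indicator, margin_m,
                             hinge = "squared_distance") {
  n <- nrow(embeddings)
  d <- pairwise_distances(embeddings)
  d2 <- d^2
  if (hinge == "squared_distance") {
    # pair weight on (e_i - e_j): +2 attraction, -2 on active hinge
    w <- pair_labels * 1 +
      (1 - pair_labels) * indicator * (-1) * (d2 < margin_m)
  } else {
    # (m - D)_+^2: d/dD = -2 (m - D)_+ ; dD/de_i = (e_i - e_j) / D
    hinge_val <- pmax(0, margin_m - d)
    coef <- matrix(0, n, n)
    pos <- d > 0
    coef[pos] <- -hinge_val[pos] / d[pos]
    w <- pair_labels * 1 + (1 - pair_labels) * indicator * coef
  }
  diag(w) <- 0
  2 * (rowSums(w) * embeddings - w %*% embeddings)
}

#' Combine supervised and contrastive components
#'
#' `L = L_label + w * L_contra` when the contrastive term is enabled;
#' the supervised loss alone otherwise (the "wc" ablation). Which contrastive
#' value to pass (dynamic vs static) is decided by the caller from
#' `config$dynamic_enabled` (the "wd" ablation uses the static form).
#'
#' @param supervised Scalar supervised loss.
#' @param contrastive Scalar contrastive loss (ignored when
#'   `config$contrastive_enabled` is `FALSE`).
#' @param config A [loss_config()].
#' @return Scalar combined loss.
#' @export
combined_loss <- function(supervised, contrastive, config) {
  stopifnot(inherits(config, "loss_config"))
  if (!is.finite(supervised)) stop("combined_loss(): non-finite supervised loss")
  if (!config$contrastive_enabled) return(supervised)
  if (!is.finite(contrastive)) stop("combined_loss(): non-finite contrastive loss")
  supervised + config$weight_w * contrastive
}

# One-call evaluation of the contrastive part for a labelled embedding batch:
# builds pair labels, selects hard negatives at `fraction`, returns value,
# gradient and the battery (for logging |K| and |H|).
contrastive_pass <- function(embeddings, labels, config, fraction) {
  n <- nrow(embeddings)
  pl <- outer(labels, labels, "==") * 1
  if (!config$dynamic_enabled) fraction <- 1
  dmat <- pairwise_distances(embeddings)
  battery <- suppressWarnings(select_hard_negatives(dmat, pl, fraction))
  value <- contrastive_dynamic(battery, config$margin_m, config$hinge)
  grad <- contrastive_grad(embeddings, pl, battery$indicator,
                           config$margin_m, config$hinge)
  list(value = value, grad = grad, battery = battery)
}
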