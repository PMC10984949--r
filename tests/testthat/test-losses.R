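test_that("supervised loss matches closed forms and per-sample enumeration", {
  # symmetric logits: probability exactly (0.5, 0.5) per sample -> ln 2
  expect_equal(supervised_loss(matrix(0, 2, 2), c(0L, 1L)), log(2))
  # probability ~1 on the true class in the large-logit limit -> ~0
  expect_equal(supervised_loss(matrix(c(-50, 50, 50, -50), 2, 2), c(1L, 0L)),
               0, tolerance = 1e-12)
  # independent by-hand sum of -log p_true / k
  set.seed(9)
  logits <- matrix(rnorm(8), 4, 2)
  labels <- c(1L, 0L, 1L, 1L)
  by_hand <- 0
  for (i in 1:4) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    by_hand <- by_hand - log(p[labels[i] + 1]) / 4
  }
  expect_equal(supervised_loss(logits, labels), by_hand, tolerance = 1e-12)
  expect_error(supervised_loss(matrix(0, 2, 2), c(0L, 2L)), "0/1")
})

test_that("supervised gradient matches finite differences", {
  set.seed(4)
  logits <- matrix(rnorm(10), 5, 2)
  labels <- c(1L, 0L, 0L, 1L, 1L)
  g <- molfewshot:::supervised_loss_grad(logits, labels)
  h <- 1e-6
  for (k in seq_along(logits)) {
    lp <- logits; lp[k] <- lp[k] + h
    lm <- logits; lm[k] <- lm[k] - h
    fd <- (supervised_loss(lp, labels) - supervised_loss(lm, labels)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-5)
  }
})

test_that("pairwise distances agree with per-pair norms", {
  expect_equal(pairwise_distances(matrix(1, 3, 4)), matrix(0, 3, 3))
  expect_equal(pairwise_distances(matrix(c(0, 3), 2, 1))[1, 2], 3)
  set.seed(11)
  emb <- matrix(rnorm(15), 5, 3)
  d <- pairwise_distances(emb)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sqrt(sum((emb[i, ] - emb[j, ])^2)),
                 tolerance = 1e-12)
    expect_equal(d[i, j], d[j, i])
  }
  expect_equal(diag(d), rep(0, 5))
  expect_error(pairwise_distances(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
  expect_error(pairwise_distances(matrix(1, 1, 3)), "at least 2")
})

test_that("static contrastive loss reproduces hand-enumerated pair terms", {
  mk <- function(x, labels) {
    emb <- matrix(x, ncol = 1)
    list(distances = pairwise_distances(emb),
         pair_labels = outer(labels, labels, "==") * 1)
  }
  # two same-class samples at identical embeddings: attraction term 0
  expect_equal(contrastive_static(mk(c(2, 2), c(1, 1)), 1), 0)
  # two different-class samples with D^2 >= m: margin satisfied
  expect_equal(contrastive_static(mk(c(0, 3), c(1, 0)), 4), 0)
  # three points {0,1,3}, labels {1,1,0}, m = 4: pairs contribute 1 + 0 + 0
  expect_equal(contrastive_static(mk(c(0, 1, 3), c(1, 1, 0)), 4), 1)
  expect_error(contrastive_static(mk(c(0, 1), c(1, 0)), -1), "m must be > 0")
})

test_that("decay schedule follows its closed form and is monotone", {
  cfg <- loss_config(alpha_start = 1, alpha_end = 0.2, beta = 0.01)
  f0 <- hard_fraction(training_clock(0L), cfg)
  expect_equal(f0$raw, 1.2)
  expect_equal(f0$fraction, 1.0)
  expect_equal(hard_fraction(100L, cfg)$raw, exp(-1) + 0.2, tolerance = 1e-12)
  expect_equal(hard_fraction(1e7, cfg)$raw, 0.2, tolerance = 1e-6)
  f <- vapply(0:500, function(t) hard_fraction(t, cfg)$raw, numeric(1))
  expect_true(all(diff(f) < 0))
  expect_equal(f[1], cfg$alpha_start + cfg$alpha_end)
})

test_that("hard-negative selection takes the closest fraction with stable ties", {
  emb <- matrix(c(0, 0.5, 10, 12, 13), ncol = 1)
  labels <- c(1, 1, 0, 0, 0)
  pl <- outer(labels, labels, "==") * 1
  d <- pairwise_distances(emb)

  all_sel <- select_hard_negatives(d, pl, 1)
  expect_equal(all_sel$hard_pair_count, all_sel$negative_pair_count)
  none <- select_hard_negatives(d, pl, 0)
  expect_equal(none$hard_pair_count, 0L)
  expect_equal(none$indicator, pl * (1 - diag(5)))

  # negative-pair distances {9.5, 11.5, 12.5, 10, 12, 13}; fraction 1/6 keeps
  # only the closest pair (2,3)
  one <- select_hard_negatives(d, pl, 1 / 6)
  expect_equal(one$hard_pair_count, 1L)
  expect_equal(one$indicator[2, 3], 1)
  expect_equal(one$indicator[3, 2], 1)
  expect_equal(sum(one$indicator * (1 - pl)), 2)

  # exact ties broken by lexicographic pair index
  emb2 <- matrix(c(0, 0, 1, 1), ncol = 1)
  labels2 <- c(1, 1, 0, 0)
  tie <- select_hard_negatives(pairwise_distances(emb2),
                               outer(labels2, labels2, "==") * 1, 0.25)
  expect_equal(tie$hard_pair_count, 1L)
  expect_equal(tie$indicator[1, 3], 1)   # (1,3) precedes (1,4) and (2,3)
  expect_equal(tie$indicator[1, 4], 0)

  # all-positive batch: warning, zero hard pairs
  expect_warning(
    res <- select_hard_negatives(pairwise_distances(emb2),
                                 matrix(1, 4, 4), 0.5),
    "no different-class pairs")
  expect_equal(res$hard_pair_count, 0L)
})

test_that("dynamic contrastive loss matches the brute-force oracle", {
  mkb <- function(x, labels, fraction) {
    emb <- matrix(x, ncol = 1)
    select_hard_negatives(pairwise_distances(emb),
                          outer(labels, labels, "==") * 1, fraction)
  }
  # full selection reduces exactly to the static loss
  b <- mkb(c(0, 1, 3), c(1, 1, 0), 1)
  expect_identical(contrastive_dynamic(b, 4), contrastive_static(b, 4))
  # fraction 0 keeps only the same-class attraction term
  expect_equal(contrastive_dynamic(mkb(c(0, 1, 3), c(1, 1, 0), 0), 4), 1)

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    emb <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    frac <- runif(1)
    m <- runif(1, 0.5, 30)
    b <- select_hard_negatives(pairwise_distances(emb),
                               outer(labels, labels, "==") * 1, frac)
    expect_equal(contrastive_dynamic(b, m),
                 oracle_contrastive(emb, labels, m, frac),
                 tolerance = 1e-6)
    expect_equal(contrastive_static(b, m),
                 oracle_contrastive(emb, labels, m),
                 tolerance = 1e-6)
  }
})

test_that("the alternative distance hinge matches its oracle", {
  set.seed(31)
  emb <- matrix(rnorm(12), 6, 2)
  labels <- c(1L, 0L, 1L, 0L, 1L, 0L)
  b <- select_hard_negatives(pairwise_distances(emb),
                             outer(labels, labels, "==") * 1, 0.5)
  expect_equal(contrastive_dynamic(b, 2, hinge = "distance"),
               oracle_contrastive(emb, labels, 2, 0.5, hinge = "distance"),
               tolerance = 1e-6)
})

test_that("contrastive loss is invariant to sample order", {
  set.seed(5)
  emb <- matrix(rnorm(16), 8, 2)
  labels <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  val <- function(e, l) {
    b <- select_hard_negatives(pairwise_distances(e),
                               outer(l, l, "==") * 1, 0.5)
    contrastive_dynamic(b, 3)
  }
  perm <- sample(8)
  expect_equal(val(emb, labels), val(emb[perm, , drop = FALSE], labels[perm]),
               tolerance = 1e-10)
})

test_that("contrastive gradient matches finite differences and moves pairs
          in the documented directions", {
  set.seed(7)
  emb <- matrix(rnorm(10), 5, 2)
  labels <- c(1L, 1L, 0L, 0L, 1L)
  pl <- outer(labels, labels, "==") * 1
  b <- select_hard_negatives(pairwise_distances(emb), pl, 0.6)
  g <- molfewshot:::contrastive_grad(emb, pl, b$indicator, 2)
  h <- 1e-6
  for (k in seq_along(emb)) {
    ep <- emb; ep[k] <- ep[k] + h
    em <- emb; em[k] <- em[k] - h
    # indicator held fixed, as in the implementation
    val <- function(e) {
      d <- pairwise_distances(e)
      molfewshot:::.contrastive_sum(d, pl, 2, "squared_distance", b$indicator)
    }
    expect_equal(g[k], (val(ep) - val(em)) / (2 * h), tolerance = 1e-4)
  }

  # one gradient step attracts same-class pairs ...
  two <- matrix(c(0, 0, 1, 0.5), 2, 2)
  same <- outer(c(1, 1), c(1, 1), "==") * 1
  gs <- molfewshot:::contrastive_grad(two, same, same * (1 - diag(2)), 1)
  after <- two - 0.05 * gs
  expect_lt(pairwise_distances(after)[1, 2], pairwise_distances(two)[1, 2])
  # ... and repels different-class pairs inside the margin
  diff_lab <- outer(c(1, 0), c(1, 0), "==") * 1
  ind <- 1 - diag(2)
  gd <- molfewshot:::contrastive_grad(two, diff_lab, ind, 10)
  after_d <- two - 0.05 * gd
  expect_gt(pairwise_distances(after_d)[1, 2], pairwise_distances(two)[1, 2])
})

test_that("combined loss honours the weight and the ablation switches", {
  expect_equal(combined_loss(0.5, 2.0, loss_config(weight_w = 0)), 0.5)
  expect_equal(combined_loss(0.5, 2.0, loss_config(weight_w = 1)), 2.5)
  for (w in c(0.1, 1, 10)) {
    expect_s3_class(loss_config(weight_w = w), "loss_config")
  }
  expect_error(loss_config(weight_w = -1), ">= 0")
  expect_error(loss_config(margin_m = 0), "> 0")
  expect_error(loss_config(dynamic_enabled = TRUE, contrastive_enabled = FALSE),
               "requires")
  wc <- ablation_variant("wc")
  expect_equal(combined_loss(0.7, 123, wc), 0.7)
})

test_that("training clock counts completed outer steps monotonically", {
  ck <- training_clock()
  expect_equal(ck$t, 0L)
  clock_tick(ck); clock_tick(ck)
  expect_equal(ck$t, 2L)
})
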