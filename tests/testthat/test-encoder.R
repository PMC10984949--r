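test_that("embedding shapes follow the configuration contract", {
  fam <- dev_family()
  graphs <- lapply(fam$table$smiles[1:8], parse_smiles)
  for (jk in c("sum", "last", "max", "concat")) {
    cfg <- encoder_config(n_layers = 3L, hidden_dim = 16L, jk_mode = jk)
    params <- init_encoder_params(cfg, 1)
    eb <- encode(cfg, graphs, params)
    expect_equal(dim(eb$embeddings), c(8L, embedding_dim(cfg)), label = jk)
    expect_equal(dim(eb$logits), c(8L, 2L), label = jk)
  }
  expect_equal(embedding_dim(encoder_config(n_layers = 5, hidden_dim = 32)),
               32L)
  expect_equal(embedding_dim(encoder_config(n_layers = 5, hidden_dim = 32,
                                            jk_mode = "concat")), 160L)
})

test_that("the encoder is invariant to node permutation and duplicates rows
          for duplicated graphs", {
  fam <- dev_family()
  graphs <- lapply(fam$table$smiles[1:6], parse_smiles)
  cfg <- encoder_config(n_layers = 3L, hidden_dim = 12L)
  params <- init_encoder_params(cfg, 3)
  base <- encode(cfg, graphs, params)
  set.seed(8)
  for (g in graphs[1:4]) {
    perm <- sample(g$n_atoms)
    gp <- permute_mol_graph(g, perm)
    e1 <- encode(cfg, list(g), params)$embeddings
    e2 <- encode(cfg, list(gp), params)$embeddings
    expect_equal(e1, e2, tolerance = 1e-5)
  }
  dup <- encode(cfg, c(graphs[1], graphs, graphs[1]), params)
  expect_equal(dup$embeddings[1, ], dup$embeddings[8, ], tolerance = 1e-10)
  expect_equal(dup$embeddings[1, ], base$embeddings[1, ], tolerance = 1e-10)
})

test_that("a single-atom graph reproduces the hand-evaluated update rule", {
  cfg <- encoder_config(n_layers = 1L, hidden_dim = 2L, jk_mode = "last")
  params <- init_encoder_params(cfg, 5)
  g <- parse_smiles("C")
  eb <- encode(cfg, list(g), params)
  # by hand: x = atom embeddings; a = (1+eps) x (no neighbours);
  # out = BN_eval(W2' relu(W1' a + b1) + b2), running stats (0, 1)
  x <- params$atom_z[6, ] + params$atom_chi[1, ]
  a <- (1 + params$`l1.eps`[1, 1]) * x
  z1 <- as.numeric(a %*% params$`l1.W1`) + as.numeric(params$`l1.b1`)
  r <- pmax(z1, 0)
  z2 <- as.numeric(r %*% params$`l1.W2`) + as.numeric(params$`l1.b2`)
  out <- as.numeric(params$`l1.bn_gamma`) * z2 / sqrt(1 + 1e-5) +
    as.numeric(params$`l1.bn_beta`)
  expect_equal(as.numeric(eb$embeddings), out, tolerance = 1e-10)
  expect_equal(as.numeric(eb$logits),
               as.numeric(out %*% params$head.W) + as.numeric(params$head.b),
               tolerance = 1e-10)
})

test_that("hand-derived gradients match finite differences", {
  fam <- dev_family()
  ds <- task_dataset(fam$table, fam$split$train_tasks[1])
  graphs <- ds$graphs[1:6]
  labels <- ds$labels[1:6]
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  lc <- loss_config(weight_w = 0.5, margin_m = 50)

  for (jk in c("sum", "concat")) {
    cfg <- encoder_config(n_layers = 2L, hidden_dim = 4L, jk_mode = jk)
    params <- init_encoder_params(cfg, 2)
    state <- molfewshot:::init_encoder_state(cfg)
    batch <- pack_graphs(graphs)
    for (training in c(FALSE, TRUE)) {
      loss_at <- function(p) {
        fw <- encoder_forward(cfg, p, state, batch, training = training)
        cp <- molfewshot:::contrastive_pass(fw$embeddings, labels, lc, 0.5)
        supervised_loss(fw$logits, labels) + lc$weight_w * cp$value
      }
      fw <- encoder_forward(cfg, params, state, batch, training = training)
      dlog <- molfewshot:::supervised_loss_grad(fw$logits, labels)
      cp <- molfewshot:::contrastive_pass(fw$embeddings, labels, lc, 0.5)
      gr <- molfewshot:::encoder_backward(cfg, params, fw$cache,
                                          lc$weight_w * cp$grad, dlog)
      set.seed(17)
      for (nm in names(params)) {
        for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
          h <- 1e-5
          pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
          pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
          fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
          expect_equal(gr[[nm]][k], fd, tolerance = 1e-4,
                       label = sprintf("%s[%d] jk=%s training=%s",
                                       nm, k, jk, training))
        }
      }
    }
  }
})

test_that("embeddings stay finite across many generator molecules", {
  fam <- generate_task_family(synthetic_spec(
    n_tasks = 5L, n_molecules_per_task = 200L, positive_fraction = 0.2,
    seed = 99L, n_test_tasks = 1L))
  graphs <- lapply(fam$table$smiles, parse_smiles)
  expect_gte(length(graphs), 1000L)
  cfg <- encoder_config(n_layers = 5L, hidden_dim = 16L)
  params <- init_encoder_params(cfg, 7)
  eb <- encode(cfg, graphs, params)
  expect_true(all(is.finite(eb$embeddings)))
  expect_true(all(is.finite(eb$logits)))
})

test_that("checkpoints round-trip and enforce the shape contract", {
  cfg <- encoder_config(n_layers = 2L, hidden_dim = 8L)
  params <- init_encoder_params(cfg, 1)
  state <- molfewshot:::init_encoder_state(cfg)
  path <- withr::local_tempfile(fileext = ".rds")

  save_checkpoint(params, path, state)
  ck <- load_checkpoint(cfg, path)
  expect_identical(ck$params, params)
  expect_identical(ck$state, state)
  expect_false(ck$fresh_head)

  # archive without the head: trunk loads, head is reported fresh
  trunk_only <- params[setdiff(names(params), c("head.W", "head.b"))]
  save_checkpoint(trunk_only, path)
  expect_message(ck2 <- load_checkpoint(cfg, path, seed = 4), "freshly")
  expect_true(ck2$fresh_head)
  expect_identical(ck2$params$atom_z, params$atom_z)
  expect_equal(dim(ck2$params$head.W), c(8L, 2L))

  # wrong hidden_dim: error naming mismatched entries
  wide <- encoder_config(n_layers = 2L, hidden_dim = 16L)
  save_checkpoint(init_encoder_params(wide, 1), path)
  expect_error(load_checkpoint(cfg, path), "mismatched shapes.*atom_z")

  writeLines("not a checkpoint", path)
  expect_error(load_checkpoint(cfg, path), "corrupt|not a recognised")
  expect_error(load_checkpoint(cfg, file.path(tempdir(), "missing.rds")),
               "does not exist")
})

test_that("packing rejects empty inputs", {
  expect_error(pack_graphs(list()), "empty")
  expect_error(pack_graphs(list(1)), "mol_graph")
})
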