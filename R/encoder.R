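# Graph isomorphism network (GIN) encoder with jumping-knowledge pooling.
#
# Per layer l the node update is
#   h_v <- BN_l( MLP_l( (1 + eps_l) h_v + sum_{u in N(v)} (h_u + e_emb_l(uv)) ) )
# with eps_l learnable, MLP_l two affine maps with an interior ReLU, and a
# batch-normalisation step whose evaluation mode uses running statistics.
# Categorical atom/bond codes enter through learned embedding tables that are
# summed per node / per edge. The graph-level readout sums node states per
# graph at every layer; the jumping-knowledge (JK) combination merges the
# per-layer readouts (elementwise sum by default). A linear head maps the
# graph embedding to two class logits; the contrastive objective acts on the
# pre-head embedding.
#
# Gradients are hand-derived reverse-mode passes validated against finite
# differences in the test suite.

.BN_EPS <- 1e-5

#' Encoder configuration
#'
#' @param n_layers Number of GIN layers (default 5).
#' @param hidden_dim Width of node states and embedding tables.
#' @param jk_mode Jumping-knowledge combination of per-layer graph readouts:
#'   `"sum"` (default), `"last"`, `"max"` or `"concat"`.
#' @param dropout Dropout probability on inter-layer activations during
#'   training; in `[0, 1)`.
#' @param checkpoint_path Optional path to a parameter archive to load.
#' @return A validated `encoder_config`.
#' @export
encoder_config <- function(n_layers = 5L, hidden_dim = 64L,
                           jk_mode = c("sum", "last", "max", "concat"),
                           dropout = 0, checkpoint_path = NULL) {
  jk_mode <- match.arg(jk_mode)
  n_layers <- as.integer(n_layers); hidden_dim <- as.integer(hidden_dim)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (hidden_dim < 1L) stop("hidden_dim must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(n_layers = n_layers, hidden_dim = hidden_dim,
                 jk_mode = jk_mode, dropout = dropout,
                 checkpoint_path = checkpoint_path),
            class = "encoder_config")
}

#' Embedding dimension produced by a configuration
#' @param config An [encoder_config()].
#' @return Integer embedding dimension (`hidden_dim`, or
#'   `n_layers * hidden_dim` for `jk_mode = "concat"`).
#' @export
embedding_dim <- function(config) {
  if (config$jk_mode == "concat") config$n_layers * config$hidden_dim
  else config$hidden_dim
}

# expected shapes of every trainable parameter, keyed by flat name
encoder_param_shapes <- function(config) {
  h <- config$hidden_dim
  dims <- mol_feature_dims()
  shapes <- list(atom_z = c(dims$atomic_num, h), atom_chi = c(dims$chirality, h))
  for (l in seq_len(config$n_layers)) {
    p <- sprintf("l%d.", l)
    shapes[[paste0(p, "edge_type")]] <- c(dims$bond_type, h)
    shapes[[paste0(p, "edge_dir")]] <- c(dims$bond_dir, h)
    shapes[[paste0(p, "eps")]] <- c(1, 1)
    shapes[[paste0(p, "W1")]] <- c(h, h)
    shapes[[paste0(p, "b1")]] <- c(1, h)
    shapes[[paste0(p, "W2")]] <- c(h, h)
    shapes[[paste0(p, "b2")]] <- c(1, h)
    shapes[[paste0(p, "bn_gamma")]] <- c(1, h)
    shapes[[paste0(p, "bn_beta")]] <- c(1, h)
  }
  shapes$head.W <- c(embedding_dim(config), 2)
  shapes$head.b <- c(1, 2)
  shapes
}

.HEAD_NAMES <- c("head.W", "head.b")

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weights and embedding tables, zero biases, `eps = 0`,
#' batch-norm scale 1 / shift 0. Deterministic for a fixed seed.
#'
#' @param config An [encoder_config()].
#' @param seed Integer RNG seed.
#' @return Named list of parameter matrices (flat name -> matrix).
#' @export
init_encoder_params <- function(config, seed = 1L) {
  shapes <- encoder_param_shapes(config)
  run_seeded(seed, {
    params <- lapply(names(shapes), function(nm) {
      s <- shapes[[nm]]
      if (grepl("\\.(b1|b2|bn_beta|eps)$|^head\\.b$", nm)) {
        matrix(0, s[1], s[2])
      } else if (grepl("bn_gamma$", nm)) {
        matrix(1, s[1], s[2])
      } else {
        glorot(s[1], s[2])
      }
    })
    names(params) <- names(shapes)
    params
  })
}

# batch-norm running statistics (non-trainable state)
init_encoder_state <- function(config) {
  h <- config$hidden_dim
  list(bn_mean = replicate(config$n_layers, numeric(h), simplify = FALSE),
       bn_var = replicate(config$n_layers, rep(1, h), simplify = FALSE),
       momentum = 0.1)
}

#' Pack a list of molecular graphs into one batch
#'
#' Concatenates node/edge tensors with node indices offset per graph, the
#' form consumed by [encoder_forward()].
#'
#' @param graphs Non-empty list of [parse_smiles()] graphs.
#' @return List with `node_features`, `edge_index`, `edge_features`,
#'   `graph_id`, `n_nodes`, `n_graphs`.
#' @export
pack_graphs <- function(graphs) {
  if (length(graphs) == 0L) stop("pack_graphs(): empty graph list")
  ok <- vapply(graphs, function(g) inherits(g, "mol_graph") && g$n_atoms >= 1L,
               logical(1))
  if (!all(ok)) stop("pack_graphs(): all inputs must be non-empty mol_graph objects")
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  node_features <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  edge_index <- do.call(cbind, Map(function(g, o) g$edge_index + o,
                                   graphs, offsets))
  edge_features <- do.call(rbind, lapply(graphs, function(g) g$edge_features))
  list(node_features = node_features,
       edge_index = edge_index,
       edge_features = edge_features,
       graph_id = rep(seq_along(graphs), sizes),
       n_nodes = sum(sizes),
       n_graphs = length(graphs))
}

#' Forward pass of the GIN encoder
#'
#' @param config An [encoder_config()].
#' @param params Parameter list from [init_encoder_params()] or
#'   [load_checkpoint()].
#' @param state Batch-norm running statistics; `NULL` for fresh state.
#' @param batch A packed batch from [pack_graphs()].
#' @param training If `TRUE`, batch-norm uses batch statistics (updating the
#'   returned state) and dropout is active; if `FALSE`, running statistics
#'   are used and the pass is deterministic.
#' @return List with `embeddings` (`n_graphs x d`), `logits`
#'   (`n_graphs x 2`), `state` (possibly updated) and `cache` (intermediates
#'   for [encoder_backward()]).
#' @export
encoder_forward <- function(config, params, state = NULL, batch,
                            training = FALSE) {
  if (is.null(state)) state <- init_encoder_state(config)
  L <- config$n_layers
  N <- batch$n_nodes
  src <- batch$edge_index[1, ]; dst <- batch$edge_index[2, ]
  et <- batch$edge_features[, 1]; ed <- batch$edge_features[, 2]

  x <- params$atom_z[batch$node_features[, 1], , drop = FALSE] +
    params$atom_chi[batch$node_features[, 2], , drop = FALSE]

  layer_caches <- vector("list", L)
  layer_out <- vector("list", L)
  inp <- x
  for (l in seq_len(L)) {
    p <- sprintf("l%d.", l)
    eps <- params[[paste0(p, "eps")]][1, 1]
    if (length(src) > 0L) {
      msg <- inp[src, , drop = FALSE] +
        params[[paste0(p, "edge_type")]][et, , drop = FALSE] +
        params[[paste0(p, "edge_dir")]][ed, , drop = FALSE]
      agg <- scatter_sum(msg, dst, N)
    } else {
      agg <- matrix(0, N, config$hidden_dim)
    }
    a <- (1 + eps) * inp + agg
    z1 <- a %*% params[[paste0(p, "W1")]] +
      rep(params[[paste0(p, "b1")]], each = N)
    r <- relu(z1)
    z2 <- r %*% params[[paste0(p, "W2")]] +
      rep(params[[paste0(p, "b2")]], each = N)

    if (training) {
      mu <- colMeans(z2)
      v <- col_vars_biased(z2)
      state$bn_mean[[l]] <- (1 - state$momentum) * state$bn_mean[[l]] +
        state$momentum * mu
      state$bn_var[[l]] <- (1 - state$momentum) * state$bn_var[[l]] +
        state$momentum * v
    } else {
      mu <- state$bn_mean[[l]]
      v <- state$bn_var[[l]]
    }
    inv_sd <- 1 / sqrt(v + .BN_EPS)
    xhat <- sweep(z2, 2, mu) %*% diag(inv_sd, length(inv_sd))
    out <- xhat %*% diag(as.numeric(params[[paste0(p, "bn_gamma")]])) +
      rep(params[[paste0(p, "bn_beta")]], each = N)

    mask <- NULL
    if (l < L) {
      nxt <- relu(out)
      if (training && config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(nxt), 1, 1 - config$dropout),
                       nrow(nxt)) / (1 - config$dropout)
        nxt <- nxt * mask
      }
    } else {
      nxt <- out
    }
    layer_caches[[l]] <- list(inp = inp, a = a, z1 = z1, r = r, z2 = z2,
                              mu = mu, v = v, inv_sd = inv_sd, xhat = xhat,
                              out = out, mask = mask)
    layer_out[[l]] <- out
    inp <- nxt
  }

  readouts <- lapply(layer_out, function(h) scatter_sum(h, batch$graph_id,
                                                        batch$n_graphs))
  emb <- switch(config$jk_mode,
    sum = Reduce(`+`, readouts),
    last = readouts[[L]],
    max = {
      m <- readouts[[1]]
      for (l in seq_len(L)[-1]) m <- pmax(m, readouts[[l]])
      m
    },
    concat = do.call(cbind, readouts)
  )
  logits <- emb %*% params$head.W + rep(params$head.b, each = batch$n_graphs)

  if (any(!is.finite(emb)) || any(!is.finite(logits))) {
    stop("encoder_forward(): non-finite values in embeddings/logits")
  }

  list(embeddings = emb, logits = logits, state = state,
       cache = list(batch = batch, layers = layer_caches,
                    readouts = readouts, emb = emb, training = training))
}

# Reverse pass: given dL/d embeddings and dL/d logits, return the gradient of
# every trainable parameter (same flat names/shapes as the parameter list).
encoder_backward <- function(config, params, cache, d_emb, d_logits) {
  L <- config$n_layers
  batch <- cache$batch
  N <- batch$n_nodes
  G <- batch$n_graphs
  src <- batch$edge_index[1, ]; dst <- batch$edge_index[2, ]
  et <- batch$edge_features[, 1]; ed <- batch$edge_features[, 2]
  h <- config$hidden_dim

  grads <- list()

  dg <- d_logits %*% t(params$head.W) + d_emb
  grads$head.W <- t(cache$emb) %*% d_logits
  grads$head.b <- matrix(colSums(d_logits), 1)

  # gradient wrt each per-layer graph readout
  d_read <- vector("list", L)
  if (config$jk_mode == "sum") {
    for (l in seq_len(L)) d_read[[l]] <- dg
  } else if (config$jk_mode == "last") {
    for (l in seq_len(L)) d_read[[l]] <- matrix(0, G, h)
    d_read[[L]] <- dg
  } else if (config$jk_mode == "max") {
    # credit each entry to the first layer attaining the max
    m <- cache$readouts[[1]]
    arg <- matrix(1L, G, h)
    for (l in seq_len(L)[-1]) {
      upd <- cache$readouts[[l]] > m
      m[upd] <- cache$readouts[[l]][upd]
      arg[upd] <- l
    }
    for (l in seq_len(L)) d_read[[l]] <- dg * (arg == l)
  } else { # concat
    for (l in seq_len(L)) {
      d_read[[l]] <- dg[, ((l - 1) * h + 1):(l * h), drop = FALSE]
    }
  }

  d_from_above <- NULL   # gradient wrt the input of layer l+1
  for (l in rev(seq_len(L))) {
    cc <- cache$layers[[l]]
    p <- sprintf("l%d.", l)
    # node-level gradient wrt this layer's BN output
    d_out <- d_read[[l]][batch$graph_id, , drop = FALSE]
    if (!is.null(d_from_above)) {
      dn <- d_from_above
      if (!is.null(cc$mask)) dn <- dn * cc$mask
      d_out <- d_out + dn * (cc$out > 0)
    }

    # batch-norm backward
    gamma <- as.numeric(params[[paste0(p, "bn_gamma")]])
    grads[[paste0(p, "bn_gamma")]] <- matrix(colSums(d_out * cc$xhat), 1)
    grads[[paste0(p, "bn_beta")]] <- matrix(colSums(d_out), 1)
    dxhat <- d_out %*% diag(gamma, length(gamma))
    if (cache$training) {
      centred <- sweep(cc$z2, 2, cc$mu)
      dvar <- colSums(dxhat * centred) * (-0.5) * cc$inv_sd^3
      dmu <- colSums(dxhat) * (-cc$inv_sd) +
        dvar * colMeans(-2 * centred)
      dz2 <- dxhat %*% diag(cc$inv_sd, length(cc$inv_sd)) +
        sweep(2 * centred, 2, dvar / N, "*") +
        matrix(dmu / N, N, h, byrow = TRUE)
    } else {
      dz2 <- dxhat %*% diag(cc$inv_sd, length(cc$inv_sd))
    }

    # MLP backward
    grads[[paste0(p, "W2")]] <- t(cc$r) %*% dz2
    grads[[paste0(p, "b2")]] <- matrix(colSums(dz2), 1)
    dr <- dz2 %*% t(params[[paste0(p, "W2")]])
    dz1 <- dr * (cc$z1 > 0)
    grads[[paste0(p, "W1")]] <- t(cc$a) %*% dz1
    grads[[paste0(p, "b1")]] <- matrix(colSums(dz1), 1)
    da <- dz1 %*% t(params[[paste0(p, "W1")]])

    # aggregation backward
    eps <- params[[paste0(p, "eps")]][1, 1]
    grads[[paste0(p, "eps")]] <- matrix(sum(cc$inp * da), 1, 1)
    d_inp <- (1 + eps) * da
    if (length(src) > 0L) {
      da_dst <- da[dst, , drop = FALSE]
      d_inp <- d_inp + scatter_sum(da_dst, src, N)
      dims <- mol_feature_dims()
      grads[[paste0(p, "edge_type")]] <- scatter_sum(da_dst, et, dims$bond_type)
      grads[[paste0(p, "edge_dir")]] <- scatter_sum(da_dst, ed, dims$bond_dir)
    } else {
      dims <- mol_feature_dims()
      grads[[paste0(p, "edge_type")]] <- matrix(0, dims$bond_type, h)
      grads[[paste0(p, "edge_dir")]] <- matrix(0, dims$bond_dir, h)
    }
    d_from_above <- d_inp
  }

  dims <- mol_feature_dims()
  grads$atom_z <- scatter_sum(d_from_above, batch$node_features[, 1],
                              dims$atomic_num)
  grads$atom_chi <- scatter_sum(d_from_above, batch$node_features[, 2],
                                dims$chirality)

  grads[names(params)]
}

#' Embed a batch of molecular graphs
#'
#' Deterministic evaluation-mode pass: maps graphs to fixed-length
#' embeddings and two-class logits.
#'
#' @param config An [encoder_config()].
#' @param graphs Non-empty list of [parse_smiles()] graphs.
#' @param parameters Parameter list (e.g. from [init_encoder_params()]).
#' @param state Optional batch-norm state (fresh state if `NULL`).
#' @param labels Optional integer 0/1 labels carried along with the batch.
#' @return An `embedding_batch`: list with `embeddings` (`n x d`), `logits`
#'   (`n x 2`) and `labels` (or `NULL`).
#' @export
encode <- function(config, graphs, parameters, state = NULL, labels = NULL) {
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(graphs), all(labels %in% c(0L, 1L)))
  }
  fw <- encoder_forward(config, parameters, state, pack_graphs(graphs),
                        training = FALSE)
  structure(list(embeddings = fw$embeddings, logits = fw$logits,
                 labels = labels),
            class = "embedding_batch")
}

#' Save encoder parameters to a checkpoint archive
#'
#' The archive is a serialized flat name -> matrix map (RDS) together with
#' the batch-norm state and a format tag; the layout is stable across package
#' versions.
#'
#' @param params Parameter list.
#' @param path Output file path.
#' @param state Optional batch-norm running statistics to store alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path, state = NULL) {
  saveRDS(list(format = "molfewshot-checkpoint-v1", params = params,
               state = state), path)
  invisible(path)
}

#' Load encoder parameters from a checkpoint archive
#'
#' Shape and name matching is strict for the encoder trunk. The linear
#' classification head may be absent from the archive, in which case it is
#' freshly initialized and reported via the `fresh_head` flag (never
#' silently).
#'
#' @param config An [encoder_config()] the archive must match.
#' @param path Path to an archive written by [save_checkpoint()].
#' @param seed Seed for initializing a missing head.
#' @return List with `params`, `state` (may be `NULL`) and `fresh_head`
#'   (logical).
#' @export
load_checkpoint <- function(config, path, seed = 1L) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' does not exist", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop(sprintf(
                    "checkpoint '%s' is corrupt: %s", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "molfewshot-checkpoint-v1")) {
    stop(sprintf("checkpoint '%s' is not a recognised parameter archive", path))
  }
  shapes <- encoder_param_shapes(config)
  trunk <- setdiff(names(shapes), .HEAD_NAMES)
  missing_trunk <- setdiff(trunk, names(obj$params))
  if (length(missing_trunk) > 0L) {
    stop(sprintf("checkpoint '%s' is missing trunk parameters: %s", path,
                 paste(missing_trunk, collapse = ", ")))
  }
  mismatched <- Filter(function(nm) {
    !identical(dim(as.matrix(obj$params[[nm]])), as.integer(shapes[[nm]]))
  }, intersect(names(obj$params), names(shapes)))
  if (length(mismatched) > 0L) {
    stop(sprintf(
      "checkpoint '%s' does not match the configuration; mismatched shapes: %s",
      path, paste(mismatched, collapse = ", ")))
  }
  params <- obj$params[intersect(names(shapes), names(obj$params))]
  fresh_head <- !all(.HEAD_NAMES %in% names(params))
  if (fresh_head) {
    fresh <- init_encoder_params(config, seed)
    for (nm in setdiff(.HEAD_NAMES, names(params))) params[[nm]] <- fresh[[nm]]
    message(sprintf(
      "checkpoint '%s': classification head absent; freshly initialized", path))
  }
  list(params = params[names(shapes)], state = obj$state,
       fresh_head = fresh_head)
}
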