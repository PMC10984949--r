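# Independent brute-force oracles. These deliberately share no code with the
# package implementation: explicit double loops, explicit sorting.

# contrastive loss by explicit pair enumeration; fraction = NULL -> static
oracle_contrastive <- function(emb, labels, m, fraction = NULL,
                               hinge = "squared_distance") {
  n <- nrow(emb)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((emb[i, ] - emb[j, ])^2))
      pairs[[length(pairs) + 1]] <- list(i = i, j = j, d = d,
                                         same = labels[i] == labels[j])
    }
  }
  selected <- rep(TRUE, length(pairs))
  if (!is.null(fraction)) {
    neg_idx <- which(!vapply(pairs, `[[`, logical(1), "same"))
    keep <- integer(0)
    if (length(neg_idx) > 0 && fraction > 0) {
      dd <- vapply(pairs[neg_idx], `[[`, numeric(1), "d")
      ii <- vapply(pairs[neg_idx], `[[`, numeric(1), "i")
      jj <- vapply(pairs[neg_idx], `[[`, numeric(1), "j")
      ord <- order(dd, ii, jj)
      keep <- neg_idx[ord[seq_len(ceiling(fraction * length(neg_idx)))]]
    }
    selected[setdiff(which(!vapply(pairs, `[[`, logical(1), "same")), keep)] <- FALSE
  }
  total <- 0
  for (k in seq_along(pairs)) {
    if (!selected[k]) next
    p <- pairs[[k]]
    term <- if (p$same) {
      p$d^2
    } else if (hinge == "squared_distance") {
      max(0, m - p$d^2)
    } else {
      max(0, m - p$d)^2
    }
    total <- total + term
  }
  total
}

# AUC by explicit concordant-pair counting, ties half credit
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) s <- s + 1
      else if (scores[i] == scores[j]) s <- s + 0.5
    }
  }
  s / (length(pos) * length(neg))
}

# brute-force labelled (non-induced) subgraph containment by recursive
# assignment of motif vertices to molecule vertices
oracle_contains_motif <- function(elements, edges, motif) {
  n <- length(elements)
  m <- length(motif$elements)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      adj[edges[e, 1], edges[e, 2]] <- TRUE
      adj[edges[e, 2], edges[e, 1]] <- TRUE
    }
  }
  madj <- matrix(FALSE, m, m)
  for (e in seq_len(nrow(motif$edges))) {
    madj[motif$edges[e, 1], motif$edges[e, 2]] <- TRUE
    madj[motif$edges[e, 2], motif$edges[e, 1]] <- TRUE
  }
  assign_next <- function(mapping) {
    k <- length(mapping) + 1
    if (k > m) return(TRUE)
    for (v in seq_len(n)) {
      if (v %in% mapping) next
      if (elements[v] != motif$elements[k]) next
      ok <- TRUE
      for (prev in seq_len(k - 1)) {
        if (madj[prev, k] && !adj[mapping[prev], v]) { ok <- FALSE; break }
      }
      if (ok && assign_next(c(mapping, v))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}

# undirected edge list (i < j) of a parsed molecular graph
mol_graph_edges <- function(g) {
  if (ncol(g$edge_index) == 0) return(matrix(integer(0), ncol = 2))
  und <- g$edge_index[, g$edge_index[1, ] < g$edge_index[2, ], drop = FALSE]
  t(und)
}

# apply a node permutation to a parsed graph (perm[i] = new index of node i)
permute_mol_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$node_features <- g$node_features[inv, , drop = FALSE]
  g2$elements <- g$elements[inv]
  g2$aromatic <- g$aromatic[inv]
  if (ncol(g$edge_index) > 0) {
    g2$edge_index <- matrix(perm[g$edge_index], nrow = 2)
  }
  g2
}

# small deterministic dev family shared by several test files
dev_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_task_family(synthetic_spec(
        n_tasks = 6L, n_molecules_per_task = 60L, positive_fraction = 0.25,
        motif_size = 3L, seed = 424L, n_test_tasks = 2L))
    }
    cache
  }
})
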