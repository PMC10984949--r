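# Synthetic motif-labelled molecular task families.
#
# Each task carries a secret structural motif: a connected labelled path of
# heteroatoms over the shared atom vocabulary. A molecule is positive for a
# task iff it contains that motif as a (non-induced) labelled subgraph.
# Background molecules are random valence-legal trees, optionally closed
# into a ring; they are carbon-dominated so that heteroatom motifs are rare
# by chance, which makes the positive fraction controllable from extreme
# imbalance (~1%) to near-balance. Molecules are emitted as SMILES so the
# real parsing path is exercised end to end — the generator never bypasses
# production code.

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, F = 1L, Cl = 1L,
              Br = 1L, I = 1L)

#' Specification of a synthetic task family
#'
#' @param n_tasks Number of binary tasks.
#' @param n_molecules_per_task Molecules generated for each task.
#' @param positive_fraction Target positive fraction per task: a scalar, or a
#'   length-2 range from which each task draws its own fraction (how the
#'   imbalance profiles of real multi-task collections are emulated).
#' @param atom_vocabulary Element symbols; must include `"C"` plus at least
#'   two heteroatoms (motifs are built from the heteroatoms).
#' @param motif_size Atoms per motif (>= 2).
#' @param seed Integer seed; the whole family is deterministic in it.
#' @param size_range Range of molecule sizes (atom counts).
#' @param ring_prob Probability a molecule is closed into a ring.
#' @param carbon_bias Probability mass on carbon when sampling background
#'   atoms.
#' @param n_test_tasks Tasks reserved for meta-testing (default: 25% of
#'   tasks, rounded up).
#' @param cliff_pairs If `TRUE`, each task additionally receives a few
#'   activity-cliff pairs: a positive molecule together with a near-identical
#'   copy whose motif is broken by a single atom swap.
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tasks = 10L, n_molecules_per_task = 100L,
                           positive_fraction = 0.2,
                           atom_vocabulary = c("C", "N", "O", "S", "P"),
                           motif_size = 3L, seed = 1L,
                           size_range = c(8L, 18L), ring_prob = 0.3,
                           carbon_bias = 0.7, n_test_tasks = NULL,
                           cliff_pairs = FALSE) {
  n_tasks <- as.integer(n_tasks)
  n_molecules_per_task <- as.integer(n_molecules_per_task)
  motif_size <- as.integer(motif_size)
  stopifnot(n_tasks >= 1L, n_molecules_per_task >= 4L, motif_size >= 2L,
            all(positive_fraction > 0), all(positive_fraction < 1),
            length(positive_fraction) %in% c(1L, 2L),
            length(size_range) == 2L, size_range[1] >= motif_size + 1L,
            ring_prob >= 0, ring_prob <= 1, carbon_bias > 0, carbon_bias < 1)
  unknown <- setdiff(atom_vocabulary, names(.VALENCE))
  if (length(unknown) > 0L) {
    stop(sprintf("unsupported element(s) in atom_vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  }
  hetero <- setdiff(atom_vocabulary, "C")
  hetero <- hetero[.VALENCE[hetero] >= 2L]   # motif interiors need valence >= 2
  if (!"C" %in% atom_vocabulary || length(hetero) < 2L) {
    stop("atom_vocabulary must contain 'C' and at least two heteroatoms of valence >= 2")
  }
  if (is.null(n_test_tasks)) n_test_tasks <- ceiling(0.25 * n_tasks)
  n_test_tasks <- as.integer(n_test_tasks)
  if (n_test_tasks < 1L || n_test_tasks >= n_tasks) {
    stop("n_test_tasks must leave at least one training task")
  }
  structure(list(n_tasks = n_tasks,
                 n_molecules_per_task = n_molecules_per_task,
                 positive_fraction = positive_fraction,
                 atom_vocabulary = atom_vocabulary, motif_size = motif_size,
                 seed = as.integer(seed), size_range = as.integer(size_range),
                 ring_prob = ring_prob, carbon_bias = carbon_bias,
                 n_test_tasks = n_test_tasks, cliff_pairs = isTRUE(cliff_pairs)),
            class = "synthetic_spec")
}

#' Imbalance-profile presets for the synthetic generator
#'
#' `"imbalanced"` draws per-task positive fractions from 0.01-0.2 (the
#' extreme-imbalance regime of screening collections); `"balanced"` from
#' 0.3-0.6.
#'
#' @param profile `"imbalanced"` or `"balanced"`.
#' @param ... Passed on to [synthetic_spec()].
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(profile = c("imbalanced", "balanced"), ...) {
  profile <- match.arg(profile)
  frac <- if (profile == "imbalanced") c(0.01, 0.2) else c(0.3, 0.6)
  args <- list(...)
  args$positive_fraction <- frac
  if (is.null(args$n_molecules_per_task) && profile == "imbalanced") {
    args$n_molecules_per_task <- 300L   # keep >= 2 positives at 1%
  }
  do.call(synthetic_spec, args)
}

# ---- raw construction graphs (element symbols + undirected edge list) ------

new_construction <- function(elements, edges) {
  list(elements = elements,
       edges = matrix(as.integer(edges), ncol = 2,
                      dimnames = list(NULL, c("a", "b"))))
}

free_valence <- function(mol) {
  deg <- tabulate(c(mol$edges[, 1], mol$edges[, 2]), length(mol$elements))
  .VALENCE[mol$elements] - deg
}

# grow a random valence-legal tree on top of `mol` until `n_atoms` atoms
grow_molecule <- function(mol, n_atoms, vocab, probs) {
  while (length(mol$elements) < n_atoms) {
    fv <- free_valence(mol)
    anchors <- which(fv >= 1L)
    if (length(anchors) == 0L) break   # fully saturated; stop short
    anchor <- if (length(anchors) == 1L) anchors else sample(anchors, 1L)
    el <- sample(vocab, 1L, prob = probs)
    mol$elements <- c(mol$elements, el)
    mol$edges <- rbind(mol$edges, c(anchor, length(mol$elements)))
  }
  mol
}

maybe_close_ring <- function(mol, ring_prob) {
  if (stats::runif(1) >= ring_prob) return(mol)
  fv <- free_valence(mol)
  open <- which(fv >= 1L)
  if (length(open) < 2L) return(mol)
  adj <- paste(mol$edges[, 1], mol$edges[, 2])
  cand <- utils::combn(open, 2L)
  ok <- !(paste(cand[1, ], cand[2, ]) %in% adj |
            paste(cand[2, ], cand[1, ]) %in% adj)
  cand <- cand[, ok, drop = FALSE]
  if (ncol(cand) == 0L) return(mol)
  pick <- cand[, sample.int(ncol(cand), 1L)]
  mol$edges <- rbind(mol$edges, pick)
  mol
}

random_background <- function(n_atoms, vocab, probs, ring_prob) {
  el0 <- sample(vocab, 1L, prob = probs)
  mol <- new_construction(el0, matrix(integer(0), ncol = 2))
  mol <- grow_molecule(mol, n_atoms, vocab, probs)
  maybe_close_ring(mol, ring_prob)
}

planted_molecule <- function(motif, n_atoms, vocab, probs, ring_prob) {
  m <- length(motif$elements)
  mol <- new_construction(motif$elements, motif$edges)
  mol <- grow_molecule(mol, n_atoms, vocab, probs)
  maybe_close_ring(mol, ring_prob)
}

# ---- SMILES emission -------------------------------------------------------

# DFS writer over the construction graph: spanning-tree bonds become the
# string skeleton, non-tree bonds become ring-closure digits. All bonds are
# single; elements are restricted to the organic subset so symbols are
# written bare.
construction_to_smiles <- function(mol) {
  n <- length(mol$elements)
  adj <- vector("list", n)
  if (nrow(mol$edges) > 0L) {
    for (e in seq_len(nrow(mol$edges))) {
      a <- mol$edges[e, 1]; b <- mol$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  visited <- logical(n)
  ring_digit <- new.env(parent = emptyenv())
  ring_digit$next_id <- 1L
  ring_marks <- vector("list", n)   # digits to print after each atom symbol
  tree_children <- vector("list", n)

  # iterative DFS assigning tree edges and ring closures
  order_visited <- integer(0)
  stack <- list(c(1L, 0L))
  seen_edge <- character(0)
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1]; parent <- top[2]
    if (visited[v]) next
    visited[v] <- TRUE
    order_visited <- c(order_visited, v)
    if (parent > 0L) tree_children[[parent]] <- c(tree_children[[parent]], v)
    for (u in rev(adj[[v]])) {
      if (!visited[u]) {
        stack[[length(stack) + 1L]] <- c(u, v)
      } else if (u != parent) {
        key <- paste(min(u, v), max(u, v))
        if (!key %in% seen_edge) {
          seen_edge <- c(seen_edge, key)
          id <- ring_digit$next_id
          ring_digit$next_id <- id + 1L
          tag <- if (id <= 9L) as.character(id) else sprintf("%%%02d", id)
          ring_marks[[u]] <- c(ring_marks[[u]], tag)
          ring_marks[[v]] <- c(ring_marks[[v]], tag)
        }
      }
    }
  }
  if (!all(visited)) stop("construction graph is disconnected")

  emit <- function(v) {
    out <- paste0(mol$elements[[v]], paste(ring_marks[[v]], collapse = ""))
    kids <- tree_children[[v]]
    if (length(kids) > 0L) {
      subs <- vapply(kids, emit, character(1))
      if (length(subs) > 1L) {
        out <- paste0(out, paste0("(", subs[-length(subs)], ")",
                                  collapse = ""), subs[length(subs)])
      } else {
        out <- paste0(out, subs)
      }
    }
    out
  }
  emit(1L)
}

# ---- motif machinery -------------------------------------------------------

#' Enumerate candidate motifs over a vocabulary
#'
#' Motifs are labelled heteroatom paths of `motif_size` atoms (element
#' sequences, deduplicated up to reversal).
#'
#' @param atom_vocabulary Element symbols (carbon is excluded from motifs).
#' @param motif_size Path length in atoms.
#' @return List of motifs, each a list with `elements` and `edges`.
#' @export
candidate_motifs <- function(atom_vocabulary, motif_size) {
  hetero <- setdiff(atom_vocabulary, "C")
  hetero <- hetero[.VALENCE[hetero] >= 2L]
  seqs <- do.call(expand.grid,
                  c(rep(list(hetero), motif_size),
                    list(stringsAsFactors = FALSE)))
  keys <- apply(seqs, 1, function(s) {
    fwd <- paste(s, collapse = "-")
    rev_ <- paste(rev(s), collapse = "-")
    min(fwd, rev_)
  })
  seqs <- seqs[!duplicated(keys), , drop = FALSE]
  lapply(seq_len(nrow(seqs)), function(i) {
    el <- as.character(unlist(seqs[i, ]))
    edges <- cbind(seq_len(motif_size - 1L), 2:motif_size)
    list(elements = el, edges = edges,
         label = paste(el, collapse = "-"))
  })
}

# element-coloured non-induced subgraph containment (VF2)
.containment_igraph <- function(elements, edges, motif) {
  if (nrow(edges) == 0L) return(FALSE)
  all_el <- sort(unique(c(elements, motif$elements)))
  target <- igraph::graph_from_edgelist(edges, directed = FALSE)
  target <- igraph::add_vertices(target,
                                 max(0L, length(elements) -
                                       igraph::vcount(target)))
  pattern <- igraph::graph_from_edgelist(motif$edges, directed = FALSE)
  # subgraph_isomorphic(pattern, target) forwards to
  # graph.subisomorphic.vf2(target, pattern): color1 belongs to the target
  igraph::subgraph_isomorphic(pattern, target, method = "vf2",
                              vertex.color1 = match(elements, all_el),
                              vertex.color2 = match(motif$elements, all_el))
}

#' Test whether a molecular graph contains a motif
#'
#' Non-induced labelled subgraph containment on element symbols and
#' connectivity (bond orders are not compared), via VF2 matching.
#'
#' @param graph A [parse_smiles()] graph, or a raw construction list with
#'   `elements` and `edges`.
#' @param motif A motif from [candidate_motifs()].
#' @return Logical.
#' @export
contains_motif <- function(graph, motif) {
  if (inherits(graph, "mol_graph")) {
    und <- graph$edge_index[, graph$edge_index[1, ] < graph$edge_index[2, ],
                            drop = FALSE]
    .containment_igraph(graph$elements, t(und), motif)
  } else {
    .containment_igraph(graph$elements, graph$edges, motif)
  }
}

# ---- family generation -----------------------------------------------------

#' Generate a synthetic motif-labelled task family
#'
#' Produces a multi-task table in which each task owns its molecules (rows of
#' other tasks are unlabeled for it), together with a task split reserving
#' `n_test_tasks` tasks for meta-testing. Every molecule's label equals the
#' result of an explicit motif-containment search: planted molecules are
#' verified to contain the task motif and background molecules are resampled
#' until motif-free, so the realized positive fraction matches the target
#' exactly (up to rounding).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [task_table()]), `split` (a [task_split()])
#'   and `motifs` (the per-task secret motifs).
#' @export
generate_task_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  run_seeded(spec$seed, {
    motifs_all <- candidate_motifs(spec$atom_vocabulary, spec$motif_size)
    if (length(motifs_all) < spec$n_tasks) {
      stop(sprintf(
        "infeasible spec: only %d distinct motifs available for %d tasks (enlarge the vocabulary or motif size)",
        length(motifs_all), spec$n_tasks))
    }
    motifs <- motifs_all[sample.int(length(motifs_all), spec$n_tasks)]
    vocab <- spec$atom_vocabulary
    hetero <- setdiff(vocab, "C")
    probs <- ifelse(vocab == "C", spec$carbon_bias,
                    (1 - spec$carbon_bias) / length(hetero))

    task_names <- sprintf("task_%02d", seq_len(spec$n_tasks))
    n <- spec$n_molecules_per_task
    all_smiles <- character(0)
    label_cols <- list()

    for (ti in seq_len(spec$n_tasks)) {
      motif <- motifs[[ti]]
      frac <- if (length(spec$positive_fraction) == 2L) {
        stats::runif(1, spec$positive_fraction[1], spec$positive_fraction[2])
      } else spec$positive_fraction
      n_pos <- max(2L, round(frac * n))
      n_neg <- n - n_pos
      if (n_neg < 2L) {
        stop(sprintf("infeasible spec: positive fraction %.3f leaves %d negatives",
                     frac, n_neg))
      }
      smiles <- character(n)
      labels <- integer(n)
      for (i in seq_len(n)) {
        want_pos <- i <= n_pos
        ok <- FALSE
        for (try in seq_len(100L)) {
          size <- sample(spec$size_range[1]:spec$size_range[2], 1L)
          mol <- if (want_pos) {
            planted_molecule(motif, size, vocab, probs, spec$ring_prob)
          } else {
            random_background(size, vocab, probs, spec$ring_prob)
          }
          if (contains_motif(mol, motif) == want_pos) {
            smiles[i] <- construction_to_smiles(mol)
            labels[i] <- as.integer(want_pos)
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop(sprintf(
            "infeasible spec: could not generate a %s molecule for task '%s' (motif %s)",
            if (want_pos) "positive" else "motif-free", task_names[ti],
            motif$label))
        }
      }
      if (spec$cliff_pairs) {
        # replace the last few negatives with broken-motif copies of positives
        n_cliff <- min(3L, n_pos, n_neg)
        for (j in seq_len(n_cliff)) {
          for (try in seq_len(100L)) {
            size <- sample(spec$size_range[1]:spec$size_range[2], 1L)
            mol <- planted_molecule(motif, size, vocab, probs, spec$ring_prob)
            swap <- sample(seq_along(motif$elements), 1L)
            mol$elements[swap] <- "C"
            if (!contains_motif(mol, motif)) {
              smiles[n_pos + j] <- construction_to_smiles(mol)
              labels[n_pos + j] <- 0L
              break
            }
          }
        }
      }
      perm <- sample.int(n)
      smiles <- smiles[perm]; labels <- labels[perm]
      col <- rep(NA_integer_, spec$n_tasks * n)
      col[(ti - 1L) * n + seq_len(n)] <- labels
      label_cols[[task_names[ti]]] <- col
      all_smiles <- c(all_smiles, smiles)
    }

    table <- task_table(all_smiles,
                        as.data.frame(label_cols, check.names = FALSE))
    n_train <- spec$n_tasks - spec$n_test_tasks
    split <- task_split(task_names[seq_len(n_train)],
                       task_names[(n_train + 1L):spec$n_tasks])
    list(table = table, split = split, motifs = motifs)
  })
}

#' Hand-curated SMILES fixtures with verified atom/bond counts
#'
#' A small reference set (hydrogens implicit) used to exercise the SMILES
#' parser: each row gives a molecule, its heavy-atom count and its bond
#' count.
#'
#' @return Data frame with columns `name`, `smiles`, `atoms`, `bonds`.
#' @export
fixture_smiles <- function() {
  data.frame(
    name = c("methane", "ethanol", "benzene", "pyridine", "isopropanol",
             "acetic acid", "cyclohexane", "alanine", "dichloromethane",
             "naphthalene", "tert-butanol", "L-alanine", "carbon dioxide",
             "pyrrole", "acetonitrile"),
    smiles = c("C", "CCO", "c1ccccc1", "c1ccncc1", "CC(C)O", "CC(=O)O",
               "C1CCCCC1", "CC(N)C(=O)O", "ClCCl", "c1ccc2ccccc2c1",
               "CC(C)(C)O", "C[C@@H](N)C(=O)O", "O=C=O", "c1cc[nH]c1",
               "CC#N"),
    atoms = c(1L, 3L, 6L, 6L, 4L, 4L, 6L, 6L, 3L, 10L, 5L, 6L, 3L, 5L, 3L),
    bonds = c(0L, 2L, 6L, 6L, 3L, 3L, 6L, 5L, 2L, 11L, 4L, 5L, 2L, 5L, 2L),
    stringsAsFactors = FALSE
  )
}
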