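# SMILES -> attributed molecular graph.
#
# The featurization is deliberately minimal: two categorical codes per atom
# (atomic number, chirality tag) and two per bond (bond type, bond direction).
# This is the feature set used by the attribute-masking pretrained GIN
# lineage, so externally pretrained checkpoints remain interchangeable.
# Hydrogens are implicit and never become nodes.

# Atomic numbers for the elements the parser accepts. Two-letter symbols are
# matched greedily before one-letter ones.
.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Ti = 22, Cr = 24, Mn = 25, Fe = 26, Co = 27, Ni = 28,
  Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, Zr = 40, Mo = 42, Ru = 44,
  Rh = 45, Pd = 46, Ag = 47, Cd = 48, Sn = 50, Sb = 51, Te = 52, I = 53,
  Pt = 78, Au = 79, Hg = 80, Pb = 82, Bi = 83
)

.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s", "se", "as")

# Categorical vocabulary sizes used by the encoder's embedding tables.
# chirality: 1 = none, 2 = counter-clockwise (@), 3 = clockwise (@@), 4 = other
# bond type: 1 = single, 2 = double, 3 = triple, 4 = aromatic
# bond direction: 1 = none, 2 = end-up (/), 3 = end-down (\)

#' Feature vocabulary sizes of the molecular-graph featurization
#'
#' @return Named list with the number of categories for each of the four
#'   categorical feature columns: `atomic_num` (118), `chirality` (4),
#'   `bond_type` (4), `bond_dir` (3).
#' @export
mol_feature_dims <- function() {
  list(atomic_num = 118L, chirality = 4L, bond_type = 4L, bond_dir = 3L)
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Converts a SMILES string into the graph representation consumed by the
#' encoder: per-atom categorical codes (atomic number, chirality tag) and
#' per-bond codes (bond type, bond direction), with every bond stored in both
#' directions. Hydrogens are implicit. Parsing is deterministic; a
#' structure-invariant canonical key (Weisfeiler-Lehman refinement hash) is
#' attached for deduplication while the original string is retained.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `mol_graph`: a list with
#'   \describe{
#'     \item{node_features}{integer matrix, `n_atoms x 2` (atomic number,
#'       chirality code)}
#'     \item{edge_index}{integer matrix, `2 x n_edges`, 1-based endpoints;
#'       each bond appears in both directions}
#'     \item{edge_features}{integer matrix, `n_edges x 2` (bond type,
#'       bond direction)}
#'     \item{smiles}{the input string}
#'     \item{elements, aromatic}{per-atom element symbols and aromaticity
#'       flags (convenience fields for motif machinery)}
#'     \item{canonical_key}{structure hash used for deduplication}
#'   }
#' @examples
#' g <- parse_smiles("CCO")
#' g$node_features
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("parse_smiles(): 'smiles' must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  fail <- function(msg, pos = NA_integer_) {
    at <- if (is.na(pos)) "" else sprintf(" at position %d", pos)
    stop(sprintf("invalid SMILES '%s'%s: %s", smiles, at, msg), call. = FALSE)
  }

  atoms_z <- integer(0)
  atoms_chi <- integer(0)
  atoms_sym <- character(0)
  atoms_aromatic <- logical(0)
  bond_a <- integer(0); bond_b <- integer(0)
  bond_type <- integer(0); bond_dir <- integer(0)

  prev <- NA_integer_           # atom awaiting the next bond
  stack <- integer(0)           # branch stack
  pending_type <- NA_integer_   # explicit bond symbol before next atom
  pending_dir <- 1L
  rings <- list()               # ring-closure number -> c(atom, type, dir)

  add_atom <- function(sym, aromatic, chi) {
    z <- unname(.ELEMENTS[sym])
    if (is.na(z)) fail(sprintf("unknown element '%s'", sym))
    atoms_z[[length(atoms_z) + 1L]] <<- as.integer(z)
    atoms_chi[[length(atoms_chi) + 1L]] <<- chi
    atoms_sym[[length(atoms_sym) + 1L]] <<- sym
    atoms_aromatic[[length(atoms_aromatic) + 1L]] <<- aromatic
    length(atoms_z)
  }

  add_bond <- function(a, b, type, dir) {
    if (a == b) fail("self-bond")
    bond_a[[length(bond_a) + 1L]] <<- a
    bond_b[[length(bond_b) + 1L]] <<- b
    bond_type[[length(bond_type) + 1L]] <<- type
    bond_dir[[length(bond_dir) + 1L]] <<- dir
  }

  resolve_type <- function(explicit, a, b) {
    if (!is.na(explicit)) return(explicit)
    if (atoms_aromatic[[a]] && atoms_aromatic[[b]]) 4L else 1L
  }

  on_new_atom <- function(idx) {
    if (!is.na(prev)) {
      add_bond(prev, idx, resolve_type(pending_type, prev, idx), pending_dir)
    } else if (!is.na(pending_type) || pending_dir != 1L) {
      fail("bond symbol with no preceding atom")
    }
    prev <<- idx
    pending_type <<- NA_integer_
    pending_dir <<- 1L
  }

  close_ring <- function(num, pos) {
    key <- as.character(num)
    if (is.na(prev)) fail("ring closure before any atom", pos)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- c(prev, pending_type, pending_dir)
    } else {
      open <- rings[[key]]
      type_open <- open[[2]]; type_here <- pending_type
      if (!is.na(type_open) && !is.na(type_here) && type_open != type_here) {
        fail(sprintf("conflicting bond orders on ring closure %s", key), pos)
      }
      type <- if (!is.na(type_here)) type_here else type_open
      dir <- if (pending_dir != 1L) pending_dir else open[[3]]
      add_bond(open[[1]], prev, resolve_type(type, open[[1]], prev), dir)
      rings[[key]] <<- NULL
    }
    pending_type <<- NA_integer_
    pending_dir <<- 1L
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) fail("unmatched '['", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      # [isotope? symbol chiral? Hcount? charge? map?]
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) fail(sprintf("cannot parse bracket atom [%s]", body), i)
      sym <- m[[3]]
      aromatic <- sym %in% .AROMATIC_OK
      if (aromatic) {
        sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      }
      # "Hn" inside a bracket is a hydrogen count unless the symbol IS H
      if (sym == "H" && nchar(m[[2]]) == 0L && nzchar(m[[4]])) {
        fail(sprintf("cannot parse bracket atom [%s]", body), i)
      }
      chi <- if (identical(m[[4]], "@")) 2L else if (identical(m[[4]], "@@")) 3L else 1L
      idx <- add_atom(sym, aromatic, chi)
      on_new_atom(idx)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      sym <- ch
      if (i < n && ((ch == "C" && chars[[i + 1L]] == "l") ||
                    (ch == "B" && chars[[i + 1L]] == "r"))) {
        sym <- paste0(ch, chars[[i + 1L]])
        i <- i + 1L
      }
      on_new_atom(add_atom(sym, FALSE, 1L))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      on_new_atom(add_atom(toupper(ch), TRUE, 1L))
      i <- i + 1L
    } else if (ch == "-") { pending_type <- 1L; i <- i + 1L
    } else if (ch == "=") { pending_type <- 2L; i <- i + 1L
    } else if (ch == "#") { pending_type <- 3L; i <- i + 1L
    } else if (ch == ":") { pending_type <- 4L; i <- i + 1L
    } else if (ch == "/") { pending_dir <- 2L; i <- i + 1L
    } else if (ch == "\\") { pending_dir <- 3L; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch with no preceding atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'", i)
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("[0-9]", chars[[i + 1L]]) ||
          !grepl("[0-9]", chars[[i + 2L]])) fail("malformed '%' ring closure", i)
      close_ring(as.integer(paste0(chars[[i + 1L]], chars[[i + 2L]])), i)
      i <- i + 3L
    } else if (ch == ".") {
      if (!is.na(pending_type)) fail("bond symbol before '.'", i)
      prev <- NA_integer_
      i <- i + 1L
    } else {
      fail(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(stack) > 0L) fail("unmatched '('")
  if (length(rings) > 0L) {
    fail(sprintf("unclosed ring closure(s): %s",
                 paste(names(rings), collapse = ", ")))
  }
  if (length(atoms_z) == 0L) fail("no atoms")

  n_atoms <- length(atoms_z)
  node_features <- cbind(atomic_num = atoms_z, chirality = atoms_chi)
  storage.mode(node_features) <- "integer"

  nb <- length(bond_a)
  flip_dir <- function(d) ifelse(d == 2L, 3L, ifelse(d == 3L, 2L, 1L))
  if (nb > 0L) {
    edge_index <- rbind(c(bond_a, bond_b), c(bond_b, bond_a))
    edge_features <- cbind(bond_type = c(bond_type, bond_type),
                           bond_dir = c(bond_dir, flip_dir(bond_dir)))
  } else {
    edge_index <- matrix(integer(0), nrow = 2)
    edge_features <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("bond_type", "bond_dir")))
  }
  storage.mode(edge_index) <- "integer"
  storage.mode(edge_features) <- "integer"

  g <- structure(list(
    node_features = node_features,
    edge_index = edge_index,
    edge_features = edge_features,
    smiles = smiles,
    n_atoms = n_atoms,
    n_bonds = nb,
    elements = atoms_sym,
    aromatic = atoms_aromatic
  ), class = "mol_graph")
  g$canonical_key <- wl_graph_key(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s\n  %d atoms, %d bonds (%d directed edges)\n",
              x$smiles, x$n_atoms, x$n_bonds, ncol(x$edge_index)))
  invisible(x)
}

# Weisfeiler-Lehman refinement hash: a cheap structure-invariant key used to
# deduplicate molecules across differently written SMILES. Not a canonical
# SMILES; collisions are possible in principle but irrelevant at this scale.
wl_graph_key <- function(graph, rounds = 2L) {
  labels <- paste(graph$node_features[, 1], graph$node_features[, 2], sep = ".")
  src <- graph$edge_index[1, ]
  dst <- graph$edge_index[2, ]
  bt <- if (nrow(graph$edge_features) > 0) graph$edge_features[, 1] else integer(0)
  for (r in seq_len(rounds)) {
    new_labels <- labels
    for (v in seq_len(graph$n_atoms)) {
      inc <- which(dst == v)
      neigh <- sort(paste(bt[inc], labels[src[inc]], sep = ":"))
      new_labels[[v]] <- paste0(labels[[v]], "(", paste(neigh, collapse = ","), ")")
    }
    labels <- new_labels
  }
  paste0(graph$n_atoms, "b", graph$n_bonds, "|",
         paste(sort(labels), collapse = ";"))
}

# internal validator used by tests and defensive call sites
validate_mol_graph <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  if (g$n_atoms < 1L) stop("mol_graph must have at least one atom")
  if (ncol(g$edge_index) > 0L) {
    if (max(g$edge_index) > g$n_atoms || min(g$edge_index) < 1L) {
      stop("edge endpoint out of range")
    }
    fwd <- paste(g$edge_index[1, ], g$edge_index[2, ])
    rev <- paste(g$edge_index[2, ], g$edge_index[1, ])
    if (!setequal(fwd, rev)) stop("edge list is not symmetric")
  }
  dims <- mol_feature_dims()
  if (any(g$node_features[, 1] < 1L | g$node_features[, 1] > dims$atomic_num) ||
      any(g$node_features[, 2] < 1L | g$node_features[, 2] > dims$chirality)) {
    stop("node feature code outside vocabulary")
  }
  if (nrow(g$edge_features) > 0L &&
      (any(g$edge_features[, 1] < 1L | g$edge_features[, 1] > dims$bond_type) ||
       any(g$edge_features[, 2] < 1L | g$edge_features[, 2] > dims$bond_dir))) {
    stop("edge feature code outside vocabulary")
  }
  invisible(g)
}
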