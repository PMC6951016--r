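#' Atom feature schema
#'
#' Fixed, ordered description of the atom feature blocks used to build
#' node feature vectors. The blocks are: element one-hot over a fixed
#' organic vocabulary plus an "other" slot; degree one-hot (0--6);
#' implicit valence one-hot (0--6); formal charge (integer); radical
#' electron count (integer); hybridization one-hot (SP, SP2, SP3, SP3D,
#' SP3D2); aromaticity flag; total hydrogen count one-hot (0--4).
#' One-hot buckets are clipped to their stated maxima, the top bucket
#' absorbing overflow, so the total width is constant for any input.
#'
#' @param elements character vector of element symbols given their own
#'   one-hot slot; anything else maps to the trailing "other" slot.
#'   Hydrogens are implicit (heavy-atom graphs), so "H" never appears.
#' @return an object of class `atom_schema` with the ordered block
#'   widths and the total node feature width `d_node`.
#' @export
atom_feature_schema <- function(elements = c("C", "N", "O", "S", "F", "Cl",
                                             "Br", "I", "P", "B", "Si", "Se")) {
  stopifnot(is.character(elements), length(elements) >= 1, !anyDuplicated(elements))
  blocks <- list(
    atom_type        = length(elements) + 1L,  # + "other"
    degree           = 7L,                     # 0..6
    implicit_valence = 7L,                     # 0..6
    formal_charge    = 1L,                     # raw integer
    radical_electrons = 1L,                    # raw integer
    hybridization    = 5L,                     # SP SP2 SP3 SP3D SP3D2
    aromaticity      = 1L,
    total_num_h      = 5L                      # 0..4
  )
  s <- list(elements = elements, blocks = blocks,
            d_node = sum(unlist(blocks)))
  s$hash <- paste(c("v1", elements), collapse = "|")
  class(s) <- "atom_schema"
  s
}

#' @export
print.atom_schema <- function(x, ...) {
  cat("<atom_schema> d_node =", x$d_node, "\n")
  cat("  elements:", paste(x$elements, collapse = " "), "+ other\n")
  invisible(x)
}

onehot <- function(i, width) {
  # i is 0-based level; clip into [0, width-1]
  v <- numeric(width)
  v[min(max(i, 0L), width - 1L) + 1L] <- 1
  v
}

encode_atom <- function(a, schema) {
  idx <- match(a$symbol, schema$elements)
  el <- numeric(schema$blocks$atom_type)
  el[if (is.na(idx)) schema$blocks$atom_type else idx] <- 1
  c(el,
    onehot(a$degree, 7L),
    onehot(a$implicit_valence, 7L),
    a$formal_charge,
    a$radical_electrons,
    if (a$hybridization >= 1) onehot(a$hybridization - 1L, 5L) else numeric(5L),
    as.numeric(a$aromatic),
    onehot(a$total_num_h, 5L))
}

#' Featurize molecules into graphs
#'
#' Parses SMILES into heavy-atom molecular graphs with the package's
#' node feature schema and a 4-class one-hot bond feature (single,
#' double, triple, aromatic). Every bond is stored as two directed
#' edges `(v, w)` and `(w, v)` with identical bond features; atom
#' ordering follows the toolkit's canonical perception, so the result
#' is deterministic for a given input string.
#'
#' @param smiles a SMILES string (`featurize_molecule`) or character
#'   vector (`featurize_molecules`).
#' @param schema an [atom_feature_schema()].
#' @return a `mol_graph` (or list of them): `node_features`
#'   (`n_atoms x d_node`), `edge_index` (`n_edges x 2`, 1-based, pair
#'   `(tail, head)`), `edge_features` (`n_edges x 4` one-hot),
#'   `n_atoms`, and the input `smiles`.
#' @export
featurize_molecule <- function(smiles, schema = atom_feature_schema()) {
  featurize_molecules(smiles, schema)[[1L]]
}

#' @rdname featurize_molecule
#' @export
featurize_molecules <- function(smiles, schema = atom_feature_schema()) {
  res <- backend_call("perceive", smiles)
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (!isTRUE(r$ok)) {
      stop("cannot featurize ", shQuote(smiles[[i]]), ": ", r$error, call. = FALSE)
    }
    n <- r$n_atoms
    nf <- do.call(rbind, lapply(r$atoms, encode_atom, schema = schema))
    if (is.null(nf)) nf <- matrix(0, 0, schema$d_node)
    nb <- length(r$bonds)
    if (nb > 0) {
      a1 <- vapply(r$bonds, function(b) b$a1, numeric(1)) + 1L
      a2 <- vapply(r$bonds, function(b) b$a2, numeric(1)) + 1L
      cls <- vapply(r$bonds, function(b) b$bond_class, numeric(1))
      ei <- cbind(c(a1, a2), c(a2, a1))
      ef <- matrix(0, 2L * nb, 4L)
      ef[cbind(seq_len(2L * nb), rep(cls, 2L))] <- 1
    } else {
      ei <- matrix(integer(0), 0, 2)
      ef <- matrix(0, 0, 4)
    }
    g <- list(node_features = nf, edge_index = ei, edge_features = ef,
              n_atoms = as.integer(n), smiles = smiles[[i]],
              canonical_smiles = r$canonical_smiles)
    class(g) <- "mol_graph"
    g
  })
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph>", x$smiles, "-", x$n_atoms, "atoms,",
      nrow(x$edge_index), "directed edges\n")
  invisible(x)
}

edge_class_of <- function(graph) {
  if (nrow(graph$edge_features) == 0) return(integer(0))
  max.col(graph$edge_features, ties.method = "first")
}

#' Directed-edge view of a molecular graph
#'
#' Builds the index structure used by the edge-memory network. For a
#' directed edge `i = (v, w)` (tail `v`, head `w`): `reverse_index[i]`
#' is the position of `(w, v)`, and `incoming[[i]]` holds the positions
#' of the edges `(k, v)` with `k != w` -- the edges arriving at the
#' tail of `i`, excluding the reverse of `i` itself, so information
#' never flows straight back along a bond.
#'
#' @param graph a `mol_graph`.
#' @return an object of class `directed_edge_view` with fields `tails`,
#'   `heads`, `reverse_index`, `incoming`, `n_edges`.
#' @export
build_directed_edge_view <- function(graph) {
  stopifnot(inherits(graph, "mol_graph") || (!is.null(graph$edge_index)))
  ei <- graph$edge_index
  ne <- nrow(ei)
  tails <- ei[, 1L]
  heads <- ei[, 2L]
  key <- paste(tails, heads)
  rev_key <- paste(heads, tails)
  reverse_index <- match(rev_key, key)
  if (ne > 0 && anyNA(reverse_index)) {
    stop("graph is not a symmetric directed pairing: some (w,v) missing", call. = FALSE)
  }
  by_head <- split(seq_len(ne), factor(heads, levels = seq_len(graph$n_atoms)))
  incoming <- vector("list", ne)
  for (i in seq_len(ne)) {
    cand <- by_head[[tails[[i]]]]           # edges (k, v) with head = tail(i)
    incoming[[i]] <- cand[cand != reverse_index[[i]]]
  }
  structure(list(tails = tails, heads = heads,
                 reverse_index = reverse_index, incoming = incoming,
                 n_edges = ne),
            class = "directed_edge_view")
}

#' Batch molecular graphs into a disjoint union
#'
#' Stacks node and edge matrices with index offsets and records, for
#' every node, which input molecule it came from. [unbatch_graphs()]
#' inverts the operation exactly.
#'
#' @param graphs non-empty list of `mol_graph` objects.
#' @return a `mol_graph_batch`: stacked `node_features`, offset
#'   `edge_index`, stacked `edge_features`, `membership` (1-based
#'   molecule id per node), `n_mols`, `n_atoms_per_mol`, `smiles`.
#' @export
batch_graphs <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0 || inherits(graphs, "mol_graph")) {
    stop("batch_graphs() expects a non-empty list of mol_graph objects", call. = FALSE)
  }
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offs <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  ei <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edge_index
    if (nrow(e) == 0) return(matrix(integer(0), 0, 2))
    e + offs[[i]]
  }))
  b <- list(
    node_features = do.call(rbind, lapply(graphs, `[[`, "node_features")),
    edge_index = ei,
    edge_features = do.call(rbind, lapply(graphs, `[[`, "edge_features")),
    membership = rep(seq_along(graphs), times = n_atoms),
    n_atoms = sum(n_atoms),
    n_atoms_per_mol = n_atoms,
    n_mols = length(graphs),
    smiles = vapply(graphs, `[[`, character(1), "smiles")
  )
  class(b) <- c("mol_graph_batch", "mol_graph")
  b
}

#' @rdname batch_graphs
#' @param batch a `mol_graph_batch`.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "mol_graph_batch"))
  n_atoms <- batch$n_atoms_per_mol
  offs <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  emol <- batch$membership[batch$edge_index[, 1L]]
  lapply(seq_len(batch$n_mols), function(i) {
    nodes <- which(batch$membership == i)
    sel <- which(emol == i)
    g <- list(
      node_features = batch$node_features[nodes, , drop = FALSE],
      edge_index = batch$edge_index[sel, , drop = FALSE] - offs[[i]],
      edge_features = batch$edge_features[sel, , drop = FALSE],
      n_atoms = n_atoms[[i]],
      smiles = batch$smiles[[i]]
    )
    class(g) <- "mol_graph"
    g
  })
}

#' Relabel the atoms of a graph by a permutation
#'
#' Applies an atom permutation to a featurized graph: node `i` of the
#' result is node `perm[i]` of the input. Used to exercise the
#' isomorphism invariance of the models; the chemistry is unchanged.
#'
#' @param graph a `mol_graph`.
#' @param perm a permutation of `seq_len(graph$n_atoms)`.
#' @export
permute_graph <- function(graph, perm) {
  stopifnot(inherits(graph, "mol_graph"),
            length(perm) == graph$n_atoms,
            all(sort(perm) == seq_len(graph$n_atoms)))
  inv <- order(perm)  # new index of old atom j is inv[j]
  g <- graph
  g$node_features <- graph$node_features[perm, , drop = FALSE]
  if (nrow(graph$edge_index) > 0) {
    g$edge_index <- cbind(inv[graph$edge_index[, 1L]], inv[graph$edge_index[, 2L]])
  }
  g
}
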