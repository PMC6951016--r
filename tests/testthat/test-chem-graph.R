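test_that("featurization gives the expected graphs for known molecules", {
  schema <- atom_feature_schema()
  expect_equal(schema$d_node, 40L)

  eth <- featurize_molecule("CCO", schema)
  expect_equal(eth$n_atoms, 3L)
  expect_equal(nrow(eth$edge_index), 4L)              # 2 bonds, both directions
  expect_true(all(eth$edge_features[, 1] == 1))       # all single bonds
  expect_equal(dim(eth$node_features), c(3L, 40L))

  water <- featurize_molecule("O", schema)
  expect_equal(water$n_atoms, 1L)
  expect_equal(nrow(water$edge_index), 0L)

  benz <- featurize_molecule("c1ccccc1", schema)
  expect_equal(benz$n_atoms, 6L)
  expect_equal(nrow(benz$edge_index), 12L)
  expect_true(all(benz$edge_features[, 4] == 1))      # aromatic bond class
  arom_col <- length(schema$elements) + 1L + 7L + 7L + 1L + 1L + 5L + 1L
  expect_true(all(benz$node_features[, arom_col] == 1))
})

test_that("featurization rejects unparseable SMILES", {
  expect_error(featurize_molecule("not_a_smiles(("), "not_a_smiles")
})

test_that("every directed edge has its reverse with identical features", {
  for (g in fixture_graphs()) {
    if (nrow(g$edge_index) == 0) next
    dv <- build_directed_edge_view(g)
    expect_equal(dv$reverse_index[dv$reverse_index], seq_len(dv$n_edges))
    expect_equal(g$edge_features, g$edge_features[dv$reverse_index, , drop = FALSE])
    expect_true(all(g$edge_index <= g$n_atoms))
    expect_true(all(rowSums(g$edge_features) == 1))
  }
})

test_that("directed edge view excludes the reverse edge and matches degrees", {
  # linear path A-B-C (propane backbone of CCO): the message into (B,C)
  # may use (A,B) but never (C,B)
  g <- featurize_molecule("CCO")
  dv <- build_directed_edge_view(g)
  deg <- tabulate(g$edge_index[, 1L], g$n_atoms)
  for (i in seq_len(dv$n_edges)) {
    v <- dv$tails[[i]]
    expect_equal(length(dv$incoming[[i]]), deg[[v]] - 1L)
    expect_false(dv$reverse_index[[i]] %in% dv$incoming[[i]])
    # every incoming edge really arrives at the tail
    expect_true(all(dv$heads[dv$incoming[[i]]] == v))
  }
  # the middle atom of CCO has degree 2: its outgoing edges see exactly
  # one incoming edge each; terminal atoms' outgoing edges see none
  term_edges <- which(deg[dv$tails] == 1)
  expect_true(all(lengths(dv$incoming[term_edges]) == 0))

  # star centre of degree 3 (isobutane): each outgoing edge from the
  # centre sees exactly the other 2 incoming edges
  st <- featurize_molecule("CC(C)C")
  dvs <- build_directed_edge_view(st)
  centre <- which(tabulate(st$edge_index[, 1L], st$n_atoms) == 3)
  from_centre <- which(dvs$tails == centre)
  expect_true(all(lengths(dvs$incoming[from_centre]) == 2L))
  # brute-force enumeration of qualifying (k, v) pairs
  for (i in from_centre) {
    want <- which(dvs$heads == dvs$tails[[i]] &
                  dvs$tails != dvs$heads[[i]])
    expect_setequal(dvs$incoming[[i]], want)
  }
})

test_that("batching is an exact disjoint union and unbatching inverts it", {
  gs <- featurize_molecules(c("CCO", "O"))
  b <- batch_graphs(gs)
  expect_equal(b$n_atoms, 4L)
  expect_equal(b$membership, c(1L, 1L, 1L, 2L))

  single <- batch_graphs(gs[1])
  expect_equal(single$membership, c(1L, 1L, 1L))

  set.seed(7)
  gs10 <- fixture_graphs()[sample(length(fixture_graphs()), 10)]
  back <- unbatch_graphs(batch_graphs(gs10))
  for (i in seq_along(gs10)) {
    expect_identical(back[[i]]$node_features, gs10[[i]]$node_features)
    expect_equal(back[[i]]$edge_index, gs10[[i]]$edge_index)
    expect_identical(back[[i]]$edge_features, gs10[[i]]$edge_features)
  }
  expect_error(batch_graphs(list()), "non-empty")
})

test_that("atom relabeling permutes features and edges consistently", {
  set.seed(11)
  for (g in fixture_graphs()) {
    if (g$n_atoms < 2) next
    perm <- sample(g$n_atoms)
    gp <- permute_graph(g, perm)
    # equal multisets of node feature rows
    expect_equal(gp$node_features[order(perm), , drop = FALSE], g$node_features)
    # permuted edge set with preserved features
    key <- function(gg) paste(gg$edge_index[, 1], gg$edge_index[, 2],
                              max.col(gg$edge_features))
    inv <- order(perm)
    orig_key <- paste(inv[g$edge_index[, 1]], inv[g$edge_index[, 2]],
                      max.col(g$edge_features))
    expect_setequal(key(gp), orig_key)
  }
})

test_that("multi-fragment SMILES give one graph with no cross-component edges", {
  g <- featurize_molecule("CCO.CC")
  expect_equal(g$n_atoms, 5L)
  # no edge joins the two components {1,2,3} and {4,5}
  comp <- c(1, 1, 1, 2, 2)
  expect_true(all(comp[g$edge_index[, 1]] == comp[g$edge_index[, 2]]))
})

test_that("degree one-hots are consistent with bond counts", {
  schema <- atom_feature_schema()
  deg_cols <- length(schema$elements) + 1L + seq_len(7L)
  for (g in fixture_graphs()) {
    deg <- max.col(g$node_features[, deg_cols, drop = FALSE]) - 1L
    expect_equal(sum(deg), nrow(g$edge_index))  # = 2 x bond count
  }
})
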