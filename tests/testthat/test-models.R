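test_that("model_config rejects architecture/hyperparameter mismatches", {
  expect_error(model_config("selu-mpnn", att_hidden_dim = 50), "att_hidden_dim")
  expect_error(model_config("emnn", message_size = 16), "message_size")
  expect_error(model_config("ampnn", edge_embedding_size = 30), "emnn")
  cfg <- model_config("emnn")
  expect_null(cfg$message_size)
  expect_equal(cfg$edge_embedding_size, 30)
})

test_that("model configurations round-trip through the text format", {
  cfg <- model_config("ampnn", learn_rate = 3.3e-5, message_passes = 4,
                      out_layer_shrinkage = 0.37)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model_config(cfg, path)
  expect_equal(read_model_config(path), cfg)
})

test_that("summed messages match the per-node loop oracle", {
  set.seed(21)
  w <- rand_ffnn4(5, 4)
  for (g in fixture_graphs()) {
    h <- matrix(rnorm(g$n_atoms * 5, sd = 0.5), g$n_atoms, 5)
    expect_equal(mpnn_message(h, g, w), oracle_mpnn_message(h, g, w),
                 tolerance = 1e-6)
  }
  # isolated node: empty sum is the zero vector
  iso <- featurize_molecule("O")
  expect_equal(mpnn_message(matrix(rnorm(5), 1), iso, w), matrix(0, 1, 5))
  # single neighbour with f = identity: the message is the neighbour state
  path2 <- featurize_molecule("C#N")
  h2 <- matrix(rnorm(10), 2, 5)
  wid <- lapply(1:4, function(i) identity_ffnn(5))
  expect_equal(mpnn_message(h2, path2, wid), h2[c(2, 1), ], tolerance = 1e-12)
})

test_that("attention aggregation matches the explicit-softmax loop oracle", {
  set.seed(22)
  fw <- rand_ffnn4(5, 4)
  gw <- rand_ffnn4(5, 4)
  for (g in fixture_graphs()) {
    h <- matrix(rnorm(g$n_atoms * 5, sd = 0.5), g$n_atoms, 5)
    expect_equal(attention_aggregate(h, g, fw, gw),
                 oracle_ampnn_message(h, g, fw, gw), tolerance = 1e-6)
  }
  # one neighbour: softmax of a singleton is exactly 1, so m = f(h_w)
  hcn <- featurize_molecule("C#N")
  h <- matrix(rnorm(10), 2, 5)
  m <- attention_aggregate(h, hcn, fw, gw)
  expect_equal(m[1, ], as.numeric(ffnn_val(fw[[3]], h[2, ])), tolerance = 1e-10)
  # two identical neighbours, same bond class: weights 0.5/0.5
  prop <- featurize_molecule("CCC")
  hsym <- rbind(c(1, 0, 2, -1, 0.5), c(0, 1, 0, 1, 1), c(1, 0, 2, -1, 0.5))
  msym <- attention_aggregate(hsym, prop, fw, gw)
  expect_equal(msym[2, ], as.numeric(ffnn_val(fw[[1]], hsym[1, ])), tolerance = 1e-10)
})

test_that("attention weights over each neighbourhood sum to one", {
  # with f constant at 1, the weighted sum returns exactly the
  # per-element total attention weight, which must be 1 everywhere
  set.seed(23)
  gw <- rand_ffnn4(5, 4)
  f1 <- lapply(1:4, function(i) const_ffnn(5, 5, 1))
  for (g in fixture_graphs()) {
    if (nrow(g$edge_index) == 0) next
    h <- matrix(rnorm(g$n_atoms * 5), g$n_atoms, 5)
    m <- attention_aggregate(h, g, f1, gw)
    has_nb <- tabulate(g$edge_index[, 1L], g$n_atoms) > 0
    expect_equal(m[has_nb, , drop = FALSE],
                 matrix(1, sum(has_nb), 5), tolerance = 1e-6)
  }
})

test_that("gru_update implements the standard gate equations", {
  set.seed(24)
  w <- gru_weights(2, 2)
  # zero biases, zero state, zero message: zero is a fixed point
  expect_equal(gru_update(matrix(0, 3, 2), matrix(0, 3, 2), w), matrix(0, 3, 2))
  # one update from zero state is bounded by the tanh candidate
  x <- matrix(rnorm(10, sd = 3), 5, 2)
  out <- gru_update(matrix(0, 5, 2), x, w)
  expect_true(all(abs(out) < 1))
  # hand-evaluated gate computation on a 2-unit cell
  wh <- gru_weights(2, 2)
  wh$bz[] <- c(0.1, -0.2); wh$br[] <- c(0.3, 0); wh$bn[] <- c(-0.1, 0.2)
  h0 <- matrix(c(0.5, -0.3), 1)
  m0 <- matrix(c(1.0, 0.25), 1)
  expect_equal(gru_update(h0, m0, wh), oracle_gru(wh, m0, h0), tolerance = 1e-12)
  expect_error(gru_update(matrix(0, 2, 2), matrix(0, 3, 2), w))
})

test_that("edge embeddings are order-sensitive concatenations", {
  set.seed(25)
  w <- rand_ffnn(4 + 80, 6, 5)
  # ethane: both endpoints are identical CH3 carbons, so the two
  # directed embeddings of the bond coincide
  eth <- featurize_molecule("CC")
  e_eth <- emnn_edge_embed(eth, w)
  expect_equal(e_eth[1, ], e_eth[2, ])
  # C-O bond of ethanol joins distinct atoms: the two directed
  # embeddings differ for generic weights
  g <- featurize_molecule("CCO")
  e1 <- emnn_edge_embed(g, w)
  dv <- build_directed_edge_view(g)
  co <- which(dv$heads == 3)
  expect_gt(max(abs(e1[co, ] - e1[dv$reverse_index[co], ])), 1e-6)
  # zero weights: embedding collapses to the output bias
  w0 <- rand_ffnn(4 + 80, 6, 5)
  for (i in seq_along(w0$W)) w0$W[[i]][] <- 0
  w0$b[[2]][] <- 7
  expect_equal(emnn_edge_embed(g, w0), matrix(7, 4, 5))
})

test_that("edge-memory aggregation matches the per-edge loop oracle", {
  set.seed(26)
  fw <- rand_ffnn(5, 4, 5)
  gw <- rand_ffnn(5, 4, 5)
  for (g in fixture_graphs()) {
    if (nrow(g$edge_index) == 0) next
    dv <- build_directed_edge_view(g)
    H <- matrix(rnorm(dv$n_edges * 5, sd = 0.5), dv$n_edges, 5)
    E1 <- matrix(rnorm(dv$n_edges * 5, sd = 0.5), dv$n_edges, 5)
    expect_equal(emnn_aggregate(H, E1, dv, fw, gw),
                 oracle_emnn_aggregate(H, E1, dv, fw, gw), tolerance = 1e-6)
  }
  # terminal edge (tail of degree 1): singleton attention set, message
  # is exactly f(e')
  g <- featurize_molecule("CCO")
  dv <- build_directed_edge_view(g)
  H <- matrix(rnorm(4 * 5), 4, 5)
  E1 <- matrix(rnorm(4 * 5), 4, 5)
  m <- emnn_aggregate(H, E1, dv, fw, gw)
  term <- which(lengths(dv$incoming) == 0)
  for (i in term) {
    expect_equal(m[i, ], as.numeric(ffnn_val(fw, E1[i, ])), tolerance = 1e-10)
  }
})

test_that("no information flows back along a bond in the edge-memory path", {
  # path A-B-C: the message to (B,C) depends on h_AB and e'_BC only,
  # and is exactly invariant to h_CB
  set.seed(27)
  g <- featurize_molecule("CCO")   # A=C1, B=C2, C=O3
  dv <- build_directed_edge_view(g)
  fw <- rand_ffnn(5, 4, 5)
  gw <- rand_ffnn(5, 4, 5)
  H <- matrix(rnorm(20), 4, 5)
  E1 <- matrix(rnorm(20), 4, 5)
  bc <- which(dv$tails == 2 & dv$heads == 3)
  cb <- dv$reverse_index[bc]
  ab <- which(dv$tails == 1 & dv$heads == 2)
  m1 <- emnn_aggregate(H, E1, dv, fw, gw)
  H2 <- H; H2[cb, ] <- rnorm(5) * 10   # perturb the reverse edge
  m2 <- emnn_aggregate(H2, E1, dv, fw, gw)
  expect_identical(m1[bc, ], m2[bc, ])
  H3 <- H; H3[ab, ] <- H3[ab, ] + 1    # perturb the upstream edge
  m3 <- emnn_aggregate(H3, E1, dv, fw, gw)
  expect_gt(max(abs(m3[bc, ] - m1[bc, ])), 1e-8)
})

test_that("edge-memory attention weights sum to one over each edge set", {
  set.seed(28)
  gw <- rand_ffnn(5, 4, 5)
  f1 <- const_ffnn(5, 5, 1)
  for (g in fixture_graphs()) {
    if (nrow(g$edge_index) == 0) next
    dv <- build_directed_edge_view(g)
    H <- matrix(rnorm(dv$n_edges * 5), dv$n_edges, 5)
    E1 <- matrix(rnorm(dv$n_edges * 5), dv$n_edges, 5)
    m <- emnn_aggregate(H, E1, dv, f1, gw)
    expect_equal(m, matrix(1, dv$n_edges, 5), tolerance = 1e-6)
  }
})

test_that("node collapse sums incident directed-edge states", {
  g <- featurize_molecule("CC(=O)N")
  dv <- build_directed_edge_view(g)
  set.seed(29)
  H <- matrix(rnorm(dv$n_edges * 3), dv$n_edges, 3)
  hv <- emnn_collapse(H, g)
  for (v in seq_len(g$n_atoms)) {
    expect_equal(hv[v, ], colSums(H[dv$tails == v, , drop = FALSE]))
  }
  expect_equal(emnn_collapse(H * 0, g), matrix(0, g$n_atoms, 3))
})

test_that("the gated readout matches its loop oracle and is additive", {
  set.seed(30)
  pw <- rand_ffnn(4, 3, 6)
  qw <- rand_ffnn(8, 3, 6)
  gs <- fixture_graphs()[c(1, 4, 8)]
  b <- batch_graphs(gs)
  hK <- matrix(rnorm(b$n_atoms * 4), b$n_atoms, 4)
  h0 <- matrix(rnorm(b$n_atoms * 4), b$n_atoms, 4)
  out <- ggnn_readout(hK, h0, b$membership, b$n_mols, pw, qw)
  expect_equal(out, oracle_readout(hK, h0, b$membership, b$n_mols, pw, qw),
               tolerance = 1e-6)
  # single-node molecule: no summation
  one <- ggnn_readout(hK[1, , drop = FALSE], h0[1, , drop = FALSE], 1L, 1L, pw, qw)
  expect_equal(one, oracle_readout(hK[1, , drop = FALSE], h0[1, , drop = FALSE],
                                   1L, 1L, pw, qw))
  # two disjoint fragments scored as one graph equal the sum of the
  # fragments scored separately (nodes 1:7 are molecules 1 and 2)
  two <- ggnn_readout(hK[1:7, ], h0[1:7, ], rep(1L, 7), 1L, pw, qw)
  sep <- ggnn_readout(hK[1:7, ], h0[1:7, ], b$membership[1:7], 2L, pw, qw)
  expect_equal(two, sep[1, , drop = FALSE] + sep[2, , drop = FALSE],
               tolerance = 1e-10)
  expect_error(ggnn_readout(hK, h0, b$membership, 1L, pw, qw), "membership")
})

test_that("forward passes are invariant to graph isomorphism", {
  set.seed(31)
  for (arch in c("selu-mpnn", "ampnn", "emnn")) {
    m <- init_model(tiny_config(arch), 40, 2, seed = 31)
    # same molecule, different SMILES spellings
    o1 <- forward_pass(m, featurize_molecule("OCC"))
    o2 <- forward_pass(m, featurize_molecule("CCO"))
    expect_equal(o1, o2, tolerance = 1e-6)
    # random atom relabelings
    g <- featurize_molecule("CC(=O)Oc1ccccc1")
    base <- forward_pass(m, g)
    for (r in 1:5) {
      gp <- permute_graph(g, sample(g$n_atoms))
      expect_equal(forward_pass(m, gp), base, tolerance = 1e-6)
    }
  }
})

test_that("K = 0 reduces the forward pass to a readout of initial states", {
  m0 <- init_model(tiny_config("ampnn", K = 0), 40, 1, seed = 32)
  g <- featurize_molecule("CCO")
  out <- forward_pass(m0, g)
  expect_true(is.finite(out))
  # composition-only baseline: any molecule with the same atom multiset
  # scores identically regardless of bonding
  g2 <- featurize_molecule("COC")   # same formula, different graph
  expect_false(isTRUE(all.equal(g$node_features, g2$node_features)))
})

test_that("the receptive field grows by one bond per message pass", {
  # hexane backbone: perturbing an atom more than K bonds away from
  # atom 1 leaves h_1^(K) exactly unchanged
  g <- featurize_molecule("CCCCCC")
  set.seed(33)
  w <- rand_ffnn4(5, 4)
  gruw <- gru_weights(5, 5)
  roll <- function(h0, K) {
    h <- h0
    for (t in seq_len(K)) h <- gru_update(h, mpnn_message(h, g, w), gruw)
    h
  }
  h0 <- matrix(rnorm(30), 6, 5)
  for (K in 1:3) {
    hp <- h0
    hp[K + 2, ] <- hp[K + 2, ] + 5   # K+1 bonds away from atom 1
    expect_identical(roll(h0, K)[1, ], roll(hp, K)[1, ])
    hq <- h0
    hq[K + 1, ] <- hq[K + 1, ] + 5   # exactly K bonds away: reachable
    expect_gt(max(abs(roll(hq, K)[1, ] - roll(h0, K)[1, ])), 1e-8)
  }
})

test_that("forward on a batch equals forwards on the single molecules", {
  set.seed(34)
  gs <- fixture_graphs()[c(2, 3, 5, 7)]
  for (arch in c("selu-mpnn", "ampnn", "emnn")) {
    m <- init_model(tiny_config(arch), 40, 2, seed = 34)
    b <- forward_pass(m, batch_graphs(gs))
    singles <- do.call(rbind, lapply(gs, function(g) forward_pass(m, g)))
    expect_equal(b, singles, tolerance = 1e-8)
  }
})
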