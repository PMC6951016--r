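# Value-level reference implementations used as independent oracles:
# plain double loops over nodes/edges/neighbour sets, no shared code
# with the batched tape implementations they check.

selu_val <- function(x) {
  a <- 1.6732632423543772
  l <- 1.0507009873554805
  l * ifelse(x > 0, x, a * (exp(x) - 1))
}

ffnn_val <- function(w, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  nl <- length(w$W)
  for (i in seq_len(nl)) {
    x <- sweep(x %*% w$W[[i]], 2L, as.numeric(w$b[[i]]), `+`)
    if (i < nl) x <- selu_val(x)
  }
  x
}

identity_ffnn <- function(d) list(W = list(diag(d)), b = list(matrix(0, 1, d)))
const_ffnn <- function(d_in, d_out, value = 1) {
  list(W = list(matrix(0, d_in, d_out)), b = list(matrix(value, 1, d_out)))
}
rand_ffnn <- function(d_in, hidden, d_out) ffnn_weights(d_in, hidden, d_out)
rand_ffnn4 <- function(d, hidden) lapply(1:4, function(i) ffnn_weights(d, hidden, d))

graph_edge_class <- function(graph) max.col(graph$edge_features, ties.method = "first")

# m_v = sum over neighbours w of f^(class vw)(h_w)
oracle_mpnn_message <- function(h, graph, weights) {
  D <- ncol(h)
  cls <- graph_edge_class(graph)
  m <- matrix(0, graph$n_atoms, D)
  for (v in seq_len(graph$n_atoms)) {
    for (e in seq_len(nrow(graph$edge_index))) {
      if (graph$edge_index[e, 1L] == v) {
        w <- graph$edge_index[e, 2L]
        m[v, ] <- m[v, ] + ffnn_val(weights[[cls[[e]]]], h[w, ])
      }
    }
  }
  m
}

softmax_cols <- function(G) {
  # softmax down each column (the neighbour axis)
  E <- exp(sweep(G, 2L, apply(G, 2L, max)))
  sweep(E, 2L, colSums(E), `/`)
}

oracle_ampnn_message <- function(h, graph, f_weights, g_weights) {
  D <- ncol(h)
  cls <- graph_edge_class(graph)
  m <- matrix(0, graph$n_atoms, D)
  for (v in seq_len(graph$n_atoms)) {
    sel <- which(graph$edge_index[, 1L] == v)
    if (!length(sel)) next
    FF <- do.call(rbind, lapply(sel, function(e) {
      ffnn_val(f_weights[[cls[[e]]]], h[graph$edge_index[e, 2L], ])
    }))
    GG <- do.call(rbind, lapply(sel, function(e) {
      ffnn_val(g_weights[[cls[[e]]]], h[graph$edge_index[e, 2L], ])
    }))
    m[v, ] <- colSums(FF * softmax_cols(GG))
  }
  m
}

oracle_emnn_aggregate <- function(H, E1, dview, f_weights, g_weights) {
  D <- ncol(E1)
  m <- matrix(0, dview$n_edges, D)
  for (i in seq_len(dview$n_edges)) {
    X <- rbind(H[dview$incoming[[i]], , drop = FALSE], E1[i, ])
    FF <- ffnn_val(f_weights, X)
    GG <- ffnn_val(g_weights, X)
    m[i, ] <- colSums(FF * softmax_cols(GG))
  }
  m
}

oracle_readout <- function(hK, h0, membership, n_mols, p_weights, q_weights) {
  out <- NULL
  for (g in seq_len(n_mols)) {
    nodes <- which(membership == g)
    acc <- 0
    for (v in nodes) {
      acc <- acc + ffnn_val(p_weights, hK[v, ]) *
        stats::plogis(ffnn_val(q_weights, cbind(matrix(hK[v, ], 1), matrix(h0[v, ], 1))))
    }
    out <- rbind(out, acc)
  }
  out
}

oracle_gru <- function(w, x, h) {
  # hand-evaluated gate computation for a single row
  z <- stats::plogis(x %*% w$Wz + h %*% w$Uz + as.numeric(w$bz))
  r <- stats::plogis(x %*% w$Wr + h %*% w$Ur + as.numeric(w$br))
  n <- tanh(x %*% w$Wn + r * (h %*% w$Un) + as.numeric(w$bn))
  (1 - z) * n + z * h
}

# fixed small molecules; all six heavy atoms or fewer
SIX_ATOM_SMILES <- c("CCO", "O", "C=O", "CC(=O)N", "C#N", "CC(C)C",
                     "C1CC1", "c1ccoc1", "CCOC", "CC=CC", "N", "OCC=O")

fixture_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- featurize_molecules(SIX_ATOM_SMILES)
    cache
  }
})

tiny_config <- function(arch, K = 2) {
  if (arch == "emnn") {
    model_config("emnn", message_passes = K, msg_hidden_dim = 8, att_hidden_dim = 6,
                 edge_emb_hidden_dim = 8, edge_embedding_size = 6, gather_width = 6,
                 gather_emb_hidden_dim = 5, gather_att_hidden_dim = 5,
                 out_hidden_dim = 10, out_layer_shrinkage = 0.5)
  } else {
    model_config(arch, message_passes = K, message_size = 8, msg_hidden_dim = 8,
                 gather_width = 6, gather_emb_hidden_dim = 5,
                 gather_att_hidden_dim = 5, out_hidden_dim = 10,
                 out_layer_shrinkage = 0.5,
                 att_hidden_dim = if (arch == "ampnn") 6 else NULL)
  }
}
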