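# The three architectures. A shared skeleton -- K rounds of
# (aggregate neighbour information, GRU state update), a gated
# sum readout, and a shrinking SELU output stack -- with three
# aggregation schemes:
#
#   selu-mpnn  m_v  = sum_w f^(bond class vw)(h_w)
#   ampnn      m_v  = sum_w f^(c)(h_w) * softmax_w(g^(c)(h_w))   (elementwise)
#   emnn       states live on directed edges; the message to edge (v,w)
#              attends over the edges arriving at its tail v (never the
#              reverse edge (w,v)) plus the edge's own static embedding.

ARCHITECTURES <- c("selu-mpnn", "ampnn", "emnn")

#' Model configuration
#'
#' Collects the architecture selector and its hyperparameters. Fields
#' not applicable to the chosen architecture must be left `NULL`
#' (passing, say, `att_hidden_dim` for `"selu-mpnn"` or `message_size`
#' for `"emnn"` is a configuration error); applicable fields get
#' defaults from the small end of the search domain. For `"emnn"` the
#' directed-edge hidden state width equals `edge_embedding_size`, which
#' is why `message_size` does not apply.
#'
#' @param architecture one of `"selu-mpnn"`, `"ampnn"`, `"emnn"`.
#' @param learn_rate optimizer learning rate.
#' @param message_size node hidden state width D (`selu-mpnn`/`ampnn`).
#' @param message_passes number of message passing rounds K.
#' @param msg_hidden_dim hidden width of the message networks `f`.
#' @param gather_width readout output width.
#' @param gather_emb_hidden_dim,gather_att_hidden_dim hidden widths of
#'   the readout `p` and `q` networks.
#' @param out_hidden_dim first width of the post-readout stack.
#' @param out_dropout_p dropout probability in the output stack.
#' @param out_layer_shrinkage successive output widths scale by this.
#' @param att_hidden_dim hidden width of the attention weighting
#'   networks `g` (`ampnn`/`emnn` only).
#' @param edge_emb_hidden_dim,edge_embedding_size hidden width and
#'   output width of the edge embedding network (`emnn` only).
#' @return an object of class `model_config`.
#' @export
model_config <- function(architecture = c("selu-mpnn", "ampnn", "emnn"),
                         learn_rate = 1e-4,
                         message_size = NULL,
                         message_passes = 3,
                         msg_hidden_dim = 50,
                         gather_width = 30,
                         gather_emb_hidden_dim = 15,
                         gather_att_hidden_dim = 15,
                         out_hidden_dim = 360,
                         out_dropout_p = 0.0,
                         out_layer_shrinkage = 0.4,
                         att_hidden_dim = NULL,
                         edge_emb_hidden_dim = NULL,
                         edge_embedding_size = NULL) {
  architecture <- match.arg(architecture)
  if (architecture == "emnn") {
    if (!is.null(message_size)) {
      stop("message_size does not apply to emnn (state width = edge_embedding_size)",
           call. = FALSE)
    }
    if (is.null(att_hidden_dim)) att_hidden_dim <- 50
    if (is.null(edge_emb_hidden_dim)) edge_emb_hidden_dim <- 60
    if (is.null(edge_embedding_size)) edge_embedding_size <- 30
  } else {
    if (!is.null(edge_emb_hidden_dim) || !is.null(edge_embedding_size)) {
      stop("edge embedding hyperparameters apply to emnn only", call. = FALSE)
    }
    if (is.null(message_size)) message_size <- 16
    if (architecture == "selu-mpnn") {
      if (!is.null(att_hidden_dim)) {
        stop("att_hidden_dim does not apply to selu-mpnn", call. = FALSE)
      }
    } else if (is.null(att_hidden_dim)) {
      att_hidden_dim <- 50
    }
  }
  stopifnot(learn_rate > 0, message_passes >= 0,
            out_layer_shrinkage > 0, out_layer_shrinkage <= 1,
            out_dropout_p >= 0, out_dropout_p < 1)
  cfg <- list(architecture = architecture, learn_rate = learn_rate,
              message_size = message_size, message_passes = as.integer(message_passes),
              msg_hidden_dim = msg_hidden_dim, gather_width = gather_width,
              gather_emb_hidden_dim = gather_emb_hidden_dim,
              gather_att_hidden_dim = gather_att_hidden_dim,
              out_hidden_dim = out_hidden_dim, out_dropout_p = out_dropout_p,
              out_layer_shrinkage = out_layer_shrinkage,
              att_hidden_dim = att_hidden_dim,
              edge_emb_hidden_dim = edge_emb_hidden_dim,
              edge_embedding_size = edge_embedding_size)
  class(cfg) <- "model_config"
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$architecture, "\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  flds$architecture <- NULL
  for (nm in names(flds)) cat(" ", nm, "=", format(flds[[nm]]), "\n")
  invisible(x)
}

#' Write and read model configurations
#'
#' Plain `key: value` text, round-trippable.
#' @param config a [model_config()]; `path` a file path.
#' @param path file to write to / read from.
#' @export
write_model_config <- function(config, path) {
  flds <- config[!vapply(config, is.null, logical(1))]
  lines <- vapply(names(flds), function(nm) {
    paste0(nm, ": ", format(flds[[nm]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  args <- stats::setNames(lapply(kv, function(x) {
    v <- x[[2L]]
    if (x[[1L]] == "architecture") v else as.numeric(v)
  }), vapply(kv, `[[`, character(1), 1L))
  do.call(model_config, args)
}

state_width <- function(config) {
  if (config$architecture == "emnn") config$edge_embedding_size else config$message_size
}

#' Initialize model weights
#'
#' @param config a [model_config()].
#' @param d_node node feature width the model will consume.
#' @param n_tasks number of output tasks.
#' @param seed optional RNG seed for reproducible initialization.
#' @return an object of class `molmpnn_model` holding the config,
#'   dimensions, and the nested parameter list.
#' @export
init_model <- function(config, d_node, n_tasks, seed = NULL) {
  stopifnot(inherits(config, "model_config"), d_node >= 1, n_tasks >= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- state_width(config)
  p <- list()
  if (d_node > D) {
    p$embed_in <- ffnn_weights(d_node, integer(0), D)  # linear projection
  }
  sh1 <- max(1L, round(config$out_hidden_dim * config$out_layer_shrinkage))
  sh2 <- max(1L, round(sh1 * config$out_layer_shrinkage))
  if (config$architecture %in% c("selu-mpnn", "ampnn")) {
    p$msg_f <- lapply(1:4, function(c) ffnn_weights(D, config$msg_hidden_dim, D))
    if (config$architecture == "ampnn") {
      p$att_g <- lapply(1:4, function(c) ffnn_weights(D, config$att_hidden_dim, D))
    }
    p$gru <- gru_weights(D, D)
  } else {
    De <- config$edge_embedding_size
    p$edge_emb <- ffnn_weights(4L + 2L * d_node, config$edge_emb_hidden_dim, De)
    p$msg_f <- ffnn_weights(De, config$msg_hidden_dim, De)
    p$att_g <- ffnn_weights(De, config$att_hidden_dim, De)
    p$gru <- gru_weights(De, De)
  }
  p$read_p <- ffnn_weights(D, config$gather_emb_hidden_dim, config$gather_width)
  p$read_q <- ffnn_weights(2L * D, config$gather_att_hidden_dim, config$gather_width)
  p$out <- ffnn_weights(config$gather_width, c(config$out_hidden_dim, sh1, sh2), n_tasks)
  m <- list(config = config, d_node = d_node, n_tasks = n_tasks, params = p)
  class(m) <- "molmpnn_model"
  m
}

#' @export
print.molmpnn_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, numeric(1)))
  cat("<molmpnn_model>", x$config$architecture, "-", format(np), "parameters,",
      x$n_tasks, "task(s)\n")
  invisible(x)
}

# ---- tape-level building blocks ----------------------------------------

# h_v^(0): pad with zero columns up to D, or linearly project down.
embed_initial_tape <- function(tape, node_features, D, pn) {
  d <- ncol(node_features)
  if (d == D) return(ad_const(tape, node_features))
  if (d < D) {
    return(ad_const(tape, cbind(node_features, matrix(0, nrow(node_features), D - d))))
  }
  ffnn_fwd(tape, pn$embed_in, ad_const(tape, node_features))
}

# per-bond-class row masks for the directed edge list
class_row_masks <- function(edge_class, width) {
  lapply(1:4, function(c) {
    m <- matrix(0, length(edge_class), width)
    m[edge_class == c, ] <- 1
    m
  })
}

# apply one ffnn per bond class and recombine rows (edges partition by class)
per_class_fwd <- function(tape, nets, x, edge_class, width) {
  masks <- class_row_masks(edge_class, width)
  out <- NULL
  for (c in 1:4) {
    if (!any(edge_class == c)) next
    piece <- ad_mul_const(tape, ffnn_fwd(tape, nets[[c]], x), masks[[c]])
    out <- if (is.null(out)) piece else ad_add(tape, out, piece)
  }
  out
}

mpnn_message_tape <- function(tape, h, edge_index, edge_class, msg_f, n_nodes) {
  D <- ncol(h$val)
  if (nrow(edge_index) == 0) return(ad_const(tape, matrix(0, n_nodes, D)))
  hw <- ad_gather(tape, h, edge_index[, 2L])
  msg_e <- per_class_fwd(tape, msg_f, hw, edge_class, D)
  ad_segsum(tape, msg_e, edge_index[, 1L], n_nodes)
}

# softmax over rows sharing a group, per column. The stabilizing shift
# is the per-group per-column max (a constant w.r.t. the gradient), so
# each group's result depends on its own rows only -- bitwise.
segment_softmax_weighted <- function(tape, f_e, g_e, groups, ngroups) {
  gf <- factor(groups, levels = seq_len(ngroups))
  groupmax <- apply(g_e$val, 2L, function(col) tapply(col, gf, max))
  if (is.null(dim(groupmax))) groupmax <- matrix(groupmax, ngroups)
  shift <- groupmax[groups, , drop = FALSE]
  w <- ad_exp(tape, ad_sub(tape, g_e, ad_const(tape, shift)))
  denom <- ad_segsum(tape, w, groups, ngroups)
  wn <- ad_div(tape, w, ad_gather(tape, denom, groups))
  ad_segsum(tape, ad_mul(tape, f_e, wn), groups, ngroups)
}

ampnn_message_tape <- function(tape, h, edge_index, edge_class, msg_f, att_g, n_nodes) {
  D <- ncol(h$val)
  if (nrow(edge_index) == 0) return(ad_const(tape, matrix(0, n_nodes, D)))
  hw <- ad_gather(tape, h, edge_index[, 2L])
  f_e <- per_class_fwd(tape, msg_f, hw, edge_class, D)
  g_e <- per_class_fwd(tape, att_g, hw, edge_class, D)
  segment_softmax_weighted(tape, f_e, g_e, edge_index[, 1L], n_nodes)
}

emnn_edge_embed_tape <- function(tape, graph, pn) {
  x <- cbind(graph$edge_features,
             graph$node_features[graph$edge_index[, 1L], , drop = FALSE],
             graph$node_features[graph$edge_index[, 2L], , drop = FALSE])
  ffnn_fwd(tape, pn$edge_emb, ad_const(tape, x))
}

emnn_aggregate_tape <- function(tape, H, e1, dview, msg_f, att_g) {
  ne <- dview$n_edges
  src <- unlist(dview$incoming, use.names = FALSE)
  dst <- rep(seq_len(ne), times = lengths(dview$incoming))
  # attention set for edge i: incoming edge states at its tail + its own
  # static embedding e'_i, so the set is never empty
  if (length(src)) {
    X <- ad_rbind(tape, ad_gather(tape, H, src), e1)
    groups <- c(dst, seq_len(ne))
  } else {
    X <- e1
    groups <- seq_len(ne)
  }
  f_x <- ffnn_fwd(tape, msg_f, X)
  g_x <- ffnn_fwd(tape, att_g, X)
  segment_softmax_weighted(tape, f_x, g_x, groups, ne)
}

ggnn_readout_tape <- function(tape, hK, h0, membership, n_mols, pn) {
  gated <- ad_mul(tape,
                  ffnn_fwd(tape, pn$read_p, hK),
                  ad_sigmoid(tape, ffnn_fwd(tape, pn$read_q, ad_cbind(tape, hK, h0))))
  ad_segsum(tape, gated, membership, n_mols)
}

out_stack_tape <- function(tape, pn, x, dropout_p, training) {
  nl <- length(pn$out$W)
  for (i in seq_len(nl)) {
    x <- ad_add_bias(tape, ad_mm(tape, x, pn$out$W[[i]]), pn$out$b[[i]])
    if (i < nl) {
      x <- ad_selu(tape, x)
      if (training && dropout_p > 0) {
        keep <- matrix(stats::runif(length(x$val)) >= dropout_p,
                       nrow(x$val), ncol(x$val)) / (1 - dropout_p)
        x <- ad_mul_const(tape, x, keep)
      }
    }
  }
  x
}

# full forward pass on the tape; batch is a mol_graph or mol_graph_batch
forward_tape <- function(model, batch, pn, tape, training = FALSE) {
  cfg <- model$config
  if (ncol(batch$node_features) != model$d_node) {
    stop("batch node feature width ", ncol(batch$node_features),
         " does not match model d_node ", model$d_node, call. = FALSE)
  }
  membership <- if (!is.null(batch$membership)) batch$membership else
    rep(1L, batch$n_atoms)
  n_mols <- max(1L, if (!is.null(batch$n_mols)) batch$n_mols else 1L)
  if (length(membership) && max(membership) > n_mols) {
    stop("membership index out of range", call. = FALSE)
  }
  D <- state_width(cfg)
  h0 <- embed_initial_tape(tape, batch$node_features, D, pn)
  ec <- edge_class_of(batch)
  if (cfg$architecture %in% c("selu-mpnn", "ampnn")) {
    h <- h0
    for (t in seq_len(cfg$message_passes)) {
      m <- if (cfg$architecture == "selu-mpnn") {
        mpnn_message_tape(tape, h, batch$edge_index, ec, pn$msg_f, batch$n_atoms)
      } else {
        ampnn_message_tape(tape, h, batch$edge_index, ec, pn$msg_f, pn$att_g,
                           batch$n_atoms)
      }
      h <- gru_fwd(tape, pn$gru, m, h)
    }
    hK <- h
  } else {
    dview <- build_directed_edge_view(batch)
    ne <- dview$n_edges
    if (ne > 0) {
      e1 <- emnn_edge_embed_tape(tape, batch, pn)
      H <- ad_const(tape, matrix(0, ne, D))
      for (t in seq_len(cfg$message_passes)) {
        m <- emnn_aggregate_tape(tape, H, e1, dview, pn$msg_f, pn$att_g)
        H <- gru_fwd(tape, pn$gru, m, H)
      }
      hK <- ad_segsum(tape, H, dview$tails, batch$n_atoms)
    } else {
      hK <- ad_const(tape, matrix(0, batch$n_atoms, D))
    }
  }
  y <- ggnn_readout_tape(tape, hK, h0, membership, n_mols, pn)
  out_stack_tape(tape, pn, y, cfg$out_dropout_p, training)
}

#' Forward pass
#'
#' Runs a batch of molecular graphs through the model. Classification
#' outputs are pre-sigmoid scores; regression outputs are in the
#' (normalized) target space the model was trained in.
#'
#' @param model a `molmpnn_model`.
#' @param batch a `mol_graph` or `mol_graph_batch`.
#' @param training if `TRUE`, dropout is active (consumes RNG).
#' @return numeric matrix `n_molecules x n_tasks`.
#' @export
forward_pass <- function(model, batch, training = FALSE) {
  tape <- ad_tape()
  pn <- ad_wrap_params(tape, model$params)
  out <- forward_tape(model, batch, pn, tape, training = training)
  out$val
}

# ---- value-level operation surface (plain matrices in and out) ----------
# These run the same tape code as forward_pass and exist so that every
# aggregation step can be checked against naive loop oracles.

run_value <- function(builder) {
  tape <- ad_tape()
  builder(tape)$val
}

#' Message passing aggregation steps
#'
#' Value-level entry points to the aggregation machinery, operating on
#' plain matrices: `mpnn_message()` is the per-bond-class summed
#' message; `attention_aggregate()` the elementwise softmax-weighted
#' sum; `gru_update()` the shared gated recurrent state update;
#' `emnn_edge_embed()`, `emnn_aggregate()` and `emnn_collapse()` the
#' directed-edge path; `ggnn_readout()` the gated readout.
#'
#' @param states hidden state matrix (rows = nodes, or directed edges
#'   for the edge-memory path).
#' @param graph a `mol_graph` (or batch).
#' @param weights,f_weights,g_weights,p_weights,q_weights weight lists:
#'   per-bond-class lists of [ffnn_weights()] for the node
#'   architectures, single [ffnn_weights()] for the edge path and
#'   readout, [gru_weights()] for `gru_update`.
#' @return a numeric matrix; see each operation's contract.
#' @export
mpnn_message <- function(states, graph, weights) {
  run_value(function(tp) {
    mpnn_message_tape(tp, ad_const(tp, states), graph$edge_index,
                      edge_class_of(graph), lapply(weights, ad_wrap_params, tape = tp),
                      graph$n_atoms)
  })
}

#' @rdname mpnn_message
#' @export
attention_aggregate <- function(states, graph, f_weights, g_weights) {
  run_value(function(tp) {
    ampnn_message_tape(tp, ad_const(tp, states), graph$edge_index,
                       edge_class_of(graph),
                       lapply(f_weights, ad_wrap_params, tape = tp),
                       lapply(g_weights, ad_wrap_params, tape = tp),
                       graph$n_atoms)
  })
}

#' @rdname mpnn_message
#' @param messages aggregated message matrix, same row count as `states`.
#' @export
gru_update <- function(states, messages, weights) {
  stopifnot(nrow(states) == nrow(messages))
  run_value(function(tp) {
    gru_fwd(tp, ad_wrap_params(tp, weights), ad_const(tp, messages),
            ad_const(tp, states))
  })
}

#' @rdname mpnn_message
#' @export
emnn_edge_embed <- function(graph, weights) {
  run_value(function(tp) {
    emnn_edge_embed_tape(tp, graph, list(edge_emb = ad_wrap_params(tp, weights)))
  })
}

#' @rdname mpnn_message
#' @param e_prime static directed-edge embeddings from [emnn_edge_embed()].
#' @param dview a [build_directed_edge_view()].
#' @export
emnn_aggregate <- function(states, e_prime, dview, f_weights, g_weights) {
  run_value(function(tp) {
    emnn_aggregate_tape(tp, ad_const(tp, states), ad_const(tp, e_prime), dview,
                        ad_wrap_params(tp, f_weights), ad_wrap_params(tp, g_weights))
  })
}

#' @rdname mpnn_message
#' @export
emnn_collapse <- function(states, graph) {
  segsum_val(states, graph$edge_index[, 1L], graph$n_atoms)
}

#' @rdname mpnn_message
#' @param final_states,initial_states node state matrices h^(K), h^(0).
#' @param membership 1-based molecule index per node.
#' @param n_mols number of molecules.
#' @export
ggnn_readout <- function(final_states, initial_states, membership, n_mols,
                         p_weights, q_weights) {
  if (length(membership) && max(membership) > n_mols) {
    stop("membership index out of range", call. = FALSE)
  }
  run_value(function(tp) {
    ggnn_readout_tape(tp, ad_const(tp, final_states), ad_const(tp, initial_states),
                      membership, n_mols,
                      list(read_p = ad_wrap_params(tp, p_weights),
                           read_q = ad_wrap_params(tp, q_weights)))
  })
}
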