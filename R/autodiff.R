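# Minimal reverse-mode automatic differentiation over dense matrices.
# Nodes are environments appended to a tape in creation order; backward
# replays the tape in reverse. This is the differentiation engine behind
# every architecture in the package; it supports exactly the operations
# the models need (matrix product, broadcast bias, elementwise algebra,
# SELU/sigmoid/tanh, row gather, segment sum, column concatenation, and
# fused masked losses).

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ad_node(tape, x)
}

acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$val))
    acc(nd$parents[[2L]], t(nd$parents[[1L]]$val) %*% nd$grad)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad)
    acc(nd$parents[[2L]], nd$grad)
  })
}

# x: n x k, bias: 1 x k broadcast over rows
ad_add_bias <- function(tape, x, bias) {
  ad_node(tape, sweep(x$val, 2L, as.numeric(bias$val), `+`), list(x, bias),
          function(nd) {
            acc(nd$parents[[1L]], nd$grad)
            acc(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
          })
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$val - b$val, list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad)
    acc(nd$parents[[2L]], -nd$grad)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$val)
    acc(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$val)
  })
}

ad_div <- function(tape, a, b) {
  ad_node(tape, a$val / b$val, list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad / nd$parents[[2L]]$val)
    acc(nd$parents[[2L]], -nd$grad * nd$val / nd$parents[[2L]]$val)
  })
}

# multiply by a constant matrix (e.g. a dropout or row mask)
ad_mul_const <- function(tape, x, m) {
  ad_node(tape, x$val * m, list(x), function(nd) {
    acc(nd$parents[[1L]], nd$grad * m)
  })
}

ad_scale <- function(tape, x, s) {
  ad_node(tape, x$val * s, list(x), function(nd) {
    acc(nd$parents[[1L]], nd$grad * s)
  })
}

SELU_ALPHA <- 1.6732632423543772
SELU_LAMBDA <- 1.0507009873554805

ad_selu <- function(tape, x) {
  pos <- x$val > 0
  ex <- exp(pmin(x$val, 0))
  val <- SELU_LAMBDA * ifelse(pos, x$val, SELU_ALPHA * (ex - 1))
  dv <- SELU_LAMBDA * ifelse(pos, 1, SELU_ALPHA * ex)
  ad_node(tape, val, list(x), function(nd) acc(nd$parents[[1L]], nd$grad * dv))
}

ad_sigmoid <- function(tape, x) {
  val <- 1 / (1 + exp(-x$val))
  ad_node(tape, val, list(x), function(nd) {
    acc(nd$parents[[1L]], nd$grad * nd$val * (1 - nd$val))
  })
}

ad_tanh <- function(tape, x) {
  val <- tanh(x$val)
  ad_node(tape, val, list(x), function(nd) {
    acc(nd$parents[[1L]], nd$grad * (1 - nd$val^2))
  })
}

ad_exp <- function(tape, x) {
  val <- exp(x$val)
  ad_node(tape, val, list(x), function(nd) acc(nd$parents[[1L]], nd$grad * nd$val))
}

# out[i, ] = x[idx[i], ]
ad_gather <- function(tape, x, idx) {
  nr <- nrow(x$val)
  ad_node(tape, x$val[idx, , drop = FALSE], list(x), function(nd) {
    g <- matrix(0, nr, ncol(nd$val))
    if (length(idx)) {
      ag <- rowsum(nd$grad, group = idx)
      g[as.integer(rownames(ag)), ] <- ag
    }
    acc(nd$parents[[1L]], g)
  })
}

# out[g, ] = sum over rows i with groups[i] == g; groups in 1..ngroups,
# empty groups give zero rows.
segsum_val <- function(x, groups, ngroups) {
  out <- matrix(0, ngroups, ncol(x))
  if (length(groups)) {
    ag <- rowsum(x, group = groups)
    out[as.integer(rownames(ag)), ] <- ag
  }
  out
}

ad_segsum <- function(tape, x, groups, ngroups) {
  ad_node(tape, segsum_val(x$val, groups, ngroups), list(x), function(nd) {
    acc(nd$parents[[1L]], nd$grad[groups, , drop = FALSE])
  })
}

ad_rbind <- function(tape, a, b) {
  na <- nrow(a$val)
  ad_node(tape, rbind(a$val, b$val), list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad[seq_len(na), , drop = FALSE])
    acc(nd$parents[[2L]], nd$grad[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind <- function(tape, a, b) {
  ka <- ncol(a$val)
  ad_node(tape, cbind(a$val, b$val), list(a, b), function(nd) {
    acc(nd$parents[[1L]], nd$grad[, seq_len(ka), drop = FALSE])
    acc(nd$parents[[2L]], nd$grad[, -seq_len(ka), drop = FALSE])
  })
}

ad_sum <- function(tape, x) {
  ad_node(tape, matrix(sum(x$val), 1L, 1L), list(x), function(nd) {
    acc(nd$parents[[1L]],
        matrix(nd$grad[1L, 1L], nrow(nd$parents[[1L]]$val), ncol(nd$parents[[1L]]$val)))
  })
}

# Fused masked losses: the gradient at missing cells is identically
# zero by construction, which is exactly the masking contract.
ad_masked_bce <- function(tape, scores, labels, mask) {
  n_obs <- sum(mask)
  s <- scores$val
  # numerically stable log(1 + exp(-|s|)) formulation
  per <- pmax(s, 0) - s * labels + log1p(exp(-abs(s)))
  val <- if (n_obs > 0) sum(per * mask) / n_obs else 0
  ad_node(tape, matrix(val, 1L, 1L), list(scores), function(nd) {
    if (n_obs > 0) {
      p <- 1 / (1 + exp(-s))
      acc(nd$parents[[1L]], nd$grad[1L, 1L] * (p - labels) * mask / n_obs)
    }
  })
}

ad_masked_mse <- function(tape, preds, labels, mask) {
  n_obs <- sum(mask)
  d <- (preds$val - labels) * mask
  val <- if (n_obs > 0) sum(d^2) / n_obs else 0
  ad_node(tape, matrix(val, 1L, 1L), list(preds), function(nd) {
    if (n_obs > 0) acc(nd$parents[[1L]], nd$grad[1L, 1L] * 2 * d / n_obs)
  })
}

# ---- parameter plumbing -------------------------------------------------

# Wrap a nested list of numeric matrices into tape nodes of the same
# shape; ad_extract_grads() walks the wrapped structure back out.
ad_wrap_params <- function(tape, params) {
  if (is.matrix(params) || is.numeric(params)) {
    return(ad_const(tape, params))
  }
  lapply(params, ad_wrap_params, tape = tape)
}

ad_extract_grads <- function(wrapped) {
  if (is.environment(wrapped)) {
    g <- wrapped$grad
    if (is.null(g)) g <- matrix(0, nrow(wrapped$val), ncol(wrapped$val))
    return(g)
  }
  lapply(wrapped, ad_extract_grads)
}

# ---- Adam ---------------------------------------------------------------

flatten_params <- function(params, prefix = "") {
  if (is.matrix(params) || is.numeric(params)) {
    out <- list(params)
    names(out) <- prefix
    return(out)
  }
  nms <- names(params)
  if (is.null(nms)) nms <- as.character(seq_along(params))
  out <- list()
  for (i in seq_along(params)) {
    out <- c(out, flatten_params(params[[i]], paste0(prefix, "/", nms[[i]])))
  }
  out
}

relist_like <- function(flat, skeleton, prefix = "") {
  if (is.matrix(skeleton) || is.numeric(skeleton)) return(flat[[prefix]])
  nms <- names(skeleton)
  if (is.null(nms)) nms <- as.character(seq_along(skeleton))
  out <- vector("list", length(skeleton))
  names(out) <- names(skeleton)
  for (i in seq_along(skeleton)) {
    out[[i]] <- relist_like(flat, skeleton[[i]], paste0(prefix, "/", nms[[i]]))
  }
  out
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(fp)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * fg[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * fg[[k]]^2
    fp[[k]] <- fp[[k]] - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = relist_like(fp, params), state = state)
}
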