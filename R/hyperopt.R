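# Bayesian hyperparameter optimization: a Gaussian-process surrogate
# with an RBF kernel over the encoded search space, Expected
# Improvement as the acquisition function, and local penalization of
# already-chosen points for batch suggestion. Discrete dimensions are
# one-hot encoded in the surrogate; the learning rate is searched on a
# log scale. No dedicated Bayesian-optimization package ships with the
# R distribution used here, so the (standard) GP posterior algebra is
# done in-package with base linear algebra.

dim_spec <- function(name, type, lower = NA, upper = NA, values = NULL) {
  list(name = name, type = type, lower = lower, upper = upper, values = values)
}

#' Hyperparameter search domain
#'
#' The per-architecture search space: the learning rate on a
#' log-uniform range, the dropout and output-shrinkage rates on linear
#' ranges, message passes as an integer range (capped at 8 for the
#' edge-memory network), and the width hyperparameters as discrete
#' choice lists (slightly tightened for the edge-memory network, which
#' has more parameter tensors per width).
#'
#' @param architecture one of `"selu-mpnn"`, `"ampnn"`, `"emnn"`.
#' @return an object of class `search_domain`: a list of dimension
#'   specs with `name`, `type` (`"log"`, `"continuous"`, `"int"`,
#'   `"choice"`) and range/levels.
#' @export
build_domain <- function(architecture = c("selu-mpnn", "ampnn", "emnn")) {
  architecture <- match.arg(architecture)
  emnn <- architecture == "emnn"
  dims <- list(
    dim_spec("learn_rate", "log", 1e-6, 1e-4),
    if (!emnn) dim_spec("message_size", "choice", values = c(10, 16, 25, 40)),
    dim_spec("message_passes", "int", 1, if (emnn) 8 else 10),
    dim_spec("msg_hidden_dim", "choice", values = c(50, 85, 150)),
    dim_spec("gather_width", "choice", values = c(30, 45, 70, 100)),
    dim_spec("gather_emb_hidden_dim", "choice",
             values = if (emnn) c(15, 26, 45) else c(15, 26, 45, 80)),
    dim_spec("gather_att_hidden_dim", "choice",
             values = if (emnn) c(15, 26, 45) else c(15, 26, 45, 80)),
    dim_spec("out_hidden_dim", "choice", values = c(360, 450, 560)),
    dim_spec("out_dropout_p", "continuous", 0.0, 0.1),
    dim_spec("out_layer_shrinkage", "continuous", 0.2, 0.6),
    if (architecture != "selu-mpnn") dim_spec("att_hidden_dim", "choice",
                                              values = c(50, 85, 150)),
    if (emnn) dim_spec("edge_emb_hidden_dim", "choice", values = c(60, 105, 180)),
    if (emnn) dim_spec("edge_embedding_size", "choice", values = c(30, 50, 80))
  )
  dims <- dims[!vapply(dims, is.null, logical(1))]
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, architecture = architecture, class = "search_domain")
}

#' @export
print.search_domain <- function(x, ...) {
  cat("<search_domain>", attr(x, "architecture"), "-", length(x), "dimensions\n")
  for (d in x) {
    cat(" ", d$name, ": ",
        if (d$type == "choice") paste0("{", paste(d$values, collapse = ","), "}")
        else paste0("[", d$lower, ", ", d$upper, "]",
                    if (d$type == "log") " (log)" else
                    if (d$type == "int") " (integer)" else ""), "\n", sep = "")
  }
  invisible(x)
}

#' Check a point against a search domain
#'
#' @param domain a [build_domain()].
#' @param point named list of hyperparameter values.
#' @return `TRUE` if every dimension value lies inside the domain.
#' @export
in_domain <- function(domain, point) {
  all(vapply(domain, function(d) {
    v <- point[[d$name]]
    if (is.null(v)) return(FALSE)
    switch(d$type,
           choice = v %in% d$values,
           int = v >= d$lower && v <= d$upper && v == round(v),
           v >= d$lower && v <= d$upper)
  }, logical(1)))
}

# unit-cube coordinate vector -> named point
decode_u <- function(domain, u) {
  pt <- list()
  for (i in seq_along(domain)) {
    d <- domain[[i]]
    ui <- min(max(u[[i]], 0), 1 - 1e-12)
    pt[[d$name]] <- switch(d$type,
      log = exp(log(d$lower) + ui * (log(d$upper) - log(d$lower))),
      continuous = d$lower + ui * (d$upper - d$lower),
      int = d$lower + floor(ui * (d$upper - d$lower + 1)),
      choice = d$values[[1L + floor(ui * length(d$values))]])
  }
  pt
}

# named point -> GP feature vector (one-hot for choices)
encode_point <- function(domain, point) {
  unlist(lapply(domain, function(d) {
    v <- point[[d$name]]
    switch(d$type,
      log = (log(v) - log(d$lower)) / (log(d$upper) - log(d$lower)),
      continuous = (v - d$lower) / (d$upper - d$lower),
      int = (v - d$lower) / max(1, d$upper - d$lower),
      choice = as.numeric(d$values == v))
  }), use.names = FALSE)
}

#' Turn a domain point into a model configuration
#'
#' @param domain a [build_domain()].
#' @param point named list of in-domain values.
#' @export
config_from_point <- function(domain, point) {
  do.call(model_config, c(list(architecture = attr(domain, "architecture")), point))
}

# ---- GP surrogate -------------------------------------------------------

gp_fit <- function(X, y, noise = 1e-4) {
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  d2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.3, 0.7, 1.5)) {
    K <- exp(-0.5 * d2 / ell^2) + diag(noise, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    lml <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - 0.5 * nrow(X) * log(2 * pi)
    if (is.null(best) || lml > best$lml) {
      best <- list(lml = lml, ell = ell, chol = ch, alpha = alpha)
    }
  }
  if (is.null(best)) stop("GP fit failed", call. = FALSE)
  c(best, list(X = X, mu_y = mu_y, sd_y = sd_y, noise = noise))
}

gp_predict <- function(fit, Xs) {
  d2 <- outer(rowSums(Xs^2), rowSums(fit$X^2), `+`) - 2 * Xs %*% t(fit$X)
  Ks <- exp(-0.5 * pmax(d2, 0) / fit$ell^2)
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(1 + fit$noise - colSums(v^2), 1e-12)
  list(mean = fit$mu_y + fit$sd_y * mu, sd = fit$sd_y * sqrt(var))
}

expected_improvement <- function(mu, sd, best, xi = 0.01) {
  imp <- mu - best - xi
  z <- imp / sd
  imp * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Suggest a batch of configurations
#'
#' With fewer than five evaluated points, returns a space-filling
#' (Latin hypercube) initial design. Otherwise fits the GP surrogate to
#' the history, scores a random candidate pool by Expected Improvement
#' (maximization convention), and picks `batch_size` points greedily,
#' multiplying the acquisition by a local penalization factor around
#' each already-chosen point so the batch spreads out.
#'
#' @param history list with `points` (list of named in-domain lists)
#'   and `scores` (numeric, higher is better); may be empty.
#' @param domain a [build_domain()].
#' @param batch_size number of suggestions.
#' @param n_candidates size of the random candidate pool.
#' @return list of `batch_size` named points, pairwise distinct and
#'   in-domain. Consumes RNG; seed the session for reproducibility.
#' @export
suggest_batch <- function(history, domain, batch_size, n_candidates = 300L) {
  nd <- length(domain)
  n_hist <- length(history$scores)
  if (n_hist < 5L) {
    U <- lhs::randomLHS(max(batch_size, 5L), nd)
    pts <- lapply(seq_len(nrow(U)), function(i) decode_u(domain, U[i, ]))
    return(unique_points(pts, history$points)[seq_len(batch_size)])
  }
  X <- do.call(rbind, lapply(history$points, encode_point, domain = domain))
  fit <- gp_fit(X, history$scores)
  U <- matrix(stats::runif(n_candidates * nd), n_candidates, nd)
  cand <- lapply(seq_len(n_candidates), function(i) decode_u(domain, U[i, ]))
  cand <- unique_points(cand, history$points)
  Xc <- do.call(rbind, lapply(cand, encode_point, domain = domain))
  pr <- gp_predict(fit, Xc)
  acq <- expected_improvement(pr$mean, pr$sd, max(history$scores))
  chosen <- list()
  chosen_X <- NULL
  for (b in seq_len(min(batch_size, length(cand)))) {
    pen <- rep(1, length(cand))
    if (!is.null(chosen_X)) {
      for (r in seq_len(nrow(chosen_X))) {
        dd <- sqrt(rowSums(sweep(Xc, 2L, chosen_X[r, ])^2))
        pen <- pen * (1 - exp(-0.5 * (dd / 0.2)^2))
      }
    }
    i <- which.max(acq * pen + 1e-12 * stats::runif(length(cand)))
    chosen[[b]] <- cand[[i]]
    chosen_X <- rbind(chosen_X, Xc[i, ])
    acq[[i]] <- -Inf
  }
  chosen
}

# drop duplicates (within the list and against already-evaluated points)
unique_points <- function(pts, prev = NULL) {
  key <- function(p) paste(vapply(p, function(v) format(v, digits = 12), character(1)),
                           collapse = "|")
  prev_keys <- vapply(prev %||% list(), key, character(1))
  out <- list()
  seen <- character(0)
  for (p in pts) {
    k <- key(p)
    if (k %in% seen || k %in% prev_keys) next
    seen <- c(seen, k)
    out[[length(out) + 1L]] <- p
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian hyperparameter optimization loop
#'
#' Repeatedly suggests configurations, evaluates the objective, and
#' returns the incumbent best with the full audit trail. Objective
#' failures (errors or non-finite values) are recorded as a worst-case
#' score and the search continues.
#'
#' @param domain a [build_domain()].
#' @param objective function taking a named point (hyperparameter list)
#'   and returning a scalar score.
#' @param budget total number of objective evaluations.
#' @param batch_size suggestions per iteration.
#' @param direction `"max"` (e.g. AUC) or `"min"` (e.g. RMSE; scores
#'   are negated internally so the search always maximizes).
#' @param seed RNG seed for the whole search.
#' @return list of class `hyperopt_result`: `best_point`,
#'   `best_config`, `best_score` (on the objective's own scale), and
#'   `trail` (every evaluated point with its score, in order).
#' @export
optimize_hyper <- function(domain, objective, budget = 20L, batch_size = 1L,
                           direction = c("max", "min"), seed = 0L) {
  direction <- match.arg(direction)
  sgn <- if (direction == "max") 1 else -1
  set.seed(seed)
  history <- list(points = list(), scores = numeric(0))
  raw_scores <- numeric(0)
  while (length(history$scores) < budget) {
    k <- min(batch_size, budget - length(history$scores))
    pts <- suggest_batch(history, domain, k)
    for (p in pts) {
      val <- tryCatch(objective(p), error = function(e) NA_real_)
      raw_scores <- c(raw_scores, val)
      sc <- if (is.finite(val)) sgn * val else NA_real_
      if (is.na(sc)) {
        fin <- history$scores[is.finite(history$scores)]
        sc <- if (length(fin)) min(fin) - stats::sd(c(fin, 0)) - 1 else -1e6
      }
      history$points[[length(history$points) + 1L]] <- p
      history$scores <- c(history$scores, sc)
    }
  }
  i <- which.max(history$scores)
  structure(list(best_point = history$points[[i]],
                 best_config = config_from_point(domain, history$points[[i]]),
                 best_score = raw_scores[[i]],
                 trail = list(points = history$points, scores = raw_scores,
                              internal_scores = history$scores)),
            class = "hyperopt_result")
}

#' @export
print.hyperopt_result <- function(x, ...) {
  cat("<hyperopt_result>", length(x$trail$scores), "evaluations; best score",
      format(x$best_score, digits = 5), "\n")
  invisible(x)
}
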