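# Train/validation/test splitting (random and Bemis-Murcko scaffold)
# and per-task target normalization fitted on training data only.

split_spec <- function(method, ratios, seed, train, valid, test) {
  structure(list(method = method, ratios = ratios, seed = seed,
                 train = as.integer(train), valid = as.integer(valid),
                 test = as.integer(test)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec>", x$method, "- train/valid/test =",
      length(x$train), "/", length(x$valid), "/", length(x$test), "\n")
  invisible(x)
}

#' Random split
#'
#' Deterministic shuffle split of `n` rows into train/valid/test at the
#' given ratios; a fixed seed reproduces the same membership, and
#' distinct seeds give the repeat splits of the evaluation protocol.
#'
#' @param n number of rows.
#' @param ratios length-3 fractions summing to 1 (default 80/10/10).
#' @param seed integer RNG seed.
#' @return a `split_spec` with disjoint index vectors covering `1:n`.
#' @export
random_split <- function(n, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  if (n < 3) stop("need at least as many rows as sets (3)", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  i1 <- floor(n * ratios[[1L]])
  i2 <- floor(n * (ratios[[1L]] + ratios[[2L]]))
  split_spec("random", ratios, seed,
             perm[seq_len(i1)],
             perm[seq.int(i1 + 1L, i2)],
             perm[seq.int(i2 + 1L, n)])
}

#' Bemis-Murcko scaffold
#'
#' The molecular framework: ring systems plus the linkers between them,
#' with side chains removed. Acyclic molecules map to the empty
#' scaffold `""`.
#'
#' @param smiles character vector.
#' @return character vector of canonical scaffold SMILES.
#' @export
murcko_scaffold <- function(smiles) {
  res <- backend_call("scaffold", smiles)
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    stop("murcko_scaffold failed for ", shQuote(smiles[[bad[[1L]]]]), ": ",
         res[[bad[[1L]]]]$error, call. = FALSE)
  }
  vapply(res, `[[`, character(1), "scaffold")
}

#' Scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold and assigns whole groups
#' greedily -- largest first, ties broken by scaffold string -- to
#' train, then validation, then test, so no scaffold ever spans two
#' sets. A single group larger than the train target still goes to
#' train, with a warning.
#'
#' @param smiles character vector (all parseable).
#' @param ratios length-3 fractions summing to 1.
#' @return a `split_spec`; the `seed` field is `NA` since the split is
#'   fully deterministic.
#' @export
scaffold_split <- function(smiles, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  n <- length(smiles)
  if (n < 3) stop("need at least as many rows as sets (3)", call. = FALSE)
  scaf <- murcko_scaffold(smiles)
  groups <- split(seq_len(n), scaf)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  train_cutoff <- ratios[[1L]] * n
  valid_cutoff <- (ratios[[1L]] + ratios[[2L]]) * n
  train <- valid <- test <- integer(0)
  for (g in groups) {
    if (length(g) > train_cutoff) {
      warning("a scaffold class exceeds the train fraction; assigned to train",
              call. = FALSE)
      train <- c(train, g)
    } else if (length(train) + length(g) <= train_cutoff) {
      train <- c(train, g)
    } else if (length(train) + length(valid) + length(g) <= valid_cutoff) {
      valid <- c(valid, g)
    } else {
      test <- c(test, g)
    }
  }
  split_spec("scaffold", ratios, NA_integer_, train, valid, test)
}

#' Write and read split index files
#'
#' Splits are persisted as a single JSON object with three integer
#' arrays so an exact membership can be reused across runs.
#'
#' @param split a `split_spec`.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(method = split$method, ratios = split$ratios,
                            seed = split$seed, train = split$train,
                            valid = split$valid, test = split$test),
                       path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_spec(x$method, x$ratios,
             if (is.null(x$seed) || is.na(x$seed)) NA_integer_ else x$seed,
             x$train, x$valid, x$test)
}

#' Per-task target normalization
#'
#' `fit_normalization()` computes per-task mean and (sample) standard
#' deviation over the observed training cells; `apply_normalization()`
#' and `invert_normalization()` transform label matrices to and from
#' the standardized space. Models train on normalized targets and
#' predictions are transformed back before any metric is computed.
#'
#' @param labels numeric matrix (training rows).
#' @param mask logical observation mask of the same shape; defaults to
#'   all observed.
#' @return `fit_normalization()`: an object of class `norm_stats` with
#'   fields `mean` and `sd` per task.
#' @export
fit_normalization <- function(labels, mask = NULL) {
  labels <- as.matrix(labels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  mu <- sdv <- numeric(ncol(labels))
  for (j in seq_len(ncol(labels))) {
    x <- labels[mask[, j], j]
    if (length(x) < 2) stop("task ", j, ": fewer than two observed training values",
                            call. = FALSE)
    mu[[j]] <- mean(x)
    sdv[[j]] <- stats::sd(x)
    if (!is.finite(sdv[[j]]) || sdv[[j]] <= 0) {
      nm <- colnames(labels)[j]
      stop("task ", if (!is.null(nm)) nm else j, " is constant on the training set",
           call. = FALSE)
    }
  }
  structure(list(mean = mu, sd = sdv), class = "norm_stats")
}

#' @rdname fit_normalization
#' @param stats a `norm_stats`.
#' @export
apply_normalization <- function(labels, stats) {
  sweep(sweep(as.matrix(labels), 2L, stats$mean, `-`), 2L, stats$sd, `/`)
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(labels, stats) {
  sweep(sweep(as.matrix(labels), 2L, stats$sd, `*`), 2L, stats$mean, `+`)
}
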