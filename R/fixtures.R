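# Synthetic molecule sets and tasks with known generative rules. Every
# label is a deterministic function of the molecular graph, so training
# runs can be scored against the generating rule itself. The fragment
# grammar keeps molecules to ~12 heavy atoms so exhaustive oracle
# comparisons stay cheap.

FIXTURE_SCAFFOLDS <- c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1cc[nH]c1",
                       "C1CCCCC1", "C1CCCC1", "C1CCOC1", "")
FIXTURE_CHAINS <- c("C", "CC", "CCC", "O", "N", "CO", "CN", "CCO", "CCN",
                    "C(=O)O", "C(=O)N", "C=C", "C#N", "Cl", "F", "Br", "S", "OC")
FIXTURE_SALTS <- c("CC(=O)[O-].[Na+]", "CCC(=O)[O-].[Na+]", "c1ccccc1C(=O)[O-].[K+]",
                   "CC[NH3+].[Cl-]", "c1ccncc1.[Na+].[Cl-]", "CNC.[Cl-].[NH4+]",
                   "CS(=O)(=O)[O-].[K+]", "OCC[NH3+].[Br-]")

#' Generate fixture molecules
#'
#' Assembles valid SMILES from a small fragment grammar: a ring
#' scaffold (or none) decorated with up to two side chains, all kept to
#' at most `max_heavy` heavy atoms, canonicalized and deduplicated.
#' Deterministic for a fixed seed.
#'
#' @param n number of unique molecules to return.
#' @param seed RNG seed.
#' @param scaffold_diversity how many distinct ring scaffolds the
#'   grammar may draw from (1--8; the last slot is the acyclic class).
#' @param salt_frac fraction of outputs drawn from the charged
#'   salt-pair grammar (multi-fragment SMILES with counterions), for
#'   exercising charge-parent standardization.
#' @param max_heavy heavy-atom cap per molecule.
#' @return character vector of `n` unique canonical-form SMILES.
#' @export
gen_molecules <- function(n, seed = 1L, scaffold_diversity = 6L,
                          salt_frac = 0, max_heavy = 12L) {
  stopifnot(n >= 1, scaffold_diversity >= 1,
            scaffold_diversity <= length(FIXTURE_SCAFFOLDS),
            salt_frac >= 0, salt_frac <= 1)
  set.seed(seed)
  scaffolds <- FIXTURE_SCAFFOLDS[seq_len(scaffold_diversity)]
  n_salt <- round(n * salt_frac)
  out <- character(0)
  seen <- character(0)
  draw_plain <- function() {
    sc <- sample(scaffolds, 1L)
    k <- sample(0:2, 1L)
    chains <- sample(FIXTURE_CHAINS, k, replace = TRUE)
    if (sc == "") {
      base <- if (k == 0) "CC" else paste0("C", paste(chains, collapse = ""))
    } else if (k == 0) {
      base <- sc
    } else if (k == 1) {
      base <- paste0(chains[[1L]], sc)
    } else {
      # substitute at two ring positions: prefix + inline branch
      core <- sub("1ccc", paste0("1cc(", chains[[2L]], ")c"), sc)
      if (identical(core, sc)) core <- sc  # scaffold without that motif
      base <- paste0(chains[[1L]], core)
    }
    base
  }
  tries <- 0L
  while (length(out) < n && tries < 200L * n) {
    tries <- tries + 1L
    want_salt <- sum(grepl(".", out, fixed = TRUE)) < n_salt
    cand <- if (want_salt) sample(FIXTURE_SALTS, 1L) else draw_plain()
    res <- backend_call("perceive", cand)[[1L]]
    if (!isTRUE(res$ok) || res$n_atoms > max_heavy) next
    can <- res$canonical_smiles
    if (can %in% seen) next
    seen <- c(seen, can)
    out <- c(out, cand)
  }
  if (length(out) < n) {
    stop("fragment grammar exhausted at ", length(out), " unique molecules",
         call. = FALSE)
  }
  out
}

# ---- graph-computable label rules --------------------------------------

n_components_of <- function(graph) {
  n <- graph$n_atoms
  parent <- seq_len(n)
  find <- function(i) { while (parent[[i]] != i) { parent[[i]] <<- parent[[parent[[i]]]]; i <- parent[[i]] }; i }
  ei <- graph$edge_index
  for (r in seq_len(nrow(ei))) {
    a <- find(as.integer(ei[r, 1L])); b <- find(as.integer(ei[r, 2L]))
    if (a != b) parent[[a]] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

element_block <- function(graph, schema) {
  graph$node_features[, seq_len(length(schema$elements) + 1L), drop = FALSE]
}

aromatic_col <- function(schema) {
  length(schema$elements) + 1L + 7L + 7L + 1L + 1L + 5L + 1L
}

fixture_rule_value <- function(rule, graph, schema) {
  arom <- graph$node_features[, aromatic_col(schema)]
  el <- element_block(graph, schema)
  elem_counts <- colSums(el)
  names(elem_counts) <- c(schema$elements, "other")
  ec <- edge_class_of(graph)
  n_bonds <- nrow(graph$edge_index) / 2
  switch(rule,
    n_atoms = graph$n_atoms,
    n_aromatic_atoms = sum(arom),
    n_hetero = graph$n_atoms - elem_counts[["C"]],
    has_aromatic = as.numeric(sum(arom) > 0),
    has_nitrogen = as.numeric(elem_counts[["N"]] > 0),
    has_ring = as.numeric(n_bonds - graph$n_atoms + n_components_of(graph) > 0),
    has_carbonyl = {
      # a C=O bond: double-bond edge whose endpoints are C and O
      hit <- FALSE
      ei <- graph$edge_index
      for (r in which(ec == 2L)) {
        syms <- c(which(el[ei[r, 1L], ] == 1), which(el[ei[r, 2L], ] == 1))
        if (setequal(syms, match(c("C", "O"), c(schema$elements, "other")))) hit <- TRUE
      }
      as.numeric(hit)
    },
    additive_property = {
      # fixed per-element weights plus an aromaticity bonus; additive
      # over atoms, hence exactly representable by a summed readout
      w <- c(C = 1, N = 2.5, O = -1.5, S = 3, F = -2, Cl = 2, Br = 4, I = 5,
             P = 2, B = 1, Si = 1, Se = 3, other = 0)
      sum(elem_counts * w[names(elem_counts)]) + 0.5 * sum(arom)
    },
    stop("unknown fixture rule: ", rule, call. = FALSE)
  )
}

#' Generate labels for fixture molecules
#'
#' Computes deterministic graph-derived labels and samples an
#' observation mask. Each task spec is a list with `name`, `rule`, and
#' optional `missing_rate` (cells masked as missing), `noise_sd`
#' (Gaussian noise added to regression values), and `flip_prob`
#' (label noise for classification). Available rules: `n_atoms`,
#' `n_aromatic_atoms`, `n_hetero`, `additive_property` (regression);
#' `has_aromatic`, `has_nitrogen`, `has_ring`, `has_carbonyl`
#' (classification). Correlated task groups are obtained by repeating a
#' rule with independent noise.
#'
#' @param smiles character vector of molecules.
#' @param tasks list of task specs.
#' @param task_kind `"classification"` or `"regression"` (all tasks in
#'   a table share a kind).
#' @param seed RNG seed for mask and noise sampling.
#' @param schema the [atom_feature_schema()] used for rule evaluation.
#' @return a [task_table()].
#' @export
gen_labels <- function(smiles, tasks,
                       task_kind = c("classification", "regression"),
                       seed = 1L, schema = atom_feature_schema()) {
  task_kind <- match.arg(task_kind)
  set.seed(seed)
  graphs <- featurize_molecules(smiles, schema)
  labels <- matrix(0, length(smiles), length(tasks))
  mask <- matrix(TRUE, length(smiles), length(tasks))
  nms <- character(length(tasks))
  for (j in seq_along(tasks)) {
    tk <- tasks[[j]]
    nms[[j]] <- if (!is.null(tk$name)) tk$name else tk$rule
    vals <- vapply(graphs, fixture_rule_value, numeric(1),
                   rule = tk$rule, schema = schema)
    if (task_kind == "regression") {
      if (!is.null(tk$noise_sd) && tk$noise_sd > 0) {
        vals <- vals + stats::rnorm(length(vals), sd = tk$noise_sd)
      }
    } else {
      if (!all(vals %in% c(0, 1))) {
        stop("rule ", tk$rule, " is not binary; use task_kind = \"regression\"",
             call. = FALSE)
      }
      if (!is.null(tk$flip_prob) && tk$flip_prob > 0) {
        flip <- stats::runif(length(vals)) < tk$flip_prob
        vals[flip] <- 1 - vals[flip]
      }
    }
    labels[, j] <- vals
    mr <- if (is.null(tk$missing_rate)) 0 else tk$missing_rate
    if (mr > 0) mask[, j] <- stats::runif(length(vals)) >= mr
  }
  colnames(labels) <- nms
  task_table(smiles, labels, mask, nms, task_kind)
}
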