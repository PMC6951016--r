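# SMD ("Standardised Missing Data") preprocessing: replace each SMILES
# by its charge parent -- the neutralized largest organic covalent unit
# of a salt or complex -- and keep unlabelled cells as explicit missing
# values instead of imputing them as inactive.

#' Multitask property table
#'
#' Aligned SMILES, a label matrix, and an observation mask. Missing
#' cells carry `0` in `labels` and `FALSE` in `mask`; every downstream
#' loss and metric consults the mask and never the placeholder value.
#'
#' @param smiles character vector of SMILES.
#' @param labels numeric matrix `n_molecules x n_tasks`; classification
#'   labels are 1 (active) / 0 (inactive).
#' @param mask logical matrix of the same shape, `TRUE` = observed.
#'   Defaults to all-observed.
#' @param task_names column names for the tasks.
#' @param task_kind `"classification"` or `"regression"`.
#' @return an object of class `task_table`.
#' @export
task_table <- function(smiles, labels, mask = NULL,
                       task_names = colnames(labels),
                       task_kind = c("classification", "regression")) {
  task_kind <- match.arg(task_kind)
  labels <- as.matrix(labels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(labels), ncol(labels))
  mask <- as.matrix(mask)
  stopifnot(length(smiles) == nrow(labels),
            identical(dim(labels), dim(mask)),
            is.logical(mask))
  if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(labels)))
  labels[!mask] <- 0
  if (task_kind == "classification") {
    obs <- labels[mask]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("classification labels must be 0/1", call. = FALSE)
    }
  }
  dimnames(labels) <- list(NULL, task_names)
  structure(list(smiles = as.character(smiles), labels = labels, mask = mask,
                 task_names = task_names, task_kind = task_kind),
            class = "task_table")
}

#' @export
print.task_table <- function(x, ...) {
  cat("<task_table>", length(x$smiles), "molecules x", length(x$task_names),
      sprintf("%s task(s); %.1f%% of cells observed\n", x$task_kind,
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
`[.task_table` <- function(x, i) {
  task_table(x$smiles[i], x$labels[i, , drop = FALSE], x$mask[i, , drop = FALSE],
             x$task_names, x$task_kind)
}

#' Charge-parent standardization
#'
#' Returns the uncharged form of the largest organic covalent unit of
#' each input: counterions and minor fragments are dropped and the
#' remaining fragment neutralized where chemically possible (a
#' quaternary nitrogen, for instance, keeps its charge and is flagged).
#' The output is canonical and the operation is idempotent.
#'
#' @param smiles character vector.
#' @return character vector of canonical charge-parent SMILES, with a
#'   logical attribute `charged` marking outputs whose net charge could
#'   not be neutralized. Unparseable input is an error.
#' @export
charge_parent <- function(smiles) {
  res <- backend_call("charge_parent", smiles)
  bad <- which(!vapply(res, function(r) isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    stop("charge_parent failed for ", shQuote(smiles[[bad[[1L]]]]), ": ",
         res[[bad[[1L]]]]$error, call. = FALSE)
  }
  out <- vapply(res, `[[`, character(1), "smiles")
  attr(out, "charged") <- vapply(res, function(r) r$residual_charge != 0, logical(1))
  out
}

parse_raw_labels <- function(df, smiles_col, missing_markers) {
  if (!smiles_col %in% names(df)) {
    stop("table has no ", shQuote(smiles_col), " column", call. = FALSE)
  }
  task_cols <- setdiff(names(df), smiles_col)
  if (!length(task_cols)) stop("table has no task columns", call. = FALSE)
  raw <- as.matrix(df[task_cols])
  chr <- trimws(ifelse(is.na(raw), "", as.character(raw)))
  mask <- !(chr %in% missing_markers)
  dim(mask) <- dim(raw)
  labels <- suppressWarnings(as.numeric(chr))
  labels[!mask] <- 0
  dim(labels) <- dim(raw)
  if (anyNA(labels[mask])) stop("non-numeric label cell in table", call. = FALSE)
  list(labels = labels, mask = mask, task_names = task_cols)
}

#' Apply SMD preprocessing to a raw table
#'
#' Standardizes the SMILES column to charge parents and turns empty
#' cells into explicit missing-value masks. Molecules whose
#' standardization fails are dropped (their count is reported in the
#' `n_dropped` attribute and a message).
#'
#' @param df a data frame as read from a MoleculeNet-style CSV: one
#'   SMILES column plus task columns, empty cells marking missing
#'   labels.
#' @param smiles_col name of the SMILES column.
#' @param task_kind `"classification"` or `"regression"`.
#' @param missing_markers cell values treated as missing.
#' @return a [task_table()] with attributes `n_dropped` and `charged`
#'   (count of rows whose parent kept a net charge).
#' @export
apply_smd <- function(df, smiles_col = "smiles",
                      task_kind = c("classification", "regression"),
                      missing_markers = c("", "NA")) {
  task_kind <- match.arg(task_kind)
  parsed <- parse_raw_labels(df, smiles_col, missing_markers)
  smi <- as.character(df[[smiles_col]])
  res <- backend_call("charge_parent", smi)
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("apply_smd: dropped ", n_dropped, " molecule(s) that failed standardization")
  }
  std <- vapply(res[ok], `[[`, character(1), "smiles")
  charged <- vapply(res[ok], function(r) r$residual_charge != 0, logical(1))
  tbl <- task_table(std, parsed$labels[ok, , drop = FALSE],
                    parsed$mask[ok, , drop = FALSE],
                    parsed$task_names, task_kind)
  attr(tbl, "n_dropped") <- n_dropped
  attr(tbl, "charged") <- sum(charged)
  tbl
}

#' Impute missing labels as inactive
#'
#' Converts a masked table to the "original dataset" convention in
#' which unlabelled cells are treated as observed inactives.
#'
#' @param table a [task_table()].
#' @export
impute_missing_as_inactive <- function(table) {
  stopifnot(inherits(table, "task_table"))
  labels <- table$labels
  labels[!table$mask] <- 0
  task_table(table$smiles, labels, mask = NULL, table$task_names, table$task_kind)
}

#' Label census
#'
#' Exact counts of actives, inactives, and missing cells per task and
#' in total, plus the two active-fraction conventions: over all cells
#' with missing imputed as inactive, and over observed cells only.
#'
#' @param table a classification [task_table()].
#' @return an object of class `label_census`.
#' @export
census <- function(table) {
  stopifnot(inherits(table, "task_table"))
  if (table$task_kind != "classification") {
    stop("census() is defined for classification tables only", call. = FALSE)
  }
  act <- colSums(table$labels == 1 & table$mask)
  inact <- colSums(table$labels == 0 & table$mask)
  mis <- colSums(!table$mask)
  per_task <- data.frame(task = table$task_names, actives = act,
                         inactives = inact, missing = mis, row.names = NULL)
  label_census_from_counts(sum(act), sum(inact), sum(mis), per_task = per_task)
}

#' @rdname census
#' @param actives,inactives,missing total cell counts, e.g. taken from
#'   a published dataset summary, when the underlying table itself is
#'   not at hand.
#' @param per_task optional per-task count data frame.
#' @export
label_census_from_counts <- function(actives, inactives, missing, per_task = NULL) {
  total <- actives + inactives + missing
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  observed <- actives + inactives
  structure(list(
    actives = actives, inactives = inactives, missing = missing, total = total,
    missing_ratio = frac(missing, total),
    # both conventions are undefined on a table with no observed cell
    active_fraction_imputed = if (observed > 0) frac(actives, total) else NA_real_,
    active_fraction_observed = frac(actives, observed),
    per_task = per_task
  ), class = "label_census")
}

#' @export
print.label_census <- function(x, ...) {
  cat("<label_census>", x$total, "cells:", x$actives, "active,",
      x$inactives, "inactive,", x$missing, "missing\n")
  cat(sprintf("  active fraction: %.4g%% (missing imputed inactive), %.4g%% (observed only)\n",
              100 * x$active_fraction_imputed, 100 * x$active_fraction_observed))
  invisible(x)
}

#' Read and write MoleculeNet-style CSV tables
#'
#' `read_raw_table()` returns the file as a character data frame with
#' empty cells preserved; `write_task_table()` writes a [task_table()]
#' back out with empty cells at masked positions, so SMD output flows
#' through the same readers as the raw data.
#'
#' @param path CSV path.
#' @export
read_raw_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = NULL)
}

#' @rdname read_raw_table
#' @param table a [task_table()].
#' @param smiles_col name for the SMILES column on disk.
#' @export
write_task_table <- function(table, path, smiles_col = "smiles") {
  stopifnot(inherits(table, "task_table"))
  cells <- matrix(as.character(table$labels), nrow(table$labels))
  cells[!table$mask] <- ""
  df <- data.frame(table$smiles, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(smiles_col, table$task_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
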