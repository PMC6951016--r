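# Bridge to the bundled RDKit helper script. All chemistry perception
# (SMILES parsing, standardization, scaffolds) runs through here so the
# rest of the package never re-implements a chemistry primitive.

the_backend <- new.env(parent = emptyenv())

backend_python <- function() {
  p <- Sys.getenv("MOLMPNN_PYTHON", unset = "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stop("no 'python' interpreter found on PATH; molmpnn needs Python with rdkit",
         call. = FALSE)
  }
  p
}

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "molmpnn")
  if (!nzchar(path)) stop("chem_backend.py not found in installed package", call. = FALSE)
  path
}

backend_call_raw <- function(op, smiles) {
  req <- jsonlite::toJSON(list(op = op, smiles = as.list(as.character(smiles))),
                          auto_unbox = TRUE)
  out <- suppressWarnings(
    system2(backend_python(), shQuote(backend_script()), input = as.character(req),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (exit status ", status, ")", call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)$results
}

# One Python process per *batch* of molecules; results memoised per
# (op, smiles) so repeated featurization of the same structures in a
# session costs one subprocess total.
backend_call <- function(op, smiles) {
  smiles <- as.character(smiles)
  keys <- paste0(op, "\r", smiles)
  res <- vector("list", length(smiles))
  cached <- vapply(keys, function(k) !is.null(the_backend[[k]]), logical(1))
  for (i in which(cached)) res[[i]] <- the_backend[[keys[[i]]]]
  todo <- which(!cached)
  if (length(todo)) {
    fresh <- backend_call_raw(op, smiles[todo])
    for (j in seq_along(todo)) {
      res[[todo[[j]]]] <- fresh[[j]]
      the_backend[[keys[[todo[[j]]]]]] <- fresh[[j]]
    }
  }
  res
}
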