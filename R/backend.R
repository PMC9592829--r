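# Bridge to the bundled RDKit helper (inst/python/chem_backend.py).
# Every call spawns one python process and exchanges a single JSON
# request/response pair over stdin/stdout; results are memoised per
# session so repeated featurization of the same molecules is free.

the <- new.env(parent = emptyenv())

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "fpgnn")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may not be installed yet
    path <- file.path("inst", "python", "chem_backend.py")
  }
  if (!file.exists(path)) stop("chem_backend.py not found", call. = FALSE)
  path
}

python_binary <- function() {
  Sys.getenv("FPGNN_PYTHON", unset = "python")
}

chem_call <- function(op, ...) {
  req <- jsonlite::toJSON(c(list(op = op), list(...)),
                          auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(req, tf)
  out <- suppressWarnings(system2(python_binary(), backend_script(),
                                  stdin = tf, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (op = ", op, ")", call. = FALSE)
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(res$ok)) {
    stop("chemistry backend error: ", res$error %||% "unknown", call. = FALSE)
  }
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Check that the RDKit molecule backend is available
#'
#' The package delegates molecule parsing, standardization, fingerprints,
#' scaffolds and depiction to RDKit through a bundled Python helper. This
#' verifies the `python` interpreter on `PATH` (override with the
#' `FPGNN_PYTHON` environment variable) can import RDKit.
#'
#' @return Invisibly, a list with the RDKit version and feature widths.
#' @export
rdkit_available <- function() {
  invisible(chem_call("ping"))
}

# memoised per-molecule backend query: fn maps a character vector of
# SMILES to a list of results (one per molecule)
cached_query <- function(key, smiles, fn) {
  if (is.null(the$cache)) the$cache <- new.env(parent = emptyenv())
  store <- the$cache[[key]]
  if (is.null(store)) {
    store <- new.env(parent = emptyenv())
    the$cache[[key]] <- store
  }
  miss <- unique(smiles[!vapply(smiles, exists, logical(1), envir = store)])
  if (length(miss) > 0) {
    vals <- fn(miss)
    for (i in seq_along(miss)) assign(miss[[i]], vals[[i]], envir = store)
  }
  lapply(smiles, get, envir = store)
}

clear_chem_cache <- function() {
  the$cache <- new.env(parent = emptyenv())
  invisible(NULL)
}
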