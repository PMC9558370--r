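#' @keywords internal
chem_python <- function() {
  getOption("alchemal.python", Sys.getenv("ALCHEMAL_PYTHON", "python"))
}

#' Is the chemistry backend available?
#'
#' Chemistry-dependent functionality (fragment decomposition, library
#' enumeration, descriptor featurization, t-SNE embeddings) is delegated to
#' a bundled Python helper using RDKit and scikit-learn. This checks that
#' the `python` interpreter (option `alchemal.python` or env var
#' `ALCHEMAL_PYTHON`, default `"python"`) can import RDKit.
#'
#' @return `TRUE` or `FALSE`.
#' @export
has_chem_backend <- function() {
  res <- tryCatch(
    suppressWarnings(system2(chem_python(), c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)),
    error = function(e) 1L
  )
  identical(res, 0L)
}

#' Run one operation of the bundled chemistry helper
#'
#' @param op Operation name understood by `inst/python/chem_backend.py`.
#' @param ... Operation arguments, JSON-serializable.
#' @return The parsed response list (without the `ok` field).
#' @keywords internal
run_chem_op <- function(op, ...) {
  script <- system.file("python", "chem_backend.py", package = "alchemal",
                        mustWork = TRUE)
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(c(list(op = op), list(...)), req,
                       auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(
    system2(chem_python(), c(script, req, res), stdout = TRUE, stderr = TRUE)
  )
  if (!file.exists(res) || length(attr(status, "status")) > 0) {
    stop("chemistry backend failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  out <- jsonlite::fromJSON(res, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!isTRUE(out$ok)) stop("chemistry backend: ", out$error, call. = FALSE)
  out$ok <- NULL
  out
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; unparseable entries error.
#' @export
smiles_canonicalize <- function(smiles) {
  out <- run_chem_op("canonicalize", smiles = as.list(smiles))
  bad <- unlist(out$invalid)
  if (length(bad) > 0) {
    stop("unparseable SMILES: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unlist(out$canonical)
}
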