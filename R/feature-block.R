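#' Construct a feature block
#'
#' A feature block is the package's container for a named matrix of
#' per-ligand numeric features: rows align with ligand identifiers, columns
#' carry unique feature names, and standardization state (per-column center
#' and scale fitted on a declared set of ligands) travels with the block.
#'
#' @param matrix Numeric matrix, one row per ligand.
#' @param ligand_ids Character vector aligned with rows.
#' @param feature_names Character vector aligned with columns (defaults to
#'   existing column names).
#' @param name Block name, e.g. `"2D_3D"`, `"atom_hot"`, `"external:PLEC"`.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(matrix, ligand_ids, feature_names = colnames(matrix),
                          name = "block") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (length(ligand_ids) != nrow(matrix)) {
    stop("ligand_ids must align with matrix rows", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  dimnames(matrix) <- list(as.character(ligand_ids), feature_names)
  structure(
    list(name = name, matrix = matrix, standardized = FALSE,
         center = NULL, scale = NULL, fit_ids = NULL,
         dropped_features = character(0)),
    class = "feature_block"
  )
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block '%s'> %d ligands x %d features%s\n", x$name,
              nrow(x$matrix), ncol(x$matrix),
              if (x$standardized) " (standardized)" else ""))
  if (length(x$dropped_features) > 0) {
    cat(sprintf("  %d non-finite feature(s) dropped\n",
                length(x$dropped_features)))
  }
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$matrix)

#' Ligand identifiers of a feature block
#' @param block A `feature_block`.
#' @return Character vector of row identifiers.
#' @export
block_ids <- function(block) rownames(block$matrix)

#' @importFrom tibble as_tibble
#' @export
as_tibble.feature_block <- function(x, ...) {
  tibble::as_tibble(x$matrix) |>
    tibble::add_column(ligand_id = rownames(x$matrix), .before = 1)
}

#' Drop feature columns with non-finite values
#' @keywords internal
drop_nonfinite_columns <- function(block) {
  bad <- apply(block$matrix, 2, function(v) any(!is.finite(v)))
  if (any(bad)) {
    block$dropped_features <- c(block$dropped_features,
                                colnames(block$matrix)[bad])
    message(sum(bad), " feature(s) dropped from '", block$name,
            "' (non-finite for some ligand)")
    block$matrix <- block$matrix[, !bad, drop = FALSE]
  }
  block
}

#' Standardize a feature block to zero mean and unit variance
#'
#' The affine transform is fitted on the rows named by `fit_ids` only and
#' then applied to every row, so statistics never leak from outside the
#' fitting set (e.g. from unevaluated library ligands into model training).
#' Columns constant on the fitting set are centered but left unscaled.
#'
#' @param block A `feature_block`.
#' @param fit_ids Ligand ids defining the fitting set (default: all rows).
#' @return A standardized `feature_block` with `center`/`scale` recorded.
#' @export
standardize_block <- function(block, fit_ids = block_ids(block)) {
  stopifnot(inherits(block, "feature_block"))
  fit_ids <- as.character(fit_ids)
  if (length(fit_ids) == 0) stop("fit_ids must be non-empty", call. = FALSE)
  missing <- setdiff(fit_ids, block_ids(block))
  if (length(missing) > 0) {
    stop("fit_ids not in block: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fit <- block$matrix[fit_ids, , drop = FALSE]
  ctr <- colMeans(fit)
  scl <- apply(fit, 2, stats::sd)
  constant <- !is.finite(scl) | scl == 0
  scl[constant] <- 1
  block$matrix <- sweep(sweep(block$matrix, 2, ctr, "-"), 2, scl, "/")
  block$standardized <- TRUE
  block$center <- ctr
  block$scale <- scl
  block$fit_ids <- fit_ids
  block
}

#' Invert standardization of a feature block
#' @param block A standardized `feature_block`.
#' @return The block on its original scale.
#' @export
unstandardize_block <- function(block) {
  stopifnot(inherits(block, "feature_block"), isTRUE(block$standardized))
  block$matrix <- sweep(sweep(block$matrix, 2, block$scale, "*"),
                        2, block$center, "+")
  block$standardized <- FALSE
  block$center <- block$scale <- block$fit_ids <- NULL
  block
}

#' Attach a precomputed external feature matrix
#'
#' Ingests feature matrices computed outside the package — e.g.
#' protein–ligand interaction fingerprints or per-residue force-field
#' interaction energies — from a CSV whose first column is `ligand_id`.
#' Rows are reordered to library order; extra ligands are dropped with a
#' warning and missing ligands are a hard error.
#'
#' @param path CSV path (header row; first column `ligand_id`).
#' @param name Block name; conventionally prefixed `"external:"`.
#' @param library A ligand tibble defining the required ids and order.
#' @return A `feature_block`.
#' @export
attach_external_block <- function(path, name, library) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"ligand_id" %in% names(df)) {
    stop("external feature CSV must have a ligand_id column", call. = FALSE)
  }
  df$ligand_id <- as.character(df$ligand_id)
  missing <- setdiff(library$ligand_id, df$ligand_id)
  if (length(missing) > 0) {
    stop("external block '", name, "' missing ligand(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(df$ligand_id, library$ligand_id)
  if (length(extra) > 0) {
    warning(length(extra), " ligand(s) in '", name,
            "' not in the library were ignored", call. = FALSE)
  }
  df <- df[match(library$ligand_id, df$ligand_id), , drop = FALSE]
  m <- as.matrix(df[setdiff(names(df), "ligand_id")])
  feature_block(m, library$ligand_id, colnames(m), name = name)
}

#' Write / read a feature block as CSV
#'
#' The on-disk dialect is a plain CSV with a header row of feature names
#' and a leading `ligand_id` column.
#'
#' @param block A `feature_block`.
#' @param path CSV path.
#' @return `write_feature_block()` returns the block invisibly;
#'   `read_feature_block()` returns a `feature_block`.
#' @export
write_feature_block <- function(block, path) {
  readr::write_csv(as_tibble(block), path)
  invisible(block)
}

#' @rdname write_feature_block
#' @param name Block name for the block read back.
#' @export
read_feature_block <- function(path, name = "block") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[setdiff(names(df), "ligand_id")])
  feature_block(m, as.character(df$ligand_id), colnames(m), name = name)
}

#' Column-bind feature blocks over a common ligand set
#' @param ... `feature_block` objects sharing identical ligand ids.
#' @param name Name of the combined block.
#' @return A `feature_block` with namespaced feature names.
#' @export
cbind_blocks <- function(..., name = "combined") {
  blocks <- list(...)
  ids <- block_ids(blocks[[1]])
  mats <- lapply(blocks, function(b) {
    stopifnot(identical(block_ids(b), ids))
    m <- b$matrix
    colnames(m) <- paste(b$name, colnames(m), sep = ".")
    m
  })
  feature_block(do.call(cbind, mats), ids, name = name)
}
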