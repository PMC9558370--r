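#' Affinity record tibble
#'
#' Oracle outputs are tibbles with columns `ligand_id`, `dg` (binding free
#' energy, kcal/mol, more negative = stronger), `uncertainty` (standard
#' error, kcal/mol), `source` (`"experiment"`, `"computed"`, `"synthetic"`)
#' and `n_replicates`.
#'
#' @keywords internal
affinity_tbl <- function(ligand_id, dg, uncertainty, source, n_replicates) {
  stopifnot(all(is.finite(dg)), all(uncertainty >= 0))
  tibble::tibble(ligand_id = as.character(ligand_id), dg = dg,
                 uncertainty = uncertainty, source = source,
                 n_replicates = as.integer(n_replicates))
}

#' Lookup oracle over a table of measured affinities
#'
#' The retrospective mode: the expensive free-energy calculation step is
#' replaced by a lookup into a table of measured binding free energies.
#'
#' @param batch Character vector of ligand ids to evaluate.
#' @param table A data frame with columns `ligand_id`, `dg` and optionally
#'   `uncertainty` (defaults to 0), or a named numeric vector of dg values.
#' @return An affinity tibble in batch order with `source = "experiment"`.
#' @export
lookup_oracle <- function(batch, table) {
  if (is.numeric(table)) {
    table <- tibble::tibble(ligand_id = names(table), dg = unname(table))
  }
  if (!"uncertainty" %in% names(table)) table$uncertainty <- 0
  batch <- as.character(batch)
  idx <- match(batch, table$ligand_id)
  if (anyNA(idx)) {
    stop("ligand(s) absent from the affinity table: ",
         paste(batch[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  affinity_tbl(batch, table$dg[idx], table$uncertainty[idx],
               "experiment", 1L)
}

#' Synthetic free-energy oracle with replicate noise
#'
#' Emulates a replicate-based alchemical oracle: each queried ligand's true
#' binding free energy is perturbed by `n_replicates` independent Gaussian
#' draws of standard deviation `sigma`; the replicate mean is returned as
#' `dg` and the replicate standard error as `uncertainty`. The default
#' `sigma` of 1.1 kcal/mol matches the typical accuracy of alchemical
#' free-energy estimates against experiment; the default of 5 replicates
#' mirrors a 5-repeat simulation protocol.
#'
#' @param batch Ligand ids to evaluate.
#' @param truth Data frame with `ligand_id`, `dg_true`, or a named numeric
#'   vector.
#' @param sigma Per-replicate noise standard deviation, kcal/mol.
#' @param n_replicates Replicates per ligand.
#' @param seed RNG seed for reproducibility.
#' @param cluster_bias Optional named numeric vector of systematic offsets
#'   keyed by ligand id (e.g. a per-cluster bias); default none.
#' @return An affinity tibble with `source = "synthetic"`.
#' @export
synthetic_oracle <- function(batch, truth, sigma = 1.1, n_replicates = 5L,
                             seed = 1L, cluster_bias = NULL) {
  stopifnot(sigma >= 0, n_replicates >= 1)
  if (is.numeric(truth)) {
    truth <- tibble::tibble(ligand_id = names(truth), dg_true = unname(truth))
  }
  batch <- as.character(batch)
  idx <- match(batch, truth$ligand_id)
  if (anyNA(idx)) {
    stop("ligand(s) absent from the truth table: ",
         paste(batch[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  dg_true <- truth$dg_true[idx]
  if (!is.null(cluster_bias)) {
    dg_true <- dg_true + ifelse(is.na(cluster_bias[batch]), 0,
                                cluster_bias[batch])
  }
  reps <- withr::with_seed(seed, {
    matrix(stats::rnorm(length(batch) * n_replicates, mean = rep(dg_true,
           each = n_replicates), sd = sigma), nrow = n_replicates)
  })
  dg <- colMeans(reps)
  se <- if (n_replicates > 1) {
    apply(reps, 2, stats::sd) / sqrt(n_replicates)
  } else {
    rep(0, length(batch))
  }
  affinity_tbl(batch, dg, se, "synthetic", n_replicates)
}

#' Convert relative to absolute binding free energy
#'
#' Relative free energies from a star-map of perturbations against a
#' reference ligand are combined with the reference's known absolute
#' binding free energy; uncertainties propagate in quadrature.
#'
#' @param ddg Relative binding free energy, kcal/mol.
#' @param reference_dg Absolute binding free energy of the reference,
#'   kcal/mol.
#' @param ddg_err,reference_err Optional standard errors.
#' @return A tibble with `dg` and `uncertainty`.
#' @export
rel_to_abs <- function(ddg, reference_dg, ddg_err = 0, reference_err = 0) {
  stopifnot(all(is.finite(ddg)), all(is.finite(reference_dg)))
  tibble::tibble(dg = reference_dg + ddg,
                 uncertainty = sqrt(ddg_err^2 + reference_err^2))
}

#' Write a batch manifest for an external free-energy engine
#'
#' Bridges the loop to an external engine: each iteration's batch is
#' exported as a CSV manifest (`ligand_id`, `smiles`, `reference_id`,
#' `iteration`); results come back as a CSV (`ligand_id`, `ddg`, `stderr`)
#' read by [read_oracle_results()].
#'
#' @param batch Ligand ids in the batch.
#' @param library A ligand tibble supplying SMILES.
#' @param iteration Iteration number.
#' @param reference_id Reference ligand id for relative free energies.
#' @param path Output CSV path.
#' @return The manifest tibble, invisibly.
#' @export
write_oracle_manifest <- function(batch, library, iteration, reference_id,
                                  path) {
  idx <- match(batch, library$ligand_id)
  if (anyNA(idx)) {
    stop("batch ligand(s) missing from library: ",
         paste(batch[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  manifest <- tibble::tibble(ligand_id = batch, smiles = library$smiles[idx],
                             reference_id = reference_id,
                             iteration = iteration)
  readr::write_csv(manifest, path)
  invisible(manifest)
}

#' Read external-engine results and convert to absolute free energies
#'
#' @param path Results CSV with columns `ligand_id`, `ddg`, `stderr`.
#' @param reference_dg Absolute dg of the reference ligand, kcal/mol.
#' @param reference_err Standard error of the reference dg.
#' @param expected Optional ids expected back; any absent are reported in
#'   the `pending` attribute rather than erroring (partial results).
#' @return An affinity tibble (`source = "computed"`) with attribute
#'   `pending` listing awaited ligand ids.
#' @export
read_oracle_results <- function(path, reference_dg, reference_err = 0,
                                expected = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("ligand_id", "ddg", "stderr")
  if (!all(need %in% names(df))) {
    stop("results file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$ddg) | !is.finite(df$stderr))
  if (length(bad) > 0) {
    stop("malformed results row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  conv <- rel_to_abs(df$ddg, reference_dg, df$stderr, reference_err)
  out <- affinity_tbl(df$ligand_id, conv$dg, conv$uncertainty, "computed", 5L)
  attr(out, "pending") <- if (is.null(expected)) character(0) else
    setdiff(as.character(expected), df$ligand_id)
  out
}
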