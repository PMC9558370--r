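#' Evaluation metrics for one iteration of active learning
#'
#' Computes the four panel metrics used to compare selection strategies:
#' prediction RMSE and Kendall rank correlation over an id set, the
#' fraction of the true top-N binders already evaluated, and the true
#' positive rate at an affinity threshold (among ligands whose true free
#' energy is at or below the threshold, the fraction predicted at or
#' below it).
#'
#' @param predictions Prediction tibble (`ligand_id`, `mean_dg`).
#' @param truth Tibble `ligand_id`, `dg_true` (or named numeric vector)
#'   covering the prediction ids.
#' @param evaluated_ids Ids already evaluated by the oracle.
#' @param top_n Size of the true top-N set (default 50).
#' @param tpr_threshold Free-energy threshold, kcal/mol (default -13.29,
#'   the experimental affinity of the strongest validation binder in a
#'   PDE2-style run).
#' @param ids Id set over which RMSE and Kendall tau are computed
#'   (default: all prediction ids).
#' @return A one-row tibble: `rmse`, `kendall_tau`, `top_n_recovered`,
#'   `tpr`, `n_evaluated`.
#' @export
compute_metrics <- function(predictions, truth, evaluated_ids,
                            top_n = 50L, tpr_threshold = -13.29,
                            ids = predictions$ligand_id) {
  if (is.numeric(truth)) {
    truth <- tibble::tibble(ligand_id = names(truth), dg_true = unname(truth))
  }
  ids <- as.character(ids)
  if (length(ids) == 0) stop("empty id set", call. = FALSE)
  pred <- predictions$mean_dg[match(ids, predictions$ligand_id)]
  tru <- truth$dg_true[match(ids, truth$ligand_id)]
  if (anyNA(tru) || anyNA(pred)) {
    stop("truth or predictions do not cover the requested ids", call. = FALSE)
  }
  top_ids <- truth$ligand_id[order(truth$dg_true)][seq_len(min(top_n,
                                                               nrow(truth)))]
  is_pos <- tru <= tpr_threshold
  tibble::tibble(
    rmse = sqrt(mean((pred - tru)^2)),
    kendall_tau = if (stats::sd(pred) == 0 || stats::sd(tru) == 0) {
      NA_real_
    } else {
      stats::cor(pred, tru, method = "kendall")
    },
    top_n_recovered = mean(top_ids %in% evaluated_ids),
    tpr = if (any(is_pos)) mean(pred[is_pos] <= tpr_threshold) else NA_real_,
    n_evaluated = length(unique(evaluated_ids))
  )
}
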