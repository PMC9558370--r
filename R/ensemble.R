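#' Training hyper-parameters for the perceptron ensemble
#'
#' Defaults follow the training protocol used throughout the package:
#' L1 loss weighted by inverse target frequency, stochastic gradient
#' descent with momentum 0.9 and mini-batches of up to 500 ligands, a
#' learning rate decaying as `lr0 * 0.1^(epoch/lr_decay_per)` (0.005 at
#' epoch 0, one decade per 10000 epochs), and early stopping on the
#' held-fold loss with a patience of 10% of the epoch budget.
#'
#' @param hidden_layer_widths Integer vector of hidden-layer widths
#'   (ReLU); `integer(0)` gives a purely linear model.
#' @param epochs Maximum training epochs.
#' @param lr0,lr_decay_per Learning-rate schedule, see [lr_schedule()].
#' @param momentum SGD momentum.
#' @param batch_cap Maximum mini-batch size.
#' @param target_scale,target_bias Affine transform applied to targets
#'   before training (`y' = (y - bias)/scale`); `NULL` = fitted from the
#'   training targets (mean/sd). Predictions are always reported back in
#'   kcal/mol.
#' @param early_stop_patience Epochs without held-fold improvement before
#'   stopping; `NULL` = 10% of `epochs`.
#' @param eval_every Epoch interval between held-fold evaluations.
#' @param kde_bandwidth Bandwidth for inverse-frequency weights (kcal/mol);
#'   `NULL` = Scott's rule.
#' @param seed Base RNG seed; each ensemble member derives a distinct seed.
#' @return A list of class `train_hyper`.
#' @export
train_hyper <- function(hidden_layer_widths = c(64L, 32L), epochs = 2000L,
                        lr0 = 0.005, lr_decay_per = 10000, momentum = 0.9,
                        batch_cap = 500L, target_scale = NULL,
                        target_bias = NULL, early_stop_patience = NULL,
                        eval_every = 10L, kde_bandwidth = NULL, seed = 1L) {
  stopifnot(epochs > 0, lr0 > 0, batch_cap >= 1)
  if (is.null(early_stop_patience)) {
    early_stop_patience <- max(1L, as.integer(0.1 * epochs))
  }
  structure(list(hidden_layer_widths = as.integer(hidden_layer_widths),
                 epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay_per = lr_decay_per, momentum = momentum,
                 batch_cap = as.integer(batch_cap),
                 target_scale = target_scale, target_bias = target_bias,
                 early_stop_patience = as.integer(early_stop_patience),
                 eval_every = as.integer(eval_every),
                 kde_bandwidth = kde_bandwidth, seed = as.integer(seed)),
            class = "train_hyper")
}

#' @keywords internal
combine_blocks <- function(blocks) {
  if (inherits(blocks, "feature_block")) return(blocks)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (length(blocks) == 1) return(blocks[[1]])
  do.call(cbind_blocks, c(unname(blocks), list(name = "combined")))
}

#' Train a cross-validation ensemble of perceptron regressors
#'
#' Per repeat, the training ligands receive a fresh seeded k-fold split;
#' per fold, one perceptron is trained on the other k-1 folds with
#' inverse-frequency-weighted L1 loss and early-stopped on the held-out
#' fold, each member starting from distinct random weights. The ensemble's
#' cross-validation RMSE pools every member's held-fold predictions.
#' Feature standardization, the target affine transform and the loss
#' weights are all computed from the training records only, never from
#' unevaluated library ligands.
#'
#' @param blocks A `feature_block` (unstandardized) or list of blocks to
#'   concatenate.
#' @param records Affinity tibble of training data (`ligand_id`, `dg`).
#' @param hyper A [train_hyper()] object.
#' @param k_folds Folds per repeat (default 5).
#' @param n_repeats Repeats of the whole CV procedure; the ensemble has
#'   `k_folds * n_repeats` members (e.g. 25 with 5 repeats).
#' @param uncertainty Which member spread statistic downstream selection
#'   consumes: standard error (`"se"`, default) or standard deviation
#'   (`"sd"`).
#' @return An object of class `al_ensemble`.
#' @export
train_ensemble <- function(blocks, records, hyper = train_hyper(),
                           k_folds = 5L, n_repeats = 1L,
                           uncertainty = c("se", "sd")) {
  uncertainty <- match.arg(uncertainty)
  block <- combine_blocks(blocks)
  stopifnot(!block$standardized)
  ids <- as.character(records$ligand_id)
  if (!all(ids %in% block_ids(block))) {
    stop("training records missing from feature block: ",
         paste(setdiff(ids, block_ids(block)), collapse = ", "),
         call. = FALSE)
  }
  n <- length(ids)
  if (n < k_folds) stop("need at least k_folds training examples", call. = FALSE)

  std <- standardize_block(block, fit_ids = ids)
  X <- std$matrix[ids, , drop = FALSE]
  y <- records$dg
  t_bias <- hyper$target_bias %||% mean(y)
  t_scale <- hyper$target_scale %||% stats::sd(y)
  if (!is.finite(t_scale) || t_scale == 0) t_scale <- 1
  y_t <- (y - t_bias) / t_scale

  members <- list()
  fold_assignments <- list()
  cv_pred <- rep(NA_real_, 0)
  cv_obs <- rep(NA_real_, 0)
  n_abort <- 0
  for (r in seq_len(n_repeats)) {
    folds <- withr::with_seed(hyper$seed + 7919L * r, {
      sample(rep_len(seq_len(k_folds), n))
    })
    fold_assignments[[r]] <- stats::setNames(folds, ids)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      w <- inverse_frequency_weights(y[tr], hyper$kde_bandwidth)
      member_seed <- hyper$seed + (r - 1L) * k_folds + f
      fit <- mlp_train_cpp(
        X[tr, , drop = FALSE], y_t[tr], w,
        X[!tr, , drop = FALSE], y_t[!tr],
        hyper$hidden_layer_widths, hyper$epochs, hyper$lr0,
        hyper$lr_decay_per, hyper$momentum, hyper$batch_cap,
        hyper$early_stop_patience, hyper$eval_every, member_seed
      )
      if (!isTRUE(fit$ok)) {
        n_abort <- n_abort + 1
        warning("ensemble member (repeat ", r, ", fold ", f,
                ") aborted: ", fit$error, call. = FALSE)
        next
      }
      held <- mlp_predict_cpp(fit, X[!tr, , drop = FALSE]) * t_scale + t_bias
      cv_pred <- c(cv_pred, held)
      cv_obs <- c(cv_obs, y[!tr])
      members[[length(members) + 1]] <- list(
        model = fit[c("W", "b")], fold = f, repeat_idx = r,
        seed = member_seed, val_loss = fit$val_loss,
        best_epoch = fit$best_epoch, stopped_epoch = fit$stopped_epoch
      )
    }
  }
  if (n_abort > k_folds * n_repeats / 2) {
    stop("more than half of the ensemble members aborted", call. = FALSE)
  }
  structure(list(
    members = members,
    fold_assignments = fold_assignments,
    cv_rmse = sqrt(mean((cv_pred - cv_obs)^2)),
    feature_names = colnames(X),
    block_name = block$name,
    center = std$center, scale = std$scale,
    target_bias = t_bias, target_scale = t_scale,
    uncertainty = uncertainty,
    k_folds = as.integer(k_folds), n_repeats = as.integer(n_repeats),
    n_train = n, hyper = hyper
  ), class = "al_ensemble")
}

#' @export
print.al_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<al_ensemble '%s'> %d members (%d folds x %d repeats),",
                     " %d features, cv RMSE %.3f kcal/mol\n"),
              x$block_name, length(x$members), x$k_folds, x$n_repeats,
              length(x$feature_names), x$cv_rmse))
  invisible(x)
}

#' @keywords internal
ensemble_matrix <- function(object, blocks, ligand_ids) {
  block <- combine_blocks(blocks)
  ligand_ids <- as.character(ligand_ids)
  missing <- setdiff(ligand_ids, block_ids(block))
  if (length(missing) > 0) {
    stop("features missing for ligand(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- block$matrix[ligand_ids, , drop = FALSE]
  if (!all(object$feature_names %in% colnames(m))) {
    stop("feature block lacks feature(s) the ensemble was trained on",
         call. = FALSE)
  }
  m <- m[, object$feature_names, drop = FALSE]
  if (!block$standardized) {
    m <- sweep(sweep(m, 2, object$center, "-"), 2, object$scale, "/")
  }
  m
}

#' Predict binding free energies with an ensemble
#'
#' The prediction for each ligand is the arithmetic mean of the member
#' predictions; the reported `uncertainty` column is the member standard
#' error or standard deviation according to the ensemble's configuration.
#'
#' @param object An `al_ensemble`.
#' @param blocks Feature block(s) as in [train_ensemble()] (unstandardized;
#'   the ensemble's stored transform is applied).
#' @param ligand_ids Ids to predict (default: all rows of the block).
#' @param ... Unused.
#' @return A tibble `ligand_id`, `mean_dg`, `stderr_dg`, `sd_dg`,
#'   `uncertainty` (kcal/mol) with the member prediction matrix in
#'   attribute `"member_values"`.
#' @export
predict.al_ensemble <- function(object, blocks,
                                ligand_ids = NULL, ...) {
  block <- combine_blocks(blocks)
  if (is.null(ligand_ids)) ligand_ids <- block_ids(block)
  m <- ensemble_matrix(object, block, ligand_ids)
  preds <- vapply(object$members, function(mem) {
    mlp_predict_cpp(mem$model, m) * object$target_scale + object$target_bias
  }, numeric(nrow(m)))
  preds <- matrix(preds, nrow = nrow(m),
                  dimnames = list(ligand_ids, NULL))
  k <- ncol(preds)
  sd_dg <- if (k > 1) apply(preds, 1, stats::sd) else rep(0, nrow(preds))
  out <- tibble::tibble(
    ligand_id = ligand_ids,
    mean_dg = unname(rowMeans(preds)),
    stderr_dg = unname(sd_dg) / sqrt(k),
    sd_dg = unname(sd_dg)
  )
  out$uncertainty <- if (object$uncertainty == "se") out$stderr_dg else out$sd_dg
  attr(out, "member_values") <- preds
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train_ensemble
#' @param x An `al_ensemble`.
#' @export
tidy.al_ensemble <- function(x, ...) {
  purrr::map_dfr(x$members, function(m) {
    tibble::tibble(repeat_idx = m$repeat_idx, fold = m$fold, seed = m$seed,
                   held_fold_loss = m$val_loss, best_epoch = m$best_epoch,
                   stopped_epoch = m$stopped_epoch)
  })
}

#' @rdname train_ensemble
#' @export
glance.al_ensemble <- function(x, ...) {
  tibble::tibble(block = x$block_name, n_members = length(x$members),
                 k_folds = x$k_folds, n_repeats = x$n_repeats,
                 n_train = x$n_train, n_features = length(x$feature_names),
                 cv_rmse = x$cv_rmse)
}

#' Integrated-Gradients attributions of an ensemble
#'
#' Attribution of feature j at input x is
#' `(x_j - baseline_j) * mean_k dF/dx_j(baseline + (k - 1/2)/m * (x - baseline))`,
#' a midpoint Riemann approximation of the path integral of the model
#' gradient from the baseline to the input, averaged over ensemble
#' members. The baseline is the all-zeros vector in standardized feature
#' space (the training-set mean ligand).
#'
#' @param object An `al_ensemble`.
#' @param blocks Feature block(s).
#' @param ligand_ids Probe ligands (default: all rows).
#' @param m_steps Riemann steps (default 256).
#' @return A matrix (probe ligands x features) of attributions in
#'   kcal/mol.
#' @export
integrated_gradients <- function(object, blocks, ligand_ids = NULL,
                                 m_steps = 256L) {
  block <- combine_blocks(blocks)
  if (is.null(ligand_ids)) ligand_ids <- block_ids(block)
  x <- ensemble_matrix(object, block, ligand_ids)
  total <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  alphas <- (seq_len(m_steps) - 0.5) / m_steps
  for (mem in object$members) {
    grad_sum <- matrix(0, nrow(x), ncol(x))
    for (a in alphas) {
      grad_sum <- grad_sum + mlp_input_grad_cpp(mem$model, a * x)
    }
    total <- total + x * grad_sum / m_steps
  }
  total * object$target_scale / length(object$members)
}

#' Filter features by mean Integrated-Gradients importance
#'
#' Per-feature importance is the mean over probe ligands and ensemble
#' members of the absolute attribution, normalized per probe so that the
#' absolute attributions of each ligand sum to 1 (making the threshold
#' scale-free). Features with importance below `threshold` are dropped.
#'
#' @inheritParams integrated_gradients
#' @param threshold Importance cutoff (default 0.02).
#' @return Character vector of retained feature names, with the importance
#'   table in attribute `"importance"`.
#' @export
importance_filter <- function(object, blocks, threshold = 0.02,
                              ligand_ids = NULL, m_steps = 256L) {
  stopifnot(threshold >= 0)
  attr_mat <- abs(integrated_gradients(object, blocks, ligand_ids, m_steps))
  norm <- rowSums(attr_mat)
  norm[norm == 0] <- 1
  importance <- colMeans(attr_mat / norm)
  keep <- names(importance)[importance >= threshold]
  if (length(keep) == 0) {
    stop("all features fell below the importance threshold; lower it",
         call. = FALSE)
  }
  attr(keep, "importance") <- tibble::tibble(
    feature = names(importance), importance = unname(importance)
  )
  keep
}
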