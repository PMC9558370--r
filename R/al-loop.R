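#' Assemble and validate an active-learning run configuration
#'
#' @param library A ligand tibble, or a `synthetic_landscape` (in which
#'   case blocks, embedding and truth default to the landscape's).
#' @param blocks Named list of unstandardized `feature_block`s covering
#'   the library. The first is the main representation used for training
#'   and greedy-phase selection; additional blocks are the alternative
#'   representations for the narrowing phase.
#' @param oracle Oracle spec: `list(type = "lookup", table = <affinity
#'   table>)` or `list(type = "synthetic", truth = <truth table>, sigma =
#'   1.1, n_replicates = 5)`.
#' @param policy Selection policy: `"greedy"`, `"uncertain"`, `"mixed"`,
#'   `"random"`, `"narrowing"`, or `"random2greedy"`.
#' @param batch_size Ligands evaluated per iteration (default 100).
#' @param max_iterations Iterations after initialization (default 6).
#' @param embedding 2D coordinates for the weighted-random initialization
#'   (tibble `ligand_id`, `dim1`, `dim2`), a `feature_block` to t-SNE
#'   embed, or `NULL` to embed the main block.
#' @param truth Optional truth table (`ligand_id`, `dg_true`) for metric
#'   computation.
#' @param hyper A [train_hyper()]; its seed is re-derived per iteration.
#' @param k_folds CV folds (default 5).
#' @param n_repeats CV repeats per iteration; a scalar or a vector indexed
#'   by iteration (e.g. `c(1, 1, 1, 1, 5, 5, 5)` to widen late ensembles).
#' @param pool_factor Mixed-strategy pool ratio (default 3).
#' @param n_models,per_model_top Narrowing parameters (default 5 and 20).
#' @param switch_after Broad-phase length of composite policies.
#' @param top_n,tpr_threshold Metric parameters (see [compute_metrics()]).
#' @param uncertainty Member spread statistic: `"se"` or `"sd"`.
#' @param stop_on_plateau Optionally halt when the best free energy found
#'   fails to improve for two consecutive iterations.
#' @param seed Master seed; all per-iteration seeds derive from it.
#' @param checkpoint_dir Directory for per-iteration state checkpoints
#'   (`NULL` = no checkpointing).
#' @return A list of class `al_config`.
#' @export
al_config <- function(library, blocks = NULL, oracle = NULL,
                      policy = "greedy", batch_size = 100L,
                      max_iterations = 6L, embedding = NULL, truth = NULL,
                      hyper = train_hyper(), k_folds = 5L, n_repeats = 1L,
                      pool_factor = 3, n_models = 5L, per_model_top = 20L,
                      switch_after = 3L, top_n = 50L,
                      tpr_threshold = -13.29, uncertainty = c("se", "sd"),
                      stop_on_plateau = FALSE, seed = 1L,
                      checkpoint_dir = NULL) {
  uncertainty <- match.arg(uncertainty)
  if (inherits(library, "synthetic_landscape")) {
    landscape <- library
    library <- landscape$ligands
    blocks <- blocks %||% landscape$representations
    embedding <- embedding %||% landscape$embedding
    truth <- truth %||% landscape$truth
    oracle <- oracle %||% list(type = "lookup",
                               table = tibble::tibble(
                                 ligand_id = landscape$truth$ligand_id,
                                 dg = landscape$truth$dg_true))
  }
  stopifnot(is.data.frame(library), !is.null(blocks), !is.null(oracle))
  if (inherits(blocks, "feature_block")) blocks <- list(main = blocks)
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)))
  if (!oracle$type %in% c("lookup", "synthetic")) {
    stop("oracle$type must be 'lookup' or 'synthetic'", call. = FALSE)
  }
  policy_schedule(1L, policy)  # validates the policy name
  cfg <- list(library = library, blocks = blocks, oracle = oracle,
              policy = policy, batch_size = as.integer(batch_size),
              max_iterations = as.integer(max_iterations),
              embedding = embedding, truth = truth, hyper = hyper,
              k_folds = as.integer(k_folds), n_repeats = n_repeats,
              pool_factor = pool_factor, n_models = as.integer(n_models),
              per_model_top = as.integer(per_model_top),
              switch_after = as.integer(switch_after),
              top_n = as.integer(top_n), tpr_threshold = tpr_threshold,
              uncertainty = uncertainty, stop_on_plateau = stop_on_plateau,
              seed = as.integer(seed), checkpoint_dir = checkpoint_dir)
  class(cfg) <- "al_config"
  cfg
}

#' @keywords internal
config_hash <- function(config) {
  # max_iterations excluded so a checkpointed run can resume with an
  # extended budget; checkpoint_dir is location, not identity
  rlang::hash(config[setdiff(names(config),
                             c("checkpoint_dir", "max_iterations"))])
}

#' @keywords internal
oracle_evaluate <- function(config, batch_ids, iteration) {
  orc <- config$oracle
  rec <- if (orc$type == "lookup") {
    lookup_oracle(batch_ids, orc$table)
  } else {
    synthetic_oracle(batch_ids, orc$truth, sigma = orc$sigma %||% 1.1,
                     n_replicates = orc$n_replicates %||% 5L,
                     seed = config$seed + 1009L * iteration,
                     cluster_bias = orc$cluster_bias)
  }
  rec$iteration <- as.integer(iteration)
  rec
}

#' @keywords internal
iter_hyper <- function(config, iteration) {
  h <- config$hyper
  h$seed <- config$seed + 97L * iteration
  h
}

#' @keywords internal
iter_repeats <- function(config, iteration) {
  nr <- config$n_repeats
  as.integer(nr[min(iteration + 1L, length(nr))])
}

#' @keywords internal
main_block <- function(config) config$blocks[[1]]

#' @keywords internal
al_checkpoint <- function(state, config) {
  dir <- config$checkpoint_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(state, file.path(dir, "state.rds"))
  jsonlite::write_json(
    c(list(iteration = state$iteration,
           n_evaluated = nrow(state$evaluated)),
      as.list(state$metrics_history[nrow(state$metrics_history), ])),
    file.path(dir, sprintf("iter_%02d.json", state$iteration)),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @keywords internal
al_train_predict <- function(config, state, iteration) {
  records <- state$evaluated
  ens <- train_ensemble(main_block(config), records,
                        hyper = iter_hyper(config, iteration),
                        k_folds = config$k_folds,
                        n_repeats = iter_repeats(config, iteration),
                        uncertainty = config$uncertainty)
  pred <- predict(ens, main_block(config),
                  ligand_ids = config$library$ligand_id)
  pred$iteration <- as.integer(iteration)
  state$ensemble <- ens
  state$predictions_history[[iteration + 1L]] <- pred
  if (!is.null(config$truth)) {
    m <- compute_metrics(pred, config$truth, state$evaluated$ligand_id,
                         top_n = config$top_n,
                         tpr_threshold = config$tpr_threshold)
    m$iteration <- as.integer(iteration)
    m$strategy <- state$batches$strategy[nrow(state$batches)]
    state$metrics_history <- dplyr::bind_rows(state$metrics_history, m)
  }
  state
}

#' Run the active-learning cycle
#'
#' Orchestrates the full loop: iteration 0 draws a diversity-weighted
#' random batch, queries the oracle, trains a cross-validation ensemble
#' and predicts the whole library; each subsequent iteration selects a
#' new disjoint batch according to the policy schedule, evaluates it,
#' retrains and repredicts. State is checkpointed after every iteration
#' when a checkpoint directory is configured and a run can be resumed
#' from its checkpoint.
#'
#' @param config An [al_config()].
#' @param resume Resume from `config$checkpoint_dir` if a state file is
#'   present (config must hash-match the checkpointed run).
#' @return An `al_state`: evaluated records, batches, per-iteration
#'   predictions and metrics, and the final ensemble.
#' @export
run_active_learning <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "al_config"))
  hash <- config_hash(config)
  state <- NULL
  if (resume && !is.null(config$checkpoint_dir)) {
    path <- file.path(config$checkpoint_dir, "state.rds")
    if (file.exists(path)) {
      state <- readRDS(path)
      if (!identical(state$config_hash, hash)) {
        stop("checkpointed state was produced by a different configuration",
             call. = FALSE)
      }
    }
  }
  if (is.null(state)) {
    init <- weighted_random_init(config$library,
                                 config$embedding %||% main_block(config),
                                 batch_size = config$batch_size,
                                 seed = config$seed)
    state <- structure(list(
      config_hash = hash, iteration = 0L,
      evaluated = oracle_evaluate(config, init$ligand_id, 0L),
      batches = init,
      predictions_history = list(), metrics_history = tibble::tibble(),
      ensemble = NULL, best_dg_history = numeric(0)
    ), class = "al_state")
    state <- al_train_predict(config, state, 0L)
    state$best_dg_history <- min(state$evaluated$dg)
    al_checkpoint(state, config)
  }
  while (state$iteration < config$max_iterations) {
    it <- state$iteration + 1L
    strategy <- policy_schedule(it, config$policy, config$switch_after)
    excluded <- state$evaluated$ligand_id
    prev_pred <- state$predictions_history[[state$iteration + 1L]]
    batch <- switch(
      strategy,
      greedy = select_greedy(prev_pred, excluded, config$batch_size, it),
      uncertain = select_uncertain(prev_pred, excluded, config$batch_size,
                                   it),
      mixed = select_mixed(prev_pred, excluded, config$batch_size,
                           config$pool_factor, it),
      random = select_random(config$library$ligand_id, excluded,
                             config$batch_size,
                             seed = config$seed + 313L * it, iteration = it),
      narrowing = {
        n_avail <- length(config$blocks)
        n_mod <- min(config$n_models, n_avail)
        per_top <- ceiling(config$batch_size / n_mod)
        ensembles <- purrr::imap(config$blocks, function(b, nm) {
          h <- iter_hyper(config, it)
          h$seed <- h$seed + match(nm, names(config$blocks))
          train_ensemble(b, state$evaluated, hyper = h,
                         k_folds = config$k_folds, n_repeats = 1L,
                         uncertainty = config$uncertainty)
        })
        preds <- purrr::map2(ensembles, config$blocks, function(e, b) {
          predict(e, b, ligand_ids = config$library$ligand_id)
        })
        select_narrowing(ensembles, preds, excluded, n_models = n_mod,
                         per_model_top = per_top, iteration = it) |>
          utils::head(config$batch_size)
      },
      stop("unsupported strategy: ", strategy, call. = FALSE)
    )
    if (nrow(batch) == 0) break
    rec <- oracle_evaluate(config, batch$ligand_id, it)
    state$evaluated <- dplyr::bind_rows(state$evaluated, rec)
    state$batches <- dplyr::bind_rows(state$batches, batch)
    state$iteration <- it
    state <- al_train_predict(config, state, it)
    state$best_dg_history <- c(state$best_dg_history,
                               min(state$evaluated$dg))
    al_checkpoint(state, config)
    if (config$stop_on_plateau && length(state$best_dg_history) >= 3) {
      last3 <- utils::tail(state$best_dg_history, 3)
      if (last3[2] >= last3[1] && last3[3] >= last3[1]) break
    }
  }
  state
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("<al_state> iteration %d, %d ligands evaluated\n",
              x$iteration, nrow(x$evaluated)))
  if (nrow(x$metrics_history) > 0) {
    print(x$metrics_history)
  }
  invisible(x)
}

#' @rdname run_active_learning
#' @param x An `al_state`.
#' @param ... Unused.
#' @export
tidy.al_state <- function(x, ...) {
  x$metrics_history
}

#' @rdname run_active_learning
#' @export
glance.al_state <- function(x, ...) {
  tibble::tibble(iterations = x$iteration,
                 n_evaluated = nrow(x$evaluated),
                 best_dg = min(x$evaluated$dg),
                 final_cv_rmse = x$ensemble$cv_rmse %||% NA_real_)
}
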