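# Shared fixtures, built once per test run.

fast_hyper <- function(seed = 1L, ...) {
  train_hyper(hidden_layer_widths = c(16L, 8L), epochs = 200L, seed = seed,
              ...)
}

# small noisy landscape for loop/selection tests
test_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_landscape(n_ligands = 400L,
                                                     seed = 42L)
    cache
  }
})

# a noise-free landscape plus a trained ensemble, reused by several files
test_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ls <- generate_landscape(n_ligands = 300L, noise_free = TRUE,
                               seed = 7L)
      tr_ids <- withr::with_seed(77L, sample(ls$truth$ligand_id, 200L))
      rec <- lookup_oracle(tr_ids,
                           data.frame(ligand_id = ls$truth$ligand_id,
                                      dg = ls$truth$dg_true))
      ens <- train_ensemble(ls$features, rec, hyper = fast_hyper(3L),
                            k_folds = 5L)
      cache <<- list(landscape = ls, records = rec, ensemble = ens,
                     held_ids = setdiff(ls$truth$ligand_id, tr_ids))
    }
    cache
  }
})

# hand-built ensemble of linear members with known outputs, for exercising
# the prediction path with controlled member values
stub_linear_ensemble <- function(intercepts, n_features = 2L) {
  members <- lapply(seq_along(intercepts), function(i) {
    list(model = list(W = list(matrix(0, 1, n_features)),
                      b = list(intercepts[i])),
         fold = i, repeat_idx = 1L, seed = i, val_loss = 0,
         best_epoch = 0L, stopped_epoch = 0L)
  })
  structure(list(
    members = members, fold_assignments = list(),
    cv_rmse = 0, feature_names = paste0("f", seq_len(n_features)),
    block_name = "stub", center = rep(0, n_features),
    scale = rep(1, n_features), target_bias = 0, target_scale = 1,
    uncertainty = "se", k_folds = length(intercepts), n_repeats = 1L,
    n_train = 0L, hyper = train_hyper()
  ), class = "al_ensemble")
}

# full strategy-comparison experiment shared by the acceptance checks:
# default 2000-ligand landscapes, batches of 100, 6 iterations, 5 paired
# seeds, synthetic oracle at sigma = 1.1 kcal/mol
acceptance_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- compare_strategies(
        strategies = c("greedy", "narrowing", "uncertain", "random"),
        seeds = 1:5)
    }
    cache
  }
})

random_prediction_table <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      ligand_id = sprintf("L%04d", sample.int(9999, n)),
      mean_dg = round(stats::runif(n, -17, -6), 2),
      uncertainty = round(stats::runif(n, 0, 2), 2)
    )
  })
}
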