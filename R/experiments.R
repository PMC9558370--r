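#' Compare selection strategies on synthetic landscapes over paired seeds
#'
#' Runs the full active-learning cycle for each strategy on the same
#' sequence of synthetic landscapes (one per seed, shared across
#' strategies so comparisons are paired) and collects the final-iteration
#' metrics. This is the package's desk-scale analogue of a retrospective
#' strategy benchmark: which strategies recover the most designated
#' strong binders at a fixed evaluation budget, and which describe the
#' whole library best.
#'
#' @param strategies Character vector of policies (see [al_config()]).
#' @param seeds Integer vector of paired seeds.
#' @param n_ligands,batch_size,max_iterations Experiment geometry
#'   (defaults: 2000-ligand landscape, batches of 100, 6 iterations after
#'   initialization, i.e. 700 evaluated = 35% of the library).
#' @param sigma Oracle noise passed to the synthetic oracle (kcal/mol).
#' @param hyper A [train_hyper()] for the per-iteration ensembles.
#' @param top_n Strong-binder set size for recovery metrics.
#' @param ... Further arguments passed to [al_config()].
#' @return A tibble with one row per (strategy, seed): final
#'   `top_n_recovered`, `rmse`, `kendall_tau`, `tpr`, `best_dg`,
#'   `n_evaluated`.
#' @export
compare_strategies <- function(strategies = c("greedy", "narrowing",
                                              "uncertain", "random"),
                               seeds = 1:5, n_ligands = 2000L,
                               batch_size = 100L, max_iterations = 6L,
                               sigma = 1.1,
                               hyper = train_hyper(
                                 hidden_layer_widths = c(32L, 16L),
                                 epochs = 400L),
                               top_n = 50L, ...) {
  purrr::map_dfr(seeds, function(s) {
    landscape <- generate_landscape(n_ligands = n_ligands, seed = 100L + s)
    purrr::map_dfr(stats::setNames(strategies, strategies), function(pol) {
      cfg <- al_config(landscape, policy = pol, batch_size = batch_size,
                       max_iterations = max_iterations, hyper = hyper,
                       top_n = top_n, seed = s,
                       oracle = list(type = "synthetic",
                                     truth = landscape$truth,
                                     sigma = sigma, n_replicates = 5L), ...)
      state <- run_active_learning(cfg)
      final <- state$metrics_history[nrow(state$metrics_history), ]
      tibble::tibble(strategy = pol, seed = s,
                     top_n_recovered = final$top_n_recovered,
                     rmse = final$rmse, kendall_tau = final$kendall_tau,
                     tpr = final$tpr, best_dg = min(state$evaluated$dg),
                     n_evaluated = final$n_evaluated)
    })
  })
}
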