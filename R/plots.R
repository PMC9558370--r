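#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot metric trajectories of an active-learning run
#'
#' One panel per metric (RMSE, Kendall tau, top-N recovery, TPR) against
#' iteration number.
#'
#' @param object An `al_state` with a metrics history.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.al_state <- function(object, ...) {
  stopifnot(nrow(object$metrics_history) > 0)
  long <- object$metrics_history |>
    dplyr::select("iteration", "rmse", "kendall_tau", "top_n_recovered",
                  "tpr") |>
    tidyr::pivot_longer(-"iteration", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic landscape in its 2D embedding
#'
#' @param object A `synthetic_landscape`.
#' @param ... Unused.
#' @return A ggplot of the embedding colored by true free energy, strong
#'   binders outlined.
#' @export
autoplot.synthetic_landscape <- function(object, ...) {
  df <- dplyr::left_join(object$embedding, object$truth, by = "ligand_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = .data$dg_true)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$strong), shape = 1,
                        size = 2, color = "black") +
    ggplot2::scale_color_viridis_c(name = expression(Delta * G ~
                                                       "(kcal/mol)")) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2") +
    ggplot2::theme_minimal()
}

#' Plot the free energies of selected batches per iteration
#'
#' Shows the oracle free energies of each iteration's batch, the
#' trajectory of training-set enrichment in strong binders.
#'
#' @param state An `al_state`.
#' @return A ggplot.
#' @export
plot_selection_progress <- function(state) {
  ggplot2::ggplot(state$evaluated,
                  ggplot2::aes(factor(.data$iteration), .data$dg)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "iteration",
                  y = expression(Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}
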