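#' Exponentially decaying learning-rate schedule
#'
#' `lr(epoch) = lr0 * 0.1^(epoch / decay_per)`: the learning rate loses one
#' decade every `decay_per` epochs. Defaults give 0.005 at epoch 0 and
#' 0.0005 at epoch 10000.
#'
#' @param epoch Epoch number(s), >= 0.
#' @param lr0 Initial learning rate.
#' @param decay_per Epochs per decade of decay.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, lr0 = 0.005, decay_per = 10000) {
  stopifnot(all(epoch >= 0), lr0 > 0, decay_per > 0)
  lr0 * 0.1^(epoch / decay_per)
}

#' Scott's rule bandwidth
#' @param x Numeric sample.
#' @return Bandwidth for a Gaussian kernel density estimate.
#' @export
scott_bandwidth <- function(x) {
  n <- length(x)
  stats::sd(x) * n^(-1 / 5)
}

#' Inverse-frequency loss weights from a Gaussian KDE of the targets
#'
#' Training sets accumulated by affinity-driven selection over-represent
#' medium and high affinity ligands. To counter this, each example's loss
#' weight is proportional to the reciprocal of a Gaussian kernel density
#' estimate of the training free energies evaluated at that example's
#' target, renormalized so the mean weight is 1.
#'
#' @param targets Training free energies, kcal/mol (length >= 2).
#' @param bandwidth Gaussian kernel bandwidth, kcal/mol; default Scott's
#'   rule on the targets.
#' @return Positive weights, one per target, mean 1.
#' @export
inverse_frequency_weights <- function(targets, bandwidth = NULL) {
  stopifnot(length(targets) >= 2)
  if (is.null(bandwidth)) bandwidth <- scott_bandwidth(targets)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    return(rep(1, length(targets)))  # degenerate targets: uniform weights
  }
  d <- outer(targets, targets, "-") / bandwidth
  dens <- rowMeans(stats::dnorm(d)) / bandwidth
  w <- 1 / dens
  w / mean(w)
}
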