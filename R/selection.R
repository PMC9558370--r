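#' @keywords internal
new_batch <- function(ligand_id, strategy, iteration, rank = seq_along(ligand_id),
                      rationale = strategy) {
  tibble::tibble(iteration = as.integer(iteration), strategy = strategy,
                 ligand_id = as.character(ligand_id),
                 rank = as.integer(rank), rationale = rationale)
}

#' @keywords internal
candidate_pool <- function(predictions, excluded) {
  pool <- dplyr::filter(predictions, !.data$ligand_id %in% excluded)
  if (nrow(pool) == 0) {
    warning("candidate pool is exhausted; returning an empty batch",
            call. = FALSE)
  }
  pool
}

#' Embed a library into 2D for diversity-weighted sampling
#'
#' Computes a 2-component t-SNE embedding of a feature block (typically
#' the 2D-feature set: constitutional and graph descriptors plus MACCS and
#' BCUT2D fingerprints) via the bundled Python backend. Because
#' stochastic-neighbor embeddings vary run to run, the embedding is
#' seeded, and callers are encouraged to cache the returned coordinates.
#'
#' @param block A `feature_block`.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   for small libraries).
#' @param seed RNG seed for the embedding.
#' @return A tibble `ligand_id`, `dim1`, `dim2`.
#' @export
embed_library <- function(block, perplexity = 30, seed = 1L) {
  m <- block$matrix
  keep <- apply(m, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  out <- run_chem_op("tsne", matrix = unname(m[, keep, drop = FALSE]),
                     perplexity = perplexity, seed = seed)
  coords <- do.call(rbind, lapply(out$coords, unlist))
  tibble::tibble(ligand_id = block_ids(block),
                 dim1 = coords[, 1], dim2 = coords[, 2])
}

#' Bin 2D embedding coordinates into unit squares
#'
#' @param coords A tibble `ligand_id`, `dim1`, `dim2`.
#' @param bin_side Side length of the square histogram bins in embedding
#'   units (default 1).
#' @return `coords` with `bin` (a string key) and `bin_count` columns.
#' @export
embedding_bins <- function(coords, bin_side = 1) {
  stopifnot(bin_side > 0)
  coords |>
    dplyr::mutate(bin = paste(floor(.data$dim1 / bin_side),
                              floor(.data$dim2 / bin_side), sep = ",")) |>
    dplyr::add_count(.data$bin, name = "bin_count")
}

#' Diversity-weighted random initialization batch
#'
#' Iteration-0 selection: ligands are drawn without replacement with
#' probability inversely proportional to the number of ligands sharing
#' their 2D-histogram bin in the embedding, so densely populated regions
#' of chemical space do not dominate the first training set.
#'
#' @param library A ligand tibble (or any data frame with `ligand_id`).
#' @param embedding Either a coordinate tibble (`ligand_id`, `dim1`,
#'   `dim2`) or a `feature_block` to embed via [embed_library()].
#' @param batch_size Number of ligands to select.
#' @param seed RNG seed for sampling (and embedding, if computed here).
#' @param bin_side Histogram bin side length (embedding units).
#' @return A selection-batch tibble (iteration 0).
#' @export
weighted_random_init <- function(library, embedding, batch_size = 100L,
                                 seed = 1L, bin_side = 1) {
  stopifnot(nrow(library) >= batch_size)
  coords <- if (inherits(embedding, "feature_block")) {
    embed_library(embedding, seed = seed)
  } else {
    embedding
  }
  stopifnot(all(c("ligand_id", "dim1", "dim2") %in% names(coords)))
  coords <- embedding_bins(coords, bin_side)
  coords <- coords[match(library$ligand_id, coords$ligand_id), ]
  if (anyNA(coords$ligand_id)) {
    stop("embedding does not cover the library", call. = FALSE)
  }
  picked <- withr::with_seed(seed, {
    sample(coords$ligand_id, batch_size, replace = FALSE,
           prob = 1 / coords$bin_count)
  })
  new_batch(picked, "weighted_random_init", 0L)
}

#' Greedy selection: top predicted binders
#'
#' Selects the `batch_size` candidates with the most negative predicted
#' binding free energy. Ties are broken lexicographically by ligand id so
#' every strategy is deterministic.
#'
#' @param predictions Prediction tibble (`ligand_id`, `mean_dg`,
#'   `uncertainty`), e.g. from [predict.al_ensemble()].
#' @param excluded Ids already evaluated (never re-selected).
#' @param batch_size Batch size.
#' @param iteration Iteration tag for the batch.
#' @return A selection-batch tibble.
#' @export
select_greedy <- function(predictions, excluded = character(0),
                          batch_size = 100L, iteration = NA_integer_) {
  pool <- candidate_pool(predictions, excluded) |>
    dplyr::arrange(.data$mean_dg, .data$ligand_id) |>
    utils::head(batch_size)
  new_batch(pool$ligand_id, "greedy", iteration,
            rationale = sprintf("pred_dg=%.3f", pool$mean_dg))
}

#' Uncertainty selection: least confident predictions
#'
#' Selects the candidates with the largest prediction uncertainty (member
#' spread), the pure exploration counterpart of [select_greedy()].
#'
#' @inheritParams select_greedy
#' @return A selection-batch tibble.
#' @export
select_uncertain <- function(predictions, excluded = character(0),
                             batch_size = 100L, iteration = NA_integer_) {
  pool <- candidate_pool(predictions, excluded) |>
    dplyr::arrange(dplyr::desc(.data$uncertainty), .data$ligand_id) |>
    utils::head(batch_size)
  new_batch(pool$ligand_id, "uncertain", iteration,
            rationale = sprintf("uncertainty=%.3f", pool$uncertainty))
}

#' Mixed selection: most uncertain among the strongest predicted binders
#'
#' First pools the `pool_factor * batch_size` candidates with the
#' strongest predicted affinity, then selects the `batch_size` most
#' uncertain predictions among them. With `pool_factor = 1` the selected
#' set is exactly the greedy batch (reported in uncertainty order); when
#' the pool covers the whole candidate set the batch is exactly the
#' uncertainty selection.
#'
#' @inheritParams select_greedy
#' @param pool_factor Ratio of the affinity pool to the batch size
#'   (default 3, i.e. a 3:1 ratio).
#' @return A selection-batch tibble.
#' @export
select_mixed <- function(predictions, excluded = character(0),
                         batch_size = 100L, pool_factor = 3,
                         iteration = NA_integer_) {
  stopifnot(pool_factor >= 1)
  pool <- candidate_pool(predictions, excluded) |>
    dplyr::arrange(.data$mean_dg, .data$ligand_id) |>
    utils::head(ceiling(pool_factor * batch_size)) |>
    dplyr::arrange(dplyr::desc(.data$uncertainty), .data$ligand_id) |>
    utils::head(batch_size)
  new_batch(pool$ligand_id, "mixed", iteration,
            rationale = sprintf("pred_dg=%.3f,unc=%.3f", pool$mean_dg,
                                pool$uncertainty))
}

#' Narrowing selection: top binders across several representations
#'
#' For the broad phase of the narrowing policy: rank the available
#' ensembles (one per ligand representation) by cross-validation RMSE,
#' keep the best `n_models`, and let each contribute its `per_model_top`
#' best predicted binders. When several models nominate the same ligand,
#' the models are visited round-robin in ascending cv-RMSE order and each
#' contributes its next-best unclaimed ligand, so the batch always holds
#' `n_models * per_model_top` unique ligands (100 with the defaults)
#' unless the candidate pool is exhausted.
#'
#' @param ensembles Named list of `al_ensemble` objects.
#' @param predictions Named list of prediction tibbles, parallel to
#'   `ensembles`.
#' @param excluded Ids already evaluated.
#' @param n_models Number of best models to use (default 5).
#' @param per_model_top Ligands contributed per model (default 20).
#' @param iteration Iteration tag.
#' @return A selection-batch tibble whose `rationale` names the source
#'   model.
#' @export
select_narrowing <- function(ensembles, predictions,
                             excluded = character(0), n_models = 5L,
                             per_model_top = 20L, iteration = NA_integer_) {
  stopifnot(length(ensembles) == length(predictions))
  if (length(ensembles) < n_models) {
    stop("need at least n_models = ", n_models, " ensembles, got ",
         length(ensembles), call. = FALSE)
  }
  cv <- purrr::map_dbl(ensembles, "cv_rmse")
  chosen <- names(sort(cv))[seq_len(n_models)]
  ranked <- purrr::map(predictions[chosen], function(p) {
    candidate_pool(p, excluded) |>
      dplyr::arrange(.data$mean_dg, .data$ligand_id) |>
      dplyr::pull("ligand_id")
  })
  target <- n_models * per_model_top
  taken <- character(0)
  source_model <- character(0)
  pos <- stats::setNames(rep(1L, n_models), chosen)
  repeat {
    progressed <- FALSE
    for (mod in chosen) {
      if (length(taken) >= target) break
      while (pos[mod] <= length(ranked[[mod]]) &&
             ranked[[mod]][pos[mod]] %in% taken) {
        pos[mod] <- pos[mod] + 1L
      }
      if (pos[mod] <= length(ranked[[mod]])) {
        taken <- c(taken, ranked[[mod]][pos[mod]])
        source_model <- c(source_model, mod)
        pos[mod] <- pos[mod] + 1L
        progressed <- TRUE
      }
    }
    if (length(taken) >= target || !progressed) break
  }
  if (length(taken) < target) {
    warning("candidate pool smaller than the requested batch; returning ",
            length(taken), " ligands", call. = FALSE)
  }
  new_batch(taken, "narrowing", iteration, rationale = source_model)
}

#' Map a selection policy and iteration to a concrete strategy
#'
#' Two composite policies switch strategy after the broad initial phase:
#' `"narrowing"` uses multi-representation narrowing selection for the
#' first `switch_after` iterations and greedy afterwards;
#' `"random2greedy"` uses random selection first, then greedy. Plain
#' policies (`"greedy"`, `"uncertain"`, `"mixed"`, `"random"`) map to
#' themselves. Iteration 0 is always the weighted-random initialization.
#'
#' @param iteration Iteration number (0 = initialization).
#' @param policy_name Policy name.
#' @param switch_after Iterations of the broad phase for composite
#'   policies (default 3).
#' @return The strategy name for this iteration.
#' @export
policy_schedule <- function(iteration, policy_name, switch_after = 3L) {
  if (iteration == 0) return("weighted_random_init")
  switch(policy_name,
    narrowing = if (iteration <= switch_after) "narrowing" else "greedy",
    random2greedy = if (iteration <= switch_after) "random" else "greedy",
    greedy = ,
    uncertain = ,
    mixed = ,
    random = policy_name,
    stop("unknown policy: ", policy_name, call. = FALSE)
  )
}

#' Uniform random selection batch
#'
#' @inheritParams select_greedy
#' @param candidates Character vector of candidate ligand ids.
#' @param seed RNG seed.
#' @return A selection-batch tibble.
#' @export
select_random <- function(candidates, excluded = character(0),
                          batch_size = 100L, seed = 1L,
                          iteration = NA_integer_) {
  pool <- setdiff(as.character(candidates), excluded)
  if (length(pool) == 0) {
    warning("candidate pool is exhausted; returning an empty batch",
            call. = FALSE)
  }
  picked <- withr::with_seed(seed, {
    sample(pool, min(batch_size, length(pool)))
  })
  new_batch(picked, "random", iteration)
}
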