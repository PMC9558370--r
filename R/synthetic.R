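#' Generate a synthetic affinity landscape
#'
#' Builds a clustered ligand library in a latent feature space together
#' with a ground-truth binding free-energy surface, emulating the
#' statistical structure of congeneric-series affinity data: ligands form
#' a few clusters of chemically similar compounds, a small fraction of
#' strong binders is concentrated in a few of those clusters, and the
#' free-energy range spans roughly -17 to -6 kcal/mol. The latent
#' features are consumed directly as a feature block, so model, selection
#' and loop logic can be exercised without any chemistry toolkit.
#'
#' Ligand positions are Gaussian clusters; the true free energy is a
#' smooth cluster-dependent function of latent position (cluster base
#' affinity plus a radial term weakening away from the cluster center),
#' optionally perturbed by mild ruggedness, then rescaled onto
#' `dg_range`. The strong threshold is placed so that exactly
#' `ceiling(strong_fraction * n_ligands)` ligands fall below it, all of
#' them inside the designated strong clusters.
#'
#' @param n_ligands Library size (default 2000).
#' @param n_clusters Number of latent clusters (default 8).
#' @param n_strong_clusters Clusters harboring the strong binders
#'   (default 3).
#' @param strong_fraction Fraction of ligands below the strong threshold
#'   (default 0.025, i.e. 50 of 2000); must be in (0, 0.5).
#' @param dg_range Range of true free energies, kcal/mol.
#' @param noise_free Disable the ruggedness term (smooth surface).
#' @param latent_dim Latent feature dimensionality (default 8).
#' @param n_representations Number of alternative feature views generated
#'   for multi-representation (narrowing) selection (default 5; the first
#'   is the latent block itself).
#' @param seed RNG seed; generation is bit-reproducible under it.
#' @return An object of class `synthetic_landscape` with elements
#'   `ligands` (ligand tibble), `features` (`feature_block` "latent"),
#'   `representations` (named list of feature blocks), `truth` (tibble
#'   `ligand_id`, `dg_true`, `cluster`, `strong`), `strong_threshold`,
#'   `embedding` (2D PCA coords for diversity-weighted initialization),
#'   and the generating parameters.
#' @export
generate_landscape <- function(n_ligands = 2000L, n_clusters = 8L,
                               n_strong_clusters = 3L,
                               strong_fraction = 0.025,
                               dg_range = c(-17, -6), noise_free = FALSE,
                               latent_dim = 8L, n_representations = 5L,
                               seed = 1L) {
  stopifnot(n_strong_clusters <= n_clusters, strong_fraction > 0,
            strong_fraction < 0.5, dg_range[1] < dg_range[2],
            n_ligands >= n_clusters)
  n_strong <- ceiling(strong_fraction * n_ligands)
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(n_clusters * latent_dim, sd = 4),
                      n_clusters, latent_dim)
    z <- sort(sample(rep_len(seq_len(n_clusters), n_ligands)))
    x <- centers[z, ] + matrix(stats::rnorm(n_ligands * latent_dim, sd = 0.6),
                               n_ligands, latent_dim)
    base <- c(stats::runif(n_strong_clusters, -8, -6),
              stats::runif(n_clusters - n_strong_clusters, -3, 0))
    d_own <- sqrt(rowSums((x - centers[z, ])^2))
    raw <- base[z] + 1.0 * d_own
    if (!noise_free) raw <- raw + stats::rnorm(n_ligands, sd = 0.3)
    dg <- dg_range[1] + (raw - min(raw)) / (max(raw) - min(raw)) *
      diff(dg_range)
    ord <- order(dg)
    if (!all(z[ord[seq_len(n_strong)]] <= n_strong_clusters)) {
      stop("infeasible parameters: strong binders not confined to strong ",
           "clusters; increase cluster separation or lower strong_fraction",
           call. = FALSE)
    }
    thr <- mean(dg[ord[n_strong + 0:1]])
    ids <- sprintf("synth_%05d", seq_len(n_ligands))
    rownames(x) <- ids
    reps <- list(latent = feature_block(x, ids, name = "latent"))
    if (n_representations > 1) {
      for (k in seq_len(n_representations - 1)) {
        q <- matrix(stats::rnorm(latent_dim^2), latent_dim)
        q <- qr.Q(qr(q))  # random rotation
        v <- x %*% q + matrix(stats::rnorm(n_ligands * latent_dim,
                                           sd = 0.2 * k),
                              n_ligands, latent_dim)
        reps[[paste0("view", k)]] <- feature_block(v, ids,
                                                   name = paste0("view", k))
      }
    }
    pca <- stats::prcomp(x, rank. = 2)
    emb <- tibble::tibble(ligand_id = ids, dim1 = pca$x[, 1],
                          dim2 = pca$x[, 2])
    structure(list(
      ligands = ligand_tbl(ids, NA_character_, provenance = "synthetic"),
      features = reps$latent,
      representations = reps,
      cluster_assignments = stats::setNames(z, ids),
      truth = tibble::tibble(ligand_id = ids, dg_true = dg, cluster = z,
                             strong = dg < thr),
      strong_threshold = thr,
      embedding = emb,
      params = list(n_ligands = n_ligands, n_clusters = n_clusters,
                    n_strong_clusters = n_strong_clusters,
                    strong_fraction = strong_fraction, dg_range = dg_range,
                    noise_free = noise_free, latent_dim = latent_dim,
                    n_representations = n_representations),
      seed = as.integer(seed)
    ), class = "synthetic_landscape")
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_landscape> %d ligands, %d clusters ",
                     "(%d strong), %d strong binders below %.2f kcal/mol\n"),
              nrow(x$ligands), x$params$n_clusters,
              x$params$n_strong_clusters, sum(x$truth$strong),
              x$strong_threshold))
  invisible(x)
}

#' Export a landscape as CSV files plus a ready-to-run config
#'
#' Writes the latent feature block (`features.csv`, feature-block CSV
#' dialect), the truth table (`truth.csv`) and a `config.yaml` pointing a
#' lookup or synthetic oracle at the truth table, with the generating
#' seed recorded.
#'
#' @param landscape A `synthetic_landscape`.
#' @param dir Output directory (created if needed).
#' @param batch_size,max_iterations,seed Run parameters recorded in the
#'   generated config.
#' @return `dir`, invisibly.
#' @export
export_landscape <- function(landscape, dir, batch_size = 100L,
                             max_iterations = 6L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_block(landscape$features, file.path(dir, "features.csv"))
  readr::write_csv(landscape$truth, file.path(dir, "truth.csv"))
  readr::write_csv(landscape$embedding, file.path(dir, "embedding.csv"))
  yaml::write_yaml(list(
    library = "truth.csv", blocks = list(latent = "features.csv"),
    embedding = "embedding.csv", truth = "truth.csv",
    oracle = list(type = "synthetic", truth = "truth.csv", sigma = 1.1,
                  n_replicates = 5),
    policy = "greedy", batch_size = batch_size,
    max_iterations = max_iterations, seed = seed,
    landscape_seed = landscape$seed,
    strong_threshold = landscape$strong_threshold
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a landscape exported with [export_landscape()]
#'
#' @param dir Directory written by [export_landscape()].
#' @return A list with `features` (feature block), `truth` (tibble) and
#'   `config` (parsed YAML).
#' @export
load_landscape <- function(dir) {
  list(
    features = read_feature_block(file.path(dir, "features.csv"),
                                  name = "latent"),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE),
    config = yaml::read_yaml(file.path(dir, "config.yaml"))
  )
}

#' Packaged fixture molecules
#'
#' A small set of real drug-like SMILES sharing a pyridazinone-like core
#' with varied R-groups and embedded 3D coordinates, used to exercise the
#' chemistry-dependent paths (decomposition, enumeration, descriptor and
#' voxel featurization). The molecules are synthetic fixtures assembled
#' for testing, not a published ligand series.
#'
#' @return A ligand tibble with an `sdf_path` attribute pointing at the
#'   packaged SDF holding 3D coordinates.
#' @export
fixture_molecules <- function() {
  smi_path <- system.file("extdata", "fixture_ligands.smi",
                          package = "alchemal", mustWork = TRUE)
  lig <- read_smiles(smi_path)
  lig$provenance <- "input"
  attr(lig, "sdf_path") <- system.file("extdata", "fixture_ligands.sdf",
                                       package = "alchemal", mustWork = TRUE)
  attr(lig, "core") <- readLines(system.file("extdata", "fixture_core.smi",
                                             package = "alchemal",
                                             mustWork = TRUE))[1]
  lig
}
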