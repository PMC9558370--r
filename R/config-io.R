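#' Build an active-learning configuration from a YAML file
#'
#' The on-disk run configuration mirrors [al_config()]: file paths are
#' resolved relative to the YAML's directory.
#'
#' ```yaml
#' library: library.smi            # or a CSV with ligand_id,smiles
#' blocks:
#'   latent: features.csv          # feature-block CSVs, first = main
#' embedding: embedding.csv        # optional ligand_id,dim1,dim2
#' truth: truth.csv                # optional ligand_id,dg_true
#' oracle:
#'   type: synthetic               # or lookup (table: affinities.csv)
#'   truth: truth.csv
#'   sigma: 1.1
#'   n_replicates: 5
#' policy: greedy
#' batch_size: 100
#' max_iterations: 6
#' seed: 1
#' hyper:
#'   hidden_layer_widths: [64, 32]
#'   epochs: 2000
#' ```
#'
#' @param path YAML file path.
#' @param checkpoint_dir Optional override for the checkpoint directory.
#' @return An [al_config()].
#' @export
al_config_from_yaml <- function(path, checkpoint_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  read_lib <- function(p) {
    if (grepl("\\.csv$", p)) {
      df <- readr::read_csv(rel(p), show_col_types = FALSE)
      ligand_tbl(df$ligand_id, df[["smiles"]] %||% NA_character_)
    } else {
      read_smiles(rel(p))
    }
  }
  library <- read_lib(y$library)
  blocks <- purrr::imap(y$blocks, function(p, nm) {
    read_feature_block(rel(p), name = nm)
  })
  oracle <- y$oracle
  if (oracle$type == "lookup" && is.character(oracle$table)) {
    oracle$table <- readr::read_csv(rel(oracle$table),
                                    show_col_types = FALSE)
    if (!"dg" %in% names(oracle$table) && "dg_true" %in% names(oracle$table)) {
      oracle$table$dg <- oracle$table$dg_true
    }
  }
  if (oracle$type == "synthetic" && is.character(oracle$truth)) {
    oracle$truth <- readr::read_csv(rel(oracle$truth),
                                    show_col_types = FALSE)
  }
  truth <- if (!is.null(y$truth)) {
    readr::read_csv(rel(y$truth), show_col_types = FALSE)
  }
  embedding <- if (!is.null(y$embedding)) {
    readr::read_csv(rel(y$embedding), show_col_types = FALSE)
  }
  hyper <- do.call(train_hyper, y$hyper %||% list())
  args <- list(library = library, blocks = blocks, oracle = oracle,
               truth = truth, embedding = embedding, hyper = hyper,
               checkpoint_dir = checkpoint_dir %||% rel(y$checkpoint_dir))
  scalars <- intersect(names(y), c("policy", "batch_size", "max_iterations",
                                   "k_folds", "n_repeats", "pool_factor",
                                   "n_models", "per_model_top",
                                   "switch_after", "top_n", "tpr_threshold",
                                   "uncertainty", "stop_on_plateau", "seed"))
  do.call(al_config, c(args, y[scalars]))
}
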