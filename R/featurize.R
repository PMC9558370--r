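#' Load a descriptor catalogue manifest
#'
#' The 2D_3D representation is defined by an explicit, versioned manifest
#' of descriptor and fingerprint names rather than by toolkit reflection,
#' so the block's composition is reproducible across toolkit versions. The
#' packaged default manifest lists the full RDKit 2D descriptor set plus
#' MACCS keys and a 1024-bit radius-2 Morgan fingerprint.
#'
#' @param path YAML manifest; default: the packaged catalogue.
#' @return A list with elements `version`, `descriptors`, `fingerprints`.
#' @export
read_catalogue <- function(path = system.file("extdata", "catalogue_2d3d.yaml",
                                              package = "alchemal")) {
  cat <- yaml::read_yaml(path)
  stopifnot(is.character(cat$version), length(cat$descriptors) > 0)
  cat
}

#' Compute the 2D_3D descriptor/fingerprint block
#'
#' Encodes each ligand as the concatenation of the constitutional,
#' electrotopological and surface-area descriptors plus the folded
#' fingerprints named in the catalogue manifest. Columns that come out
#' non-finite for any ligand (descriptors undefined for some molecules)
#' are dropped and logged on the block.
#'
#' @param ligands A ligand tibble; all SMILES must parse.
#' @param catalogue A catalogue manifest (see [read_catalogue()]).
#' @param smiles_col Column to featurize (`"smiles"` or `"rgroup_smiles"`).
#' @return A `feature_block` named after the catalogue.
#' @export
compute_2d3d <- function(ligands, catalogue = read_catalogue(),
                         smiles_col = "smiles") {
  stopifnot(smiles_col %in% names(ligands))
  smi <- ligands[[smiles_col]]
  if (any(is.na(smi))) {
    stop("missing ", smiles_col, " for ligand(s): ",
         paste(ligands$ligand_id[is.na(smi)], collapse = ", "), call. = FALSE)
  }
  out <- run_chem_op(
    "descriptors", smiles = as.list(smi), ids = as.list(ligands$ligand_id),
    descriptors = as.list(catalogue$descriptors),
    fingerprints = catalogue$fingerprints
  )
  m <- do.call(rbind, lapply(out$matrix, function(r) {
    unlist(lapply(r, function(v) if (is.null(v)) NaN else v))
  }))
  block <- feature_block(m, ligands$ligand_id, unlist(out$feature_names),
                         name = catalogue$name %||% "2D_3D")
  drop_nonfinite_columns(block)
}

#' R-group-only feature block
#'
#' Applies the same descriptor pipeline to the R-group substructures
#' (`rgroup_smiles`), the representation used for congeneric libraries
#' that share a fixed core. Descriptors uncomputable on the much smaller
#' substructures are dropped like any other non-finite column.
#'
#' @inheritParams compute_2d3d
#' @return A `feature_block` named `"<catalogue>_rgroup"`.
#' @export
rgroup_block <- function(ligands, catalogue = read_catalogue()) {
  if (!"rgroup_smiles" %in% names(ligands) || any(is.na(ligands$rgroup_smiles))) {
    stop("every ligand needs rgroup_smiles for an R-group block", call. = FALSE)
  }
  block <- compute_2d3d(ligands, catalogue, smiles_col = "rgroup_smiles")
  block$name <- paste0(block$name, "_rgroup")
  block
}
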