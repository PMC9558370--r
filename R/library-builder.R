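#' Build a ligand tibble
#'
#' Ligand libraries are plain tibbles with columns `ligand_id`, `smiles`,
#' optional `rgroup_smiles`, and `provenance` (one of `"input"`,
#' `"enumerated"`, `"synthetic"`).
#'
#' @param ligand_id Unique identifiers.
#' @param smiles SMILES strings.
#' @param rgroup_smiles Optional R-group substructure SMILES.
#' @param provenance Provenance tag, recycled.
#' @return A tibble with one row per ligand.
#' @export
ligand_tbl <- function(ligand_id, smiles, rgroup_smiles = NA_character_,
                       provenance = "input") {
  if (anyDuplicated(ligand_id)) {
    stop("ligand_id values must be unique", call. = FALSE)
  }
  tibble::tibble(
    ligand_id = as.character(ligand_id),
    smiles = as.character(smiles),
    rgroup_smiles = rgroup_smiles,
    provenance = provenance
  )
}

#' Decompose a congeneric series into linker and terminus fragments
#'
#' Removes the common `core` from every ligand and fragments the remaining
#' R-groups with the BRICS rules while keeping track of attachment points.
#' Fragments bonded directly to the core are classified as linkers; all
#' other fragments are termini (they decorate a linker). Attachment points
#' are encoded as dummy atoms with atom-map numbers: map 1 is the
#' core-facing site of a linker, maps 2.. are termini-facing sites, and a
#' terminus carries a single map-2 site.
#'
#' Fragments recurring in several ligands are deduplicated by canonical
#' form, keeping the first `origin_ligand_id`. Ligands that do not contain
#' the core are skipped with a warning.
#'
#' @param ligands A ligand tibble (see [ligand_tbl()]).
#' @param core Core SMILES (attachment markers, if any, are ignored for
#'   matching).
#' @return A tibble of fragments: `fragment_id`, `smiles` (with attachment
#'   maps), `kind` (`"linker"`/`"terminus"`), `n_termini_sites`,
#'   `origin_ligand_id`.
#' @export
decompose_series <- function(ligands, core) {
  stopifnot(is.data.frame(ligands), all(c("ligand_id", "smiles") %in% names(ligands)))
  out <- run_chem_op(
    "decompose", core = core,
    ligands = purrr::pmap(ligands[c("ligand_id", "smiles")], list)
  )
  skipped <- unlist(out$skipped)
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " ligand(s) lacking the core: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  frs <- purrr::map_dfr(out$fragments, tibble::as_tibble)
  if (nrow(frs) == 0) {
    return(tibble::tibble(fragment_id = character(), smiles = character(),
                          kind = character(), n_termini_sites = integer(),
                          origin_ligand_id = character()))
  }
  frs |>
    dplyr::mutate(
      n_termini_sites = as.integer(.data$n_termini_sites),
      fragment_id = sprintf("%s_%03d", substr(.data$kind, 1, 4),
                            dplyr::row_number())
    ) |>
    dplyr::select("fragment_id", "smiles", "kind", "n_termini_sites",
                  "origin_ligand_id")
}

#' Enumerate a combinatorial core + linker + termini library
#'
#' Assembles every combination of the core, one linker attached through the
#' linker's core-facing site (the same atom by which it was bonded to the
#' core in the source series), and 0..`max_termini` termini placed on the
#' linker's termini-facing sites. All site subsets are enumerated;
#' assemblies that only differ by a permutation of symmetry-equivalent
#' sites collapse under canonicalization. Chemically invalid assemblies
#' (valence failures) are skipped and counted.
#'
#' @param core Core SMILES carrying an attachment dummy `[*:1]` at the
#'   R-group position.
#' @param linkers,termini Fragment tibbles (rows of the output of
#'   [decompose_series()]), or character vectors of fragment SMILES with
#'   attachment maps.
#' @param max_termini Maximum number of termini per product (default 3).
#' @return A ligand tibble with `provenance = "enumerated"` plus columns
#'   `linker_id` and `termini_ids` (comma-separated), and an attribute
#'   `n_invalid` counting skipped assemblies. Products are deduplicated by
#'   canonical SMILES; ordering is deterministic (linker-major,
#'   first-seen).
#' @export
enumerate_library <- function(core, linkers, termini, max_termini = 3L) {
  stopifnot(max_termini >= 0)
  l_smi <- if (is.data.frame(linkers)) linkers$smiles else as.character(linkers)
  t_smi <- if (is.data.frame(termini)) termini$smiles else as.character(termini)
  l_ids <- if (is.data.frame(linkers)) linkers$fragment_id else
    sprintf("link_%03d", seq_along(l_smi))
  t_ids <- if (is.data.frame(termini)) termini$fragment_id else
    sprintf("term_%03d", seq_along(t_smi))
  out <- run_chem_op("enumerate", core = core, linkers = as.list(l_smi),
                     termini = as.list(t_smi), max_termini = max_termini)
  prods <- out$products
  if (length(prods) == 0) {
    res <- ligand_tbl(character(), character(), provenance = character())
    res$linker_id <- character()
    res$termini_ids <- character()
    attr(res, "n_invalid") <- out$n_invalid
    return(res)
  }
  res <- tibble::tibble(
    ligand_id = sprintf("enum_%05d", seq_along(prods)),
    smiles = purrr::map_chr(prods, "smiles"),
    rgroup_smiles = purrr::map_chr(prods, ~ .x$rgroup_smiles %||% NA_character_),
    provenance = "enumerated",
    linker_id = l_ids[purrr::map_int(prods, "linker_index")],
    termini_ids = purrr::map_chr(prods, function(p) {
      idx <- unlist(p$termini_indices)
      if (length(idx) == 0) "" else paste(t_ids[idx], collapse = ",")
    })
  )
  attr(res, "n_invalid") <- out$n_invalid
  res
}

#' Read a SMILES library file
#'
#' One molecule per line, optionally followed by a tab and an identifier.
#'
#' @param path File path.
#' @return A ligand tibble.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  ids <- ifelse(nzchar(parts[, 2]), parts[, 2],
                sprintf("lig_%05d", seq_along(lines)))
  ligand_tbl(ids, trimws(parts[, 1]))
}

#' Write a library as SMILES + CSV manifest
#'
#' @param library A ligand tibble (from [enumerate_library()] or elsewhere).
#' @param smiles_path Path for the SMILES file (`smiles<TAB>id` lines).
#' @param manifest_path Optional CSV manifest path (`ligand_id`, `smiles`,
#'   `linker_id`, `termini_ids`).
#' @return `library`, invisibly.
#' @export
write_library <- function(library, smiles_path, manifest_path = NULL) {
  writeLines(paste(library$smiles, library$ligand_id, sep = "\t"), smiles_path)
  if (!is.null(manifest_path)) {
    cols <- intersect(c("ligand_id", "smiles", "linker_id", "termini_ids"),
                      names(library))
    readr::write_csv(library[cols], manifest_path)
  }
  invisible(library)
}
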