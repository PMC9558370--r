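#' Define a cubic voxel grid over a binding site
#'
#' @param origin Numeric length-3: grid origin in Angstrom (lower corner).
#' @param edge Voxel edge length in Angstrom (default 2, the grid
#'   resolution used for atom-hot encodings).
#' @param dims Integer length-3: voxel counts along x, y, z.
#' @param elements Chemical element channels; atoms of other elements are
#'   logged and counted in a shared `"other"` channel.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, edge = 2, dims,
                       elements = c("C", "N", "O", "S", "F", "Cl", "Br", "H")) {
  stopifnot(length(origin) == 3, edge > 0, length(dims) == 3, all(dims >= 1))
  structure(list(origin = as.numeric(origin), edge = as.numeric(edge),
                 dims = as.integer(dims), elements = as.character(elements)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d voxels, edge %.2f A, %d element channels\n",
              x$dims[1], x$dims[2], x$dims[3], x$edge, length(x$elements)))
  invisible(x)
}

#' Voxel index of coordinates (half-open binning)
#'
#' Voxels cover half-open intervals `[origin + i*edge, origin + (i+1)*edge)`
#' along each axis, so an atom sitting exactly on a voxel face belongs to
#' the higher-index cell. Returns NA for atoms outside the grid.
#'
#' @param coords n x 3 matrix of coordinates (Angstrom).
#' @param grid A `voxel_grid`.
#' @return Integer vector of zero-based flat voxel indices
#'   (`ix + dims1*(iy + dims2*iz)`), NA when out of bounds.
#' @export
voxel_index <- function(coords, grid) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  idx <- floor(sweep(coords, 2, grid$origin, "-") / grid$edge)
  inb <- idx[, 1] >= 0 & idx[, 1] < grid$dims[1] &
    idx[, 2] >= 0 & idx[, 2] < grid$dims[2] &
    idx[, 3] >= 0 & idx[, 3] < grid$dims[3]
  flat <- idx[, 1] + grid$dims[1] * (idx[, 2] + grid$dims[2] * idx[, 3])
  flat[!inb] <- NA
  as.integer(flat)
}

#' Atom-hot voxel encoding
#'
#' Counts the ligand atoms of each chemical element in each voxel of the
#' grid and flattens the (element x voxel) count tensor into a single
#' feature vector per ligand (column order: all voxels of element 1, then
#' element 2, ...). Atoms outside the grid are not silently dropped: they
#' are tallied in per-element `overflow_*` columns and logged. Elements
#' not in the grid's channel list count toward an `"other"` channel.
#'
#' @param atoms A tibble of atom records with columns `ligand_id`,
#'   `element`, `x`, `y`, `z` (Angstrom), e.g. from [read_sdf_atoms()].
#' @param grid A `voxel_grid`.
#' @param surface_mask Optional logical vector over voxels (length
#'   `prod(grid$dims)`); when given, voxel columns are restricted to
#'   masked voxels (the surface variant of the encoding).
#' @param ligand_ids Row order of the block (default: order of appearance).
#' @return A `feature_block` named `"atom_hot"` (or `"atom_hot_surf"`).
#' @export
compute_atom_hot <- function(atoms, grid, surface_mask = NULL,
                             ligand_ids = unique(atoms$ligand_id)) {
  stopifnot(inherits(grid, "voxel_grid"),
            all(c("ligand_id", "element", "x", "y", "z") %in% names(atoms)))
  n_vox <- prod(grid$dims)
  if (!is.null(surface_mask)) stopifnot(length(surface_mask) == n_vox)
  channels <- c(grid$elements, "other")
  elem <- ifelse(atoms$element %in% grid$elements, atoms$element, "other")
  n_other <- sum(elem == "other")
  if (n_other > 0) {
    message(n_other, " atom(s) of unlisted elements counted in 'other' channel")
  }
  flat <- voxel_index(cbind(atoms$x, atoms$y, atoms$z), grid)
  n_over <- sum(is.na(flat))
  if (n_over > 0) {
    message(n_over, " atom(s) outside the grid counted in overflow bins")
  }
  lig <- factor(atoms$ligand_id, levels = ligand_ids)
  ch <- factor(elem, levels = channels)
  m <- matrix(0, nrow = length(ligand_ids), ncol = length(channels) * n_vox)
  overflow <- matrix(0, length(ligand_ids), length(channels))
  inb <- !is.na(flat)
  if (any(inb)) {
    cnt <- dplyr::count(
      tibble::tibble(row = as.integer(lig)[inb],
                     col = (as.integer(ch)[inb] - 1L) * n_vox + flat[inb] + 1L),
      .data$row, .data$col)
    m[cbind(cnt$row, cnt$col)] <- cnt$n
  }
  if (any(!inb)) {
    cnt <- dplyr::count(
      tibble::tibble(row = as.integer(lig)[!inb], col = as.integer(ch)[!inb]),
      .data$row, .data$col)
    overflow[cbind(cnt$row, cnt$col)] <- cnt$n
  }
  colnames(m) <- unlist(lapply(channels, function(e) {
    paste0(e, "_v", seq_len(n_vox) - 1L)
  }))
  if (!is.null(surface_mask)) {
    keep <- rep(as.logical(surface_mask), times = length(channels))
    m <- m[, keep, drop = FALSE]
  }
  colnames(overflow) <- paste0("overflow_", channels)
  block <- feature_block(cbind(m, overflow), ligand_ids,
                         name = if (is.null(surface_mask)) "atom_hot"
                                else "atom_hot_surf")
  block
}

#' Read atom coordinates from an SDF file
#'
#' Parses an SDF (V2000) text file into a tidy atom table suitable for
#' [compute_atom_hot()]. Molecule names in the SDF header become ligand
#' ids.
#'
#' @param path SDF file path.
#' @return A tibble with `ligand_id`, `element`, `x`, `y`, `z`.
#' @export
read_sdf_atoms <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required to read SDF files", call. = FALSE)
  }
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  purrr::map_dfr(seq_along(ids), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    tibble::tibble(
      ligand_id = ids[i],
      element = gsub("_.*", "", rownames(ab)),
      x = ab[, 1], y = ab[, 2], z = ab[, 3]
    )
  })
}
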