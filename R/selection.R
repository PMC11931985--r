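#' Atom selections
#'
#' A selection names the atoms an analysis operates on: a `mode` picks atom
#' names (`"ca"` for C-alpha only, `"backbone"` for N/CA/C/O when present,
#' `"custom"` for an explicit atom-name set), then residue include/exclude
#' filters are applied. The printed loop ranges of the receptor model
#' (ICLs 102-108, 179-189, 263-314; ECLs 138-145, 217-231, 347-354) are
#' available via [loop_residues()] for the loop-masked analyses.
#'
#' @param mode `"ca"`, `"backbone"` or `"custom"`.
#' @param include_residues Optional residue ids to keep (default all).
#' @param exclude_residues Optional residue ids to drop.
#' @param atom_names Atom names for `mode = "custom"`.
#' @return An `atom_selection` object.
#' @examples
#' sel <- atom_selection("ca", exclude_residues = loop_residues())
#' @export
atom_selection <- function(mode = c("ca", "backbone", "custom"),
                           include_residues = NULL,
                           exclude_residues = NULL,
                           atom_names = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom" && (is.null(atom_names) || !length(atom_names))) {
    stop("mode = \"custom\" requires atom_names", call. = FALSE)
  }
  if (!is.null(include_residues) && !is.null(exclude_residues) &&
      length(intersect(include_residues, exclude_residues))) {
    stop("include_residues and exclude_residues overlap", call. = FALSE)
  }
  structure(list(mode = mode,
                 include_residues = include_residues,
                 exclude_residues = exclude_residues,
                 atom_names = atom_names),
            class = "atom_selection")
}

#' Residue ids of the intracellular and extracellular loops
#'
#' The six loop ranges excluded from the loop-masked PCA: ICL1 102-108,
#' ICL2 179-189, ICL3 263-314, ECL1 138-145, ECL2 217-231, ECL3 347-354.
#'
#' @return Integer vector of loop residue ids (101 residues).
#' @export
loop_residues <- function() {
  c(102:108, 179:189, 263:314, 138:145, 217:231, 347:354)
}

# canonical atom-name order within a residue
.atom_name_order <- c("N", "CA", "C", "O")

#' Resolve a selection to atom indices
#'
#' Deterministic resolution: the mode filter picks atom names, then residue
#' include/exclude filters apply; indices are ordered by ascending residue
#' id, then canonical backbone atom-name order (N, CA, C, O), then name.
#'
#' @param structure An `md_structure`.
#' @param selection An [atom_selection()].
#' @return Integer vector of row indices into the structure's atom table.
#' @export
resolve_selection <- function(structure, selection) {
  stopifnot(inherits(structure, "md_structure"),
            inherits(selection, "atom_selection"))
  at <- structure$atoms
  keep <- switch(selection$mode,
    ca = at$atom_name == "CA",
    backbone = at$atom_name %in% .atom_name_order,
    custom = at$atom_name %in% selection$atom_names)
  if (!is.null(selection$include_residues)) {
    keep <- keep & at$residue_id %in% selection$include_residues
  }
  if (!is.null(selection$exclude_residues)) {
    keep <- keep & !(at$residue_id %in% selection$exclude_residues)
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection resolves to no atoms", call. = FALSE)
  rank_name <- match(at$atom_name[idx], .atom_name_order)
  rank_name[is.na(rank_name)] <- length(.atom_name_order) + 1L
  idx[order(at$residue_id[idx], rank_name, at$atom_name[idx])]
}
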