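#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into an [new_md_structure()]
#' object. Coordinates are in Angstrom; residue ids are taken verbatim from
#' the file (author numbering, no renumbering); masses are inferred from the
#' element column, falling back to the first letter of the atom name.
#' Files containing insertion codes or alternate-location indicators are
#' rejected with an error rather than silently normalized.
#'
#' @param path Path to a PDB file.
#' @param format Only `"pdb"` is supported.
#' @return An `md_structure`.
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  pdb_model_to_structure(pdb)
}

# reject malformed/unsupported records early, reporting the line number
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  }
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed PDB record at line ", i, ": too short", call. = FALSE)
    }
    if (substr(ln, 17, 17) != " ") {
      stop("alternate location indicator at line ", i,
           " is not supported", call. = FALSE)
    }
    if (substr(ln, 27, 27) != " ") {
      stop("insertion code at line ", i, " is not supported", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      stop("malformed coordinates in PDB record at line ", i, call. = FALSE)
    }
  }
  invisible(TRUE)
}

pdb_model_to_structure <- function(pdb) {
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- trimws(elem)
  elem[!nzchar(elem)] <- substr(trimws(at$elety[!nzchar(elem)]), 1, 1)
  atoms <- tibble::tibble(residue_id = as.integer(at$resno),
                          atom_name = trimws(at$elety),
                          element = elem,
                          mass = element_mass(elem))
  chain <- at$chain[1]
  if (is.na(chain) || !nzchar(chain)) chain <- "A"
  coords <- cbind(at$x, at$y, at$z)
  new_md_structure(atoms, coords, chain_id = chain)
}

#' Write a structure to a PDB file
#'
#' ATOM records only; occupancy 1.00, B-factor 0.00. Writers are bit-stable
#' for a fixed input.
#'
#' @param structure An `md_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$coords)),
                   resno = at$residue_id,
                   resid = rep("ALA", nrow(at)),
                   elety = at$atom_name,
                   chain = rep(structure$chain_id, nrow(at)),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a trajectory
#'
#' Two plain-text formats are supported: multi-model PDB (MODEL/ENDMDL
#' blocks; the frame index, starting at 0, is used as the time axis) and a
#' flat TSV table with header `frame, time_ns, residue_id, atom_name, x, y,
#' z` which supplies explicit times.
#'
#' @param path Input file.
#' @param topology `md_structure` the frames must be congruent with.
#' @param format `"multi_model_pdb"` or `"flat_table"`.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, topology,
                            format = c("multi_model_pdb", "flat_table")) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "md_structure"))
  n_atoms <- nrow(topology$coords)
  if (format == "multi_model_pdb") {
    validate_pdb_lines(path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (ncol(xyz) != 3L * n_atoms) {
      stop("shape-mismatch: frames have ", ncol(xyz) / 3,
           " atoms, topology has ", n_atoms, call. = FALSE)
    }
    nf <- nrow(xyz)
    frames <- array(NA_real_, c(nf, n_atoms, 3L))
    for (i in seq_len(nf)) {
      frames[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    }
    new_md_trajectory(topology, frames, times_ns = as.numeric(seq_len(nf) - 1L))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("frame", "time_ns", "residue_id", "atom_name", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      stop("flat trajectory table must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    fr_ids <- sort(unique(tab$frame))
    counts <- table(tab$frame)
    bad <- names(counts)[counts != n_atoms]
    if (length(bad)) {
      stop("shape-mismatch: frame ", bad[1], " has ", counts[bad[1]],
           " atoms, topology has ", n_atoms, call. = FALSE)
    }
    nf <- length(fr_ids)
    frames <- array(NA_real_, c(nf, n_atoms, 3L))
    times <- numeric(nf)
    key_top <- paste(topology$atoms$residue_id, topology$atoms$atom_name)
    for (i in seq_len(nf)) {
      sub <- tab[tab$frame == fr_ids[i], ]
      ord <- match(key_top, paste(sub$residue_id, sub$atom_name))
      if (anyNA(ord)) {
        stop("shape-mismatch: frame ", fr_ids[i],
             " does not match topology atoms", call. = FALSE)
      }
      frames[i, , ] <- cbind(sub$x[ord], sub$y[ord], sub$z[ord])
      times[i] <- sub$time_ns[1]
    }
    new_md_trajectory(topology, frames, times_ns = times)
  }
}

#' Write a trajectory
#'
#' @param traj An `md_trajectory`.
#' @param path Output file.
#' @param format `"multi_model_pdb"` or `"flat_table"` (TSV with header).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("multi_model_pdb", "flat_table")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "md_trajectory"))
  top <- traj$topology
  if (format == "multi_model_pdb") {
    nf <- n_frames(traj)
    xyz <- matrix(NA_real_, nf, 3L * nrow(top$coords))
    for (i in seq_len(nf)) {
      xyz[i, ] <- as.vector(t(traj$frames[i, , , drop = TRUE]))
    }
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = top$atoms$residue_id,
                     resid = rep("ALA", nrow(top$atoms)),
                     elety = top$atoms$atom_name,
                     chain = rep(top$chain_id, nrow(top$atoms)),
                     o = rep(1, nrow(top$atoms)),
                     b = rep(0, nrow(top$atoms)))
  } else {
    tab <- tidy(traj)
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}
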