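#' Molecular structure and trajectory containers
#'
#' An `md_structure` holds one conformation: an atom table (residue id,
#' atom name, element, mass in amu) plus an `n x 3` coordinate matrix in
#' Angstrom. An `md_trajectory` holds ordered frames congruent with a
#' topology `md_structure` and a strictly increasing time axis in ns.
#'
#' @param atoms Tibble with columns `residue_id`, `atom_name`, `element`,
#'   `mass`.
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param chain_id Single chain label.
#' @return `new_md_structure()` returns an `md_structure`;
#'   `new_md_trajectory()` an `md_trajectory`.
#' @export
new_md_structure <- function(atoms, coords, chain_id = "A") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("residue_id", "atom_name", "element", "mass") %in% names(atoms)),
            is.matrix(coords), ncol(coords) == 3L, nrow(coords) == nrow(atoms),
            all(is.finite(coords)), all(atoms$mass > 0))
  if (anyDuplicated(atoms[, c("residue_id", "atom_name")])) {
    stop("duplicate (residue_id, atom_name) in structure", call. = FALSE)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, chain_id = chain_id),
            class = "md_structure")
}

#' @rdname new_md_structure
#' @param topology An `md_structure` describing the atoms of every frame.
#' @param frames 3-d array `n_frames x n_atoms x 3` (Angstrom), or a list of
#'   `n_atoms x 3` matrices.
#' @param times_ns Strictly increasing frame times in ns (default: frame
#'   index starting at 0).
#' @export
new_md_trajectory <- function(topology, frames, times_ns = NULL) {
  stopifnot(inherits(topology, "md_structure"))
  if (is.list(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[2] == nrow(topology$coords), dim(frames)[3] == 3L)
  dimnames(frames) <- list(NULL, NULL, c("x", "y", "z"))
  n <- dim(frames)[1]
  if (is.null(times_ns)) times_ns <- as.numeric(seq_len(n) - 1L)
  stopifnot(length(times_ns) == n)
  if (n > 1L && any(diff(times_ns) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, frames = frames, times_ns = times_ns),
            class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("<md_structure> ", nrow(x$coords), " atoms, ",
      length(unique(x$atoms$residue_id)), " residues, chain ", x$chain_id,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", dim(x$frames)[1], " frames x ", dim(x$frames)[2],
      " atoms; t = ", format(x$times_ns[1]), " .. ",
      format(x$times_ns[length(x$times_ns)]), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$frames)[1]
}

#' Extract one frame of a trajectory as a structure
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based).
#' @return An `md_structure` with the frame's coordinates.
#' @export
trajectory_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"),
            i >= 1L, i <= n_frames(traj))
  new_md_structure(traj$topology$atoms, traj$frames[i, , , drop = TRUE],
                   traj$topology$chain_id)
}

#' @export
tidy.md_structure <- function(x, ...) {
  dplyr::bind_cols(x$atoms,
                   tibble::as_tibble(x$coords))
}

#' @export
tidy.md_trajectory <- function(x, ...) {
  n <- n_frames(x)
  purrr::map_dfr(seq_len(n), function(i) {
    dplyr::bind_cols(
      tibble::tibble(frame = i, time_ns = x$times_ns[i],
                     residue_id = x$topology$atoms$residue_id,
                     atom_name = x$topology$atoms$atom_name),
      tibble::as_tibble(x$frames[i, , , drop = TRUE],
                        .name_repair = ~ c("x", "y", "z")))
  })
}

# masses for elements appearing in toy and typical protein PDB files
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971)

element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}
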