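#' Weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two congruent point sets, via SVD of the weighted covariance of
#' the centred coordinates. The reflection case (negative determinant) is
#' corrected by flipping the sign of the smallest singular axis, so the
#' returned rotation always has determinant +1.
#'
#' @param mobile `n x 3` coordinate matrix to be moved (Angstrom).
#' @param reference `n x 3` target coordinates.
#' @param weights Optional per-point weights (e.g. masses in amu); unit
#'   weights when `NULL`.
#' @return A list with `rotation` (3x3, applied on coordinate rows as
#'   `x %*% t(R)`), `translation` (length 3), and `rmsd` (weighted, in
#'   Angstrom). The transformed mobile set is
#'   `sweep(mobile %*% t(rotation), 2, translation, "+")`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate input: need at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(reference, 2, cr)

  # degenerate (collinear / coincident) reference geometry
  if (qr(xr * sqrt(w))$rank < 2L) {
    stop("degenerate input: reference points are collinear or coincident",
         call. = FALSE)
  }

  h <- t(xm * w) %*% xr
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  flip <- diag(c(1, 1, d))
  rot <- sv$v %*% flip %*% t(sv$u)

  fitted <- xm %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - xr)^2)))
  translation <- as.numeric(cr - rot %*% cm)
  list(rotation = rot, translation = translation, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param fit Result of [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Kabsch-aligns each frame over the atoms of `selection` (fit atoms), then
#' applies the fitted transform to all atoms of the frame. The reference is
#' either a structure or a frame of the trajectory itself (default: frame 1).
#'
#' @param traj An `md_trajectory`.
#' @param selection An [atom_selection()] naming the fit atoms.
#' @param reference An `md_structure`, or `NULL` to use `reference_frame`.
#' @param reference_frame Frame index used when `reference` is `NULL`.
#' @param mass_weighted Use atomic masses as fit weights.
#' @return A new `md_trajectory` with superposed frames.
#' @export
superpose_trajectory <- function(traj, selection, reference = NULL,
                                 reference_frame = 1L, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- resolve_selection(traj$topology, selection)
  ref_coords <- if (is.null(reference)) {
    traj$frames[reference_frame, idx, , drop = TRUE]
  } else {
    idx_ref <- resolve_selection(reference, selection)
    reference$coords[idx_ref, , drop = FALSE]
  }
  w <- if (mass_weighted) traj$topology$atoms$mass[idx] else NULL
  out <- traj$frames
  for (i in seq_len(n_frames(traj))) {
    fit <- kabsch_superpose(out[i, idx, , drop = TRUE], ref_coords, weights = w)
    out[i, , ] <- apply_superposition(out[i, , , drop = TRUE], fit)
  }
  new_md_trajectory(traj$topology, out, traj$times_ns)
}
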