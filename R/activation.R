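#' Specification of the A100 activation index
#'
#' The A100 index scores class A GPCR activation as a linear combination of
#' five inter-residue C-alpha distances (in Angstrom):
#'
#' `A100 = -14.43 r(95-382) - 7.62 r(120-160) + 9.11 r(165-192)
#'         - 6.32 r(262-322) - 5.22 r(346-362) + 278.88`
#'
#' The residue pairs are, in receptor numbering: V95-L382, D120-T160,
#' H165-A192, Q262-C322 and A346-L362. Distances are C-alpha to C-alpha in
#' Angstrom: the published thresholds (0, 25, 55) are only consistent with
#' Angstrom-scale distances. The spec object is immutable once constructed.
#'
#' @return An `a100_spec` with fields `pairs` (5 x 2 integer matrix),
#'   `coefficients` (per-Angstrom weights) and `intercept` (278.88).
#' @examples
#' sp <- a100_spec()
#' sp$intercept  # 278.88
#' @export
a100_spec <- function() {
  out <- list(
    pairs = matrix(c(95L, 382L,
                     120L, 160L,
                     165L, 192L,
                     262L, 322L,
                     346L, 362L), ncol = 2L, byrow = TRUE),
    coefficients = c(-14.43, -7.62, 9.11, -6.32, -5.22),
    intercept = 278.88)
  class(out) <- "a100_spec"
  out
}

ca_row <- function(topology, res) {
  hit <- which(topology$atoms$residue_id == res & topology$atoms$atom_name == "CA")
  if (length(hit) != 1L) {
    stop("missing-atom: no unique CA for residue ", res, call. = FALSE)
  }
  hit
}

#' C-alpha distance time series
#'
#' Per-frame Euclidean distance between the C-alpha atoms of two residues,
#' in Angstrom. No superposition is applied (distances are invariant to
#' rigid motion). The canonical activation readouts are the ionic-lock pair
#' R173-E318 and the TM5 pair Q262-E318.
#'
#' @param traj An `md_trajectory`.
#' @param res_a,res_b Residue ids.
#' @param references Optional named numeric vector (e.g.
#'   `c(closed = 8.5, open = 16.2)`) recorded as attributes for plotting.
#' @return A tibble with columns `time_ns`, `distance`; the residue pair is
#'   carried in attribute `"pair"`, any reference levels in `"references"`.
#' @export
ca_distance_series <- function(traj, res_a, res_b, references = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  ia <- ca_row(traj$topology, res_a)
  ib <- ca_row(traj$topology, res_b)
  nf <- n_frames(traj)
  diff <- traj$frames[, ia, , drop = FALSE] - traj$frames[, ib, , drop = FALSE]
  d <- sqrt(rowSums(matrix(diff, nf, 3L)^2))
  out <- tibble::tibble(time_ns = traj$times_ns, distance = d)
  attr(out, "pair") <- c(res_a, res_b)
  attr(out, "references") <- references
  out
}

#' A100 activation-index time series
#'
#' Evaluates the A100 score per frame from the five C-alpha distances of
#' [a100_spec()] and attaches both state classifications.
#'
#' @param traj An `md_trajectory`.
#' @param spec An [a100_spec()].
#' @return A tibble with columns `time_ns`, `score`, `label3`
#'   (inactive/intermediate/active) and `label2` (inactive/active).
#' @export
a100_series <- function(traj, spec = a100_spec()) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "a100_spec"))
  score <- rep(spec$intercept, n_frames(traj))
  for (p in seq_len(nrow(spec$pairs))) {
    d <- ca_distance_series(traj, spec$pairs[p, 1], spec$pairs[p, 2])$distance
    score <- score + spec$coefficients[p] * d
  }
  tibble::tibble(time_ns = traj$times_ns, score = score,
                 label3 = classify_state(score, "three_state"),
                 label2 = classify_state(score, "two_state"))
}

#' Classify an A100 score into activation states
#'
#' Three-state model: `score < 0` inactive, `0 <= score < 55` intermediate,
#' `score >= 55` active. Two-state model: `score < 25` inactive,
#' `score >= 25` active. Boundaries are left-closed on the active side
#' (a score of exactly 55, or 25, is active); the published rule states
#' only strict inequalities for the lower classes.
#'
#' @param score Numeric vector of finite A100 scores.
#' @param model `"three_state"` or `"two_state"`.
#' @return Character vector of labels.
#' @export
classify_state <- function(score, model = c("three_state", "two_state")) {
  model <- match.arg(model)
  if (any(!is.finite(score))) {
    stop("invalid-input: scores must be finite", call. = FALSE)
  }
  if (model == "three_state") {
    dplyr::case_when(score < 0 ~ "inactive",
                     score < 55 ~ "intermediate",
                     TRUE ~ "active")
  } else {
    ifelse(score < 25, "inactive", "active")
  }
}

#' RMSD time series against a reference structure
#'
#' Per-frame mass-weighted RMSD over a selection, after Kabsch superposition
#' of each frame onto the reference over the same selection.
#'
#' @param traj An `md_trajectory`.
#' @param reference An `md_structure`.
#' @param selection An [atom_selection()].
#' @param mass_weighted Mass-weight the fit and the RMSD (default `TRUE`).
#' @return A tibble with columns `time_ns`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference, selection, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(reference, "md_structure"))
  idx <- resolve_selection(traj$topology, selection)
  idx_ref <- resolve_selection(reference, selection)
  if (length(idx) != length(idx_ref)) {
    stop("selection resolves to different atom counts on trajectory and reference",
         call. = FALSE)
  }
  ref <- reference$coords[idx_ref, , drop = FALSE]
  w <- if (mass_weighted) traj$topology$atoms$mass[idx] else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(traj$frames[i, idx, , drop = TRUE], ref, weights = w)$rmsd
  }, numeric(1))
  tibble::tibble(time_ns = traj$times_ns, rmsd = vals)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each selected atom about its time-mean position, optionally
#' after superposing every frame onto the time-averaged structure over the
#' selection (computed in a first pass from frames aligned to frame 1).
#'
#' @param traj An `md_trajectory` with at least 2 frames.
#' @param selection An [atom_selection()].
#' @param align Superpose frames onto the mean structure first (default
#'   `TRUE`).
#' @return A tibble with columns `residue_id`, `atom_name`, `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(traj, selection, align = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2L) {
    stop("insufficient-frames: RMSF needs at least 2 frames", call. = FALSE)
  }
  idx <- resolve_selection(traj$topology, selection)
  if (align) {
    pre <- superpose_trajectory(traj, selection)
    mean_coords <- apply(pre$frames[, idx, , drop = FALSE], c(2, 3), mean)
    mean_struct <- new_md_structure(traj$topology$atoms[idx, ], mean_coords)
    sub_sel <- atom_selection("custom",
                              atom_names = unique(traj$topology$atoms$atom_name[idx]),
                              include_residues = unique(traj$topology$atoms$residue_id[idx]))
    traj <- superpose_trajectory(traj, sub_sel, reference = mean_struct)
  }
  x <- traj$frames[, idx, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  vals <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames of |dx|^2
  tibble::tibble(residue_id = traj$topology$atoms$residue_id[idx],
                 atom_name = traj$topology$atoms$atom_name[idx],
                 rmsf = vals)
}
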