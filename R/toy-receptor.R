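#' Toy seven-helix receptor
#'
#' Builds a deterministic C-alpha model of a class A GPCR-like fold:
#' residues 70-399 (330 residues) arranged as seven idealized
#' transmembrane helices (rise 1.5 A/residue, 100 degrees/residue, radius
#' 2.3 A) placed on a bundle circle with alternating up/down direction,
#' connected by loop segments interpolated between helix ends with small
#' deterministic lateral offsets plus a tiny seeded jitter so that no two
#' residues coincide. Only the topology matters for the analyses (helix
#' contiguity, a distinct TM6 block at residues 315-346); the geometry is
#' not meant to be structurally realistic.
#'
#' The Ballesteros-Weinstein map carries the labels used by the activation
#' index and the distance metrics; residue ids are the ground truth and the
#' labels are metadata only (the index's published form labels both T160
#' and A192 as 4.42, so the second is stored under `"4.42b"`).
#'
#' @param seed Integer seed; the same seed always yields bitwise-identical
#'   coordinates.
#' @return A `toy_receptor`: list with `structure` (an `md_structure` of 330
#'   CA pseudo-atoms carrying per-residue masses in amu), `bw_map` (named
#'   integer vector label -> residue id), and `segments` (named list of
#'   residue-id ranges, including `TM6`).
#' @examples
#' rec <- make_toy_receptor(seed = 1)
#' rec$bw_map[["3.50"]]  # 173
#' @export
make_toy_receptor <- function(seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  segments <- list(
    TM1 = 70:101,  ICL1 = 102:108, TM2 = 109:137, ECL1 = 138:145,
    TM3 = 146:178, ICL2 = 179:189, TM4 = 190:216, ECL2 = 217:231,
    TM5 = 232:262, ICL3 = 263:314, TM6 = 315:346, ECL3 = 347:354,
    TM7 = 355:399)
  helices <- c("TM1", "TM2", "TM3", "TM4", "TM5", "TM6", "TM7")
  # helix axis anchor points on a bundle circle (x, y), Angstrom
  bundle_r <- 11
  angles <- 2 * pi * (seq_along(helices) - 1L) / length(helices)

  coords <- matrix(NA_real_, 330, 3)
  ids <- 70:399
  row_of <- function(res) match(res, ids)

  for (h in seq_along(helices)) {
    res <- segments[[helices[h]]]
    n <- length(res)
    up <- (h %% 2L) == 1L                    # alternate up/down
    t <- seq_len(n) - 1L
    phase <- t * (100 * pi / 180)
    z <- (t - (n - 1) / 2) * 1.5 * (if (up) 1 else -1)
    cx <- bundle_r * cos(angles[h]) + 2.3 * cos(phase)
    cy <- bundle_r * sin(angles[h]) + 2.3 * sin(phase)
    coords[row_of(res), ] <- cbind(cx, cy, z)
  }
  loops <- setdiff(names(segments), helices)
  for (lp in loops) {
    res <- segments[[lp]]
    n <- length(res)
    a <- coords[row_of(min(res) - 1L), ]
    b <- coords[row_of(max(res) + 1L), ]
    lambda <- seq_len(n) / (n + 1)
    base <- outer(1 - lambda, a) + outer(lambda, b)
    # arc the loop outward so its residues never collapse onto the line
    perp <- c(-(b - a)[2], (b - a)[1], 0)
    np <- sqrt(sum(perp^2))
    perp <- if (np > 1e-8) perp / np else c(0, 0, 1)
    bow <- 4 * sin(pi * lambda)
    coords[row_of(res), ] <- base + outer(bow, perp)
  }

  jitter <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(length(coords), sd = 0.05), nrow(coords), 3)
  })
  coords <- coords + jitter

  # deterministic per-residue masses cycling through the 20 residue masses
  aa_masses <- c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12,
                 57.05, 137.14, 113.16, 113.16, 128.17, 131.19, 147.18,
                 97.12, 87.08, 101.10, 186.21, 163.18, 99.13)
  masses <- aa_masses[((ids - 70L) %% 20L) + 1L]

  atoms <- tibble::tibble(residue_id = as.integer(ids),
                          atom_name = "CA", element = "C", mass = masses)
  bw_map <- c("1.53" = 95L, "2.50" = 120L, "4.42" = 160L, "3.42" = 165L,
              "3.50" = 173L, "4.42b" = 192L, "5.66" = 262L, "6.30" = 318L,
              "6.34" = 322L, "6.58" = 346L, "7.35" = 362L, "7.55" = 382L)
  structure(list(structure = new_md_structure(atoms, coords),
                 bw_map = bw_map, segments = segments),
            class = "toy_receptor")
}

#' @export
print.toy_receptor <- function(x, ...) {
  cat("<toy_receptor> residues 70..399 (330 CA), TM6 block ",
      min(x$segments$TM6), "-", max(x$segments$TM6), "\n", sep = "")
  invisible(x)
}

#' Closed/open reference pair from a toy receptor
#'
#' The "open" (active-like) reference differs from the "closed" (inactive)
#' one by a rigid outward displacement of the TM6 block (residues 315-346)
#' of magnitude `tm6_shift`, applied along the unit vector from the R173
#' C-alpha to the E318 C-alpha of the closed conformation, so that the
#' R173-E318 distance difference between the two references equals
#' `tm6_shift` exactly; all other residues are identical. This mimics the
#' hallmark TM6 outward tilt that opens the intracellular transducer
#' cavity (roughly 8 A in transducer-bound experimental structures, about
#' 4 A in partially-open intermediates).
#'
#' @param receptor A [make_toy_receptor()] result.
#' @param tm6_shift Outward displacement magnitude in Angstrom (> 0).
#' @param seed Unused; accepted for generator-API symmetry (the pair is a
#'   deterministic function of the receptor).
#' @return A list with `md_structure` elements `closed` and `open`, plus
#'   `tm6_block` (residue ids) and `shift_axis` (unit vector).
#' @export
make_reference_pair <- function(receptor, tm6_shift, seed = NULL) {
  stopifnot(inherits(receptor, "toy_receptor"))
  if (!is.numeric(tm6_shift) || length(tm6_shift) != 1L || tm6_shift <= 0) {
    stop("tm6_shift must be a single positive length in Angstrom",
         call. = FALSE)
  }
  closed <- receptor$structure
  ids <- closed$atoms$residue_id
  r173 <- closed$coords[match(173L, ids), ]
  e318 <- closed$coords[match(318L, ids), ]
  axis <- (e318 - r173) / sqrt(sum((e318 - r173)^2))
  block <- receptor$segments$TM6
  open_coords <- closed$coords
  rows <- ids %in% block
  open_coords[rows, ] <- open_coords[rows, ] +
    matrix(tm6_shift * axis, sum(rows), 3, byrow = TRUE)
  open_ <- new_md_structure(closed$atoms, open_coords, closed$chain_id)
  list(closed = closed, open = open_, tm6_block = block, shift_axis = axis)
}

#' Two-state collapse trajectory
#'
#' Interpolates from the "open" toward the "closed" conformation with a
#' monotone mixing coefficient lambda(t) decreasing linearly from 1 at
#' frame 1 to 0 at `collapse_frame`, constant 0 afterwards (modelling the
#' rapid open-to-closed collapse seen in unliganded receptor simulations),
#' plus i.i.d. Gaussian noise per coordinate. Frame times are
#' `dt_ns * (0:(n_frames-1))`.
#'
#' @param closed,open_ Congruent `md_structure`s (same atoms).
#' @param n_frames Number of frames.
#' @param collapse_frame Frame (0-based time index) at which lambda reaches
#'   0; `0` means every frame is already closed.
#' @param noise_sd Gaussian noise SD in Angstrom (>= 0).
#' @param seed Integer seed (fixed seed gives identical frames).
#' @param dt_ns Frame spacing in ns (default 0.1, the usual analysis
#'   cadence).
#' @return An `md_trajectory`.
#' @export
generate_two_state_trajectory <- function(closed, open_, n_frames,
                                          collapse_frame, noise_sd = 0,
                                          seed = 1L, dt_ns = 0.1) {
  stopifnot(inherits(closed, "md_structure"), inherits(open_, "md_structure"),
            n_frames >= 1L, noise_sd >= 0,
            collapse_frame >= 0L, collapse_frame <= n_frames)
  if (!identical(dim(closed$coords), dim(open_$coords)) ||
      !identical(closed$atoms$residue_id, open_$atoms$residue_id)) {
    stop("shape-mismatch: closed and open structures are not congruent",
         call. = FALSE)
  }
  t0 <- seq_len(n_frames) - 1L
  lambda <- if (collapse_frame == 0L) rep(0, n_frames) else {
    pmax(0, 1 - t0 / collapse_frame)
  }
  na <- nrow(closed$coords)
  frames <- array(NA_real_, c(n_frames, na, 3L))
  noise <- withr::with_seed(as.integer(seed), {
    if (noise_sd > 0) {
      array(stats::rnorm(n_frames * na * 3L, sd = noise_sd),
            c(n_frames, na, 3L))
    } else {
      array(0, c(n_frames, na, 3L))
    }
  })
  for (i in seq_len(n_frames)) {
    frames[i, , ] <- lambda[i] * open_$coords +
      (1 - lambda[i]) * closed$coords + noise[i, , ]
  }
  new_md_trajectory(closed, frames, times_ns = dt_ns * t0)
}
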