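# Small structures/trajectories built in code for the unit tests.

make_point_structure <- function(coords, residue_ids = NULL, masses = NULL) {
  n <- nrow(coords)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (is.null(masses)) masses <- rep(12.011, n)
  new_md_structure(
    tibble::tibble(residue_id = as.integer(residue_ids), atom_name = "CA",
                   element = "C", mass = masses),
    coords)
}

make_static_trajectory <- function(structure, n = 5L) {
  frames <- array(rep(structure$coords, each = n), c(n, nrow(structure$coords), 3L))
  for (i in seq_len(n)) frames[i, , ] <- structure$coords
  new_md_trajectory(structure, frames)
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

# structure in which all five activation-index residue pairs coincide, so
# every index distance is a chosen constant
a100_pair_structure <- function(separation = 0) {
  pairs <- a100_spec()$pairs
  coords <- matrix(NA_real_, 10, 3)
  ids <- integer(10)
  for (p in seq_len(nrow(pairs))) {
    base <- c(10 * p, 0, 0)
    coords[2 * p - 1, ] <- base
    coords[2 * p, ] <- base + c(0, separation, 0)
    ids[2 * p - 1] <- pairs[p, 1]
    ids[2 * p] <- pairs[p, 2]
  }
  ord <- order(ids)
  make_point_structure(coords[ord, , drop = FALSE], residue_ids = ids[ord])
}

one_frame_trajectory <- function(structure) {
  make_static_trajectory(structure, n = 1L)
}

small_double_well <- function() {
  potential_spec("double_well", domain = c(0, 2), barrier = 2,
                 minima = c(0.5, 1.5))
}
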