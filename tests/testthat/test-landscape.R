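make_line_trajectory <- function(n = 20, n_atoms = 6, seed = 2) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(n_atoms * 3, sd = 5), n_atoms, 3)
  })
  s <- make_point_structure(base)
  dir <- matrix(0, n_atoms, 3)
  dir[1, 1] <- 1
  dir[2, 1] <- -1
  frames <- array(NA_real_, c(n, n_atoms, 3))
  amp <- seq(-1, 1, length.out = n)
  for (i in seq_len(n)) frames[i, , ] <- base + amp[i] * dir
  new_md_trajectory(s, frames)
}

test_that("PCA conserves variance and finds rank-1 motion", {
  traj <- make_line_trajectory()
  sel <- atom_selection("ca")
  model <- fit_pca(traj, sel, superpose = FALSE)
  expect_false(is.unsorted(rev(model$eigenvalues)))
  expect_true(all(model$eigenvalues >= 0))
  # total-variance conservation
  expect_equal(sum(model$eigenvalues), model$trace, tolerance = 1e-8)
  # one-directional motion: first eigenvalue carries essentially everything
  expect_gt(model$eigenvalues[1] / sum(model$eigenvalues), 0.999)
  # orthonormal modes
  v <- model$eigenvectors[, 1:5]
  expect_equal(crossprod(v), diag(5), tolerance = 1e-8)
  # static trajectory: all eigenvalues zero
  static <- make_static_trajectory(make_point_structure(
    matrix(rnorm(12), 4, 3)), 5)
  m0 <- fit_pca(static, sel, superpose = FALSE)
  expect_equal(m0$eigenvalues, rep(0, length(m0$eigenvalues)),
               tolerance = 1e-10)
})

test_that("isotropic displacements give a flat eigenvalue spectrum", {
  # equal masses, iid Gaussian displacement on every coordinate: all modes
  # carry the same variance up to chi-square sampling spread
  n_atoms <- 4L
  nf <- 3000L
  withr::with_seed(55, {
    base <- matrix(rnorm(n_atoms * 3, sd = 5), n_atoms, 3)
    frames <- array(rnorm(nf * n_atoms * 3, sd = 0.2), c(nf, n_atoms, 3))
  })
  for (i in seq_len(nf)) frames[i, , ] <- frames[i, , ] + base
  traj <- new_md_trajectory(make_point_structure(base), frames)
  model <- fit_pca(traj, atom_selection("ca"), superpose = FALSE)
  lam <- model$eigenvalues / 12.011  # unit-mass scale
  # sd of a sample-covariance eigenvalue ~ lambda * sqrt(2/nf); allow the
  # extra spread from ordering 12 eigenvalues
  expect_lt(max(lam) / min(lam), 1 + 12 * sqrt(2 / nf))
  expect_equal(mean(lam), 0.04, tolerance = 0.05)
})

test_that("projection reproduces the PCA identities", {
  traj <- make_line_trajectory(n = 25)
  sel <- atom_selection("ca")
  model <- fit_pca(traj, sel, superpose = FALSE)
  proj <- project_trajectory(traj, model, n_components = 3)
  # per-component sample variance equals the eigenvalue
  expect_equal(var(proj$PC1), model$eigenvalues[1], tolerance = 1e-6)
  expect_equal(var(proj$PC2), model$eigenvalues[2], tolerance = 1e-6)
  # projecting the mean structure gives the origin
  mu_coords <- apply(traj$frames, c(2, 3), mean)
  mean_traj <- make_static_trajectory(
    make_point_structure(mu_coords), 1)
  p0 <- project_trajectory(mean_traj, model, n_components = 2)
  expect_equal(unlist(p0[, c("PC1", "PC2")]), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-8)
  # projection is per-frame: splitting the trajectory changes nothing
  half1 <- new_md_trajectory(traj$topology,
                             traj$frames[1:10, , , drop = FALSE],
                             traj$times_ns[1:10])
  p_half <- project_trajectory(half1, model, n_components = 2)
  expect_equal(p_half$PC1, proj$PC1[1:10])
  expect_error(project_trajectory(traj, model, n_components = 1e6),
               "exceeds")
})

test_that("k-means recovers well-separated blobs and obeys tie rules", {
  withr::with_seed(31, {
    blob1 <- cbind(rnorm(40, 0, 0.1), rnorm(40, 0, 0.1))
    blob2 <- cbind(rnorm(40, 10, 0.1), rnorm(40, 10, 0.1))
  })
  proj <- tibble::tibble(frame = 1:80, time_ns = 0:79,
                         PC1 = c(blob1[, 1], blob2[, 1]),
                         PC2 = c(blob1[, 2], blob2[, 2]))
  res <- kmeans_cluster(proj, k = 2, seed = 3)
  truth <- rep(1:2, each = 40)
  agree <- max(mean(res$assignments$cluster == truth),
               mean(res$assignments$cluster == 3 - truth))
  expect_equal(agree, 1)
  # centroid frames are members of their own cluster
  for (cl in 1:2) {
    expect_equal(res$assignments$cluster[res$centroid_frames[cl]], cl)
  }
  # fixed seed reproduces labels
  res2 <- kmeans_cluster(proj, k = 2, seed = 3)
  expect_identical(res$assignments$cluster, res2$assignments$cluster)
  # k = 1: center is the projection mean
  res1 <- kmeans_cluster(proj, k = 1, seed = 3)
  expect_equal(as.numeric(res1$centers),
               c(mean(proj$PC1), mean(proj$PC2)), tolerance = 1e-8)
  # duplicate frames: centroid frame tie-break takes the lowest index
  dup <- tibble::tibble(frame = 1:6, time_ns = 0:5,
                        PC1 = c(0, 0, 0, 5, 5, 5),
                        PC2 = c(0, 0, 0, 5, 5, 5))
  resd <- kmeans_cluster(dup, k = 2, seed = 1)
  expect_true(all(resd$centroid_frames %in% c(1, 4)))
  expect_error(kmeans_cluster(dup, k = 7, seed = 1), "k")
  # auto k picks the obvious 2-blob structure by silhouette
  auto <- kmeans_cluster(proj, k = "auto", seed = 3)
  expect_equal(auto$k, 2L)
})

test_that("two-state trajectory separates into schedule clusters", {
  rec <- make_toy_receptor(seed = 1)
  pair <- make_reference_pair(rec, tm6_shift = 8)
  traj <- generate_two_state_trajectory(pair$closed, pair$open, 200, 50,
                                        noise_sd = 0.1, seed = 8)
  sel <- atom_selection("ca", exclude_residues = loop_residues())
  aligned <- superpose_trajectory(traj, sel)
  model <- fit_pca(aligned, sel, superpose = FALSE)
  proj <- project_trajectory(aligned, model)
  res <- kmeans_cluster(proj, k = 2, seed = 1)
  lambda <- pmax(0, 1 - (0:199) / 50)
  truth <- ifelse(lambda >= 0.5, 1L, 2L)
  got <- res$assignments$cluster
  agree <- max(mean(got == truth), mean(got == 3L - truth))
  expect_gte(agree, 0.95)
})

test_that("reference comparison labels centroids by nearest state", {
  rec <- make_toy_receptor(seed = 1)
  pair <- make_reference_pair(rec, tm6_shift = 8)
  sel <- atom_selection("ca")
  refs <- list(closed = pair$closed, open = pair$open)
  cmp <- compare_to_references(pair$open, refs, sel)
  expect_equal(cmp$rmsd[cmp$reference == "open"], 0, tolerance = 1e-8)
  expect_equal(cmp$reference[cmp$nearest], "open")
  expect_error(compare_to_references(pair$open, list(), sel), "empty")
  expect_error(compare_to_references(pair$open, list(pair$closed), sel),
               "named")
})

test_that("TM6 outward shift readout recovers the constructed geometry", {
  rec <- make_toy_receptor(seed = 1)
  pair <- make_reference_pair(rec, tm6_shift = 8)
  expect_equal(tm6_outward_shift(pair$closed, pair$closed), 0,
               tolerance = 1e-8)
  expect_equal(tm6_outward_shift(pair$open, pair$closed), 8,
               tolerance = 1e-6)
  # half-mixture frame reads ~4 A
  traj <- generate_two_state_trajectory(pair$closed, pair$open, 3, 2,
                                        noise_sd = 0, seed = 1)
  half <- trajectory_frame(traj, 2)  # lambda = 0.5
  expect_equal(tm6_outward_shift(half, pair$closed), 4, tolerance = 1e-6)
  expect_error(tm6_outward_shift(pair$open, pair$closed,
                                 tm6_block = integer()), "empty")
})
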