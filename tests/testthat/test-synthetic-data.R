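test_that("toy receptor covers residues 70-399 with the expected labels", {
  rec <- make_toy_receptor(seed = 1)
  ids <- rec$structure$atoms$residue_id
  expect_identical(ids, 70:399)
  expect_length(ids, 330L)
  expect_false(is.unsorted(ids, strictly = TRUE))
  expect_identical(rec$bw_map[["3.50"]], 173L)
  expect_identical(rec$bw_map[["6.30"]], 318L)
  # all index/distance labels resolve
  needed <- c("1.53", "2.50", "4.42", "3.42", "4.42b", "5.66", "6.34",
              "6.58", "7.35", "7.55", "3.50", "6.30")
  expect_true(all(needed %in% names(rec$bw_map)))
  # no two residues coincide
  d <- as.matrix(dist(rec$structure$coords))
  diag(d) <- Inf
  expect_gt(min(d), 0.05)
})

test_that("toy receptor generation is deterministic in the seed", {
  expect_identical(make_toy_receptor(seed = 3)$structure$coords,
                   make_toy_receptor(seed = 3)$structure$coords)
  expect_false(identical(make_toy_receptor(seed = 3)$structure$coords,
                         make_toy_receptor(seed = 4)$structure$coords))
})

test_that("reference pair displaces only TM6 by the requested magnitude", {
  rec <- make_toy_receptor(seed = 1)
  for (shift in c(8, 4)) {
    pair <- make_reference_pair(rec, tm6_shift = shift)
    ids <- rec$structure$atoms$residue_id
    in_block <- ids %in% pair$tm6_block
    delta <- pair$open$coords - pair$closed$coords
    expect_equal(max(abs(delta[!in_block, ])), 0)
    expect_equal(sqrt(rowSums(delta[in_block, ]^2)),
                 rep(shift, sum(in_block)))
    # the ionic-lock distance difference equals the shift exactly
    d <- function(s, a, b) sqrt(sum((s$coords[match(a, ids), ] -
                                       s$coords[match(b, ids), ])^2))
    expect_equal(d(pair$open, 173, 318) - d(pair$closed, 173, 318), shift)
    expect_gt(d(pair$open, 173, 318), d(pair$closed, 173, 318))
  }
  expect_error(make_reference_pair(rec, tm6_shift = 0), "positive")
  expect_error(make_reference_pair(rec, tm6_shift = -1), "positive")
})

test_that("two-state trajectory interpolates open to closed on schedule", {
  rec <- make_toy_receptor(seed = 1)
  pair <- make_reference_pair(rec, tm6_shift = 8)
  # degenerate schedule: collapse at frame 0 means always closed
  tr0 <- generate_two_state_trajectory(pair$closed, pair$open, 10, 0,
                                       noise_sd = 0, seed = 1)
  for (i in 1:10) expect_equal(tr0$frames[i, , ], pair$closed$coords)
  # lambda(0) = 1: first frame is the open reference
  tr <- generate_two_state_trajectory(pair$closed, pair$open, 40, 20,
                                      noise_sd = 0, seed = 1)
  expect_equal(tr$frames[1, , ], pair$open$coords)
  expect_equal(tr$frames[40, , ], pair$closed$coords)
  # exact frame-wise interpolation (lambda-convexity) without noise
  lambda <- pmax(0, 1 - (0:39) / 20)
  for (i in c(5, 15, 21, 35)) {
    expect_equal(tr$frames[i, , ],
                 lambda[i] * pair$open$coords +
                   (1 - lambda[i]) * pair$closed$coords)
  }
  # ionic-lock distance decays monotonically to the closed level
  d <- ca_distance_series(tr, 173, 318)$distance
  expect_true(all(diff(d[1:21]) <= 1e-9))
  expect_equal(d[21], d[40])
  # determinism with noise
  trA <- generate_two_state_trajectory(pair$closed, pair$open, 8, 4,
                                       noise_sd = 0.3, seed = 9)
  trB <- generate_two_state_trajectory(pair$closed, pair$open, 8, 4,
                                       noise_sd = 0.3, seed = 9)
  expect_identical(trA$frames, trB$frames)
  # incongruent structures are rejected
  small <- make_point_structure(matrix(rnorm(9), 3, 3))
  expect_error(generate_two_state_trajectory(pair$closed, small, 5, 2),
               "congruent|mismatch")
})

test_that("umbrella samples match the harmonic-bias closed form", {
  # flat potential: biased density is exactly Gaussian, var = RT/k
  flat <- potential_spec("harmonic", domain = c(-2, 2), k = 0, x0 = 0)
  ds <- generate_umbrella_dataset(flat, n_windows = 2, spacing = 1.2,
                                  force_const = 1000, n_samples = 4000,
                                  temperature = 310, seed = 11)
  rt <- rt_kcal(310)
  k_kcal <- 1000 / 4.184
  for (w in ds$windows) {
    expect_lt(abs(mean(w$samples) - w$center), 5 * sqrt(rt / k_kcal / 4000))
    v <- var(w$samples)
    se_var <- v * sqrt(2 / (4000 - 1))
    expect_lt(abs(v - rt / k_kcal), 5 * se_var * 3)  # thinning margin
  }
})

test_that("adjacent umbrella windows overlap and sampling is deterministic", {
  pot <- small_double_well()
  ds <- generate_umbrella_dataset(pot, n_windows = 12, spacing = 0.15,
                                  force_const = 1000, n_samples = 1500,
                                  seed = 5)
  h <- build_histograms(ds, n_bins = 100)
  expect_true(all(h$overlap$shared_bins > 0))
  ds2 <- generate_umbrella_dataset(pot, n_windows = 12, spacing = 0.15,
                                   force_const = 1000, n_samples = 1500,
                                   seed = 5)
  expect_identical(lapply(ds$windows, `[[`, "samples"),
                   lapply(ds2$windows, `[[`, "samples"))
  expect_error(generate_umbrella_dataset(pot, n_windows = 50, spacing = 0.15,
                                         force_const = 1000, n_samples = 10),
               "domain too small")
  expect_error(generate_umbrella_dataset(pot, n_windows = 5, spacing = 0.1,
                                         force_const = 0, n_samples = 10),
               "force_const")
})

test_that("analytic PMF evaluates potentials with the stated shapes", {
  har <- potential_spec("harmonic", domain = c(-2, 2), k = 2, x0 = 0)
  prof <- analytic_pmf(har, c(0, 1))
  expect_equal(prof$free_energy, c(0, 1))  # 0.5 * 2 * 1^2
  flat <- potential_spec("harmonic", domain = c(0, 1), k = 0, x0 = 0)
  expect_equal(analytic_pmf(flat, seq(0, 1, 0.1))$free_energy,
               rep(0, 11))
  dw <- potential_spec("double_well", domain = c(0, 4), barrier = 3,
                       minima = c(1, 3))
  g <- seq(1, 3, length.out = 201)
  u <- analytic_pmf(dw, g)$free_energy
  expect_equal(max(u) - min(u), 3)
  expect_equal(potential_energy(dw, c(1, 2, 3)), c(0, 3, 0))
  # piecewise table interpolates linearly
  pt <- potential_spec("piecewise_table", domain = c(0, 1),
                       table = data.frame(x = c(0, 1), y = c(0, 2)))
  expect_equal(potential_energy(pt, 0.25), 0.5)
  expect_equal(analytic_pmf(dw, g)$stderr, rep(0, length(g)))
})
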