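test_that("histograms conserve counts and diagnose overlap", {
  w1 <- list(center = 0.5, force_const = 1000, samples = rep(0.5, 20),
             temperature = 310)
  w2 <- list(center = 2.5, force_const = 1000, samples = rep(2.5, 10),
             temperature = 310)
  ds <- new_umbrella_dataset(list(w1, w2))
  expect_warning(h <- build_histograms(ds, n_bins = 30, range = c(0, 3)),
                 "zero histogram overlap")
  expect_equal(sum(h$counts), 30)  # total counts conserved
  expect_equal(max(h$counts[1, ]), 20)  # all samples of w1 in one bin
  expect_true(any(h$overlap$shared_bins == 0))
  expect_error(build_histograms(ds, n_bins = 0), "n_bins")
})

test_that("a single unbiased window reduces WHAM to a histogram estimate", {
  withr::with_seed(21, {
    x <- stats::rnorm(4000, mean = 1, sd = 0.3)
  })
  ds <- new_umbrella_dataset(list(list(center = 1, force_const = 0,
                                       samples = x, temperature = 310)))
  prof <- wham_solve(ds, n_bins = 40)
  occ <- !is.na(prof$free_energy)
  h <- build_histograms(ds, n_bins = 40)
  rt <- rt_kcal(310)
  expected <- -rt * log(h$counts[1, occ])
  diff <- prof$free_energy[occ] - expected
  expect_lt(max(abs(diff - mean(diff))), 1e-8)  # equal up to a constant
})

test_that("WHAM window free energies agree with the MBAR-style oracle", {
  pot <- potential_spec("harmonic", domain = c(-1, 1), k = 4, x0 = 0)
  ds <- generate_umbrella_dataset(pot, n_windows = 5, spacing = 0.35,
                                  force_const = 500, n_samples = 800,
                                  temperature = 310, seed = 13)
  f_oracle <- mbar_window_free_energies(ds)
  prof <- wham_solve(ds, n_bins = 400)
  f_wham <- attr(prof, "window_free_energies")
  f_wham <- f_wham - f_wham[1]
  expect_lt(max(abs(f_wham - f_oracle)), 0.05)
})

test_that("WHAM recovers a harmonic potential from umbrella windows", {
  pot <- potential_spec("harmonic", domain = c(-1.2, 1.2), k = 2, x0 = 0)
  ds <- generate_umbrella_dataset(pot, n_windows = 12, spacing = 0.2,
                                  force_const = 1000, n_samples = 3000,
                                  temperature = 310, seed = 17)
  prof <- wham_solve(ds)
  occ <- !is.na(prof$free_energy)
  truth <- potential_energy(pot, prof$bin_center[occ])
  est <- prof$free_energy[occ]
  est <- est - mean(est) + mean(truth)
  expect_lt(sqrt(mean((est - truth)^2)), 0.1)
})

test_that("WHAM is gauge invariant under constant potential shifts", {
  pot <- small_double_well()
  shifted <- potential_spec("piecewise_table", domain = pot$domain,
                            table = data.frame(
                              x = seq(0, 2, length.out = 400),
                              y = potential_energy(
                                pot, seq(0, 2, length.out = 400)) + 7))
  args <- list(n_windows = 10, spacing = 0.18, force_const = 1000,
               n_samples = 1200, temperature = 310, seed = 23)
  ds1 <- do.call(generate_umbrella_dataset, c(list(pot), args))
  ds2 <- do.call(generate_umbrella_dataset, c(list(shifted), args))
  p1 <- zero_to_bulk(wham_solve(ds1, n_bins = 120), c(0.3, 0.7))
  p2 <- zero_to_bulk(wham_solve(ds2, n_bins = 120), c(0.3, 0.7))
  occ <- !is.na(p1$free_energy) & !is.na(p2$free_energy)
  expect_equal(p1$free_energy[occ], p2$free_energy[occ], tolerance = 0.05)
})

test_that("non-convergence raises an error carrying the residual", {
  pot <- small_double_well()
  ds <- generate_umbrella_dataset(pot, n_windows = 8, spacing = 0.2,
                                  force_const = 1000, n_samples = 500,
                                  seed = 2)
  expect_error(wham_solve(ds, max_iter = 3), "convergence-failure")
})

test_that("bulk zeroing is idempotent and shift invariant", {
  grid <- seq(0, 4, length.out = 50)
  prof <- new_pmf_profile(grid, sin(grid) + 2, rep(0.1, 50))
  z1 <- zero_to_bulk(prof, c(3.5, 4))
  z2 <- zero_to_bulk(z1, c(3.5, 4))
  expect_equal(z1$free_energy, z2$free_energy, tolerance = 1e-12)
  # constant profile zeroes to all-zero
  flat <- new_pmf_profile(grid, rep(3, 50))
  expect_equal(zero_to_bulk(flat, c(0, 4))$free_energy, rep(0, 50))
  # gauge invariance: +c then zeroing gives the identical output
  shifted <- new_pmf_profile(grid, sin(grid) + 9, rep(0.1, 50))
  z3 <- zero_to_bulk(shifted, c(3.5, 4))
  expect_equal(z1$free_energy, z3$free_energy, tolerance = 1e-12)
  expect_error(zero_to_bulk(prof, c(10, 11)), "no occupied bin")
})

test_that("binding free energy reads the site minimum of a zeroed profile", {
  grid <- seq(0, 4, by = 0.025)  # includes the well center 0.8 exactly
  fe <- -12.19 * exp(-(grid - 0.8)^2 / 0.02)  # well of depth -12.19, bulk 0
  prof <- new_pmf_profile(grid, fe, rep(0.3, length(grid)))
  bfe <- binding_free_energy(prof, c(0, 2), site_label = "OBP",
                             state_label = "open")
  expect_equal(bfe$dg, min(fe), tolerance = 1e-12)
  expect_equal(bfe$sd, 0.3)
  # flat zero profile: dg = 0
  flat <- new_pmf_profile(grid, rep(0, length(grid)))
  expect_equal(binding_free_energy(flat, c(0, 2))$dg, 0)
  # deepening the well by delta lowers dg by exactly delta
  prof2 <- new_pmf_profile(grid, fe - 2 * exp(-(grid - 0.8)^2 / 0.02))
  expect_equal(binding_free_energy(prof2, c(0, 2))$dg, bfe$dg - 2,
               tolerance = 1e-9)
  expect_error(binding_free_energy(prof, c(10, 11)), "no occupied bin")
})

test_that("subpocket differences and occupancy ratios follow the Boltzmann law", {
  mk <- function(dg, sd, site, state) {
    structure(list(dg = dg, sd = sd, site_label = site, state_label = state,
                   at = NA_real_), class = "binding_free_energy")
  }
  # printed-table arithmetic
  expect_equal(ddg(mk(-7.05, 0.64, "EBP", "open"),
                   mk(-12.19, 0.74, "OBP", "open"))$ddg, 5.14)
  expect_equal(ddg(mk(-6.46, 0.38, "EBP", "closed"),
                   mk(-13.12, 0.95, "OBP", "closed"))$ddg, 6.66)
  expect_equal(ddg(mk(-5, 0.1, "EBP", "open"),
                   mk(-5, 0.2, "OBP", "open"))$ddg, 0)
  # error modes
  d <- ddg(mk(-7.05, 0.64, "EBP", "open"), mk(-12.19, 0.74, "OBP", "open"))
  expect_equal(d$sd, sqrt(0.64^2 + 0.74^2))
  dl <- ddg(mk(-7.05, 0.64, "EBP", "open"), mk(-12.19, 0.74, "OBP", "open"),
            error_mode = "linear_sum")
  expect_equal(dl$sd, 0.64 + 0.74)
  expect_error(ddg(mk(-7, 0.1, "EBP", "open"), mk(-12, 0.1, "OBP", "closed")),
               "states")
  # occupancy ratio
  expect_equal(occupancy_ratio(0, 310)$ratio, 1)
  expect_equal(occupancy_ratio(0, 310)$orders_of_magnitude, 0L)
  expect_equal(occupancy_ratio(5.14, 310)$orders_of_magnitude, 3L)
  expect_equal(occupancy_ratio(6.63, 310)$orders_of_magnitude, 4L)
  expect_error(occupancy_ratio(1, -5), "temperature")
  # strictly increasing, log-linear with slope 1/(RT ln 10)
  dd <- seq(0, 8, by = 0.5)
  lr <- vapply(dd, function(g) log10(occupancy_ratio(g, 310)$ratio),
               numeric(1))
  expect_true(all(diff(lr) > 0))
  slope <- diff(lr) / diff(dd)
  expect_equal(slope, rep(1 / (rt_kcal(310) * log(10)), length(slope)),
               tolerance = 1e-10)
})

test_that("Bayesian bootstrap quantifies sampling uncertainty", {
  pot <- small_double_well()
  ds <- generate_umbrella_dataset(pot, n_windows = 10, spacing = 0.18,
                                  force_const = 1000, n_samples = 600,
                                  seed = 19)
  # single replicate: stderr identically zero
  p1 <- bayesian_bootstrap(ds, n_boot = 1, seed = 4, n_bins = 100)
  expect_equal(p1$stderr, rep(0, 100))
  # stderr strictly positive on interior occupied bins
  p20 <- bayesian_bootstrap(ds, n_boot = 20, seed = 4, n_bins = 100)
  occ <- which(!is.na(p20$free_energy))
  interior <- occ[occ > min(occ) + 2 & occ < max(occ) - 2]
  expect_true(all(p20$stderr[interior] > 0))
  # determinism
  p20b <- bayesian_bootstrap(ds, n_boot = 20, seed = 4, n_bins = 100)
  expect_identical(p20$stderr, p20b$stderr)
  # more sampling shrinks the uncertainty
  ds_big <- generate_umbrella_dataset(pot, n_windows = 10, spacing = 0.18,
                                      force_const = 1000, n_samples = 4800,
                                      seed = 19)
  pbig <- bayesian_bootstrap(ds_big, n_boot = 20, seed = 4, n_bins = 100)
  occ2 <- !is.na(pbig$free_energy) & !is.na(p20$free_energy)
  expect_lt(median(pbig$stderr[occ2]), median(p20$stderr[occ2]))
})
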