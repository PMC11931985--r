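#' PMF profile container
#'
#' A tibble subclass with columns `bin_center` (nm), `free_energy`
#' (kcal/mol; `NA` on unoccupied bins) and `stderr` (kcal/mol), carrying
#' attributes `zero_region` (nm interval, or `NULL` before zeroing),
#' `window_free_energies` (converged per-window free energies, kcal/mol)
#' and `convergence` (iterations, final residual).
#'
#' @param bin_center,free_energy,stderr Equal-length numeric vectors.
#' @param zero_region Optional length-2 interval (nm).
#' @param window_free_energies Optional numeric vector.
#' @param convergence Optional list.
#' @return A `pmf_profile` tibble.
#' @export
new_pmf_profile <- function(bin_center, free_energy, stderr = NULL,
                            zero_region = NULL,
                            window_free_energies = NULL,
                            convergence = NULL) {
  if (is.null(stderr)) stderr <- rep(0, length(bin_center))
  out <- tibble::tibble(bin_center = bin_center, free_energy = free_energy,
                        stderr = stderr)
  class(out) <- c("pmf_profile", class(out))
  attr(out, "zero_region") <- zero_region
  attr(out, "window_free_energies") <- window_free_energies
  attr(out, "convergence") <- convergence
  out
}

#' Histogram an umbrella dataset on a shared binning
#'
#' All windows are binned on one fixed uniform grid; an adjacent-pair
#' overlap diagnostic (number of bins occupied by both windows of each
#' pair, windows ordered by center) flags gaps in sampling that would
#' disconnect the WHAM solution.
#'
#' @param dataset An `umbrella_dataset`.
#' @param n_bins Number of uniform bins (default 200).
#' @param range Length-2 interval (nm); default spans all samples.
#' @param clip Drop samples outside `range` (default `FALSE`: error).
#' @return A list with `bin_centers`, `breaks`, `counts` (windows x bins
#'   matrix, rows ordered by window center), `window_order`, and `overlap`
#'   (tibble: `pair`, `shared_bins`) with a warning when any adjacent pair
#'   shares no occupied bin.
#' @export
build_histograms <- function(dataset, n_bins = 200L, range = NULL,
                             clip = FALSE) {
  stopifnot(inherits(dataset, "umbrella_dataset"), n_bins >= 1L)
  all_x <- unlist(lapply(dataset$windows, `[[`, "samples"))
  if (is.null(range)) {
    range <- base::range(all_x)
    range <- range + c(-1, 1) * 1e-9 * max(1, diff(range))
  }
  stopifnot(length(range) == 2L, range[1] < range[2])
  if (!clip && (any(all_x < range[1]) || any(all_x > range[2]))) {
    stop("samples outside range; pass clip = TRUE to drop them",
         call. = FALSE)
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ord <- order(vapply(dataset$windows, `[[`, numeric(1), "center"))
  counts <- t(vapply(dataset$windows[ord], function(w) {
    x <- w$samples
    x <- x[x >= range[1] & x <= range[2]]
    as.numeric(table(cut(x, breaks = breaks, include.lowest = TRUE,
                         labels = FALSE)) [as.character(seq_len(n_bins))])
  }, numeric(n_bins)))
  counts[is.na(counts)] <- 0
  overlap <- if (nrow(counts) > 1L) {
    shared <- vapply(seq_len(nrow(counts) - 1L), function(i) {
      sum(counts[i, ] > 0 & counts[i + 1L, ] > 0)
    }, numeric(1))
    tibble::tibble(pair = paste(ord[-length(ord)], ord[-1], sep = "-"),
                   shared_bins = shared)
  } else {
    tibble::tibble(pair = character(), shared_bins = numeric())
  }
  if (nrow(overlap) && any(overlap$shared_bins == 0)) {
    warning("adjacent windows with zero histogram overlap: ",
            paste(overlap$pair[overlap$shared_bins == 0], collapse = ", "),
            call. = FALSE)
  }
  list(bin_centers = centers, breaks = breaks, counts = counts,
       window_order = ord, overlap = overlap)
}

# core self-consistent iteration on prebuilt histograms.
# counts: W x B; centers/k_kcal: per window (ordered as counts rows);
# weights: per-window Dirichlet-style multipliers (bootstrap), default 1.
wham_iterate <- function(counts, centers, k_kcal, bin_centers, rt,
                         tol = 1e-7, max_iter = 100000L, f_init = NULL,
                         weights = NULL, min_count = 10) {
  nw <- nrow(counts)
  nb <- ncol(counts)
  if (is.null(weights)) weights <- rep(1, nw)
  n_i <- rowSums(counts) * weights
  c_b <- colSums(counts * weights)
  occupied <- c_b > 0
  if (!any(occupied)) stop("no occupied bins", call. = FALSE)
  # bias energies in units of RT; exp(-w/RT) precomputed once
  wrt <- outer(k_kcal, rep(1, nb)) *
    0.5 * sweep(matrix(rep(bin_centers, each = nw), nw, nb), 1, centers)^2 / rt
  ew <- exp(-wrt)
  g <- if (is.null(f_init)) rep(0, nw) else f_init / rt
  iter <- 0L
  repeat {
    iter <- iter + 1L
    a <- n_i * exp(g)
    denom <- as.vector(crossprod(ew, a))       # per-bin normalizer
    p <- ifelse(occupied & denom > 0, c_b / denom, 0)
    z <- as.vector(ew %*% p)
    g_new <- -log(z)
    g_new <- g_new - g_new[1]
    resid <- max(abs(g_new - g))
    g <- g_new
    if (resid < tol || iter >= max_iter) break
  }
  if (resid >= tol) {
    stop("convergence-failure: WHAM residual ", format(resid),
         " after ", iter, " iterations", call. = FALSE)
  }
  p <- p / sum(p)                              # fixed normalization (gauge)
  # every occupied bin enters the iteration; undersampled bins (raw counts
  # below min_count) are masked only in the reported profile, since
  # -RT log(n) carries shot noise of about RT/sqrt(n)
  reported <- occupied & colSums(counts) >= min_count
  if (!any(reported)) reported <- occupied
  f_bin <- ifelse(reported, -rt * log(p), NA_real_)
  list(free_energy = f_bin, window_f = g * rt, p = p,
       iterations = iter, residual = resid, occupied = reported)
}

#' Solve the WHAM equations for an umbrella dataset
#'
#' Self-consistent iteration of the weighted-histogram equations for
#' harmonically biased windows: the unnormalized bin probability is
#' `P(b) = sum_i n_i(b) / sum_i N_i exp((F_i - w_i(b))/RT)` and the window
#' free energies satisfy `F_i = -RT log sum_b P(b) exp(-w_i(b)/RT)`,
#' iterated until the largest window free-energy change drops below
#' `tol * RT`. The PMF is `-RT log P(b)` on occupied bins (unoccupied
#' bins are `NA`); the profile is unzeroed — apply [zero_to_bulk()] to fix
#' the gauge. Force constants arrive in kJ mol^-1 nm^-2 and are converted
#' internally (exact factor 4.184); energies are reported in kcal/mol.
#' `k = 0` windows (unbiased sampling) are allowed.
#'
#' Bins holding fewer than `min_count` samples in total are reported as
#' unsampled (`NA`): the free energy of a bin with `n` counts carries shot
#' noise of about `RT / sqrt(n)`, so a handful of stray counts at the edge
#' of the sampled range would otherwise dominate the profile error.
#'
#' @param dataset An `umbrella_dataset`.
#' @param n_bins,range,clip Passed to [build_histograms()].
#' @param temperature Temperature in K (default: the dataset's).
#' @param tol Convergence tolerance, in units of RT (default 1e-7).
#' @param max_iter Iteration cap (default 100000).
#' @param min_count Minimum total raw counts for a bin to be reported
#'   (default 10, i.e. shot noise up to ~0.32 RT); use 1 to report every
#'   occupied bin.
#' @return An unzeroed [new_pmf_profile()] with `stderr = 0`, carrying the
#'   converged per-window free energies and convergence info as
#'   attributes.
#' @export
wham_solve <- function(dataset, n_bins = 200L, range = NULL, clip = FALSE,
                       temperature = NULL, tol = 1e-7, max_iter = 100000L,
                       min_count = 10) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (is.null(temperature)) temperature <- dataset$temperature
  rt <- rt_kcal(temperature)
  h <- build_histograms(dataset, n_bins = n_bins, range = range, clip = clip)
  ord <- h$window_order
  centers <- vapply(dataset$windows[ord], `[[`, numeric(1), "center")
  k_kcal <- kj_to_kcal(vapply(dataset$windows[ord], `[[`, numeric(1),
                              "force_const"))
  sol <- wham_iterate(h$counts, centers, k_kcal, h$bin_centers, rt,
                      tol = tol, max_iter = max_iter, min_count = min_count)
  new_pmf_profile(h$bin_centers, sol$free_energy,
                  stderr = rep(0, length(h$bin_centers)),
                  window_free_energies = sol$window_f,
                  convergence = list(iterations = sol$iterations,
                                     residual = sol$residual,
                                     tol = tol, temperature = temperature))
}

#' Bayesian-bootstrap uncertainty for a WHAM profile
#'
#' Re-solves WHAM `n_boot` times with whole-window weights drawn from a
#' flat Dirichlet (each window's effective sample count scaled by its
#' weight), the "complete histogram" Bayesian bootstrap. Replicates are
#' warm-started from the base solution and brought to a common gauge
#' (zeroed over `bulk_region` when given, else over the jointly occupied
#' bins) before per-bin standard deviations are taken. The returned
#' profile is the base WHAM solution with the bootstrap `stderr` attached
#' (zeroed to `bulk_region` when given).
#'
#' @param dataset An `umbrella_dataset`.
#' @param n_boot Number of bootstrap replicates (convention: 250).
#' @param seed Integer seed.
#' @param bulk_region Optional length-2 interval (nm) fixing the gauge.
#' @param n_bins,range,clip,temperature,tol,max_iter,min_count As in
#'   [wham_solve()]; the undersampled-bin mask is taken from the raw
#'   (unweighted) counts so that every replicate shares one mask.
#' @return A [new_pmf_profile()] with bootstrap `stderr` (all zero when
#'   `n_boot = 1`).
#' @export
bayesian_bootstrap <- function(dataset, n_boot = 250L, seed = 1L,
                               bulk_region = NULL, n_bins = 200L,
                               range = NULL, clip = FALSE,
                               temperature = NULL, tol = 1e-7,
                               max_iter = 100000L, min_count = 10) {
  stopifnot(inherits(dataset, "umbrella_dataset"), n_boot >= 1L)
  if (is.null(temperature)) temperature <- dataset$temperature
  rt <- rt_kcal(temperature)
  h <- build_histograms(dataset, n_bins = n_bins, range = range, clip = clip)
  ord <- h$window_order
  centers <- vapply(dataset$windows[ord], `[[`, numeric(1), "center")
  k_kcal <- kj_to_kcal(vapply(dataset$windows[ord], `[[`, numeric(1),
                              "force_const"))
  base <- wham_iterate(h$counts, centers, k_kcal, h$bin_centers, rt,
                       tol = tol, max_iter = max_iter,
                       min_count = min_count)
  nw <- nrow(h$counts)
  fix_gauge <- function(fe) {
    if (!is.null(bulk_region)) {
      inb <- h$bin_centers >= bulk_region[1] &
        h$bin_centers <= bulk_region[2] & !is.na(fe)
      if (!any(inb)) stop("no occupied bin in bulk_region", call. = FALSE)
      fe - mean(fe[inb])
    } else {
      fe - mean(fe[base$occupied & !is.na(fe)])
    }
  }
  reps <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_boot), function(r) {
      wts <- stats::rexp(nw)
      wts <- wts / sum(wts) * nw
      sol <- tryCatch(
        wham_iterate(h$counts, centers, k_kcal, h$bin_centers, rt,
                     tol = tol, max_iter = max_iter,
                     f_init = base$window_f, weights = wts,
                     min_count = min_count),
        error = function(e) {
          stop("convergence-failure in bootstrap replicate ", r, ": ",
               conditionMessage(e), call. = FALSE)
        })
      fix_gauge(sol$free_energy)
    })
  })
  mat <- do.call(rbind, reps)
  stderr <- if (n_boot == 1L) rep(0, ncol(mat)) else {
    apply(mat, 2, function(v) {
      if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
    })
  }
  fe <- base$free_energy
  zr <- NULL
  if (!is.null(bulk_region)) {
    fe <- fix_gauge(fe)
    zr <- bulk_region
  }
  new_pmf_profile(h$bin_centers, fe, stderr = stderr, zero_region = zr,
                  window_free_energies = base$window_f,
                  convergence = list(iterations = base$iterations,
                                     residual = base$residual,
                                     tol = tol, temperature = temperature,
                                     n_boot = n_boot))
}

#' Barrier height of a PMF profile
#'
#' Height of the transition barrier inside `between` relative to the
#' profile minimum. Around a stationary point a smooth free-energy profile
#' is locally quadratic, so both extrema are read from local quadratic
#' fits (over bins within `fit_halfwidth` of the raw arg-extremum) rather
#' than single noisy bins, which would bias the barrier upward by the
#' per-bin noise.
#'
#' @param profile A `pmf_profile`.
#' @param between Length-2 interval (nm) bracketing the barrier top.
#' @param fit_halfwidth Half-width (nm) of the local fit neighbourhoods.
#' @return Barrier height in kcal/mol.
#' @export
pmf_barrier <- function(profile, between, fit_halfwidth = 0.3) {
  stopifnot(inherits(profile, "pmf_profile"), length(between) == 2L)
  occ <- !is.na(profile$free_energy)
  x <- profile$bin_center[occ]
  y <- profile$free_energy[occ]
  local_extremum <- function(x0) {
    sel <- abs(x - x0) <= fit_halfwidth
    if (sum(sel) < 5L) return(y[which.min(abs(x - x0))])
    fit <- stats::lm(y[sel] ~ x[sel] + I(x[sel]^2))
    co <- stats::coef(fit)
    vertex <- -co[2] / (2 * co[3])
    if (!is.finite(vertex) || vertex < min(x[sel]) || vertex > max(x[sel])) {
      return(y[which.min(abs(x - x0))])
    }
    unname(co[1] + co[2] * vertex + co[3] * vertex^2)
  }
  inb <- x >= between[1] & x <= between[2]
  if (!any(inb)) stop("no occupied bin in the barrier interval", call. = FALSE)
  top <- local_extremum(x[inb][which.max(y[inb])])
  bottom <- local_extremum(x[which.min(y)])
  top - bottom
}

#' Zero a PMF profile over a bulk region
#'
#' Subtracts the mean free energy over the occupied bins inside
#' `bulk_region` from the whole profile — the convention that the free
#' energy is zero when the ligand is in bulk water. Idempotent, and
#' invariant to any constant shift of the input.
#'
#' @param profile A `pmf_profile`.
#' @param bulk_region Length-2 interval (nm) containing occupied bins.
#' @return The zeroed `pmf_profile` with `zero_region` recorded.
#' @export
zero_to_bulk <- function(profile, bulk_region) {
  stopifnot(inherits(profile, "pmf_profile"), length(bulk_region) == 2L)
  inb <- profile$bin_center >= bulk_region[1] &
    profile$bin_center <= bulk_region[2] & !is.na(profile$free_energy)
  if (!any(inb)) {
    stop("no occupied bin in bulk_region", call. = FALSE)
  }
  shift <- mean(profile$free_energy[inb])
  out <- profile
  out$free_energy <- out$free_energy - shift
  attr(out, "zero_region") <- bulk_region
  out
}

#' Binding free energy from a zeroed PMF
#'
#' With the bulk fixed at zero, the binding free energy is the minimum of
#' the profile inside the binding-site region; its uncertainty is the
#' bootstrap standard error at the minimizing bin.
#'
#' @param profile A zeroed `pmf_profile`.
#' @param site_region Length-2 interval (nm) containing the binding site.
#' @param site_label Optional label, e.g. `"OBP"`, `"EBP"`,
#'   `"transducer_cavity"`.
#' @param state_label Optional label, e.g. `"open"`, `"closed"`.
#' @return A `binding_free_energy`: list with `dg`, `sd` (kcal/mol),
#'   `site_label`, `state_label`, `at` (minimizing bin center, nm).
#' @export
binding_free_energy <- function(profile, site_region, site_label = NA_character_,
                                state_label = NA_character_) {
  stopifnot(inherits(profile, "pmf_profile"), length(site_region) == 2L)
  ins <- profile$bin_center >= site_region[1] &
    profile$bin_center <= site_region[2] & !is.na(profile$free_energy)
  if (!any(ins)) stop("no occupied bin in site_region", call. = FALSE)
  sub <- profile[ins, ]
  i <- which.min(sub$free_energy)
  structure(list(dg = sub$free_energy[i],
                 sd = max(0, sub$stderr[i], na.rm = TRUE),
                 site_label = site_label, state_label = state_label,
                 at = sub$bin_center[i]),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("dG(%s, %s) = %.2f +/- %.2f kcal/mol at xi = %.3f nm\n",
              x$site_label, x$state_label, x$dg, x$sd, x$at))
  invisible(x)
}

#' Subpocket free-energy difference
#'
#' `ddG = dG_EBP - dG_OBP` for one receptor state; a positive value means
#' the orthosteric pocket is favored. The uncertainty combines the two
#' site uncertainties either in quadrature (default) or as a linear sum.
#'
#' @param site_ebp,site_obp [binding_free_energy()] objects for the same
#'   receptor state.
#' @param error_mode `"quadrature"` or `"linear_sum"`.
#' @return A list with `ddg`, `sd` (kcal/mol), `state_label`.
#' @examples
#' a <- structure(list(dg = -7.05, sd = 0.64, state_label = "open",
#'                     site_label = "EBP"), class = "binding_free_energy")
#' b <- structure(list(dg = -12.19, sd = 0.74, state_label = "open",
#'                     site_label = "OBP"), class = "binding_free_energy")
#' ddg(a, b)$ddg  # 5.14
#' @export
ddg <- function(site_ebp, site_obp,
                error_mode = c("quadrature", "linear_sum")) {
  error_mode <- match.arg(error_mode)
  stopifnot(inherits(site_ebp, "binding_free_energy"),
            inherits(site_obp, "binding_free_energy"))
  if (!is.na(site_ebp$state_label) && !is.na(site_obp$state_label) &&
      site_ebp$state_label != site_obp$state_label) {
    stop("cannot difference free energies of different receptor states",
         call. = FALSE)
  }
  sd_out <- switch(error_mode,
    quadrature = sqrt(site_ebp$sd^2 + site_obp$sd^2),
    linear_sum = site_ebp$sd + site_obp$sd)
  list(ddg = site_ebp$dg - site_obp$dg, sd = sd_out,
       state_label = site_ebp$state_label)
}

#' Boltzmann occupancy ratio of the two subpockets
#'
#' `p_OBP / p_EBP = exp(ddG / (R T))` with `R = 0.0019872` kcal mol^-1
#' K^-1: the relative probability of finding the ligand in the orthosteric
#' versus the extended pocket given their binding free-energy difference.
#'
#' @param ddg Free-energy difference `dG_EBP - dG_OBP` in kcal/mol (a bare
#'   number or the result of [ddg()]).
#' @param temperature Temperature in K (> 0).
#' @return An `occupancy_ratio`: list with `ddg`, `temperature`, `ratio`
#'   and `orders_of_magnitude` (`floor(log10(ratio))`).
#' @examples
#' occupancy_ratio(5.14, 310)$orders_of_magnitude  # 3
#' @export
occupancy_ratio <- function(ddg, temperature = 310) {
  if (is.list(ddg)) ddg <- ddg$ddg
  stopifnot(is.numeric(ddg), is.finite(ddg))
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  ratio <- exp(ddg / rt_kcal(temperature))
  structure(list(ddg = ddg, temperature = temperature, ratio = ratio,
                 orders_of_magnitude = as.integer(floor(log10(ratio)))),
            class = "occupancy_ratio")
}

#' @export
print.occupancy_ratio <- function(x, ...) {
  cat(sprintf("p_OBP/p_EBP = %.3g (ddG = %.2f kcal/mol at %g K; %d orders of magnitude)\n",
              x$ratio, x$ddg, x$temperature, x$orders_of_magnitude))
  invisible(x)
}
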