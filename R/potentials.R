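#' Analytic one-dimensional potentials for umbrella-sampling ground truth
#'
#' A `potential_spec` describes a closed-form 1D potential along a reaction
#' coordinate (nm), used by the synthetic umbrella-sampling generator and as
#' the known ground truth when validating the WHAM estimator. Energies are
#' in kcal/mol.
#'
#' Three kinds are supported:
#' * `"harmonic"`: `U(x) = 0.5 * k * (x - x0)^2`, `k` in kcal mol^-1 nm^-2;
#' * `"double_well"`: a quartic with minima at `minima = c(x1, x2)` (both at
#'   `U = 0`) and a central barrier of height `barrier` kcal/mol:
#'   `U(x) = barrier * ((x - c)^2 - a^2)^2 / a^4` with `c = (x1 + x2) / 2`,
#'   `a = (x2 - x1) / 2`;
#' * `"piecewise_table"`: linear interpolation through tabulated `(x, y)`
#'   knots (constant extrapolation at the ends of the table, within `domain`).
#'
#' @param kind One of `"harmonic"`, `"double_well"`, `"piecewise_table"`.
#' @param domain Closed interval (length-2 numeric, nm) on which the
#'   potential may be evaluated.
#' @param k,x0 Harmonic stiffness (kcal mol^-1 nm^-2) and minimum (nm).
#' @param barrier Barrier height (kcal/mol) of the double well.
#' @param minima Length-2 vector: locations (nm) of the two minima.
#' @param table Data frame with columns `x` (nm) and `y` (kcal/mol) for
#'   `"piecewise_table"`.
#' @return An object of class `potential_spec`.
#' @examples
#' pot <- potential_spec("double_well", domain = c(0, 4),
#'                       barrier = 3, minima = c(1, 3))
#' potential_energy(pot, c(1, 2, 3))  # 0, 3, 0
#' @export
potential_spec <- function(kind = c("harmonic", "double_well", "piecewise_table"),
                           domain,
                           k = NULL, x0 = NULL,
                           barrier = NULL, minima = NULL,
                           table = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2],
            all(is.finite(domain)))
  params <- switch(kind,
    harmonic = {
      stopifnot(is.numeric(k), k >= 0, is.numeric(x0))
      list(k = k, x0 = x0)
    },
    double_well = {
      stopifnot(is.numeric(barrier), barrier >= 0,
                is.numeric(minima), length(minima) == 2L, minima[1] < minima[2])
      list(barrier = barrier, minima = minima)
    },
    piecewise_table = {
      stopifnot(is.data.frame(table), all(c("x", "y") %in% names(table)),
                nrow(table) >= 2L, !is.unsorted(table$x, strictly = TRUE),
                all(is.finite(table$x)), all(is.finite(table$y)))
      list(table = table)
    })
  out <- structure(list(kind = kind, params = params, domain = domain),
                   class = "potential_spec")
  # the analytic evaluation must be finite everywhere on the domain
  probe <- seq(domain[1], domain[2], length.out = 101L)
  if (!all(is.finite(potential_energy(out, probe)))) {
    stop("potential is not finite on its stated domain", call. = FALSE)
  }
  out
}

#' Evaluate an analytic potential
#'
#' @param potential A [potential_spec()].
#' @param x Reaction-coordinate values (nm) within the potential's domain.
#' @return Energies in kcal/mol.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential_spec"), is.numeric(x))
  if (any(x < potential$domain[1] - 1e-9 | x > potential$domain[2] + 1e-9)) {
    stop("x outside the potential's domain", call. = FALSE)
  }
  p <- potential$params
  switch(potential$kind,
    harmonic = 0.5 * p$k * (x - p$x0)^2,
    double_well = {
      ctr <- mean(p$minima)
      a <- diff(p$minima) / 2
      p$barrier * ((x - ctr)^2 - a^2)^2 / a^4
    },
    piecewise_table = stats::approx(p$table$x, p$table$y, xout = x,
                                    rule = 2)$y)
}

#' Ground-truth PMF profile from an analytic potential
#'
#' Evaluates the potential on a grid and shifts it so that the mean over
#' `zero_region` (default: the whole grid minimum, i.e. the profile minimum
#' is zero) is zero, mirroring the zeroing convention applied to estimated
#' profiles. The returned profile has zero uncertainty everywhere.
#'
#' @param potential A [potential_spec()].
#' @param grid Bin centers (nm) inside the potential's domain.
#' @param zero_region Optional length-2 interval (nm); the mean free energy
#'   over grid points in this interval is subtracted. When `NULL` the
#'   profile minimum is set to zero.
#' @return A [pmf_profile] tibble with columns `bin_center`, `free_energy`,
#'   `stderr`.
#' @export
analytic_pmf <- function(potential, grid, zero_region = NULL) {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  u <- potential_energy(potential, grid)
  if (is.null(zero_region)) {
    u <- u - min(u)
    zr <- grid[which.min(u)] + c(0, 0)
  } else {
    stopifnot(length(zero_region) == 2L)
    in_zero <- grid >= zero_region[1] & grid <= zero_region[2]
    if (!any(in_zero)) stop("zero_region contains no grid point", call. = FALSE)
    u <- u - mean(u[in_zero])
    zr <- zero_region
  }
  new_pmf_profile(bin_center = grid, free_energy = u,
                  stderr = rep(0, length(grid)), zero_region = zr)
}
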