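#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pmf_profile <- function(x, ...) {
  tibble::as_tibble(unclass_profile(x))
}

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), "pmf_profile")
  x
}

#' @export
glance.pmf_profile <- function(x, ...) {
  occ <- !is.na(x$free_energy)
  conv <- attr(x, "convergence")
  tibble::tibble(
    n_bins = nrow(x),
    n_occupied = sum(occ),
    min_free_energy = if (any(occ)) min(x$free_energy[occ]) else NA_real_,
    max_free_energy = if (any(occ)) max(x$free_energy[occ]) else NA_real_,
    median_stderr = stats::median(x$stderr[occ], na.rm = TRUE),
    iterations = if (is.null(conv)) NA_integer_ else conv$iterations,
    residual = if (is.null(conv)) NA_real_ else conv$residual)
}

#' @export
tidy.traj_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$eigenvalues / tot,
                 cumulative_fraction = cumsum(x$eigenvalues) / tot)
}

#' @export
glance.traj_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(n_atoms = length(x$indices),
                 n_modes = length(x$eigenvalues),
                 total_variance = tot,
                 trace = x$trace,
                 pc1_fraction = x$eigenvalues[1] / tot,
                 pc2_fraction = x$eigenvalues[2] / tot)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$assignments
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia,
                 mean_silhouette = x$silhouette,
                 n_frames = nrow(x$assignments))
}

#' @export
tidy.binding_free_energy <- function(x, ...) {
  tibble::tibble(site = x$site_label, state = x$state_label,
                 dg = x$dg, sd = x$sd, at = x$at)
}

#' @export
tidy.occupancy_ratio <- function(x, ...) {
  tibble::tibble(ddg = x$ddg, temperature = x$temperature,
                 ratio = x$ratio,
                 orders_of_magnitude = x$orders_of_magnitude)
}
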