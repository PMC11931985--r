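#' Generate umbrella-sampling windows from an analytic potential
#'
#' Draws, for each window centered at `x_i` with harmonic bias
#' `0.5 * k * (x - x_i)^2`, samples from the biased Boltzmann density
#' `p(x) proportional to exp(-(U(x) + bias)/RT)` with a Metropolis
#' random walk: the step size is adapted toward ~40% acceptance during the
#' burn-in only (frozen afterwards, so the collected, thinned samples obey
#' detailed balance). Window centers are uniformly spaced by `spacing` and
#' centred within the potential's domain. Defaults mirror the usual
#' umbrella protocol for ligand unbinding: ~0.1 nm spacing and a
#' 1000 kJ mol^-1 nm^-2 restraint at 310 K.
#'
#' @param potential A [potential_spec()] (energies kcal/mol, coordinate nm).
#' @param n_windows Number of windows (>= 2).
#' @param spacing Window spacing in nm.
#' @param force_const Bias force constant in kJ mol^-1 nm^-2 (> 0).
#' @param n_samples Retained samples per window (after burn-in/thinning).
#' @param temperature Temperature in K.
#' @param seed Integer seed; fixed seed gives identical samples.
#' @param burn_in Discarded equilibration steps (default 1000).
#' @param thin Keep every `thin`-th step (default 10).
#' @return An `umbrella_dataset`: list with `windows` (each a list with
#'   `center` nm, `force_const` kJ mol^-1 nm^-2, `samples` nm,
#'   `temperature` K), `coordinate_name`, and `temperature`.
#' @export
generate_umbrella_dataset <- function(potential, n_windows, spacing,
                                      force_const = 1000, n_samples = 5000,
                                      temperature = 310, seed = 1L,
                                      burn_in = 1000L, thin = 10L) {
  stopifnot(inherits(potential, "potential_spec"),
            n_windows >= 2L, n_samples >= 1L, spacing > 0)
  if (force_const <= 0) stop("force_const must be > 0", call. = FALSE)
  dom <- potential$domain
  span <- (n_windows - 1L) * spacing
  if (span > diff(dom) + 1e-9) {
    stop("domain too small for ", n_windows, " windows at spacing ",
         spacing, " nm", call. = FALSE)
  }
  start <- dom[1] + (diff(dom) - span) / 2
  centers <- start + spacing * (seq_len(n_windows) - 1L)

  rt <- rt_kcal(temperature)
  k_kcal <- kj_to_kcal(force_const)
  # clamp proposals to the domain via rejection (log-density -Inf outside)
  logdens <- function(x, x0) {
    if (x < dom[1] || x > dom[2]) return(-Inf)
    -(potential_energy(potential, x) + 0.5 * k_kcal * (x - x0)^2) / rt
  }

  windows <- withr::with_seed(as.integer(seed), {
    lapply(centers, function(x0) {
      step <- max(2.4 * sqrt(rt / k_kcal), 1e-4)
      x <- min(max(x0, dom[1]), dom[2])
      lp <- logdens(x, x0)
      acc_win <- 0L
      # burn-in with step adaptation every 100 steps toward ~40% acceptance
      for (s in seq_len(burn_in)) {
        prop <- x + stats::rnorm(1L, sd = step)
        lpp <- logdens(prop, x0)
        if (log(stats::runif(1L)) < lpp - lp) {
          x <- prop; lp <- lpp; acc_win <- acc_win + 1L
        }
        if (s %% 100L == 0L) {
          rate <- acc_win / 100
          step <- step * exp(rate - 0.4)
          acc_win <- 0L
        }
      }
      n_tot <- n_samples * thin
      innov <- stats::rnorm(n_tot, sd = step)
      logu <- log(stats::runif(n_tot))
      out <- numeric(n_samples)
      j <- 0L
      for (s in seq_len(n_tot)) {
        prop <- x + innov[s]
        lpp <- logdens(prop, x0)
        if (logu[s] < lpp - lp) { x <- prop; lp <- lpp }
        if (s %% thin == 0L) { j <- j + 1L; out[j] <- x }
      }
      list(center = x0, force_const = force_const, samples = out,
           temperature = temperature)
    })
  })
  new_umbrella_dataset(windows, coordinate_name = "xi",
                       temperature = temperature)
}

#' Umbrella-sampling dataset container
#'
#' @param windows List of windows, each with `center` (nm), `force_const`
#'   (kJ mol^-1 nm^-2), `samples` (nm), `temperature` (K).
#' @param coordinate_name Label for the reaction coordinate.
#' @param temperature Shared temperature in K.
#' @return An `umbrella_dataset`.
#' @export
new_umbrella_dataset <- function(windows, coordinate_name = "xi",
                                 temperature = 310) {
  stopifnot(length(windows) >= 1L)
  for (w in windows) {
    stopifnot(is.numeric(w$center), w$force_const >= 0,
              length(w$samples) >= 1L)
    if (abs(w$temperature - temperature) > 1e-9) {
      stop("all windows must share one temperature", call. = FALSE)
    }
  }
  structure(list(windows = windows, coordinate_name = coordinate_name,
                 temperature = temperature),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  ctr <- vapply(x$windows, `[[`, numeric(1), "center")
  cat("<umbrella_dataset> ", length(x$windows), " windows, centers ",
      format(min(ctr)), " .. ", format(max(ctr)), " nm, T = ",
      x$temperature, " K\n", sep = "")
  invisible(x)
}

#' @export
tidy.umbrella_dataset <- function(x, ...) {
  purrr::imap_dfr(x$windows, function(w, i) {
    tibble::tibble(window = i, center = w$center,
                   force_const = w$force_const,
                   sample_index = seq_along(w$samples), xi = w$samples)
  })
}

#' Write an umbrella dataset to per-window files plus metadata
#'
#' One two-column TSV per window (`sample_index`, `xi_nm`) and a metadata
#' TSV (`file`, `center_nm`, `force_const_kj_mol_nm2`, `temperature_k`),
#' mirroring common umbrella-sampling tooling layouts.
#'
#' @param dataset An `umbrella_dataset`.
#' @param dir Output directory (created if missing).
#' @return Path to the metadata file, invisibly.
#' @export
write_umbrella_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- purrr::imap_dfr(dataset$windows, function(w, i) {
    fn <- sprintf("window_%03d.tsv", i)
    readr::write_tsv(tibble::tibble(sample_index = seq_along(w$samples),
                                    xi_nm = w$samples),
                     file.path(dir, fn), progress = FALSE)
    tibble::tibble(file = fn, center_nm = w$center,
                   force_const_kj_mol_nm2 = w$force_const,
                   temperature_k = w$temperature)
  })
  meta_path <- file.path(dir, "windows.tsv")
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(meta_path)
}

#' Read an umbrella dataset from a metadata file
#'
#' @param meta_path Path to a metadata TSV as written by
#'   [write_umbrella_dataset()].
#' @return An `umbrella_dataset`.
#' @export
read_umbrella_dataset <- function(meta_path) {
  if (!file.exists(meta_path)) {
    stop("umbrella metadata file not found: ", meta_path, call. = FALSE)
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  need <- c("file", "center_nm", "force_const_kj_mol_nm2", "temperature_k")
  if (!all(need %in% names(meta))) {
    stop("umbrella metadata must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dir <- dirname(meta_path)
  windows <- purrr::pmap(meta, function(file, center_nm,
                                        force_const_kj_mol_nm2,
                                        temperature_k, ...) {
    tab <- readr::read_tsv(file.path(dir, file), show_col_types = FALSE,
                           progress = FALSE)
    list(center = center_nm, force_const = force_const_kj_mol_nm2,
         samples = tab[[2]], temperature = temperature_k)
  })
  new_umbrella_dataset(windows, temperature = meta$temperature_k[1])
}
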