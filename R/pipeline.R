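#' Default pipeline configuration
#'
#' Returns the full default configuration of the demo workflow as a named
#' list; any subset can be overridden through `run_pipeline(config = ...)`
#' or a YAML file with the same keys. All randomness flows through `seed`.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    stage = "all",
    seed = 1L,
    out_dir = "statescan_run",
    synth = list(
      tm6_shift = 8, n_frames = 1000L, collapse_frame = 250L,
      noise_sd = 0.3,
      potential = list(kind = "double_well", barrier = 3,
                       minima = c(1, 3), domain = c(0, 4)),
      n_windows = 40L, spacing = 0.1, force_const = 1000,
      n_samples = 5000L, temperature = 310),
    activation = list(pairs = list(c(173L, 318L), c(262L, 318L))),
    landscape = list(k = 2L, n_init = 10L),
    pmf = list(n_bins = 200L, n_boot = 50L, bulk_auto_fraction = 0.1,
               site_fraction = 0.5))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the demo analysis pipeline
#'
#' Ties the stages together: `synth` generates a toy receptor, a
#' closed/open reference pair, a two-state collapse trajectory and an
#' umbrella dataset from the configured analytic potential, writing them
#' as plain-text files; `activation` computes distance and A100 series,
#' RMSD and RMSF; `landscape` runs loop-masked mass-weighted PCA, k-means
#' and reference comparison; `pmf` solves WHAM with a Bayesian bootstrap
#' and reports binding free energies. `all` runs everything in order.
#' A JSON manifest records the seed, the parameter echo and MD5 checksums
#' of every output, so a rerun with the same config and seed is
#' bit-identical for the deterministic stages.
#'
#' @param config Named list (see [default_config()]), or a path to a YAML
#'   file with the same keys; partial configs are merged over the
#'   defaults.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`) and the per-stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("configuration-error: config file not found: ", config,
           call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  stages_all <- c("synth", "activation", "landscape", "pmf")
  stages <- if (identical(cfg$stage, "all")) stages_all else cfg$stage
  if (!all(stages %in% stages_all)) {
    stop("configuration-error: unknown stage: ",
         paste(setdiff(stages, stages_all), collapse = ", "), call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s (%s)", stage, msg,
                    format(Sys.time(), "%H:%M:%S")))
  }
  path_of <- function(...) file.path(cfg$out_dir, ...)

  if ("synth" %in% stages) {
    log_stage("synth", "generating toy receptor, trajectory, umbrella data")
    s <- cfg$synth
    rec <- make_toy_receptor(seed = cfg$seed)
    pair <- make_reference_pair(rec, tm6_shift = s$tm6_shift)
    traj <- generate_two_state_trajectory(pair$closed, pair$open,
                                          n_frames = s$n_frames,
                                          collapse_frame = s$collapse_frame,
                                          noise_sd = s$noise_sd,
                                          seed = cfg$seed)
    write_structure(pair$closed, path_of("closed.pdb"))
    write_structure(pair$open, path_of("open.pdb"))
    write_trajectory(traj, path_of("trajectory.tsv"), format = "flat_table")
    pot <- do.call(potential_spec, s$potential)
    umb <- generate_umbrella_dataset(pot, n_windows = s$n_windows,
                                     spacing = s$spacing,
                                     force_const = s$force_const,
                                     n_samples = s$n_samples,
                                     temperature = s$temperature,
                                     seed = cfg$seed)
    write_umbrella_dataset(umb, path_of("umbrella"))
    outputs <- c(outputs, path_of(c("closed.pdb", "open.pdb",
                                    "trajectory.tsv",
                                    file.path("umbrella", "windows.tsv"))))
    results$synth <- list(receptor = rec, pair = pair, trajectory = traj,
                          umbrella = umb, potential = pot)
  }

  need_traj <- function() {
    if (!is.null(results$synth)) return(results$synth)
    top_path <- path_of("closed.pdb")
    trj_path <- path_of("trajectory.tsv")
    if (!file.exists(top_path) || !file.exists(trj_path)) {
      stop("configuration-error: run the synth stage first, or provide ",
           top_path, " and ", trj_path, call. = FALSE)
    }
    closed <- read_structure(top_path)
    open_ <- read_structure(path_of("open.pdb"))
    list(pair = list(closed = closed, open = open_),
         trajectory = read_trajectory(trj_path, closed,
                                      format = "flat_table"))
  }

  if ("activation" %in% stages) {
    log_stage("activation", "distance, A100, RMSD, RMSF series")
    sy <- need_traj()
    traj <- sy$trajectory
    dist_tabs <- lapply(cfg$activation$pairs, function(p) {
      d <- ca_distance_series(traj, p[1], p[2])
      dplyr::mutate(d, res_a = p[1], res_b = p[2], .before = 1)
    })
    dist_tab <- dplyr::bind_rows(dist_tabs)
    readr::write_csv(dist_tab, path_of("distances.csv"), progress = FALSE)
    a100 <- a100_series(traj)
    readr::write_csv(a100, path_of("a100.csv"), progress = FALSE)
    sel <- atom_selection("ca")
    rms <- rmsd_series(traj, sy$pair$closed, sel)
    readr::write_csv(rms, path_of("rmsd.csv"), progress = FALSE)
    flu <- rmsf(traj, sel)
    readr::write_csv(flu, path_of("rmsf.csv"), progress = FALSE)
    outputs <- c(outputs, path_of(c("distances.csv", "a100.csv",
                                    "rmsd.csv", "rmsf.csv")))
    results$activation <- list(distances = dist_tab, a100 = a100,
                               rmsd = rms, rmsf = flu)
  }

  if ("landscape" %in% stages) {
    log_stage("landscape", "loop-masked PCA + k-means clustering")
    sy <- need_traj()
    traj <- sy$trajectory
    sel <- atom_selection("ca", exclude_residues = loop_residues())
    model <- fit_pca(traj, sel)
    proj <- project_trajectory(superpose_trajectory(traj, sel), model)
    clus <- kmeans_cluster(proj, k = cfg$landscape$k, seed = cfg$seed,
                           n_init = cfg$landscape$n_init)
    readr::write_csv(tidy(clus), path_of("projection.csv"), progress = FALSE)
    readr::write_csv(tidy(model), path_of("eigenvalues.csv"),
                     progress = FALSE)
    refs <- list(closed = sy$pair$closed, open = sy$pair$open)
    cent_reports <- purrr::imap(clus$centroid_frames, function(fr, cl) {
      cent <- trajectory_frame(traj, fr)
      write_structure(cent, path_of(sprintf("centroid_%d.pdb", cl)))
      cmp <- compare_to_references(cent, refs, atom_selection("ca"))
      list(cluster = cl, frame = fr,
           tm6_shift = tm6_outward_shift(cent, sy$pair$closed),
           reference_rmsd = stats::setNames(as.list(cmp$rmsd),
                                            cmp$reference),
           nearest = cmp$reference[cmp$nearest])
    })
    jsonlite::write_json(cent_reports, path_of("centroids.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    outputs <- c(outputs, path_of(c("projection.csv", "eigenvalues.csv",
                                    "centroids.json")))
    results$landscape <- list(pca = model, clusters = clus,
                              centroids = cent_reports)
  }

  if ("pmf" %in% stages) {
    log_stage("pmf", "WHAM + Bayesian bootstrap")
    umb <- if (!is.null(results$synth)) {
      results$synth$umbrella
    } else {
      read_umbrella_dataset(path_of("umbrella", "windows.tsv"))
    }
    pm <- cfg$pmf
    ctr <- vapply(umb$windows, `[[`, numeric(1), "center")
    rng <- range(unlist(lapply(umb$windows, `[[`, "samples")))
    # bulk: the far tail of the coordinate; site: the near half
    bulk <- c(rng[2] - pm$bulk_auto_fraction * diff(rng), rng[2])
    site <- c(rng[1], rng[1] + pm$site_fraction * diff(rng))
    prof <- bayesian_bootstrap(umb, n_boot = pm$n_boot, seed = cfg$seed,
                               bulk_region = bulk, n_bins = pm$n_bins)
    readr::write_csv(
      dplyr::rename(tidy(prof), bin_center_nm = "bin_center",
                    F_kcal_mol = "free_energy"),
      path_of("pmf.csv"), progress = FALSE)
    bfe <- binding_free_energy(prof, site, site_label = "site",
                               state_label = "demo")
    report <- list(dg = bfe$dg, sd = bfe$sd, at = bfe$at,
                   bulk_region = bulk, site_region = site,
                   n_boot = pm$n_boot)
    jsonlite::write_json(report, path_of("pmf_report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    outputs <- c(outputs, path_of(c("pmf.csv", "pmf_report.json")))
    results$pmf <- list(profile = prof, binding = bfe, report = report)
  }

  checks <- tools::md5sum(outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("statescan")),
    seed = cfg$seed, stages = stages, parameters = cfg,
    checksums = stats::setNames(as.list(unname(checks)),
                                basename(names(checks))))
  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Subpocket binding report
#'
#' Builds the standard binding-free-energy comparison table from per
#' (system, state) OBP/EBP binding free energies: the subpocket
#' difference `ddG = dG_EBP - dG_OBP`, the Boltzmann occupancy ratio
#' `p_OBP/p_EBP` and its order of magnitude.
#'
#' @param dg_table Data frame with columns `system`, `state`, `site`
#'   (`"OBP"`/`"EBP"`), `dg`, `sd` — one OBP and one EBP row per
#'   (system, state).
#' @param temperature Temperature in K.
#' @param error_mode Passed to [ddg()].
#' @return A tibble with one row per (system, state): `dg_obp`, `dg_ebp`,
#'   `ddg`, `ddg_sd`, `ratio`, `orders_of_magnitude`.
#' @examples
#' tab <- tibble::tribble(
#'   ~system, ~state, ~site, ~dg, ~sd,
#'   "SERO", "open", "OBP", -12.19, 0.74,
#'   "SERO", "open", "EBP", -7.05, 0.64)
#' make_table1_report(tab)$ddg  # 5.14
#' @export
make_table1_report <- function(dg_table, temperature = 310,
                               error_mode = "quadrature") {
  need <- c("system", "state", "site", "dg", "sd")
  stopifnot(is.data.frame(dg_table), all(need %in% names(dg_table)))
  groups <- dplyr::distinct(dg_table, .data$system, .data$state)
  purrr::pmap_dfr(groups, function(system, state) {
    sub <- dg_table[dg_table$system == system & dg_table$state == state, ]
    missing <- setdiff(c("OBP", "EBP"), sub$site)
    if (length(missing)) {
      stop("incomplete pair for ", system, "/", state, ": missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    mk <- function(site) {
      row <- sub[sub$site == site, ][1, ]
      structure(list(dg = row$dg, sd = row$sd, site_label = site,
                     state_label = state, at = NA_real_),
                class = "binding_free_energy")
    }
    d <- ddg(mk("EBP"), mk("OBP"), error_mode = error_mode)
    occ <- occupancy_ratio(d$ddg, temperature)
    tibble::tibble(system = system, state = state,
                   dg_obp = mk("OBP")$dg, dg_ebp = mk("EBP")$dg,
                   ddg = d$ddg, ddg_sd = d$sd, ratio = occ$ratio,
                   orders_of_magnitude = occ$orders_of_magnitude)
  })
}
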