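#' Mass-weighted PCA of a trajectory
#'
#' Builds the mass-weighted covariance matrix of the selected coordinates
#' (each coordinate scaled by the square root of its atom's mass, then
#' mean-centred) and diagonalizes it. Frames must share a common frame of
#' reference; by default every frame is first Kabsch-aligned to frame 1
#' over the selection (`superpose = TRUE`). The intrinsically flexible
#' loops are usually excluded via
#' `atom_selection("ca", exclude_residues = loop_residues())`, otherwise
#' they dominate the eigenvalue spectrum.
#'
#' @param traj An `md_trajectory` with >= 2 frames.
#' @param selection An [atom_selection()].
#' @param superpose Align frames to `reference_frame` over the selection
#'   before the covariance is formed.
#' @param reference_frame Frame used as alignment reference.
#' @return A `traj_pca` object: `mean` (selected mean coordinates, flat
#'   vector), `eigenvalues` (A^2 amu, descending), `eigenvectors`
#'   (orthonormal columns), `selection`, `masses` (amu), `indices`.
#' @export
fit_pca <- function(traj, selection, superpose = TRUE, reference_frame = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames", call. = FALSE)
  if (superpose) {
    traj <- superpose_trajectory(traj, selection,
                                 reference_frame = reference_frame)
  }
  idx <- resolve_selection(traj$topology, selection)
  m <- traj$topology$atoms$mass[idx]
  sw <- rep(sqrt(m), each = 1L)
  nf <- n_frames(traj)
  x <- matrix(NA_real_, nf, 3L * length(idx))
  for (i in seq_len(nf)) {
    x[i, ] <- as.vector(t(traj$frames[i, idx, , drop = TRUE]))
  }
  swv <- rep(sqrt(m), each = 3L)
  xw <- sweep(x, 2, swv, "*")
  mu <- colMeans(xw)
  xc <- sweep(xw, 2, mu)
  cv <- crossprod(xc) / (nf - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(list(mean = mu, eigenvalues = ev, eigenvectors = eig$vectors,
                 selection = selection, masses = m, indices = idx,
                 trace = sum(diag(cv))),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat("<traj_pca> ", length(x$indices), " atoms, ", length(x$eigenvalues),
      " modes; PC1/PC2 variance ",
      sprintf("%.1f%%/%.1f%%", 100 * x$eigenvalues[1] / tot,
              100 * x$eigenvalues[2] / tot), "\n", sep = "")
  invisible(x)
}

#' Project a trajectory onto principal components
#'
#' Per-frame dot products of the mass-weighted, mean-centred selected
#' coordinates with the leading eigenvectors. Projection is per-frame, so
#' projecting trajectories separately or concatenated gives identical
#' values.
#'
#' @param traj An `md_trajectory` congruent with the model's selection.
#' @param model A [fit_pca()] result.
#' @param n_components Number of components (default 2).
#' @param superpose Align frames to the model's frame of reference first
#'   (uses frame 1 of `traj`; supply pre-aligned frames and set this to
#'   `FALSE` when projecting onto a model fitted from another trajectory).
#' @return A tibble with columns `frame`, `time_ns`, `PC1`, `PC2`, ...
#' @export
project_trajectory <- function(traj, model, n_components = 2L,
                               superpose = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(model, "traj_pca"))
  if (n_components > ncol(model$eigenvectors)) {
    stop("n_components exceeds available modes", call. = FALSE)
  }
  if (superpose) traj <- superpose_trajectory(traj, model$selection)
  idx <- resolve_selection(traj$topology, model$selection)
  if (length(idx) != length(model$indices)) {
    stop("selection resolves to a different atom count than the model",
         call. = FALSE)
  }
  swv <- rep(sqrt(model$masses), each = 3L)
  nf <- n_frames(traj)
  proj <- matrix(NA_real_, nf, n_components)
  vv <- model$eigenvectors[, seq_len(n_components), drop = FALSE]
  for (i in seq_len(nf)) {
    xw <- as.vector(t(traj$frames[i, idx, , drop = TRUE])) * swv
    proj[i, ] <- crossprod(vv, xw - model$mean)
  }
  colnames(proj) <- paste0("PC", seq_len(n_components))
  dplyr::bind_cols(tibble::tibble(frame = seq_len(nf),
                                  time_ns = traj$times_ns),
                   tibble::as_tibble(proj))
}

# k-means++ seeding (not provided by base R)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster a 2D projection with k-means
#'
#' Lloyd iterations (via `stats::kmeans`) from k-means++ seedings, with
#' `n_init` restarts keeping the best inertia; deterministic for a fixed
#' seed. With `k = "auto"` the cluster count is chosen by mean silhouette
#' width over k in 2..4 (one cluster is only used as a fallback for
#' degenerate projections), reflecting the convention of assigning at most
#' four conformational ensembles. Centroid frames are the frames nearest
#' each cluster center (ties broken by lowest frame index).
#'
#' @param projection Tibble from [project_trajectory()] (needs `PC1`,
#'   `PC2`).
#' @param k Integer 1..4, or `"auto"`.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @return A `cluster_result`: list with `assignments` (tibble: frame,
#'   time_ns, PC1, PC2, cluster), `centers`, `centroid_frames`, `k`,
#'   `inertia`, `silhouette` (mean width, `NA` for k = 1).
#' @export
kmeans_cluster <- function(projection, k = "auto", seed = 1L, n_init = 10L) {
  stopifnot(all(c("PC1", "PC2") %in% names(projection)))
  x <- as.matrix(projection[, c("PC1", "PC2")])
  nf <- nrow(x)
  run_k <- function(kk) {
    withr::with_seed(as.integer(seed) + kk, {
      best <- NULL
      for (r in seq_len(n_init)) {
        init <- kmeanspp_centers(x, kk)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = init,
                                         algorithm = "Lloyd",
                                         iter.max = 200L)),
          error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      best
    })
  }
  if (identical(k, "auto")) {
    cand <- 2:min(4L, nf - 1L)
    fits <- lapply(cand, run_k)
    sil <- vapply(seq_along(cand), function(i) {
      f <- fits[[i]]
      if (is.null(f) || length(unique(f$cluster)) < 2L) return(-Inf)
      mean(cluster::silhouette(f$cluster, stats::dist(x))[, "sil_width"])
    }, numeric(1))
    pick <- which.max(sil)
    fit <- fits[[pick]]
    k_used <- cand[pick]
    sil_used <- sil[pick]
  } else {
    stopifnot(is.numeric(k), k >= 1L, k <= 4L)
    if (k > nf) stop("k exceeds the number of frames", call. = FALSE)
    fit <- run_k(as.integer(k))
    k_used <- as.integer(k)
    sil_used <- if (k_used > 1L && length(unique(fit$cluster)) > 1L) {
      mean(cluster::silhouette(fit$cluster, stats::dist(x))[, "sil_width"])
    } else NA_real_
  }
  centers <- fit$centers
  centroid_frames <- vapply(seq_len(k_used), function(cl) {
    d2 <- rowSums(sweep(x, 2, centers[cl, ])^2)
    d2[fit$cluster != cl] <- Inf
    which.min(d2)  # which.min takes the lowest index on ties
  }, integer(1))
  assignments <- dplyr::mutate(
    tibble::as_tibble(projection),
    cluster = as.integer(fit$cluster))
  structure(list(assignments = assignments, centers = centers,
                 centroid_frames = centroid_frames, k = k_used,
                 inertia = fit$tot.withinss, silhouette = sil_used),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k = ", x$k, ", inertia = ",
      format(x$inertia, digits = 4), ", centroid frames: ",
      paste(x$centroid_frames, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare a centroid structure to named reference states
#'
#' Kabsch-aligned mass-weighted RMSD of the centroid against each
#' reference over a common selection; the nearest reference (lowest RMSD,
#' ties broken by name order as supplied) labels the centroid.
#'
#' @param centroid An `md_structure`.
#' @param references Named list of `md_structure`s (e.g.
#'   `list(inactive = ..., active = ...)`).
#' @param selection An [atom_selection()].
#' @return A tibble with columns `reference`, `rmsd`, `nearest` (logical).
#' @export
compare_to_references <- function(centroid, references, selection) {
  stopifnot(inherits(centroid, "md_structure"))
  if (!length(references)) stop("empty reference set", call. = FALSE)
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("references must be named", call. = FALSE)
  }
  idx_c <- resolve_selection(centroid, selection)
  w <- centroid$atoms$mass[idx_c]
  rmsds <- vapply(references, function(ref) {
    idx_r <- resolve_selection(ref, selection)
    if (length(idx_r) != length(idx_c)) {
      stop("selection is not congruent across centroid and references",
           call. = FALSE)
    }
    kabsch_superpose(centroid$coords[idx_c, , drop = FALSE],
                     ref$coords[idx_r, , drop = FALSE], weights = w)$rmsd
  }, numeric(1))
  tibble::tibble(reference = names(references), rmsd = unname(rmsds),
                 nearest = seq_along(rmsds) == which.min(rmsds))
}

#' TM6 outward displacement of a conformation
#'
#' Superposes the conformation onto the closed reference over everything
#' except the TM6 block, then reports the mean C-alpha displacement
#' magnitude of the block — the scalar readout of the TM6 outward tilt
#' that distinguishes open (~8 A), partially-open (~4 A) and closed (0 A)
#' states.
#'
#' @param conformation,closed_ref Congruent `md_structure`s.
#' @param tm6_block Residue ids of the TM6 block (default 315:346).
#' @return Mean displacement in Angstrom.
#' @export
tm6_outward_shift <- function(conformation, closed_ref, tm6_block = 315:346) {
  stopifnot(inherits(conformation, "md_structure"),
            inherits(closed_ref, "md_structure"))
  if (!length(tm6_block)) stop("empty TM6 block", call. = FALSE)
  sel_fit <- atom_selection("ca", exclude_residues = tm6_block)
  idx_fit <- resolve_selection(conformation, sel_fit)
  idx_fit_ref <- resolve_selection(closed_ref, sel_fit)
  fit <- kabsch_superpose(conformation$coords[idx_fit, , drop = FALSE],
                          closed_ref$coords[idx_fit_ref, , drop = FALSE],
                          weights = conformation$atoms$mass[idx_fit])
  moved <- apply_superposition(conformation$coords, fit)
  sel_block <- atom_selection("ca", include_residues = tm6_block)
  idx_b <- resolve_selection(conformation, sel_block)
  idx_b_ref <- resolve_selection(closed_ref, sel_block)
  disp <- moved[idx_b, , drop = FALSE] -
    closed_ref$coords[idx_b_ref, , drop = FALSE]
  mean(sqrt(rowSums(disp^2)))
}
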