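# Independent reference estimators used to cross-check the production code.

# MBAR-style self-consistent window free energies computed on the raw,
# unbinned samples (no histograms anywhere): for harmonic biases u_i(x) =
# 0.5 k_i (x - c_i)^2 / RT, iterate
#   f_i <- -log sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))
# This shares no code with the WHAM solver and serves as its oracle.
mbar_window_free_energies <- function(dataset, temperature = NULL,
                                      tol = 1e-12, max_iter = 20000L) {
  if (is.null(temperature)) temperature <- dataset$temperature
  rt <- statescan::rt_kcal(temperature)
  x <- unlist(lapply(dataset$windows, `[[`, "samples"))
  n_k <- vapply(dataset$windows, function(w) length(w$samples), integer(1))
  centers <- vapply(dataset$windows, `[[`, numeric(1), "center")
  k_kcal <- vapply(dataset$windows, `[[`, numeric(1), "force_const") / 4.184
  nw <- length(centers)
  # u[i, n]: reduced bias energy of sample n under window i
  u <- 0.5 * outer(k_kcal, rep(1, length(x))) *
    (outer(rep(1, nw), x) - outer(centers, rep(1, length(x))))^2 / rt
  f <- rep(0, nw)
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_k * exp(f - u))
    f_new <- -log(rowSums(exp(-u) / rep(denom, each = nw) *
                            matrix(1, nw, length(x))))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  f * rt  # kcal/mol, relative to window 1
}

# Brute-force weighted RMSD minimum over sampled rotations/translations is
# impractical; instead bio3d's least-squares fit is the independent
# superposition oracle.
bio3d_rmsd <- function(mobile, reference) {
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(reference)),
                   mobile = matrix(as.vector(t(mobile)), nrow = 1)))
  sqrt(mean((fit[1, ] - as.vector(t(reference)))^2) * 3)
}
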