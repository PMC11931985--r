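#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PMF profile
#'
#' Free energy versus reaction coordinate with a +/- 1 SD ribbon where
#' bootstrap uncertainties are available.
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$free_energy), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$free_energy))
  if (any(df$stderr > 0, na.rm = TRUE)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$stderr,
                   ymax = .data$free_energy + .data$stderr),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (nm)",
                  y = "free energy (kcal/mol)")
}

#' Scree plot of a trajectory PCA
#'
#' @param object A `traj_pca`.
#' @param n_components Number of leading modes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traj_pca <- function(object, n_components = 10L, ...) {
  df <- utils::head(tidy(object), n_components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance fraction")
}

#' Plot a clustered 2D projection
#'
#' PC1/PC2 scatter colored by cluster, centroid frames marked.
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tidy(object)
  cent <- df[object$centroid_frames, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = cent, colour = "black", shape = 4, size = 3) +
    ggplot2::labs(colour = "cluster")
}

#' Plot an activation time series
#'
#' Works for distance series (column `distance`) and A100 series (column
#' `score`); reference levels stored by [ca_distance_series()] are drawn
#' as horizontal lines.
#'
#' @param series Tibble from [ca_distance_series()] or [a100_series()].
#' @return A ggplot object.
#' @export
plot_activation_series <- function(series) {
  ycol <- if ("distance" %in% names(series)) "distance" else "score"
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_ns,
                                            y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)",
                  y = if (ycol == "distance") "C-alpha distance (Å)"
                      else "A100 score")
  refs <- attr(series, "references")
  if (!is.null(refs)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(refs),
                                 linetype = "dashed")
  }
  p
}
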