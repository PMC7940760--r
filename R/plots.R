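#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_hline
#'   geom_tile geom_point labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot a residue beta-sheet probability profile
#'
#' Bars per residue with the ensemble mean as a horizontal dashed line.
#'
#' @param object A `beta_profile` (from [residue_beta_profile()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$residue, y = .data$beta_probability)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = attr(object, "mean_beta"), linetype = "dashed") +
    labs(x = "residue", y = "beta-sheet probability") +
    theme_minimal()
}

#' Plot a residue-residue contact-probability map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$residue_i, y = .data$residue_j,
             fill = .data$probability)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "red", limits = c(0, 1)) +
    labs(x = "residue", y = "residue", fill = "contact\nprobability") +
    theme_minimal()
}

#' Plot per-replica dwell fractions over the rung ladder
#'
#' One line per replica; sufficient mixing shows every line fluctuating
#' around 1/n_replicas.
#'
#' @param object A `rest2_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rest2_run <- function(object, ...) {
  d <- object$diagnostics$dwell_fractions
  df <- tibble(
    replica = factor(rep(seq_len(nrow(d)), times = ncol(d))),
    rung = rep(seq_len(ncol(d)), each = nrow(d)),
    fraction = as.vector(d)
  )
  ggplot(df, aes(x = .data$rung, y = .data$fraction,
                 colour = .data$replica)) +
    geom_line() +
    geom_hline(yintercept = 1 / nrow(d), linetype = "dashed") +
    labs(x = "rung", y = "dwell fraction") +
    theme_minimal()
}

#' Plot binding-pose points coloured by cluster
#'
#' @param points Tibble from [pose_points()].
#' @param clusters A `pose_clusters` from [dbscan_cluster()] (optional).
#' @return A ggplot (x/y projection).
#' @export
plot_pose_points <- function(points, clusters = NULL) {
  points$cluster <- if (is.null(clusters)) {
    factor(1)
  } else {
    factor(clusters$labels)
  }
  ggplot(points, aes(x = .data$x, y = .data$y, colour = .data$cluster)) +
    geom_point(alpha = 0.6) +
    labs(x = "x (A)", y = "y (A)", colour = "site") +
    theme_minimal()
}
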