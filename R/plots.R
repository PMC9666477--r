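#' Plot a merge tree as a dendrogram
#'
#' Draws the classic dendrogram layout: leaves spread on the x-axis at
#' height 0 (or their own height), vertical segments up to each parent's
#' merge height, horizontal connectors at the merges.
#'
#' @param object A [merge_tree()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.merge_tree <- function(object, ...) {
  tree <- object
  kids <- tree_children(tree)
  n <- length(tree$height)
  xpos <- rep(NA_real_, n)
  counter <- 0
  assign_x <- function(v) {
    if (length(kids[[v]]) == 0L) {
      counter <<- counter + 1
      xpos[v] <<- counter
    } else {
      for (k in kids[[v]]) assign_x(k)
      xpos[v] <<- mean(xpos[kids[[v]]])
    }
  }
  assign_x(tree_root(tree))
  nonroot <- which(tree$parent != 0L)
  vertical <- tibble::tibble(
    x = xpos[nonroot], xend = xpos[nonroot],
    y = tree$height[nonroot], yend = tree$height[tree$parent[nonroot]]
  )
  horizontal <- purrr::map_dfr(which(lengths(kids) > 0L), function(v) {
    tibble::tibble(
      x = min(xpos[kids[[v]]]), xend = max(xpos[kids[[v]]]),
      y = tree$height[v], yend = tree$height[v]
    )
  })
  leaves <- tree_leaves(tree)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::bind_rows(vertical, horizontal),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_point(
      data = tibble::tibble(x = xpos[leaves], y = tree$height[leaves]),
      ggplot2::aes(x = .data$x, y = .data$y),
      size = 1.5
    ) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "merge height") +
    ggplot2::theme_minimal()
}

#' Plot group-wise height-count curves
#'
#' Pointwise group means with one-standard-deviation ribbons, the standard
#' visual summary of how much heterogeneity each cluster's trees retain at
#' every height threshold.
#'
#' @param object A `height_curve_summary` from [group_height_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.height_curve_summary <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(
      x = .data$threshold, y = .data$mean,
      color = .data$group, fill = .data$group
    )
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "height threshold",
      y = "vertices above threshold (group mean ± 1 SD)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the cluster-number selection trace
#'
#' Silhouette (and, when available, response concordance) against the
#' candidate number of clusters, with the selected k marked.
#'
#' @param object A `tree_clustering` from [ward_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tree_clustering <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"k",
    names_to = "criterion", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves per cluster
#'
#' @param object A `km_result` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_result <- function(object, ...) {
  fit <- object$fit
  strata <- rep(names(fit$strata), fit$strata)
  df <- tibble::tibble(
    time = fit$time, surv = fit$surv,
    group = sub("^group=", "", strata)
  )
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(df$group)),
    df
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv, color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "probability of no response yet",
      subtitle = paste0("log-rank p = ", format(object$p_value, digits = 3))
    ) +
    ggplot2::theme_minimal()
}
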