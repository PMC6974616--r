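#' Plot a threshold sweep
#'
#' Bi-cluster counts against the coherence threshold, one line per mark,
#' faceted by minimum support when several levels were swept.
#'
#' @param object A `sweep_result` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$corr_threshold, y = .data$n_biclusters,
    colour = .data$mark, group = .data$mark
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Pearson coherence threshold",
      y = "Number of bi-clusters",
      colour = "Mark"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(object$min_support)) > 1) {
    p <- p + ggplot2::facet_wrap(
      ~min_support,
      labeller = ggplot2::labeller(min_support = function(v) {
        paste0("min support ", v)
      })
    )
  }
  p
}

#' Plot tri-cluster membership
#'
#' Tile map of which epigenetic marks and cancer types belong to each
#' maximal tri-cluster, with clusters ordered by support.
#'
#' @param object A `tricluster_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tricluster_set
#' @export
autoplot.tricluster_set <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No tri-clusters") +
             ggplot2::theme_void())
  }
  long <- dplyr::bind_rows(
    tibble(
      cluster_id = rep(object$cluster_id, lengths(object$marks)),
      member = unlist(object$marks), dimension = "mark"
    ),
    tibble(
      cluster_id = rep(object$cluster_id, lengths(object$cancer_types)),
      member = unlist(object$cancer_types), dimension = "cancer type"
    )
  )
  long$cluster_id <- factor(long$cluster_id, levels = rev(object$cluster_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$member, y = .data$cluster_id,
                                     fill = .data$dimension)) +
    ggplot2::geom_tile(colour = "white", show.legend = FALSE) +
    ggplot2::facet_grid(. ~ dimension, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Tri-cluster (by support)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
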