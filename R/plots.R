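#' Plot an evaluation report
#'
#' Horizontal bar chart of per-group CC accuracy (groups with more than
#' `min_group_n` gold occurrences), annotated with each group's record count;
#' dashed lines mark the overall CC and C rates.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  pg <- object$per_group
  pg$group <- factor(pg$group, levels = rev(pg$group))
  ggplot2::ggplot(pg, ggplot2::aes(x = .data$cc_accuracy, y = .data$group)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       hjust = -0.1, size = 3) +
    ggplot2::geom_vline(xintercept = object$cc_rate, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$c_rate, linetype = "dotted") +
    ggplot2::expand_limits(x = c(0, 105)) +
    ggplot2::labs(
      x = "CC accuracy (%)", y = "ICD-10 group",
      title = sprintf("Exact-code accuracy by disease group (n = %d)",
                      object$n),
      subtitle = sprintf("overall CC %.1f%% (dashed), C %.1f%% (dotted)",
                         object$cc_rate, object$c_rate)
    )
}

#' Plot the cosine-distance distribution of a prediction batch
#'
#' Histogram of query-to-nearest-centroid distances, optionally with the
#' acceptance threshold marked; a useful diagnostic when choosing an
#' operating threshold for rejection.
#'
#' @param predictions Tibble from [infer_codes()].
#' @param max_distance Optional threshold to mark.
#' @param bins Histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(predictions, max_distance = NULL,
                                       bins = 30) {
  stopifnot(is.data.frame(predictions), "distance" %in% names(predictions))
  df <- predictions[!is.na(predictions$distance), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "cosine distance to nearest centroid", y = "queries")
  if (!is.null(max_distance)) {
    p <- p + ggplot2::geom_vline(xintercept = max_distance,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot centroids in the first two principal components
#'
#' A quick look at the geometry of the annotated embedding space: one point
#' per ICD-10 code, coloured by 3-character group.
#'
#' @param object A `centroid_index`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot centroid_index
#' @export
autoplot.centroid_index <- function(object, ...) {
  pc <- prcomp(object$vectors, rank. = 2)
  df <- tibble::tibble(
    code = rownames(object$vectors),
    group = icd_group(rownames(object$vectors)),
    PC1 = pc$x[, 1],
    PC2 = pc$x[, 2]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = "ICD-10 centroids, first two principal components")
}
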