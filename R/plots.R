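# ggplot2 views of fitted objects. Each autoplot() returns a ggplot the
# caller can restyle.

#' @rdname shape_pca
#' @param object A fitted object.
#' @param axes Pair of component indices to plot.
#' @param colour Metadata column used for point colour (default `group`
#'   when present, otherwise none).
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, axes = c(1, 2), colour = NULL, ...) {
  stopifnot(length(axes) == 2)
  nm <- paste0("PC", axes)
  pct <- sprintf("%.1f%%", 100 * object$variance_proportions[axes])
  df <- object$scores
  colour <- colour %||% (if ("group" %in% names(df)) "group" else NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]],
                                        y = .data[[nm[2]]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::labs(x = paste0(nm[1], " (", pct[1], ")"),
                  y = paste0(nm[2], " (", pct[2], ")")) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  }
}

#' @rdname gpa
#' @param object A `gpa_fit`.
#' @param plane Which coordinate plane of the aligned shapes to draw
#'   (`"xy"`, `"xz"`, or `"yz"`).
#' @method autoplot gpa_fit
#' @export
autoplot.gpa_fit <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- match(strsplit(plane, "")[[1]], c("x", "y", "z"))
  df <- tidy.gpa_fit(object)
  cons <- tibble::tibble(a = object$consensus[, ax[1]],
                         b = object$consensus[, ax[2]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[coord_cols[ax[1]]]],
                                   y = .data[[coord_cols[ax[2]]]])) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_point(data = cons, ggplot2::aes(x = .data$a, y = .data$b),
                        colour = "red", size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = coord_cols[ax[1]], y = coord_cols[ax[2]],
                  title = "Aligned landmarks (red: consensus)") +
    ggplot2::theme_minimal()
}

#' @rdname pairwise_dfa
#' @param object A `dfa_fit`.
#' @method autoplot dfa_fit
#' @export
autoplot.dfa_fit <- function(object, ...) {
  ggplot2::ggplot(object$loo,
                  ggplot2::aes(x = .data$score, fill = .data$true)) +
    ggplot2::geom_histogram(bins = 20, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = paste0("discriminant score (> 0 assigned to ", object$group_a, ")"),
      fill = "true group",
      title = sprintf("LOO cross-validation: D = %.3f",
                      object$mahalanobis_distance)
    ) +
    ggplot2::theme_minimal()
}
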