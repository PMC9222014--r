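#' Plot a sagittal slice of a volume
#'
#' @param v a [volume()].
#' @param slice slice index along the sagittal axis.
#' @param mask optional [labelmask()]; lesion voxels are outlined in red.
#' @return a ggplot.
#' @export
plot_slice <- function(v, slice = 1L, mask = NULL) {
  sl <- slice_get(v$data, slice, v$slice_axis)
  df <- expand.grid(row = seq_len(nrow(sl)), col = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, slice %d", v$id, slice),
                  x = "column (anterior-posterior)",
                  y = "row (superior-inferior)")
  if (!is.null(mask)) {
    les <- slice_get(mask_role(mask, "lesion") + 0, slice, v$slice_axis)
    if (any(les > 0)) {
      dl <- df[as.vector(les) > 0, ]
      p <- p + ggplot2::geom_tile(data = dl, fill = NA, colour = "red",
                                  linewidth = 0.2)
    }
  }
  p
}

#' Plot per-unit SPARCC scores
#'
#' Bar chart of the per-unit SPARCC sub-scores, highlighting the six
#' selected units.
#'
#' @param object a `bme_sparcc` result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export autoplot.bme_sparcc
autoplot.bme_sparcc <- function(object, ...) {
  df <- object$per_unit
  df$unit <- factor(df$unit, levels = df$unit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               name = "selected") +
    ggplot2::labs(y = "unit score (max 18)",
                  title = sprintf("SPARCC total %d / 108", object$total)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot feature summaries
#'
#' Mean with SD error bars per feature and group/status, faceted by feature
#' family, from [summarize_features()] output.
#'
#' @param object tibble from [summarize_features()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_feature_summary <- function(object, ...) {
  by <- setdiff(names(object), c("feature", "n", "mean", "sd", "degenerate"))[1]
  df <- object
  df$family <- factor(substr(as.character(df$feature), 1, 1),
                      levels = c("i", "g", "f"),
                      labels = c("intensity", "gradient", "GLCM"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$mean,
                                   colour = .data[[by]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(y = "mean (SD)")
}
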