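#' Plot a persistence diagram
#'
#' Birth/death scatter with the diagonal; essential points are drawn at the
#' top of the panel with open triangles, extended points as squares.
#'
#' @param diagram Diagram tibble (may hold several dimensions).
#' @return A ggplot object.
#' @export
plot_diagram <- function(diagram) {
  fin <- diagram[is.finite(diagram$death), , drop = FALSE]
  ess <- diagram[is.infinite(diagram$death), , drop = FALSE]
  top <- max(c(fin$death, fin$birth, ess$birth, 1))
  ess$death <- top * 1.05
  p <- ggplot2::ggplot(fin, ggplot2::aes(x = .data$birth, y = .data$death,
                                         colour = factor(.data$dimension),
                                         shape = .data$kind)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(ordinary = 16, extended = 15)) +
    ggplot2::labs(x = "birth", y = "death", colour = "dimension",
                  shape = "kind") +
    ggplot2::theme_minimal()
  if (nrow(ess))
    p <- p + ggplot2::geom_point(data = ess, shape = 2, size = 2)
  p
}

#' Barcode view of a persistence diagram
#'
#' One horizontal bar per feature from birth to death; essential bars run to
#' the right edge.
#'
#' @param diagram Diagram tibble.
#' @return A ggplot object.
#' @export
plot_barcode <- function(diagram) {
  d <- diagram
  cap <- max(c(d$death[is.finite(d$death)], d$birth, 1)) * 1.1
  d$death_capped <- pmin(d$death, cap)
  d <- dplyr::arrange(d, .data$dimension, .data$birth)
  d$bar <- seq_len(nrow(d))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth,
                                       xend = .data$death_capped,
                                       y = .data$bar, yend = .data$bar,
                                       colour = factor(.data$dimension))) +
    ggplot2::labs(x = "filtration value", y = NULL, colour = "dimension") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Heatmap of a Wasserstein distance matrix
#'
#' @param object An `fc_distmat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_distmat <- function(object, ...) {
  mat <- object
  df <- tidy_distance_matrix(mat)
  df2 <- df; names(df2)[1:2] <- c("to", "from")
  long <- dplyr::bind_rows(df, df2,
                           tibble(from = rownames(mat), to = rownames(mat),
                                  distance = 0))
  long$from <- factor(long$from, levels = rownames(mat))
  long$to <- factor(long$to, levels = rownames(mat))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "Wasserstein\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a few ROI time series of a panel
#'
#' @param panel Panel tibble.
#' @param subject Subject id (default the first).
#' @param rois ROI ids (default the first three of the subject).
#' @return A ggplot object.
#' @export
plot_panel_series <- function(panel, subject = NULL, rois = NULL) {
  subject <- subject %||% panel$subject_id[1]
  sl <- panel[panel$subject_id == subject, , drop = FALSE]
  rois <- rois %||% head(sl$roi_id, 3)
  sl <- sl[sl$roi_id %in% rois, , drop = FALSE]
  long <- tidyr::pivot_longer(sl, dplyr::all_of(time_cols(sl)),
                              names_to = "t", values_to = "value")
  long$t <- as.integer(sub("^t", "", long$t))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$roi_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timepoint", y = "signal", colour = "ROI",
                  title = subject) +
    ggplot2::theme_minimal()
}
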