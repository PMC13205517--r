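# ggplot2 views of the result objects. Every figure has a tabular twin
# (tidy()/export_topoplot_data()/windowed tibble), so downstream use never
# depends on graphics.

#' @describeIn susy Plot method: mean real vs surrogate Fisher-Z per
#'   segment with 95% confidence ribbons.
#' @method autoplot susy_result
#' @export
autoplot.susy_result <- function(object, ...) {
  seg <- susy_summarise(object, "segment")
  long <- dplyr::bind_rows(
    dplyr::transmute(seg, t_mid = .data$t_mid, series = "real",
                     mean = .data$mean_z_real, se = .data$se_z_real),
    dplyr::transmute(seg, t_mid = .data$t_mid, series = "surrogate",
                     mean = .data$mean_z_surrogate,
                     se = .data$se_z_surrogate)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_mid, .data$mean,
                                     colour = .data$series,
                                     fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                      ymax = .data$mean + 1.96 * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "segment midpoint (s)", y = "Fisher Z",
                  colour = NULL, fill = NULL,
                  title = sprintf("Dyadic synchrony (%s)", object$channel)) +
    ggplot2::theme_minimal()
}

#' @describeIn corrca_fit Plot method: sliding-window ISC traces of the
#'   leading components.
#' @method autoplot corrca_result
#' @export
autoplot.corrca_result <- function(object, components = 1:3, ...) {
  if (is.null(object$windowed)) {
    abort("no windowed ISC trace stored; fit on rate-carrying input")
  }
  df <- dplyr::filter(object$windowed,
                      .data$component %in% components)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$isc,
                                   colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window centre (s)", y = "ISC",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Facial topography of forward-model loadings
#'
#' Draws each landmark at its template position, coloured and sized by its
#' forward-model loading, one panel per component. Warm colours mark
#' landmarks contributing strongly to the component's shared activity.
#'
#' @param result A `corrca_result` fitted on 68 landmark features.
#' @param components Components to draw (default first 3).
#' @param template A [face_template()].
#' @return A ggplot object.
#' @export
plot_face_topography <- function(result, components = NULL,
                                 template = face_template()) {
  components <- components %||% seq_len(min(3, ncol(result$A)))
  df <- export_topoplot_data(result, template, components)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, -.data$y,
                                   colour = .data$loading,
                                   size = abs(.data$loading))) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey85",
                                    high = "#B2182B") +
    ggplot2::facet_wrap(~ component,
                        labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::guides(size = "none") +
    ggplot2::labs(x = NULL, y = NULL, colour = "loading") +
    ggplot2::theme_void()
}
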