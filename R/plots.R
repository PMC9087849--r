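raster_df <- function(arr) {
  H <- dim(arr)[1]; W <- dim(arr)[2]
  tibble(row = rep(seq_len(H) - 1L, W),
         col = rep(seq_len(W) - 1L, each = H),
         fill = grDevices::rgb(as.vector(arr[, , 1]), as.vector(arr[, , 2]),
                               as.vector(arr[, , 3]), maxColorValue = 255))
}

gg_raster <- function(df, title = NULL) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.plot_image <- function(object, ...) {
  gg_raster(raster_df(object$pixels), title = object$plot_id)
}

#' @export
autoplot.synthetic_scene <- function(object, ...) {
  gg_raster(raster_df(object$image$pixels), title = object$image$plot_id) +
    ggplot2::geom_point(data = object$boll_truth,
                        ggplot2::aes(x = .data$center_col, y = .data$center_row),
                        shape = 1, color = "red", size = 2)
}

#' @export
autoplot.boll_count_result <- function(object, ...) {
  gg_raster(raster_df(label_map_rgb(object)$pixels),
            title = sprintf("%d boll(s)", object$boll_count))
}

#' @export
autoplot.regression_report <- function(object, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "red", linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$outlier), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "Actual boll count", y = "Estimated boll count",
                  subtitle = sprintf("R² = %.3f, NRMSE = %.3f, MAPE = %.1f%%",
                                     object$r_squared, object$nrmse,
                                     object$mape_pct)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.genotype_summary <- function(object, ...) {
  d <- dplyr::mutate(object$summary,
                     genotype = factor(.data$genotype, levels = .data$genotype))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + dplyr::coalesce(.data$se, 0)),
                       vjust = -0.6, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Mean predicted boll count",
                  subtitle = sprintf("ANOVA F(%d, %d) = %.3f, p = %.3g",
                                     object$anova$df_between,
                                     object$anova$df_within,
                                     object$anova$f, object$anova$p)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
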