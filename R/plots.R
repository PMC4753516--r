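# ggplot2 visualization methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-slice fractal dimensions
#'
#' @param object An `fd_result` from [fd_stack()].
#' @param ... Unused.
#' @return A ggplot: per-slice FD profile with the maximal apical FD marked.
#' @export
autoplot.fd_result <- function(object, ...) {
  maxfd <- attr(object, "max_apical_fd")
  n <- nrow(object)
  apical_start <- n - ceiling(n / 2) + 1L
  ggplot2::ggplot(object, ggplot2::aes(x = .data$slice, y = .data$fd)) +
    ggplot2::annotate("rect", xmin = apical_start - 0.5, xmax = n + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = maxfd, linetype = "dashed",
                        color = "steelblue") +
    ggplot2::labs(x = "slice (base → apex)", y = "fractal dimension",
                  title = sprintf("maximal apical FD = %.3f", maxfd)) +
    ggplot2::theme_minimal()
}

#' Plot the box-counting fit for one slice
#'
#' @param fit A [slice_fd()] result.
#' @return A ggplot of ln(count) against ln(scale) with the OLS line.
#' @export
plot_box_count_fit <- function(fit) {
  df <- fit$log_pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_scale, y = .data$log_count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "steelblue", linewidth = 0.6) +
    ggplot2::labs(x = "ln(scale)", y = "ln(count)",
                  title = sprintf("FD = %.3f (R² = %.4f)", fit$fd,
                                  fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot per-slice ECV values
#'
#' @param object An `ecv_result` from [ecv_subject()].
#' @param ... Unused.
#' @return A ggplot of per-slice ECV with the subject mean; excluded slices
#'   are marked.
#' @export
autoplot.ecv_result <- function(object, ...) {
  subj <- attr(object, "subject_ecv_pct")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$slice, y = .data$ecv_pct,
                                       shape = .data$included)) +
    ggplot2::geom_hline(yintercept = subj, linetype = "dashed",
                        color = "indianred") +
    ggplot2::geom_point(size = 3, na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "slice", y = "ECV (%)",
                  title = sprintf("subject ECV = %.1f%%", subj)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a tertile-coded outcome regression
#'
#' @param object A `tpm_regression` from [fit_outcome_model()].
#' @param ... Unused.
#' @return A ggplot forest plot of multivariate coefficients with 95% CIs;
#'   associations passing the dual univariate-and-multivariate rule are
#'   highlighted.
#' @export
autoplot.tpm_regression <- function(object, ...) {
  df <- object$table
  df$label <- paste(df$term, df$level, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   color = .data$final_sig)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "indianred",
                                           `FALSE` = "grey50"),
                                name = "dual-rule significant") +
    ggplot2::labs(x = sprintf("coefficient on %s (95%% CI)", object$outcome),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a segmentation mask on an image slice
#'
#' @param slice Numeric image matrix.
#' @param mask Logical matrix (e.g. TPM mask or border).
#' @param title Optional plot title.
#' @return A ggplot raster with the mask outlined in color.
#' @export
plot_segmentation <- function(slice, mask, title = NULL) {
  df <- expand.grid(x = seq_len(nrow(slice)), y = seq_len(ncol(slice)))
  df$intensity <- as.vector(slice)
  df$mask <- as.vector(as_binary_matrix(mask))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = df[df$mask, ], color = "red", size = 0.2) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
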