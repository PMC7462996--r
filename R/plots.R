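#' Plot a label image
#'
#' Renders a `labeled_sheet` with one fill per cell (hues recycled so
#' neighbouring cells contrast) and background in white.
#'
#' @param sheet A `labeled_sheet`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sheet <- function(sheet, ...) {
  stopifnot(inherits(sheet, "labeled_sheet"))
  labs <- sheet$labels
  df <- tibble::tibble(
    x = rep(seq_len(ncol(labs)), each = nrow(labs)),
    y = rep(seq_len(nrow(labs)), times = ncol(labs)),
    label = as.vector(labs)
  )
  df$fill <- ifelse(df$label == 0, NA, (df$label * 7) %% 20)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$fill))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_d(na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%d cells%s", n_cells(sheet),
                      if (!is.na(sheet$true_ter)) {
                        sprintf(", true TER %.0f Ω·cm²", sheet$true_ter)
                      } else ""),
      x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.labeled_sheet <- function(object, ...) plot_sheet(object, ...)

#' @describeIn evaluate_ter_model Autoplot method: observed-vs-predicted
#'   scatter with the identity line (regression) or per-sample high-class
#'   probability against observed TER with the 0.5 decision line
#'   (discrimination).
#' @param object A `ter_eval`.
#' @param ... Unused.
#' @export
autoplot.ter_eval <- function(object, ...) {
  ps <- object$per_sample
  if (object$kind == "regression") {
    ggplot2::ggplot(ps, ggplot2::aes(x = .data$observed_ter,
                                     y = .data$predicted_ter)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(
        title = sprintf("TER prediction (%s), RMSE = %.1f Ω·cm²",
                        object$scheme, object$metrics[["rmse"]]),
        x = "measured TER (Ω·cm²)",
        y = "predicted TER (Ω·cm²)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(ps, ggplot2::aes(x = .data$observed_ter,
                                     y = .data$probability,
                                     colour = .data$observed_class)) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c(high = "#c0392b", low = "#2980b9")) +
      ggplot2::labs(
        title = sprintf("TER discrimination (%s), accuracy = %.2f",
                        object$scheme, object$metrics[["accuracy"]]),
        x = "measured TER (Ω·cm²)",
        y = "P(high TER)", colour = "observed") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn fit_ter_regression Autoplot method: standardized
#'   coefficients of the 16 explanatory variables, zero-weight variables
#'   greyed out.
#' @param object A `ter_model`.
#' @param ... Unused.
#' @export
autoplot.ter_model <- function(object, ...) {
  df <- tibble::tibble(
    term = factor(object$variable_names, levels = rev(object$variable_names)),
    estimate = unname(object$coef_std)
  )
  df$selected <- df$estimate != 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c3e50", `FALSE` = "grey80")) +
    ggplot2::labs(
      title = sprintf("%s model: standardized LASSO weights", object$kind),
      x = "standardized coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
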