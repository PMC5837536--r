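# Forest-style bias component and negative-control plots.

.forest_theme <- function() {
  ggplot2::theme_bw() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   legend.position = "bottom")
}

#' Bias component forest plot
#'
#' One row per covariate, with the conventional (OLS) bias component as a
#' filled square and the IV bias component as an open circle, horizontal
#' whiskers for the cluster-robust confidence intervals when
#' \code{show_ci = TRUE}, and a vertical reference line at zero.  Without
#' confidence intervals such plots routinely mislead -- the IV components
#' are noisier and look systematically larger -- which is exactly what the
#' \code{show_ci = FALSE} variant demonstrates.  Row order follows the
#' report; no sorting is applied.
#'
#' @param report a \code{\link{balance_table}} result.
#' @param show_ci draw CI whiskers.
#' @param scale_binary report binary covariates as risk differences x 100.
#' @param title plot title.
#' @return a \code{ggplot} object.
#' @export
bias_plot <- function(report, show_ci = TRUE, scale_binary = FALSE,
                      title = "Bias component plot") {
  stopifnot(inherits(report, "balance_report"))
  df <- as.data.frame(report, scale_binary = scale_binary)
  df <- df[!df$degenerate, , drop = FALSE]
  if (nrow(df) == 0L)
    .stop_validation("all covariates in the report are degenerate; nothing to plot")
  long <- rbind(
    data.frame(covariate = df$covariate, analysis = "Conventional (OLS)",
               estimate = df$ols_estimate, low = df$ols_low, high = df$ols_high),
    data.frame(covariate = df$covariate, analysis = "Instrumental variable",
               estimate = df$iv_estimate, low = df$iv_low, high = df$iv_high))
  long$covariate <- factor(long$covariate, levels = rev(df$covariate))
  long$analysis <- factor(long$analysis,
                          levels = c("Conventional (OLS)", "Instrumental variable"))
  pos <- ggplot2::position_dodge(width = 0.6)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$estimate, y = .data$covariate,
    shape = .data$analysis, group = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40")
  if (show_ci)
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      height = 0.25, position = pos)
  p + ggplot2::geom_point(size = 2.5, position = pos) +
    ggplot2::scale_shape_manual(values = c("Conventional (OLS)" = 15,
                                           "Instrumental variable" = 1)) +
    ggplot2::labs(title = title, x = "Bias component", y = NULL, shape = NULL) +
    .forest_theme()
}

#' Negative-control forest plot
#'
#' For a single negative-control outcome result: the conventional and IV
#' estimates with whiskers.  For a negative-control population report: one
#' row per outcome with the instrument-outcome association and its CI.
#' A zero reference line is always drawn.
#'
#' @param result an \code{nc_outcome_result} or \code{nc_report}.
#' @param title plot title.
#' @return a \code{ggplot} object.
#' @export
nc_plot <- function(result, title = NULL) {
  if (inherits(result, "nc_outcome_result")) {
    df <- as.data.frame(result)
    df$label <- c("Conventional (OLS)", "Instrumental variable")
    shp <- c("Conventional (OLS)" = 15, "Instrumental variable" = 1)
    if (is.null(title))
      title <- sprintf("Negative control outcome: %s", result$outcome)
  } else if (inherits(result, "nc_report")) {
    df <- as.data.frame(result)
    df$label <- df$outcome
    shp <- NULL
    if (is.null(title))
      title <- "Negative control population: instrument-outcome associations"
  } else {
    .stop_config("nc_plot expects an nc_outcome_result or nc_report")
  }
  df <- df[!df$degenerate & !is.na(df$estimate), , drop = FALSE]
  if (nrow(df) == 0L) .stop_validation("nothing non-degenerate to plot")
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2)
  if (!is.null(shp)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$label), size = 2.5) +
      ggplot2::scale_shape_manual(values = shp, guide = "none")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(title = title, x = "Estimate", y = NULL) + .forest_theme()
}

#' Save a plot as SVG or PNG
#'
#' SVG is the primary output (text-based and deterministic for fixed
#' input); PNG is supported for convenience.  The format is taken from the
#' file extension.
#'
#' @param plot a \code{ggplot} object.
#' @param path output path ending in \code{.svg} or \code{.png}.
#' @param width,height device size in inches.
#' @return the path, invisibly.
#' @export
save_plot <- function(plot, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else {
    .stop_config(sprintf("unsupported plot format '.%s' (use .svg or .png)", ext))
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
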