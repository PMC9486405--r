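#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   geom_errorbarh geom_vline labs theme_minimal scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_fit` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of the survival step functions by group.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$survival,
                     colour = .data$group)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Time (months)", y = "Overall survival", colour = NULL) +
    theme_minimal()
}

#' Plot the cross-validation agreement curve of a classifier fit
#'
#' @param object A `reduced_classifier_fit` from
#'   [build_reduced_classifier()].
#' @param ... Unused.
#' @return A ggplot of mean CV agreement against model size.
#' @method autoplot reduced_classifier_fit
#' @export
autoplot.reduced_classifier_fit <- function(object, ...) {
  ggplot(object$cv_report, aes(x = .data$size, y = .data$mean_agreement)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$chosen_size, linetype = "dashed") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Model size (genes)", y = "Mean CV agreement with gold calls") +
    theme_minimal()
}

#' Forest plot of hazard ratios
#'
#' @param object A `cox_fit` tibble from [cox_fit()].
#' @param ... Unused.
#' @return A ggplot forest plot (log-scaled hazard ratios with Wald CIs).
#' @method autoplot cox_fit
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- tidy(object)
  df$label <- paste0(df$term, ": ", df$level, " vs ", df$reference)
  ggplot(df, aes(x = .data$hr, y = .data$label)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "Hazard ratio (log scale)", y = NULL) +
    theme_minimal()
}
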