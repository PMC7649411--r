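#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation result
#'
#' @param x an `evaluation_result`.
#' @param ... unused.
#' @return A tibble with one row per animal: `id`, `set`, `gebv`, `pev`,
#'   `accuracy`, `tbv`.
#' @export
tidy.evaluation_result <- function(x, ...) x$animals

#' One-row summary of an evaluation result
#'
#' @param x an `evaluation_result`.
#' @param ... unused.
#' @return A tibble with `method`, `w`, `tp_size`, `n_validation`,
#'   `mean_validation_accuracy`, `cor_gebv_tbv` (empirical correlation of
#'   predicted and true breeding values in the validation set).
#' @export
glance.evaluation_result <- function(x, ...) {
  v <- x$animals[x$animals$set == "validation", ]
  tibble::tibble(method = x$method, w = x$w,
                 tp_size = x$design$tp_size,
                 n_validation = nrow(v),
                 mean_validation_accuracy = x$mean_validation_accuracy,
                 cor_gebv_tbv = stats::cor(v$gebv, v$tbv))
}

#' @export
tidy.scenario_report <- function(x, ...) x$cells

#' @export
glance.scenario_report <- function(x, ...) x$summary

#' Plot scenario accuracies
#'
#' Mean validation accuracy against training-population size, one line per
#' evaluation method, faceted by heritability and selection method.
#'
#' @param object a `scenario_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bad_arg("ggplot2 is required for plotting")
  s <- object$summary
  s$label <- ifelse(is.na(s$w), s$method, sprintf("ssGBLUP_%.2f", s$w))
  ggplot2::ggplot(s[s$pe_rate == 0, ],
                  ggplot2::aes(x = tp_size, y = mean, colour = label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(h2 ~ selection, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "training population size",
                  y = "mean validation accuracy", colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scenario_report
#' @param report a `scenario_report`.
#' @export
plot_accuracy <- function(report, ...) autoplot.scenario_report(report, ...)
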