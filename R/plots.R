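# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a metrics report into one row per metric
#'
#' @param x A `ich_metrics` object.
#' @param ... Unused.
#' @return Tibble `metric`, `estimate`, `ci_low`, `ci_high`, `n`.
#' @method tidy ich_metrics
#' @export
tidy.ich_metrics <- function(x, ...) {
  rows <- x$binary |>
    select("metric", "estimate", "ci_low", "ci_high") |>
    mutate(n = x$binary$denominator)
  rows <- bind_rows(
    rows,
    x$per_plan |>
      mutate(metric = paste0("accuracy_", tolower(sub("PLAN_", "plan_", .data$plan)))) |>
      select("metric", "estimate", "ci_low", "ci_high") |>
      mutate(n = x$per_plan$denominator),
    tibble(
      metric = "fine_accuracy", estimate = x$fine_accuracy,
      ci_low = NA_real_, ci_high = NA_real_, n = x$n
    ),
    tibble(
      metric = "kappa", estimate = x$kappa$kappa,
      ci_low = x$kappa$ci_low, ci_high = x$kappa$ci_high, n = x$kappa$n
    )
  )
  if (!is.null(x$roc)) {
    rows <- bind_rows(rows, tibble(
      metric = "auc", estimate = x$roc$auc,
      ci_low = x$roc$ci_low, ci_high = x$roc$ci_high, n = x$n
    ))
  }
  if (!is.null(x$kappa_rater2)) {
    rows <- bind_rows(rows, tibble(
      metric = "kappa_rater2", estimate = x$kappa_rater2$kappa,
      ci_low = x$kappa_rater2$ci_low, ci_high = x$kappa_rater2$ci_high,
      n = x$kappa_rater2$n
    ))
  }
  rows
}

#' One-row summary of a metrics report
#'
#' @inheritParams tidy.ich_metrics
#' @return A one-row tibble with the headline numbers.
#' @method glance ich_metrics
#' @export
glance.ich_metrics <- function(x, ...) {
  b <- setNames(x$binary$estimate, x$binary$metric)
  tibble(
    accuracy = b[["accuracy"]],
    sensitivity = b[["sensitivity"]],
    specificity = b[["specificity"]],
    ppv = b[["ppv"]], npv = b[["npv"]],
    fine_accuracy = x$fine_accuracy,
    auc = if (!is.null(x$roc)) x$roc$auc else NA_real_,
    kappa = x$kappa$kappa,
    n = x$n
  )
}

#' @method tidy ich_roc
#' @export
tidy.ich_roc <- function(x, ...) x$curve

#' @method glance ich_roc
#' @export
glance.ich_roc <- function(x, ...) {
  tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#'
#' @param object A `ich_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ich_roc
#' @export
autoplot.ich_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf(
        "ROC, AUC %.3f (95%% CI %.3f-%.3f)",
        object$auc, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a metrics report as point-ranges
#'
#' @param object A `ich_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ich_metrics
#' @export
autoplot.ich_metrics <- function(object, ...) {
  df <- tidy.ich_metrics(object)
  df <- df[!is.na(df$estimate), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$metric, .data$estimate), y = .data$estimate
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      colour = "#2c7fb8"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Estimate (95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of a decision run by plan
#'
#' @param decisions Decisions tibble from [classify_plan()].
#' @param table The logic table (for cut-point reference lines).
#' @return A ggplot.
#' @export
plot_score_distribution <- function(decisions, table = default_logic_table()) {
  ggplot2::ggplot(decisions, ggplot2::aes(x = .data$weighted_score, fill = .data$plan)) +
    ggplot2::geom_histogram(binwidth = 1 / table$normalizer, boundary = 0) +
    ggplot2::geom_vline(
      xintercept = c(table$cut_low, table$cut_high),
      linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::labs(x = "Weighted score", y = "Cases", fill = "Plan") +
    ggplot2::theme_minimal()
}
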