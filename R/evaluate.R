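# Evaluation suite: coarse (surgery vs non-surgery) confusion counts with
# Plan I as the positive class, proportion metrics with 95% CIs, ROC/AUC on
# the weighted score, per-plan accuracy over the full 3x3 table, and Cohen's
# kappa between two plan assignments.

z975 <- function() qnorm(0.975)

#' Confusion counts between predicted and gold plans
#'
#' Coarse 2x2 counts with Plan I (emergency surgery) as the positive class,
#' plus the full 3x3 table over Plans I/IIA/IIB (rows gold, columns
#' predicted) for per-plan accuracy.
#'
#' @param predicted,gold Equal-length plan vectors.
#' @return A `ich_confusion` list: `tp`, `fp`, `tn`, `fn`, `table3`, `n`.
#' @export
confusion_counts <- function(predicted, gold) {
  if (length(predicted) != length(gold) || length(gold) == 0) {
    abort("predicted and gold must be non-empty vectors of equal length")
  }
  pc <- plan_coarse(predicted)
  gc <- plan_coarse(gold)
  structure(
    list(
      tp = sum(pc == "PLAN_I" & gc == "PLAN_I"),
      fp = sum(pc == "PLAN_I" & gc == "PLAN_II"),
      tn = sum(pc == "PLAN_II" & gc == "PLAN_II"),
      fn = sum(pc == "PLAN_II" & gc == "PLAN_I"),
      table3 = table(
        gold = factor(gold, levels = plan_levels),
        predicted = factor(predicted, levels = plan_levels)
      ),
      n = length(gold)
    ),
    class = "ich_confusion"
  )
}

#' @export
print.ich_confusion <- function(x, ...) {
  cat("<ich_confusion> n =", x$n, "\n")
  cat(sprintf("  coarse: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  print(x$table3)
  invisible(x)
}

proportion_ci <- function(p, m, method = "wald") {
  if (m == 0 || is.na(p)) return(c(NA_real_, NA_real_))
  if (method == "wilson") {
    z <- z975()
    centre <- (p + z^2 / (2 * m)) / (1 + z^2 / m)
    half <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
    c(max(0, centre - half), min(1, centre + half))
  } else {
    half <- z975() * sqrt(p * (1 - p) / m)
    c(max(0, p - half), min(1, p + half))
  }
}

#' Binary classification metrics with 95% confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from the coarse counts,
#' with normal-approximation (Wald, the default) or Wilson intervals on each
#' metric's own denominator. A zero denominator reports the metric as
#' undefined (`NA`), never as 0.
#'
#' @param cm A `ich_confusion`.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return Tibble `metric`, `estimate`, `ci_low`, `ci_high`, `denominator`.
#' @export
binary_metrics <- function(cm, ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(cm, "ich_confusion"))
  defs <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    accuracy = c(cm$tp + cm$tn, cm$n),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn)
  )
  bind_rows(lapply(names(defs), function(mname) {
    num <- defs[[mname]][1]
    den <- defs[[mname]][2]
    p <- if (den > 0) num / den else NA_real_
    ci <- proportion_ci(p, den, ci_method)
    tibble(
      metric = mname, estimate = p,
      ci_low = ci[1], ci_high = ci[2], denominator = den
    )
  }))
}

#' Per-plan accuracy from the 3x3 table
#'
#' Recall of each plan: correctly predicted in-plan cases over gold in-plan
#' cases, with a 95% CI.
#'
#' @inheritParams binary_metrics
#' @return Tibble `plan`, `estimate`, `ci_low`, `ci_high`, `denominator`.
#' @export
per_plan_accuracy <- function(cm, ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  t3 <- cm$table3
  bind_rows(lapply(plan_levels, function(pl) {
    den <- sum(t3[pl, ])
    p <- if (den > 0) t3[pl, pl] / den else NA_real_
    ci <- proportion_ci(p, den, ci_method)
    tibble(plan = pl, estimate = p, ci_low = ci[1], ci_high = ci[2], denominator = den)
  }))
}

#' ROC curve and AUC on a continuous score
#'
#' The positive class is coarse Plan I. The curve is swept over every
#' distinct score threshold (descending); the AUC is the area under it by
#' the trapezoidal rule, which equals the Mann-Whitney pair statistic with
#' ties counted 1/2. The 95% CI uses the Hanley-McNeil standard error.
#'
#' @param scores Numeric vector (higher = more surgical).
#' @param gold Plan vector of the same length.
#' @return A `ich_roc` list: `auc`, `ci_low`, `ci_high`, `se`, `curve`
#'   (tibble `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, gold) {
  if (length(scores) != length(gold) || length(gold) == 0) {
    abort("scores and gold must be non-empty vectors of equal length")
  }
  pos <- plan_coarse(gold) == "PLAN_I"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined: both classes must be present")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & pos) / n1, double(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !pos) / n0, double(1))
  curve <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0))
  structure(
    list(
      auc = auc,
      ci_low = max(0, auc - z975() * se), ci_high = min(1, auc + z975() * se),
      se = se, curve = curve, n_pos = n1, n_neg = n0
    ),
    class = "ich_roc"
  )
}

#' @export
print.ich_roc <- function(x, ...) {
  cat(sprintf(
    "<ich_roc> AUC %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
    x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' ROC score of a decision table
#'
#' The continuous output fed to the ROC: the expert module's weighted score,
#' with mandate-fired cases lifted to 1.0 so they rank above every
#' score-based decision.
#'
#' @param decisions Decisions tibble from [classify_plan()].
#' @return Numeric vector.
#' @export
roc_score <- function(decisions) {
  ifelse(decisions$mandated, 1.0, decisions$weighted_score)
}

#' Cohen's kappa between two plan assignments
#'
#' Chance-corrected agreement on the fine 3-level plan labels, with a 95%
#' CI from the large-sample standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`. Perfect observed agreement
#' returns kappa 1 (including the degenerate single-category case).
#'
#' @param rater_a,rater_b Equal-length plan vectors.
#' @return A one-row tibble: `kappa`, `ci_low`, `ci_high`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b) || length(rater_a) == 0) {
    abort("rater vectors must be non-empty and of equal length")
  }
  n <- length(rater_a)
  levels <- union(plan_levels, union(unique(rater_a), unique(rater_b)))
  tab <- table(factor(rater_a, levels), factor(rater_b, levels)) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (p_o >= 1 - 1e-12) {
    return(tibble(
      kappa = 1, ci_low = 1, ci_high = 1,
      p_observed = 1, p_expected = p_e, n = n
    ))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  tibble(
    kappa = kappa,
    ci_low = max(-1, kappa - z975() * se), ci_high = min(1, kappa + z975() * se),
    p_observed = p_o, p_expected = p_e, n = n
  )
}

#' Evaluate a decision run against the gold standard
#'
#' Joins decisions and gold by `record_id` (records missing from either side
#' are dropped with a message), then emits the full metric suite: coarse
#' confusion counts and binary metrics, the 3x3 table and per-plan accuracy,
#' ROC/AUC on the weighted score, and Cohen's kappa of the decisions against
#' the gold plans (plus against a second rater when supplied).
#'
#' @param decisions Decisions tibble (from [classify_plan()] or
#'   [read_decisions()]) with a `record_id` column.
#' @param gold Gold tibble with `record_id`, `gold_plan`.
#' @param rater2 Optional tibble `record_id`, `plan` of a second rater.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return A `ich_metrics` object.
#' @export
evaluate_run <- function(decisions, gold, rater2 = NULL,
                         ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  joined <- dplyr::inner_join(
    decisions, select(gold, "record_id", "gold_plan"),
    by = "record_id"
  )
  if (nrow(joined) == 0) abort("no records shared between decisions and gold")
  dropped <- nrow(decisions) + nrow(gold) - 2 * nrow(joined)
  if (dropped > 0) {
    message(dropped, " record(s) missing from one side were dropped from the join")
  }
  cm <- confusion_counts(joined$plan, joined$gold_plan)
  auc <- tryCatch(
    roc_auc(roc_score(joined), joined$gold_plan),
    error = function(e) NULL
  )
  kappa2 <- NULL
  if (!is.null(rater2)) {
    j2 <- dplyr::inner_join(
      joined,
      dplyr::rename(select(rater2, "record_id", "plan"), rater2_plan = "plan"),
      by = "record_id"
    )
    if (nrow(j2) > 0) kappa2 <- cohens_kappa(j2$plan, j2$rater2_plan)
  }
  structure(
    list(
      confusion = cm,
      binary = binary_metrics(cm, ci_method),
      per_plan = per_plan_accuracy(cm, ci_method),
      fine_accuracy = sum(diag(cm$table3)) / cm$n,
      roc = auc,
      kappa = cohens_kappa(joined$plan, joined$gold_plan),
      kappa_rater2 = kappa2,
      n = nrow(joined),
      n_dropped = dropped
    ),
    class = "ich_metrics"
  )
}

#' @export
print.ich_metrics <- function(x, ...) {
  cat("<ich_metrics> n =", x$n, "\n")
  b <- x$binary
  for (i in seq_len(nrow(b))) {
    cat(sprintf(
      "  %-11s %s\n", b$metric[i],
      if (is.na(b$estimate[i])) {
        "undefined"
      } else {
        sprintf("%.4f (%.4f-%.4f)", b$estimate[i], b$ci_low[i], b$ci_high[i])
      }
    ))
  }
  cat(sprintf("  fine (3-plan) accuracy %.4f\n", x$fine_accuracy))
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC %.4f (%.4f-%.4f)\n", x$roc$auc, x$roc$ci_low, x$roc$ci_high))
  }
  cat(sprintf(
    "  kappa vs gold %.4f (%.4f-%.4f)\n",
    x$kappa$kappa, x$kappa$ci_low, x$kappa$ci_high
  ))
  if (!is.null(x$kappa_rater2)) {
    cat(sprintf(
      "  kappa vs rater2 %.4f (%.4f-%.4f)\n",
      x$kappa_rater2$kappa, x$kappa_rater2$ci_low, x$kappa_rater2$ci_high
    ))
  }
  invisible(x)
}

#' Write a metrics report as CSV + JSON mirror
#'
#' @param metrics A `ich_metrics`.
#' @param dir Output directory (created if needed). Writes `metrics.csv`,
#'   `metrics.json`, and `confusion3.csv`.
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- tidy.ich_metrics(metrics)
  utils::write.csv(long, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      n = metrics$n,
      metrics = long,
      confusion = list(
        tp = metrics$confusion$tp, fp = metrics$confusion$fp,
        tn = metrics$confusion$tn, fn = metrics$confusion$fn
      )
    ),
    file.path(dir, "metrics.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(
    as.data.frame.matrix(metrics$confusion$table3),
    file.path(dir, "confusion3.csv")
  )
  invisible(dir)
}
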