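test_that("confusion counts collapse to the coarse 2x2 with Plan I positive", {
  cm <- confusion_counts(c("PLAN_I", "PLAN_IIA", "PLAN_IIB"), c("PLAN_I", "PLAN_IIA", "PLAN_IIB"))
  expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn), c(1L, 2L, 0L, 0L))
  cm2 <- confusion_counts("PLAN_I", "PLAN_IIB")
  expect_identical(c(cm2$tp, cm2$tn, cm2$fp, cm2$fn), c(0L, 0L, 1L, 0L))
  cm3 <- confusion_counts(
    c("PLAN_I", "PLAN_I", "PLAN_IIA", "PLAN_IIB"),
    c("PLAN_I", "PLAN_IIA", "PLAN_IIA", "PLAN_I")
  )
  expect_identical(c(cm3$tp, cm3$fp, cm3$tn, cm3$fn), c(1L, 1L, 1L, 1L))
  expect_error(confusion_counts("PLAN_I", c("PLAN_I", "PLAN_I")), "equal length")
})

test_that("binary metrics match hand arithmetic and report undefined on empty denominators", {
  cm <- confusion_counts(
    rep(c("PLAN_I", "PLAN_IIB", "PLAN_I", "PLAN_IIB"), c(45, 5, 10, 40)),
    rep(c("PLAN_I", "PLAN_I", "PLAN_IIB", "PLAN_IIB"), c(45, 5, 10, 40))
  )
  m <- binary_metrics(cm)
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["sensitivity"]], 0.90)
  expect_equal(est[["specificity"]], 0.80)
  expect_equal(est[["accuracy"]], 0.85)
  expect_equal(est[["ppv"]], 45 / 55, tolerance = 1e-12)
  expect_equal(est[["npv"]], 40 / 45, tolerance = 1e-12)
  # Wald CI by hand for sensitivity: p +/- 1.96 sqrt(p(1-p)/50)
  half <- qnorm(0.975) * sqrt(0.9 * 0.1 / 50)
  expect_equal(m$ci_low[m$metric == "sensitivity"], 0.9 - half, tolerance = 1e-12)
  expect_true(all(m$ci_low <= m$estimate & m$estimate <= m$ci_high))

  perfect <- confusion_counts(rep(c("PLAN_I", "PLAN_IIB"), each = 50),
    rep(c("PLAN_I", "PLAN_IIB"), each = 50))
  expect_true(all(binary_metrics(perfect)$estimate == 1))

  no_pos <- confusion_counts(rep("PLAN_IIB", 4), rep("PLAN_IIB", 4))
  m0 <- binary_metrics(no_pos)
  expect_true(is.na(m0$estimate[m0$metric == "sensitivity"]))
  expect_true(is.na(m0$estimate[m0$metric == "ppv"]))
  expect_false(is.na(m0$estimate[m0$metric == "accuracy"]))
})

test_that("AUC handles perfect separation, total ties, and the worked example", {
  expect_equal(roc_auc(c(.9, .8, .2, .1), c("PLAN_I", "PLAN_I", "PLAN_IIA", "PLAN_IIB"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("PLAN_I", "PLAN_IIB"), 3))$auc, 0.5)
  r <- roc_auc(c(0.9, 0.7, 0.7, 0.2), c("PLAN_I", "PLAN_I", "PLAN_IIA", "PLAN_IIB"))
  expect_equal(r$auc, 0.875, tolerance = 1e-15)
  expect_error(roc_auc(c(.1, .2), c("PLAN_I", "PLAN_I")), "both classes")
  # curve endpoints
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-count brute force", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(4:200, 1)
    gold <- sample(c("PLAN_I", "PLAN_IIA", "PLAN_IIB"), n, replace = TRUE)
    if (length(unique(plan_coarse(gold))) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 8), 1)) # coarse rounding forces ties
    got <- roc_auc(scores, gold)$auc
    want <- auc_pair_oracle(scores, gold)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil interval brackets the point AUC and shrinks with n", {
  set.seed(303)
  make <- function(n) {
    gold <- rep(c("PLAN_I", "PLAN_IIB"), each = n / 2)
    scores <- c(rnorm(n / 2, 0.7, 0.15), rnorm(n / 2, 0.4, 0.15))
    roc_auc(scores, gold)
  }
  small <- make(40)
  big <- make(400)
  expect_true(small$ci_low <= small$auc && small$auc <= small$ci_high)
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("Cohen's kappa matches hand arithmetic, relabeling, and the degenerate cases", {
  ident <- rep(c("PLAN_I", "PLAN_IIA", "PLAN_IIB"), 4)
  expect_identical(cohens_kappa(ident, ident)$kappa, 1)
  # 2x2 agreement table [[20,5],[10,15]], n = 50: p_o 0.70, p_e 0.50
  a <- rep(c("PLAN_I", "PLAN_I", "PLAN_IIA", "PLAN_IIA"), c(20, 5, 10, 15))
  b <- rep(c("PLAN_I", "PLAN_IIA", "PLAN_I", "PLAN_IIA"), c(20, 5, 10, 15))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_observed, 0.70, tolerance = 1e-12)
  expect_equal(k$p_expected, 0.50, tolerance = 1e-12)
  expect_equal(k$kappa, 0.40, tolerance = 1e-12)
  # large-sample SE by hand
  se <- sqrt(0.7 * 0.3 / (50 * 0.25))
  expect_equal(k$ci_low, 0.4 - qnorm(0.975) * se, tolerance = 1e-12)
  # zero coincident agreement on a balanced cyclic relabeling -> kappa < 0
  r1 <- rep(c("PLAN_I", "PLAN_IIA", "PLAN_IIB"), each = 2)
  r2 <- rep(c("PLAN_IIA", "PLAN_IIB", "PLAN_I"), each = 2)
  expect_lt(cohens_kappa(r1, r2)$kappa, 0)
  # consistent relabeling in both raters leaves kappa unchanged
  perm <- c(PLAN_I = "PLAN_IIB", PLAN_IIA = "PLAN_I", PLAN_IIB = "PLAN_IIA")
  k2 <- cohens_kappa(unname(perm[a]), unname(perm[b]))
  expect_equal(k2$kappa, k$kappa, tolerance = 1e-12)
  # degenerate single-category perfect agreement
  expect_identical(cohens_kappa(rep("PLAN_I", 5), rep("PLAN_I", 5))$kappa, 1)
  expect_error(cohens_kappa("PLAN_I", c("PLAN_I", "PLAN_I")), "equal length")
})

test_that("evaluate_run joins on record_id and separates fine from coarse accuracy", {
  dec <- tibble::tibble(
    record_id = sprintf("r%02d", 1:10),
    plan = rep(c("PLAN_I", "PLAN_IIA", "PLAN_IIB"), c(3, 4, 3)),
    coarse_plan = plan_coarse(plan),
    weighted_score = seq(0.9, 0, length.out = 10),
    mandated = FALSE, insufficient_data = FALSE,
    fired_rules = replicate(10, character(0), simplify = FALSE)
  )
  gold <- tibble::tibble(record_id = dec$record_id, gold_plan = dec$plan)
  m <- evaluate_run(dec, gold)
  expect_equal(m$binary$estimate[m$binary$metric == "accuracy"], 1)
  expect_equal(m$fine_accuracy, 1)
  expect_identical(m$kappa$kappa, 1)

  # one IIA -> IIB misclassification: fine accuracy drops, coarse stays 1
  dec2 <- dec
  dec2$plan[4] <- "PLAN_IIB"
  dec2$coarse_plan[4] <- "PLAN_II"
  m2 <- evaluate_run(dec2, gold)
  expect_equal(m2$fine_accuracy, 0.9)
  expect_equal(m2$binary$estimate[m2$binary$metric == "accuracy"], 1)

  # disjoint ids: empty join is an input error
  gold_off <- gold
  gold_off$record_id <- paste0("x", gold_off$record_id)
  expect_error(evaluate_run(dec, gold_off), "no records shared")

  # second rater kappa
  r2 <- tibble::tibble(record_id = dec$record_id, plan = dec$plan)
  m3 <- evaluate_run(dec, gold, rater2 = r2)
  expect_identical(m3$kappa_rater2$kappa, 1)
})

test_that("per-plan accuracy is recall in the 3x3 table", {
  pred <- c("PLAN_I", "PLAN_I", "PLAN_IIA", "PLAN_IIB", "PLAN_IIB", "PLAN_IIA")
  gold <- c("PLAN_I", "PLAN_IIA", "PLAN_IIA", "PLAN_IIB", "PLAN_IIA", "PLAN_I")
  pp <- per_plan_accuracy(confusion_counts(pred, gold))
  est <- setNames(pp$estimate, pp$plan)
  expect_equal(est[["PLAN_I"]], 0.5) # 1 of 2 gold-I predicted I
  expect_equal(est[["PLAN_IIA"]], 1 / 3)
  expect_equal(est[["PLAN_IIB"]], 1)
})

test_that("proportion CIs shrink at the 1/sqrt(n) rate on resampled cohorts", {
  widths <- vapply(c(50, 200, 800), function(n) {
    pred <- rep(c("PLAN_I", "PLAN_IIB"), each = n / 2)
    gold <- pred
    gold[seq_len(n / 10)] <- "PLAN_IIB" # 10% errors in the positive half
    m <- binary_metrics(confusion_counts(pred, gold))
    acc <- m[m$metric == "accuracy", ]
    acc$ci_high - acc$ci_low
  }, double(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.1) # 16x n -> 4x narrower
})

test_that("tidy, glance and autoplot expose the metric suite", {
  dec <- suppressWarnings(classify_plan(sample_case_facts(60, seed = 8)))
  dec$record_id <- sprintf("r%03d", 1:60)
  gold <- tibble::tibble(
    record_id = dec$record_id,
    gold_plan = derive_gold_plan(sample_case_facts(60, seed = 8))
  )
  m <- evaluate_run(dec, gold)
  td <- tidy(m)
  expect_true(all(c("metric", "estimate", "ci_low", "ci_high", "n") %in% names(td)))
  expect_true(all(c("sensitivity", "specificity", "accuracy", "ppv", "npv", "kappa") %in% td$metric))
  gl <- glance(m)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$accuracy, 1)
  expect_s3_class(autoplot(m), "ggplot")
  if (!is.null(m$roc)) expect_s3_class(autoplot(m$roc), "ggplot")
})
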