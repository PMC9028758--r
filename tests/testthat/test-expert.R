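tbl <- default_logic_table()

# small custom table used where exact score arithmetic must be controlled
mini_table <- function() {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "cut_high: 0.5",
    "cut_low: 0.25",
    "rules:",
    "  - rule_id: big_volume",
    "    weight: 3",
    "    when:",
    "      - {field: hematoma_volume_ml, op: ge, value: 30}",
    "  - rule_id: low_gcs",
    "    weight: 2",
    "    when:",
    "      - {field: gcs_total, op: le, value: 8}",
    "  - rule_id: shifted",
    "    weight: 5",
    "    when:",
    "      - {field: midline_shift_mm, op: ge, value: 5}"
  ), tf)
  read_logic_table(tf)
}

test_that("unknown fields never fire comparators; all-unknown scores zero", {
  fired <- evaluate_rules(case_facts(), tbl)
  expect_false(any(fired$fired))
  expect_identical(compute_weighted_score(fired, tbl), 0)
  d <- suppressWarnings(classify_plan(case_facts(), tbl))
  expect_identical(d$plan, "PLAN_IIB")
  expect_identical(d$weighted_score, 0)
})

test_that("the weighted score is the normalized fired-weight sum", {
  mt <- mini_table() # weights 3, 2, 5; normalizer 10
  f <- case_facts(hematoma_volume_ml = 40, gcs_total = 7L) # fires 3 and 2
  fired <- evaluate_rules(f, mt)
  expect_identical(compute_weighted_score(fired, mt), 0.5)
  # all rules fire -> 1
  f_all <- case_facts(hematoma_volume_ml = 40, gcs_total = 7L, midline_shift_mm = 9)
  expect_identical(compute_weighted_score(evaluate_rules(f_all, mt), mt), 1)
})

test_that("default table reproduces the hand-derived plan assignments", {
  expect_identical(classify_plan(case_facts(
    bleed_location = "basal_ganglia", hematoma_volume_ml = 50,
    gcs_total = 7L, midline_shift_mm = 8
  ), tbl)$plan, "PLAN_I")
  expect_identical(classify_plan(case_facts(
    bleed_location = "lobar", hematoma_volume_ml = 8, gcs_total = 15L,
    condition_trend = "stable", midline_shift_mm = 0
  ), tbl)$plan, "PLAN_IIB")
  expect_identical(classify_plan(case_facts(
    bleed_location = "basal_ganglia", hematoma_volume_ml = 25,
    gcs_total = 13L, midline_shift_mm = 3, condition_trend = "deteriorating"
  ), tbl)$plan, "PLAN_IIA")
  # supratentorial-large-volume weighted rule fires on 50 mL basal ganglia
  fired <- evaluate_rules(
    case_facts(hematoma_volume_ml = 50, bleed_location = "basal_ganglia"), tbl
  )
  expect_true(fired$fired[fired$rule_id == "supratentorial_volume_ge30"])
  # cerebellar volume rule is a mandate
  d <- classify_plan(
    case_facts(bleed_location = "cerebellum", hematoma_volume_ml = 12), tbl
  )
  expect_identical(d$plan, "PLAN_I")
  expect_true(d$mandated)
  expect_true("cerebellar_hematoma_ge10ml" %in% d$fired_rules[[1]])
})

test_that("scores at a cut-point classify into the more aggressive plan", {
  mt <- mini_table() # normalizer 10, cut_high 0.5, cut_low 0.25
  at_high <- case_facts(hematoma_volume_ml = 40, gcs_total = 7L) # score 0.5
  expect_identical(classify_plan(at_high, mt)$plan, "PLAN_I")
  at_low <- case_facts(gcs_total = 8L) # score 2/10 = 0.2 < 0.25 -> IIB
  expect_identical(classify_plan(at_low, mt)$plan, "PLAN_IIB")
  mt2 <- with_cut_points(mt, cut_low = 0.2) # score exactly at cut_low
  expect_identical(classify_plan(at_low, mt2)$plan, "PLAN_IIA")
})

test_that("classification agrees with a naive rule-walking oracle", {
  set.seed(101)
  facts <- random_facts(300, na_prob = 0.25)
  got <- suppressWarnings(classify_plan(facts, tbl))
  for (i in seq_len(nrow(facts))) {
    want <- classify_oracle(as.list(facts[i, , drop = FALSE]), tbl)
    expect_identical(got$plan[i], want$plan)
    expect_equal(got$weighted_score[i], want$score, tolerance = 1e-12)
    expect_identical(got$mandated[i], want$mandated)
  }
})

test_that("scores stay in [0,1] and mandates force Plan I regardless of score", {
  set.seed(7)
  facts <- random_facts(500, na_prob = 0.3)
  d <- suppressWarnings(classify_plan(facts, tbl))
  expect_true(all(d$weighted_score >= 0 & d$weighted_score <= 1))
  expect_true(all(d$plan[d$mandated] == "PLAN_I"))
})

test_that("raising volume or lowering GCS never demotes the plan", {
  set.seed(11)
  facts <- random_facts(300, na_prob = 0.2)
  base <- suppressWarnings(classify_plan(facts, tbl))
  up_vol <- facts
  up_vol$hematoma_volume_ml <- ifelse(
    is.na(up_vol$hematoma_volume_ml), 20, up_vol$hematoma_volume_ml + 15
  )
  d_vol <- suppressWarnings(classify_plan(up_vol, tbl))
  expect_true(all(plan_rank(d_vol$plan) >= plan_rank(base$plan)))
  down_gcs <- facts
  down_gcs$gcs_total <- ifelse(
    is.na(down_gcs$gcs_total), NA, pmax(3L, down_gcs$gcs_total - 4L)
  )
  d_gcs <- suppressWarnings(classify_plan(down_gcs, tbl))
  expect_true(all(plan_rank(d_gcs$plan) >= plan_rank(base$plan)))
})

test_that("logic-table loading validates configuration at load time", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c(
    "cut_high: 0.5",
    "cut_low: 0.15",
    "rules:",
    "  - rule_id: ghost",
    "    weight: 1",
    "    when:",
    "      - {field: not_a_field, op: ge, value: 1}"
  ), tf)
  expect_error(read_logic_table(tf), "not_a_field")

  tf2 <- tempfile(fileext = ".yaml")
  writeLines(c(
    "cut_high: 0.1",
    "cut_low: 0.5",
    "rules:",
    "  - rule_id: r1",
    "    weight: 1",
    "    when:",
    "      - {field: gcs_total, op: le, value: 8}"
  ), tf2)
  expect_error(read_logic_table(tf2), "cut")
  expect_error(with_cut_points(default_logic_table(), cut_high = 0.1, cut_low = 0.5), "cut")
})

test_that("decisions are explained with fired rules in table order", {
  d <- classify_plan(case_facts(
    bleed_location = "cerebellum", hematoma_volume_ml = 15,
    gcs_total = 10L, condition_trend = "deteriorating"
  ), tbl)
  txt <- explain_decision(d, tbl)
  expect_match(txt, "cerebellar_hematoma_ge10ml")
  expect_match(txt, "mandatory surgical indication")
  # rules listed in table order
  pos <- vapply(d$fired_rules[[1]], function(id) regexpr(id, txt, fixed = TRUE)[1], double(1))
  expect_true(all(diff(pos) > 0))
  d0 <- suppressWarnings(classify_plan(case_facts(), tbl))
  expect_match(explain_decision(d0, tbl), "no rule fired; score 0")
  expect_match(explain_decision(d0, tbl), "insufficient")
})

test_that("an insufficient-data warning fires when GCS and volume are both unknown", {
  expect_warning(
    classify_plan(case_facts(condition_trend = "stable"), tbl),
    "insufficient"
  )
  expect_no_warning(classify_plan(case_facts(gcs_total = 12L), tbl))
})
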