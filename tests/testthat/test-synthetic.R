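test_that("sampled facts are always valid, coherent, and seed-reproducible", {
  f <- sample_case_facts(400, seed = 21)
  expect_identical(nrow(validate_case_facts(f)), 0L)
  # consciousness grade consistent with GCS banding
  band <- cut(f$gcs_total, c(2, 5, 8, 12, 15), labels = c("coma", "stupor", "drowsy", "alert"))
  expect_identical(as.character(band), f$consciousness_grade)
  # components always sum to the total
  expect_identical(f$gcs_eye + f$gcs_verbal + f$gcs_motor, f$gcs_total)
  # same seed, fresh state -> identical draw
  expect_identical(sample_case_facts(50, seed = 9), sample_case_facts(50, seed = 9))
  # midline shift couples to volume for supratentorial bleeds
  supra <- f$bleed_location %in% c("basal_ganglia", "thalamus", "lobar")
  big <- supra & f$hematoma_volume_ml >= 40
  small <- supra & f$hematoma_volume_ml <= 10
  expect_gt(mean(f$midline_shift_mm[big]), mean(f$midline_shift_mm[small]))
})

test_that("gold plans equal deployed-table classification on true facts", {
  f <- sample_case_facts(100, seed = 5)
  expect_identical(
    derive_gold_plan(f, default_logic_table()),
    suppressWarnings(classify_plan(f, default_logic_table()))$plan
  )
  expect_identical(
    derive_gold_plan(case_facts(bleed_location = "cerebellum", hematoma_volume_ml = 15)),
    "PLAN_I"
  )
  expect_identical(derive_gold_plan(case_facts()), "PLAN_IIB")
})

test_that("noiseless rendering is canonical, reproducible, and fully invertible", {
  f <- sample_case_facts(80, seed = 31)
  r1 <- render_narrative(f, noise = noise_off(), seed = 32)
  r2 <- render_narrative(f, noise = noise_off(), seed = 32)
  expect_identical(r1, r2)
  got <- extract_case_facts(r1)$facts
  for (col in setdiff(names(got), "record_id")) {
    expect_equal(got[[col]], f[[col]], tolerance = 1e-9, ignore_attr = TRUE,
      label = paste("round-trip of", col)
    )
  }
})

test_that("total field dropout leaves nothing to extract", {
  f <- sample_case_facts(10, seed = 41)
  r <- render_narrative(f, noise = noise_model(0, 0, 0, field_dropout_rate = 1, 0), seed = 42)
  facts <- extract_case_facts(r)$facts
  for (col in setdiff(names(facts), "record_id")) {
    expect_true(all(is.na(facts[[col]])), label = paste("dropout leaves", col, "unknown"))
  }
  expect_true(all(r$incomplete))
})

test_that("misspellings listed in the lexicon table do not break the round trip", {
  lex <- default_lexicon()
  f <- sample_case_facts(40, seed = 51)
  rec <- render_narrative(f, noise = noise_off(), seed = 52)
  # inject only table-listed variants (canonical -> variant substitution)
  corrupt <- function(text) {
    for (variant in names(lex$misspellings)) {
      canonical <- lex$misspellings[[variant]]
      text <- gsub(paste0("\\b", canonical, "\\b"), variant, text)
    }
    text
  }
  rec_bad <- rec
  for (col in c("chief_complaint", "history", "physical_exam", "ct_report")) {
    rec_bad[[col]] <- corrupt(rec_bad[[col]])
  }
  expect_identical(
    extract_case_facts(rec_bad)$facts,
    extract_case_facts(rec)$facts
  )
})

test_that("split sizes follow largest-remainder rounding of the ratio", {
  co <- generate_cohort(cohort_spec(10, seed = 1, noise = noise_off(),
    split_ratio = split_preset_622()
  ))
  expect_identical(as.integer(table(co$split$split)[c("train", "validation", "test")]),
    c(6L, 2L, 2L))
  co5 <- generate_cohort(cohort_spec(5, seed = 1, noise = noise_off()))
  expect_identical(as.integer(table(co5$split$split)[c("train", "validation", "test")]),
    c(3L, 1L, 1L))
})

test_that("cohorts are byte-identical under a fixed spec and seed", {
  spec <- cohort_spec(40, seed = 77, noise = noise_model())
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$gold, c2$gold)
  expect_identical(c1$split, c2$split)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_emr_corpus(c1$records, p1)
  write_emr_corpus(c2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("rejection sampling hits the requested plan mix exactly", {
  spec <- cohort_spec(60,
    seed = 3, noise = noise_off(),
    plan_mix = c(PLAN_I = 0.5, PLAN_IIA = 0.3, PLAN_IIB = 0.2)
  )
  co <- generate_cohort(spec)
  counts <- table(factor(co$gold$gold_plan, levels = c("PLAN_I", "PLAN_IIA", "PLAN_IIB")))
  expect_identical(as.integer(counts), c(30L, 18L, 12L))
})

test_that("the achieved natural plan mix converges with n (law of large numbers)", {
  co_small <- generate_cohort(cohort_spec(150, seed = 5, noise = noise_off()))
  co_big <- generate_cohort(cohort_spec(2000, seed = 5, noise = noise_off()))
  lv <- c("PLAN_I", "PLAN_IIA", "PLAN_IIB")
  p_small <- prop.table(table(factor(co_small$gold$gold_plan, levels = lv)))
  p_big <- prop.table(table(factor(co_big$gold$gold_plan, levels = lv)))
  # the large sample lies within 3 binomial sigma of itself by construction;
  # check the two estimates agree within 3 sigma of the smaller sample
  sigma <- sqrt(p_big * (1 - p_big) / 150)
  expect_true(all(abs(p_small - p_big) <= 3 * sigma + 1e-9))
})

test_that("gold tables differing in cut-points create controlled disagreement", {
  co <- generate_cohort(
    cohort_spec(400, seed = 13, noise = noise_off()),
    gold_table = with_cut_points(default_logic_table(), cut_high = 0.4)
  )
  dec <- suppressWarnings(classify_plan(
    extract_case_facts(co$records)$facts, default_logic_table()
  ))
  m <- evaluate_run(dec, co$gold)
  acc <- m$binary$estimate[m$binary$metric == "accuracy"]
  expect_gt(acc, 0.5)
  expect_lt(acc, 1.0)
})
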