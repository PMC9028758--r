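# Synthetic eEMR generator: clinically coherent case facts from documented
# literature-typical priors, a reference ("gold") logic table playing the
# role of the senior raters, template-based narrative rendering, and a
# controllable noise model emulating real-record corruption (misspellings,
# non-text symbols, abbreviations, dropped fields, unit variants).

with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# Deterministic per-stage child seed below 2^31, so stages can be re-run in
# isolation reproducibly from one run seed.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.double(seed) * 2654435 + h) %% 2147483647)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Read narrative templates / the packaged default templates
#'
#' @param path Path to a templates YAML file.
#' @return A `ich_templates` list.
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) abort(paste0("templates file not found: ", path))
  structure(yaml::yaml.load_file(path), class = "ich_templates")
}

#' @rdname read_templates
#' @export
default_templates <- function() {
  read_templates(system.file("extdata", "templates.yaml", package = "ichtriage"))
}

#' Narrative noise model
#'
#' Per-corruption probabilities emulating real emergency records: keyword
#' misspellings, inserted non-text symbol runs, abbreviated phrases, facts
#' omitted from the narrative, and alternate unit surface forms (cc for mL,
#' cm for mm). Defaults are the generator's standard operating point; use
#' [noise_off()] for canonical, fully invertible renderings.
#'
#' @param misspelling_rate Probability per keyword token.
#' @param symbol_noise_rate Probability of a symbol run per sentence.
#' @param abbreviation_rate Probability an expandable phrase is abbreviated.
#' @param field_dropout_rate Probability a fact is omitted from the text.
#' @param unit_variant_rate Probability of an alternate unit form.
#' @return A `ich_noise_model` list.
#' @export
noise_model <- function(misspelling_rate = 0.05, symbol_noise_rate = 0.10,
                        abbreviation_rate = 0.20, field_dropout_rate = 0.02,
                        unit_variant_rate = 0.10) {
  rates <- c(
    misspelling_rate = misspelling_rate, symbol_noise_rate = symbol_noise_rate,
    abbreviation_rate = abbreviation_rate, field_dropout_rate = field_dropout_rate,
    unit_variant_rate = unit_variant_rate
  )
  if (any(is.na(rates) | rates < 0 | rates > 1)) {
    abort("noise rates must all lie in [0, 1]")
  }
  structure(as.list(rates), class = "ich_noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function() noise_model(0, 0, 0, 0, 0)

#' Clinical priors of the case generator
#'
#' Literature-typical defaults: bleed-location frequencies dominated by the
#' basal ganglia; location-conditional log-normal hematoma volumes; GCS
#' coupled to volume; midline shift coupled to volume for supratentorial
#' bleeds; vitals from truncated normals. All values are configuration.
#'
#' @return A named list of prior parameters.
#' @export
clinical_priors <- function() {
  list(
    location_probs = c(
      basal_ganglia = 0.50, thalamus = 0.15, lobar = 0.15,
      cerebellum = 0.09, brainstem = 0.06, intraventricular_primary = 0.05
    ),
    volume_meanlog = log(c(
      basal_ganglia = 20, thalamus = 10, lobar = 30,
      cerebellum = 10, brainstem = 5, intraventricular_primary = 8
    )),
    volume_sdlog = 0.7,
    volume_range = c(1, 150),
    gcs_drop_midpoint_ml = 25, # volume at which expected GCS is halfway down
    gcs_sd = 1.8,
    age = c(mean = 64, sd = 15, lo = 10, hi = 80),
    heart_rate = c(mean = 85, sd = 15, lo = 40, hi = 140),
    systolic_bp = c(mean = 165, sd = 25, lo = 100, hi = 230),
    diastolic_bp = c(mean = 95, sd = 15, lo = 60, hi = 130),
    spo2 = c(mean = 96, sd = 2, lo = 80, hi = 100),
    female_prob = 0.57
  )
}

gcs_to_grade <- function(gcs) {
  cut(gcs,
    breaks = c(2, 5, 8, 12, 15),
    labels = c("coma", "stupor", "drowsy", "alert")
  ) |> as.character()
}

resample <- function(x, ...) x[sample.int(length(x), ...)]

sample_gcs_components <- function(total) {
  eye <- vapply(total, function(t) {
    resample(seq(max(1L, t - 11L), min(4L, t - 2L)), 1)
  }, numeric(1))
  verbal <- mapply(function(t, e) {
    resample(seq(max(1L, t - e - 6L), min(5L, t - e - 1L)), 1)
  }, total, eye)
  motor <- total - eye - verbal
  list(eye = as.integer(eye), verbal = as.integer(verbal), motor = as.integer(motor))
}

#' Draw clinically coherent synthetic case facts
#'
#' Location from a categorical prior; volume from a location-conditional
#' log-normal; GCS total negatively coupled to volume, with consciousness
#' grade consistent with the total (alert 13--15, drowsy 9--12, stupor 6--8,
#' coma 3--5) and components summing to it; midline shift positively coupled
#' to volume for supratentorial bleeds; pupil state, reflexes, symptoms and
#' clinical trend conditioned on severity; vitals from truncated normals.
#' Every draw passes [validate_case_facts()].
#'
#' @param n Number of cases.
#' @param priors See [clinical_priors()].
#' @param seed Optional seed (RNG state is restored afterwards).
#' @return A case-facts tibble with `n` rows, all fields known.
#' @export
sample_case_facts <- function(n, priors = clinical_priors(), seed = NULL) {
  with_seed(seed, function() {
    loc <- sample(names(priors$location_probs), n,
      replace = TRUE, prob = priors$location_probs
    )
    vol <- rlnorm(n, priors$volume_meanlog[loc], priors$volume_sdlog)
    vol <- round(pmin(pmax(vol, priors$volume_range[1]), priors$volume_range[2]), 1)
    mu_gcs <- 15 - 8 * stats::plogis((vol - priors$gcs_drop_midpoint_ml) / 12)
    gcs <- as.integer(pmin(pmax(round(mu_gcs + rnorm(n, 0, priors$gcs_sd)), 3), 15))
    comp <- sample_gcs_components(gcs)
    grade <- gcs_to_grade(gcs)
    supra <- loc %in% c("basal_ganglia", "thalamus", "lobar")
    shift <- ifelse(
      supra, pmax(0, round((vol - 15) * 0.25 + rnorm(n, 0, 1.5), 1)),
      ifelse(loc == "cerebellum", pmax(0, round(rnorm(n, -0.5, 0.8), 1)), 0)
    )
    cast <- runif(n) < stats::plogis(
      -2.2 + 2.5 * (loc == "intraventricular_primary") +
        1.5 * (loc == "thalamus") + vol / 60
    )
    shape_abn <- runif(n) < stats::plogis(-1.5 + 0.08 * shift + 1.2 * cast)
    pupil <- vapply(seq_len(n), function(i) {
      p <- switch(grade[i],
        coma = c(0.35, 0.40, 0.25),
        stupor = c(0.60, 0.35, 0.05),
        drowsy = c(0.85, 0.15, 0.00),
        alert = c(0.97, 0.03, 0.00)
      )
      sample(pupil_levels, 1, prob = p)
    }, character(1))
    reflex <- runif(n) < stats::plogis(-1.8 + 0.25 * (15 - gcs))
    cereb <- loc == "cerebellum"
    headache <- runif(n) < pmin(0.70 + 0.10 * cereb, 0.95)
    nausea <- runif(n) < pmin(0.50 + 0.15 * cereb, 0.95)
    vomiting <- runif(n) < pmin(0.45 + 0.15 * (cereb | loc == "intraventricular_primary"), 0.95)
    trend <- ifelse(
      runif(n) < stats::plogis(-1.8 + 0.18 * (15 - gcs) + vol / 80),
      "deteriorating", "stable"
    )
    lat <- ifelse(
      loc %in% c("brainstem", "intraventricular_primary"), "midline",
      sample(c("left", "right", "bilateral"), n, replace = TRUE, prob = c(0.48, 0.48, 0.04))
    )
    case_facts(
      gcs_eye = comp$eye, gcs_verbal = comp$verbal, gcs_motor = comp$motor,
      gcs_total = gcs,
      heart_rate = round(rtrunc_norm(n, priors$heart_rate["mean"], priors$heart_rate["sd"],
        priors$heart_rate["lo"], priors$heart_rate["hi"])),
      systolic_bp = round(rtrunc_norm(n, priors$systolic_bp["mean"], priors$systolic_bp["sd"],
        priors$systolic_bp["lo"], priors$systolic_bp["hi"])),
      diastolic_bp = round(rtrunc_norm(n, priors$diastolic_bp["mean"], priors$diastolic_bp["sd"],
        priors$diastolic_bp["lo"], priors$diastolic_bp["hi"])),
      spo2 = round(rtrunc_norm(n, priors$spo2["mean"], priors$spo2["sd"],
        priors$spo2["lo"], priors$spo2["hi"])),
      consciousness_grade = grade,
      pathological_reflex = reflex,
      pupil_state = pupil,
      headache = headache, nausea = nausea, vomiting = vomiting,
      bleed_location = loc, laterality = lat,
      hematoma_volume_ml = vol,
      ventricle_cast = cast, ventricle_shape_abnormal = shape_abn,
      midline_shift_mm = shift,
      condition_trend = trend
    )
  })
}

#' Gold-standard plan for true case facts
#'
#' Applies a reference ("gold") logic table to the true, pre-rendering facts
#' — the stand-in for expert raters. The gold table may equal or differ from
#' the deployed table, enabling controlled-disagreement experiments.
#'
#' @param facts Case-facts tibble.
#' @param gold_table A `ich_logic_table`.
#' @return Character vector of plans.
#' @export
derive_gold_plan <- function(facts, gold_table = default_logic_table()) {
  suppressWarnings(classify_plan(facts, gold_table)$plan)
}

fill_template <- function(template, values) {
  for (nm in names(values)) {
    template <- gsub(paste0("{", nm, "}"), values[[nm]], template, fixed = TRUE)
  }
  template
}

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

join_words <- function(words) {
  n <- length(words)
  if (n == 1) return(words)
  paste(paste(words[-n], collapse = ", "), "and", words[n])
}

# ---- per-section renderers --------------------------------------------------

render_chief_complaint <- function(f, tpl, drop) {
  symptoms <- c(headache = f$headache, nausea = f$nausea, vomiting = f$vomiting)
  symptoms <- symptoms[!is.na(symptoms)]
  symptoms <- symptoms[runif(length(symptoms)) >= drop]
  pos <- names(symptoms)[symptoms]
  neg <- names(symptoms)[!symptoms]
  lead <- if (length(pos) > 0) {
    fill_template(tpl$chief_complaint$positive, list(symptoms = join_words(pos)))
  } else {
    tpl$chief_complaint$none
  }
  if (length(neg) > 0) {
    neg_part <- fill_template(tpl$chief_complaint$negative, list(symptoms = join_words(neg)))
    paste0(lead, "; ", neg_part, ".")
  } else {
    paste0(lead, ".")
  }
}

render_history <- function(f, tpl, drop) {
  parts <- c(tpl$history$onset, tpl$history$background)
  if (!is.na(f$condition_trend) && runif(1) >= drop) {
    parts <- c(parts, fill_template(
      tpl$history$trend, list(trend = tpl$trend_words[[f$condition_trend]])
    ))
  }
  paste(parts, collapse = " ")
}

render_physical_exam <- function(f, tpl, drop) {
  parts <- character(0)
  if (!is.na(f$gcs_total) && runif(1) >= drop) {
    parts <- c(parts, fill_template(tpl$physical_exam$gcs, list(
      total = f$gcs_total, eye = f$gcs_eye, verbal = f$gcs_verbal, motor = f$gcs_motor
    )))
  }
  if (!is.na(f$consciousness_grade) && runif(1) >= drop) {
    parts <- c(parts, fill_template(
      tpl$physical_exam$consciousness,
      list(grade = tpl$consciousness_words[[f$consciousness_grade]])
    ))
  }
  if (!is.na(f$heart_rate) && runif(1) >= drop) {
    parts <- c(parts, fill_template(tpl$physical_exam$heart_rate, list(hr = fmt_num(f$heart_rate))))
  }
  if (!is.na(f$systolic_bp) && !is.na(f$diastolic_bp) && runif(1) >= drop) {
    parts <- c(parts, fill_template(tpl$physical_exam$blood_pressure, list(
      sbp = fmt_num(f$systolic_bp), dbp = fmt_num(f$diastolic_bp)
    )))
  }
  if (!is.na(f$spo2) && runif(1) >= drop) {
    parts <- c(parts, fill_template(tpl$physical_exam$spo2, list(spo2 = fmt_num(f$spo2))))
  }
  if (!is.na(f$pupil_state) && runif(1) >= drop) {
    parts <- c(parts, tpl$physical_exam$pupils[[f$pupil_state]])
  }
  if (!is.na(f$pathological_reflex) && runif(1) >= drop) {
    parts <- c(parts, if (f$pathological_reflex) {
      tpl$physical_exam$reflex_present
    } else {
      tpl$physical_exam$reflex_absent
    })
  }
  paste(parts, collapse = " ")
}

render_ct_report <- function(f, tpl, drop, unit_variant_rate) {
  parts <- character(0)
  if (!is.na(f$bleed_location) && runif(1) >= drop) {
    parts <- c(parts, if (f$bleed_location == "intraventricular_primary") {
      tpl$ct_report$location_ivh
    } else {
      surface <- tpl$location_words[[f$bleed_location]]
      surface <- surface[[sample.int(length(surface), 1)]]
      if (!is.na(f$laterality) && f$laterality != "midline") {
        fill_template(tpl$ct_report$location, list(laterality = f$laterality, location = surface))
      } else {
        fill_template(tpl$ct_report$location_midline, list(location = surface))
      }
    })
  }
  if (!is.na(f$hematoma_volume_ml) && runif(1) >= drop) {
    unit <- if (runif(1) < unit_variant_rate) "cc" else "ml"
    parts <- c(parts, fill_template(tpl$ct_report$volume, list(
      volume = fmt_num(f$hematoma_volume_ml), unit = unit
    )))
  }
  if (!is.na(f$midline_shift_mm) && runif(1) >= drop) {
    parts <- c(parts, if (f$midline_shift_mm > 0) {
      if (runif(1) < unit_variant_rate) {
        fill_template(tpl$ct_report$shift, list(
          shift = fmt_num(f$midline_shift_mm / 10), unit = "cm"
        ))
      } else {
        fill_template(tpl$ct_report$shift, list(
          shift = fmt_num(f$midline_shift_mm), unit = "mm"
        ))
      }
    } else {
      tpl$ct_report$no_shift
    })
  }
  if (!is.na(f$ventricle_cast) && runif(1) >= drop) {
    parts <- c(parts, if (f$ventricle_cast) tpl$ct_report$cast_present else tpl$ct_report$cast_absent)
  }
  if (!is.na(f$ventricle_shape_abnormal) && runif(1) >= drop) {
    parts <- c(parts, if (f$ventricle_shape_abnormal) {
      tpl$ct_report$shape_abnormal
    } else {
      tpl$ct_report$shape_normal
    })
  }
  paste(parts, collapse = " ")
}

# ---- narrative corruption ---------------------------------------------------

invert_table <- function(tbl) {
  # expansion -> first abbreviation / canonical -> variants
  out <- list()
  for (key in names(tbl)) {
    val <- tbl[[key]]
    out[[val]] <- c(out[[val]], key)
  }
  out
}

apply_abbreviation_noise <- function(text, abbrev, rate) {
  if (rate <= 0 || length(abbrev) == 0) return(text)
  expansions <- invert_table(abbrev)
  for (exp in names(expansions)[order(-nchar(names(expansions)))]) {
    if (grepl(exp, text, fixed = TRUE) && runif(1) < rate) {
      text <- gsub(exp, expansions[[exp]][1], text, fixed = TRUE)
    }
  }
  text
}

transpose_chars <- function(token) {
  if (nchar(token) < 4) return(token)
  i <- sample.int(nchar(token) - 2, 1) + 1 # interior position
  paste0(
    substr(token, 1, i - 1),
    substr(token, i + 1, i + 1), substr(token, i, i),
    substr(token, i + 2, nchar(token))
  )
}

apply_misspelling_noise <- function(text, misspellings, rate) {
  if (rate <= 0) return(text)
  variants <- invert_table(misspellings[!grepl(" ", names(misspellings))])
  m <- gregexpr("[a-z]+", text)[[1]]
  if (m[1] == -1L) return(text)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(text, starts, starts + lens - 1L)
  for (k in rev(seq_along(tokens))) { # right to left keeps offsets valid
    tok <- tokens[k]
    repl <- NULL
    if (!is.null(variants[[tok]])) {
      if (runif(1) < rate) repl <- sample(variants[[tok]], 1)
    } else if (nchar(tok) >= 5) {
      # typo outside the correction table: adjacent-character transposition
      if (runif(1) < rate / 2) repl <- transpose_chars(tok)
    }
    if (!is.null(repl)) {
      text <- paste0(
        substr(text, 1, starts[k] - 1L), repl,
        substr(text, starts[k] + lens[k], nchar(text))
      )
    }
  }
  text
}

apply_symbol_noise <- function(text, symbols, rate) {
  if (rate <= 0 || nchar(text) == 0) return(text)
  sentences <- strsplit(text, "(?<=\\.) ", perl = TRUE)[[1]]
  noisy <- vapply(sentences, function(s) {
    if (runif(1) < rate) paste0(s, " ", sample(symbols, 1)) else s
  }, character(1))
  paste(noisy, collapse = " ")
}

#' Render synthetic case facts into a narrative eEMR
#'
#' Fills one sentence per fact (chief complaint from the symptom triad;
#' history carrying the clinical trend; physical examination with GCS,
#' vitals, consciousness, pupils and reflexes; CT report with location,
#' volume, ventricular state and midline shift), then applies the noise
#' model. With all noise rates 0 the rendering is canonical and fully
#' invertible by the default lexicon.
#'
#' @param facts Case-facts tibble (any number of rows).
#' @param templates A `ich_templates` list.
#' @param noise A `ich_noise_model`.
#' @param lexicon Lexicon supplying the misspelling/abbreviation tables the
#'   noise draws from.
#' @param record_id Identifiers (default `case-00001`, ...).
#' @param demographics Optional tibble with `age`, `sex`, `weight_kg`,
#'   `height_cm` rows aligned to `facts`.
#' @param seed Optional seed.
#' @return An eEMR tibble (see [emr_record()]).
#' @export
render_narrative <- function(facts, templates = default_templates(),
                             noise = noise_off(), lexicon = default_lexicon(),
                             record_id = sprintf("case-%05d", seq_len(nrow(facts))),
                             demographics = NULL, seed = NULL) {
  with_seed(seed, function() {
    n <- nrow(facts)
    sections <- lapply(seq_len(n), function(i) {
      f <- as.list(facts[i, , drop = FALSE])
      drop <- noise$field_dropout_rate
      texts <- list(
        chief_complaint = render_chief_complaint(f, templates, drop),
        history = render_history(f, templates, drop),
        physical_exam = render_physical_exam(f, templates, drop),
        ct_report = render_ct_report(f, templates, drop, noise$unit_variant_rate)
      )
      lapply(texts, function(txt) {
        txt <- apply_abbreviation_noise(txt, lexicon$abbreviations, noise$abbreviation_rate)
        txt <- apply_misspelling_noise(txt, lexicon$misspellings, noise$misspelling_rate)
        apply_symbol_noise(txt, templates$noise_symbols, noise$symbol_noise_rate)
      })
    })
    if (is.null(demographics)) {
      pri <- clinical_priors()
      demographics <- tibble(
        age = as.integer(round(rtrunc_norm(n, pri$age["mean"], pri$age["sd"],
          pri$age["lo"], pri$age["hi"]))),
        sex = ifelse(runif(n) < pri$female_prob, "female", "male"),
        weight_kg = round(rtrunc_norm(n, 61.5, 12, 35, 120), 1),
        height_cm = round(rtrunc_norm(n, 160, 15, 120, 200))
      )
    }
    emr_record(
      record_id = record_id,
      age = demographics$age, sex = demographics$sex,
      weight_kg = demographics$weight_kg, height_cm = demographics$height_cm,
      chief_complaint = vapply(sections, `[[`, character(1), "chief_complaint"),
      history = vapply(sections, `[[`, character(1), "history"),
      physical_exam = vapply(sections, `[[`, character(1), "physical_exam"),
      ct_report = vapply(sections, `[[`, character(1), "ct_report"),
      incomplete = vapply(sections, function(s) any(!nzchar(unlist(s))), logical(1))
    )
  })
}

largest_remainder <- function(n, ratios) {
  exact <- n * ratios / sum(ratios)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    order_frac <- order(-(exact - base), seq_along(ratios))
    base[order_frac[seq_len(short)]] <- base[order_frac[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Cohort specification
#'
#' @param n_cases Number of cases (>= 1).
#' @param seed Integer seed; the cohort is fully determined by it.
#' @param plan_mix Optional named target proportions over
#'   `PLAN_I`/`PLAN_IIA`/`PLAN_IIB`, achieved by rejection sampling against
#'   the gold table; `NULL` keeps the priors' natural mix.
#' @param noise A `ich_noise_model`.
#' @param split_ratio Three non-negative proportions (train, validation,
#'   test) summing to 1. Presets: [split_preset_622()] (6:2:2) and
#'   [split_preset_paper()] (0.7/0.3/0).
#' @return A `ich_cohort_spec` list.
#' @export
cohort_spec <- function(n_cases, seed = 1L, plan_mix = NULL,
                        noise = noise_model(), split_ratio = split_preset_622()) {
  if (n_cases < 1) abort("n_cases must be >= 1")
  if (!is.null(plan_mix)) {
    if (!setequal(names(plan_mix), plan_levels)) {
      abort("plan_mix must be named over PLAN_I, PLAN_IIA, PLAN_IIB")
    }
    if (abs(sum(plan_mix) - 1) > 1e-9 || any(plan_mix < 0)) {
      abort("plan_mix proportions must be non-negative and sum to 1")
    }
    plan_mix <- plan_mix[plan_levels]
  }
  if (length(split_ratio) != 3 || any(split_ratio < 0) ||
    abs(sum(split_ratio) - 1) > 1e-9) {
    abort("split_ratio must be three non-negative proportions summing to 1")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), seed = as.integer(seed),
      plan_mix = plan_mix, noise = noise,
      split_ratio = setNames(split_ratio, c("train", "validation", "test"))
    ),
    class = "ich_cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
split_preset_622 <- function() c(0.6, 0.2, 0.2)

#' @rdname cohort_spec
#' @export
split_preset_paper <- function() c(0.7, 0.3, 0)

#' Generate a synthetic cohort with known gold-standard plans
#'
#' Draws case facts from the clinical priors (rejection-sampling to the
#' target plan mix when one is given), derives the gold plan from the gold
#' logic table, renders each case into a noisy narrative eEMR, and
#' partitions the corpus into train/validation/test by largest-remainder
#' rounding of the split ratio. Fully determined by `spec$seed`.
#'
#' @param spec A `ich_cohort_spec`.
#' @param gold_table Reference logic table producing the gold plans.
#' @param templates Narrative templates.
#' @param lexicon Lexicon for noise tables.
#' @param priors Clinical priors.
#' @return A `ich_cohort` list: `records` (eEMR tibble), `gold`
#'   (`record_id`, `gold_plan`, true facts columns), `split` (`record_id`,
#'   `split`), and the echoed `spec`.
#' @export
generate_cohort <- function(spec, gold_table = default_logic_table(),
                            templates = default_templates(),
                            lexicon = default_lexicon(),
                            priors = clinical_priors()) {
  stopifnot(inherits(spec, "ich_cohort_spec"))
  with_seed(spec$seed, function() {
    n <- spec$n_cases
    if (is.null(spec$plan_mix)) {
      facts <- sample_case_facts(n, priors)
      gold_plan <- derive_gold_plan(facts, gold_table)
    } else {
      targets <- setNames(largest_remainder(n, spec$plan_mix), plan_levels)
      kept <- list()
      kept_plan <- character(0)
      draws <- 0
      max_draws <- 1000 * n
      while (sum(targets) > 0) {
        if (draws >= max_draws) {
          abort(paste0(
            "plan_mix infeasible: ", max_draws, " draws could not fill ",
            paste(names(targets)[targets > 0], collapse = ", ")
          ))
        }
        batch_n <- min(max(200L, n), max_draws - draws)
        batch <- sample_case_facts(batch_n, priors)
        plans <- derive_gold_plan(batch, gold_table)
        draws <- draws + batch_n
        for (i in seq_len(batch_n)) {
          if (targets[plans[i]] > 0) {
            kept[[length(kept) + 1L]] <- batch[i, , drop = FALSE]
            kept_plan <- c(kept_plan, plans[i])
            targets[plans[i]] <- targets[plans[i]] - 1L
          }
        }
      }
      ord <- sample.int(length(kept))
      facts <- bind_rows(kept[ord])
      gold_plan <- kept_plan[ord]
    }
    record_id <- sprintf("case-%05d", seq_len(n))
    records <- render_narrative(
      facts, templates, spec$noise, lexicon, record_id = record_id
    )
    sizes <- largest_remainder(n, spec$split_ratio)
    split <- tibble(
      record_id = record_id,
      split = rep(c("train", "validation", "test"), times = sizes)
    )
    structure(
      list(
        records = records,
        gold = dplyr::bind_cols(tibble(record_id = record_id, gold_plan = gold_plan), facts),
        split = split,
        spec = spec
      ),
      class = "ich_cohort"
    )
  })
}

#' @export
print.ich_cohort <- function(x, ...) {
  cat(
    "<ich_cohort> ", nrow(x$records), " cases; gold mix: ",
    paste(names(table(x$gold$gold_plan)), as.integer(table(x$gold$gold_plan)),
      sep = "=", collapse = ", "
    ),
    "; split: ", paste(names(table(x$split$split)), as.integer(table(x$split$split)),
      sep = "=", collapse = ", "
    ), "\n",
    sep = ""
  )
  invisible(x)
}
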