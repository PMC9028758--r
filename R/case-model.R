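#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange bind_rows left_join group_by
#'   summarise ungroup across all_of n row_number group_modify
#' @importFrom stats rnorm rlnorm runif rbinom qnorm setNames
#' @importFrom utils head tail
NULL

# Enumerations used across the package ----------------------------------------

plan_levels <- c("PLAN_I", "PLAN_IIA", "PLAN_IIB")
coarse_levels <- c("PLAN_I", "PLAN_II")

consciousness_levels <- c("alert", "drowsy", "stupor", "coma")
pupil_levels <- c("equal_reactive", "anisocoria", "bilateral_fixed_dilated")
location_levels <- c(
  "basal_ganglia", "thalamus", "lobar", "cerebellum", "brainstem",
  "intraventricular_primary"
)
laterality_levels <- c("left", "right", "bilateral", "midline")
trend_levels <- c("stable", "deteriorating")

#' Field schema of the clinical case-facts table
#'
#' Every clinical variable the pipeline extracts or generates, with its type.
#' `NA` encodes the explicit "unknown" state in every column: emergency
#' narratives are lossy and any field may be absent from a record.
#'
#' @return A named character vector mapping field name to storage type
#'   (`"integer"`, `"double"`, `"logical"`, `"character"`).
#' @export
case_facts_schema <- function() {
  c(
    gcs_eye = "integer", gcs_verbal = "integer", gcs_motor = "integer",
    gcs_total = "integer",
    heart_rate = "double", systolic_bp = "double", diastolic_bp = "double",
    spo2 = "double",
    consciousness_grade = "character",
    pathological_reflex = "logical",
    pupil_state = "character",
    headache = "logical", nausea = "logical", vomiting = "logical",
    bleed_location = "character", laterality = "character",
    hematoma_volume_ml = "double",
    ventricle_cast = "logical", ventricle_shape_abnormal = "logical",
    midline_shift_mm = "double",
    condition_trend = "character"
  )
}

na_of_type <- function(type) {
  switch(type,
    integer = NA_integer_, double = NA_real_,
    logical = NA, character = NA_character_,
    abort(paste0("unknown schema type: ", type))
  )
}

#' Construct a case-facts tibble
#'
#' Builds a one-row (or n-row, if vector arguments are given) tibble holding
#' the normalized clinical variables of an ICH case. Omitted fields are
#' unknown (`NA`).
#'
#' @param ... Named field values; names must belong to [case_facts_schema()].
#' @param .n Number of rows when no field is supplied (default 1).
#' @return A tibble with one column per schema field.
#' @examples
#' case_facts(gcs_total = 7L, hematoma_volume_ml = 40, bleed_location = "lobar")
#' @export
case_facts <- function(..., .n = 1L) {
  vals <- list(...)
  schema <- case_facts_schema()
  bad <- setdiff(names(vals), names(schema))
  if (length(bad) > 0) {
    abort(paste0("unknown case-facts field(s): ", paste(bad, collapse = ", ")))
  }
  nr <- if (length(vals) > 0) max(lengths(vals), .n) else .n
  cols <- lapply(names(schema), function(f) {
    if (f %in% names(vals)) {
      v <- vals[[f]]
      mode <- schema[[f]]
      v <- switch(mode,
        integer = as.integer(v), double = as.double(v),
        logical = as.logical(v), character = as.character(v)
      )
      rep_len(v, nr)
    } else {
      rep(na_of_type(schema[[f]]), nr)
    }
  })
  names(cols) <- names(schema)
  as_tibble(cols)
}

#' Total Glasgow Coma Scale score from its components
#'
#' @param eye Eye-opening component, integer in 1--4.
#' @param verbal Verbal component, integer in 1--5.
#' @param motor Motor component, integer in 1--6.
#' @return Integer total in 3--15 (vectorized).
#' @examples
#' compute_gcs_total(4, 5, 6) # 15
#' compute_gcs_total(2, 2, 4) # 8
#' @export
compute_gcs_total <- function(eye, verbal, motor) {
  check_range <- function(x, lo, hi, name) {
    bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
    if (any(bad)) {
      abort(sprintf(
        "GCS component '%s' out of range [%d, %d]: %s",
        name, lo, hi, paste(x[bad], collapse = ", ")
      ))
    }
  }
  check_range(eye, 1L, 4L, "eye")
  check_range(verbal, 1L, 5L, "verbal")
  check_range(motor, 1L, 6L, "motor")
  as.integer(eye + verbal + motor)
}

#' Validate a case-facts table
#'
#' Checks every row of `facts` against the invariants of the case model:
#' GCS components in range and consistent with the total when all are known,
#' non-negative volumes and shifts, physiologic bounds on vitals, and
#' enumeration membership. Violations are returned as data, not raised.
#'
#' @param facts A case-facts tibble (see [case_facts()]).
#' @return A tibble with columns `row`, `field`, `message`; zero rows when
#'   every invariant holds.
#' @export
validate_case_facts <- function(facts) {
  stopifnot(is.data.frame(facts))
  out <- list()
  add <- function(rows, field, message) {
    if (any(rows)) {
      out[[length(out) + 1L]] <<- tibble(
        row = which(rows), field = field, message = message
      )
    }
  }
  in_range <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  add(in_range(facts$gcs_eye, 1, 4), "gcs_eye", "must be in 1-4")
  add(in_range(facts$gcs_verbal, 1, 5), "gcs_verbal", "must be in 1-5")
  add(in_range(facts$gcs_motor, 1, 6), "gcs_motor", "must be in 1-6")
  add(in_range(facts$gcs_total, 3, 15), "gcs_total", "must be in 3-15")
  comp_known <- !is.na(facts$gcs_eye) & !is.na(facts$gcs_verbal) &
    !is.na(facts$gcs_motor) & !is.na(facts$gcs_total)
  mismatch <- comp_known &
    (facts$gcs_eye + facts$gcs_verbal + facts$gcs_motor) != facts$gcs_total
  add(mismatch, "gcs_total", "does not equal the sum of eye + verbal + motor")
  add(
    !is.na(facts$hematoma_volume_ml) & facts$hematoma_volume_ml < 0,
    "hematoma_volume_ml", "must be >= 0"
  )
  add(
    !is.na(facts$midline_shift_mm) & facts$midline_shift_mm < 0,
    "midline_shift_mm", "must be >= 0"
  )
  add(in_range(facts$spo2, 0, 100), "spo2", "must be a percentage in 0-100")
  add(
    !is.na(facts$heart_rate) & facts$heart_rate <= 0,
    "heart_rate", "must be > 0"
  )
  enum_check <- function(col, levels, field) {
    add(!is.na(facts[[col]]) & !(facts[[col]] %in% levels), field,
      paste0("must be one of: ", paste(levels, collapse = ", ")))
  }
  enum_check("consciousness_grade", consciousness_levels, "consciousness_grade")
  enum_check("pupil_state", pupil_levels, "pupil_state")
  enum_check("bleed_location", location_levels, "bleed_location")
  enum_check("laterality", laterality_levels, "laterality")
  enum_check("condition_trend", trend_levels, "condition_trend")
  if (length(out) == 0) {
    tibble(row = integer(), field = character(), message = character())
  } else {
    arrange(bind_rows(out), .data$row, .data$field)
  }
}

#' Collapse a fine treatment plan to its coarse (surgery vs non-surgery) form
#'
#' Plan I is emergency surgery; Plans IIA (non-surgical, unstable) and IIB
#' (non-surgical, stable) both collapse to Plan II.
#'
#' @param plan Character vector over `"PLAN_I"`, `"PLAN_IIA"`, `"PLAN_IIB"`
#'   (coarse labels pass through unchanged, making the mapping idempotent).
#' @return Character vector over `"PLAN_I"`, `"PLAN_II"`.
#' @export
plan_coarse <- function(plan) {
  ok <- is.na(plan) | plan %in% c(plan_levels, coarse_levels)
  if (!all(ok)) {
    abort(paste0("unknown plan label(s): ", paste(unique(plan[!ok]), collapse = ", ")))
  }
  ifelse(plan %in% c("PLAN_IIA", "PLAN_IIB", "PLAN_II"), "PLAN_II", plan)
}

#' Construct an eEMR record tibble
#'
#' One row per emergency electronic medical record: demographics plus the
#' four narrative sections the pipeline reads.
#'
#' @param record_id Unique, non-empty identifier.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param weight_kg,height_cm Optional anthropometrics.
#' @param chief_complaint,history,physical_exam,ct_report Narrative sections.
#' @param incomplete Flag set when narrative sections are knowingly empty.
#' @return A tibble, one row per record.
#' @export
emr_record <- function(record_id, age = NA_integer_, sex = NA_character_,
                       weight_kg = NA_real_, height_cm = NA_real_,
                       chief_complaint = "", history = "",
                       physical_exam = "", ct_report = "",
                       incomplete = FALSE) {
  record_id <- as.character(record_id)
  if (any(is.na(record_id) | record_id == "")) {
    abort("record_id must be non-empty")
  }
  if (anyDuplicated(record_id)) {
    abort("record_id must be unique within a corpus")
  }
  if (any(!is.na(age) & (age < 10 | age > 80))) {
    warn("age outside the 10-80 year inclusion range")
  }
  tibble(
    record_id = record_id,
    age = as.integer(age), sex = as.character(sex),
    weight_kg = as.double(weight_kg), height_cm = as.double(height_cm),
    chief_complaint = as.character(chief_complaint),
    history = as.character(history),
    physical_exam = as.character(physical_exam),
    ct_report = as.character(ct_report),
    incomplete = as.logical(incomplete)
  )
}

emr_sections <- c("chief_complaint", "history", "physical_exam", "ct_report")
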