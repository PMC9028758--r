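# Expert module: weighted logical judgment of extracted clinical variables.
# A logic table is an ordered set of weighted conjunction rules over the
# case-facts fields plus two score cut-points; the weighted score is the
# normalized sum of fired-rule weights, and ties at a cut-point resolve
# toward the more aggressive plan (clinical safety bias).

logic_ops <- c("eq", "ne", "lt", "le", "gt", "ge", "in", "unknown", "known")

#' Read a treatment logic table
#'
#' Loads and validates a YAML logic table: rule ids must be unique, weights
#' non-negative, every predicate field must exist in the case-facts schema,
#' every comparator must be known, the summed weight must be positive, and
#' `0 <= cut_low < cut_high <= 1`. Validation failures are configuration
#' errors raised at load time.
#'
#' @param path Path to a logic-table YAML file.
#' @return A `ich_logic_table` object.
#' @seealso [default_logic_table()]
#' @export
read_logic_table <- function(path) {
  if (!file.exists(path)) abort(paste0("logic-table file not found: ", path))
  raw <- yaml::yaml.load_file(path)
  schema <- case_facts_schema()
  rules <- lapply(raw$rules, function(r) {
    rid <- r$rule_id %||% abort("logic rule without rule_id")
    conds <- lapply(r$when, function(cond) {
      if (!(cond$field %in% names(schema))) {
        abort(paste0("rule '", rid, "': unknown field '", cond$field, "'"))
      }
      if (!(cond$op %in% logic_ops)) {
        abort(paste0("rule '", rid, "': unknown comparator '", cond$op, "'"))
      }
      if (is.null(cond$value) && !(cond$op %in% c("unknown", "known"))) {
        abort(paste0("rule '", rid, "': comparator '", cond$op, "' needs a value"))
      }
      cond
    })
    if (length(conds) == 0) abort(paste0("rule '", rid, "': empty predicate"))
    weight <- as.double(r$weight %||% 0)
    if (is.na(weight) || weight < 0) abort(paste0("rule '", rid, "': weight must be >= 0"))
    list(
      rule_id = rid, weight = weight,
      mandate = isTRUE(r$mandate), when = conds
    )
  })
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate rule_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  normalizer <- sum(vapply(rules, function(r) r$weight, double(1)))
  if (normalizer <= 0) abort("logic table has zero total weight")
  cut_high <- as.double(raw$cut_high)
  cut_low <- as.double(raw$cut_low)
  if (is.na(cut_high) || is.na(cut_low) ||
    cut_low < 0 || cut_low >= cut_high || cut_high > 1) {
    abort("cut-points must satisfy 0 <= cut_low < cut_high <= 1")
  }
  structure(
    list(
      rules = rules, cut_high = cut_high, cut_low = cut_low,
      normalizer = normalizer
    ),
    class = "ich_logic_table"
  )
}

#' The packaged default logic table
#'
#' Encodes widely published ICH surgical indications as a documented
#' stand-in: mandate rules for cerebellar hemorrhage with mass effect,
#' large supratentorial hematoma with depressed GCS, and herniation signs;
#' graded weighted rules for volume, GCS, midline shift, ventricular cast,
#' deterioration, anisocoria, and pathological reflexes, with cut-points
#' 0.5 / 0.15. All values are configuration, not code.
#'
#' @return A `ich_logic_table` object.
#' @export
default_logic_table <- function() {
  read_logic_table(system.file("extdata", "logic_table.yaml", package = "ichtriage"))
}

#' Modify cut-points of a logic table
#'
#' Convenience for controlled-disagreement experiments: returns a copy of
#' `table` with new cut-points.
#'
#' @param table A `ich_logic_table`.
#' @param cut_high,cut_low New cut-points (defaults keep the old values).
#' @return A `ich_logic_table`.
#' @export
with_cut_points <- function(table, cut_high = table$cut_high, cut_low = table$cut_low) {
  if (cut_low < 0 || cut_low >= cut_high || cut_high > 1) {
    abort("cut-points must satisfy 0 <= cut_low < cut_high <= 1")
  }
  table$cut_high <- cut_high
  table$cut_low <- cut_low
  table
}

#' @export
print.ich_logic_table <- function(x, ...) {
  n_mandate <- sum(vapply(x$rules, function(r) r$mandate, logical(1)))
  cat(
    "<ich_logic_table> ", length(x$rules), " rules (", n_mandate, " mandate), ",
    "total weight ", x$normalizer,
    ", cut_high ", x$cut_high, ", cut_low ", x$cut_low, "\n",
    sep = ""
  )
  invisible(x)
}

eval_condition <- function(facts, cond) {
  x <- facts[[cond$field]]
  if (cond$op == "unknown") return(is.na(x))
  if (cond$op == "known") return(!is.na(x))
  v <- cond$value
  r <- switch(cond$op,
    eq = x == v, ne = x != v,
    lt = x < v, le = x <= v, gt = x > v, ge = x >= v,
    "in" = x %in% unlist(v)
  )
  r & !is.na(r) # an unknown field never satisfies a comparator
}

# n_rows x n_rules logical matrix of fired predicates
rule_fire_matrix <- function(facts, table) {
  mat <- vapply(table$rules, function(rule) {
    Reduce(`&`, lapply(rule$when, eval_condition, facts = facts))
  }, logical(nrow(facts)))
  matrix(mat, nrow = nrow(facts))
}

#' Evaluate every logic rule against case facts
#'
#' Pure function: one row per (case, rule) in table order, with the fired
#' flag and the rule's weight.
#'
#' @param facts A case-facts tibble (any number of rows).
#' @param table A `ich_logic_table`.
#' @return Tibble `row`, `rule_id`, `fired`, `weight`, `mandate`.
#' @export
evaluate_rules <- function(facts, table = default_logic_table()) {
  fired <- rule_fire_matrix(facts, table)
  tibble(
    row = rep(seq_len(nrow(facts)), times = length(table$rules)),
    rule_id = rep(vapply(table$rules, function(r) r$rule_id, character(1)),
      each = nrow(facts)
    ),
    fired = as.vector(fired),
    weight = rep(vapply(table$rules, function(r) r$weight, double(1)),
      each = nrow(facts)
    ),
    mandate = rep(vapply(table$rules, function(r) r$mandate, logical(1)),
      each = nrow(facts)
    )
  ) |>
    arrange(.data$row)
}

#' Weighted score from fired rules
#'
#' The normalized sum of fired-rule weights: 0 when nothing fires, 1 when
#' every rule fires.
#'
#' @param fired Output of [evaluate_rules()] (any number of cases).
#' @param table The same `ich_logic_table`.
#' @return Numeric vector in `[0, 1]`, one score per case row.
#' @export
compute_weighted_score <- function(fired, table) {
  fired |>
    group_by(.data$row) |>
    summarise(score = sum(.data$weight[.data$fired]) / table$normalizer) |>
    arrange(.data$row) |>
    dplyr::pull("score")
}

#' Classify cases into treatment plans
#'
#' Evaluates the logic table on each row of `facts`. If any mandate rule
#' fires the case is Plan I regardless of score; otherwise the weighted
#' score is thresholded: `score >= cut_high` is Plan I, `cut_low <= score <
#' cut_high` Plan IIA, below Plan IIB (a score exactly at a cut-point takes
#' the more aggressive plan). A case with both GCS total and hematoma volume
#' unknown is flagged `insufficient_data`.
#'
#' @param facts Case-facts tibble, optionally with a `record_id` column.
#' @param table A `ich_logic_table`.
#' @return A decisions tibble: `record_id` (if supplied), `plan`,
#'   `coarse_plan`, `weighted_score`, `mandated`, `insufficient_data`,
#'   `fired_rules` (list column of rule ids in table order).
#' @examples
#' classify_plan(case_facts(
#'   bleed_location = "basal_ganglia", hematoma_volume_ml = 50,
#'   gcs_total = 7L, midline_shift_mm = 8
#' ))
#' @export
classify_plan <- function(facts, table = default_logic_table()) {
  stopifnot(is.data.frame(facts), nrow(facts) >= 1)
  fired <- rule_fire_matrix(facts, table)
  weights <- vapply(table$rules, function(r) r$weight, double(1))
  mandates <- vapply(table$rules, function(r) r$mandate, logical(1))
  ids <- vapply(table$rules, function(r) r$rule_id, character(1))
  score <- as.vector(fired %*% weights) / table$normalizer
  mandated <- as.vector(fired[, mandates, drop = FALSE] %*%
    rep(1, sum(mandates))) > 0
  plan <- ifelse(mandated | score >= table$cut_high, "PLAN_I",
    ifelse(score >= table$cut_low, "PLAN_IIA", "PLAN_IIB")
  )
  insufficient <- is.na(facts$gcs_total) & is.na(facts$hematoma_volume_ml)
  out <- tibble(
    plan = plan,
    coarse_plan = plan_coarse(plan),
    weighted_score = score,
    mandated = mandated,
    insufficient_data = insufficient,
    fired_rules = lapply(seq_len(nrow(facts)), function(i) ids[fired[i, ]])
  )
  if ("record_id" %in% names(facts)) {
    out <- dplyr::bind_cols(tibble(record_id = facts$record_id), out)
  }
  if (any(insufficient)) {
    warn(paste0(
      sum(insufficient),
      " case(s) with both GCS total and hematoma volume unknown; ",
      "decision rests on insufficient data"
    ))
  }
  out
}

#' Human-readable rationale for a plan decision
#'
#' Lists the fired rules with their weights (in table order), the weighted
#' score against both cut-points, and whether a mandate rule forced the
#' plan. Purely presentational; nothing is recomputed.
#'
#' @param decision One row of the tibble returned by [classify_plan()].
#' @param table The `ich_logic_table` used for the decision.
#' @return A single string.
#' @export
explain_decision <- function(decision, table = default_logic_table()) {
  stopifnot(is.data.frame(decision), nrow(decision) == 1)
  fired_ids <- decision$fired_rules[[1]]
  weights <- setNames(
    vapply(table$rules, function(r) r$weight, double(1)),
    vapply(table$rules, function(r) r$rule_id, character(1))
  )
  mandates <- setNames(
    vapply(table$rules, function(r) r$mandate, logical(1)),
    names(weights)
  )
  lines <- c(
    sprintf("plan: %s (coarse %s)", decision$plan, decision$coarse_plan),
    sprintf(
      "weighted score: %.3f (cut_high %.2f, cut_low %.2f)",
      decision$weighted_score, table$cut_high, table$cut_low
    )
  )
  if (isTRUE(decision$mandated)) {
    lines <- c(lines, sprintf(
      "mandatory surgical indication fired: %s",
      paste(fired_ids[mandates[fired_ids]], collapse = ", ")
    ))
  }
  if (length(fired_ids) == 0) {
    lines <- c(lines, "no rule fired; score 0 -> PLAN_IIB")
  } else {
    lines <- c(lines, "fired rules:", sprintf(
      "  - %s (weight %g%s)", fired_ids, weights[fired_ids],
      ifelse(mandates[fired_ids], ", mandate", "")
    ))
  }
  if (isTRUE(decision$insufficient_data)) {
    lines <- c(lines, "warning: insufficient data (GCS total and hematoma volume both unknown)")
  }
  paste(lines, collapse = "\n")
}
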