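# JSON Lines dialects shared by the pipeline stages.
#
# Corpus: one eEMR per line, fields record_id, age, sex, weight_kg, height_cm,
# chief_complaint, history, physical_exam, ct_report (optional fields omitted
# when unknown). Case facts: one object per line, NA encoded as null.

jsonl_write <- function(rows, path, drop_na = FALSE) {
  lines <- vapply(rows, function(row) {
    if (drop_na) row <- row[!vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

jsonl_read <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write / read an eEMR corpus as JSON Lines
#'
#' @param records An eEMR tibble (see [emr_record()]).
#' @param path File path.
#' @return `path` (write) or the corpus tibble (read), invisibly for write.
#' @export
write_emr_corpus <- function(records, path) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    as.list(records[i, setdiff(names(records), "incomplete"), drop = FALSE])
  })
  jsonl_write(rows, path, drop_na = TRUE)
}

#' @rdname write_emr_corpus
#' @export
read_emr_corpus <- function(path) {
  rows <- jsonl_read(path)
  recs <- lapply(rows, function(r) {
    emr_record(
      record_id = r$record_id,
      age = r$age %||% NA_integer_, sex = r$sex %||% NA_character_,
      weight_kg = r$weight_kg %||% NA_real_,
      height_cm = r$height_cm %||% NA_real_,
      chief_complaint = r$chief_complaint %||% "",
      history = r$history %||% "",
      physical_exam = r$physical_exam %||% "",
      ct_report = r$ct_report %||% "",
      incomplete = all(!nzchar(c(
        r$chief_complaint %||% "", r$history %||% "",
        r$physical_exam %||% "", r$ct_report %||% ""
      )))
    )
  })
  bind_rows(recs)
}

#' Write / read case-facts tables as JSON Lines
#'
#' Unknown values are encoded as JSON `null`.
#'
#' @param facts Case-facts tibble, optionally with a `record_id` column.
#' @param path File path.
#' @return `path` (write) or a case-facts tibble (read).
#' @export
write_case_facts <- function(facts, path) {
  rows <- lapply(seq_len(nrow(facts)), function(i) as.list(facts[i, , drop = FALSE]))
  jsonl_write(rows, path)
}

#' @rdname write_case_facts
#' @export
read_case_facts <- function(path) {
  rows <- jsonl_read(path)
  schema <- case_facts_schema()
  recs <- lapply(rows, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    known <- r[intersect(names(r), names(schema))]
    row <- do.call(case_facts, known)
    if (!is.null(r$record_id) && !is.na(r$record_id)) {
      row <- dplyr::bind_cols(tibble(record_id = as.character(r$record_id)), row)
    }
    row
  })
  bind_rows(recs)
}

#' Write extracted entity mentions as JSON Lines
#'
#' One mention per line: record_id, label, field, section, start, end,
#' raw_text, value. Suitable for BIO-style training-data generation.
#'
#' @param mentions Mentions tibble from [extract_entities()].
#' @param path File path.
#' @export
write_mentions <- function(mentions, path) {
  rows <- lapply(seq_len(nrow(mentions)), function(i) as.list(mentions[i, , drop = FALSE]))
  jsonl_write(rows, path)
}

#' Write / read plan decisions as JSON Lines
#'
#' One decision per line: record_id, plan, coarse_plan, weighted_score,
#' mandated, fired_rules (array of rule ids in table order).
#'
#' @param decisions Decisions tibble from [classify_plan()].
#' @param path File path.
#' @export
write_decisions <- function(decisions, path) {
  rows <- lapply(seq_len(nrow(decisions)), function(i) {
    list(
      record_id = decisions$record_id[i],
      plan = decisions$plan[i],
      coarse_plan = decisions$coarse_plan[i],
      weighted_score = decisions$weighted_score[i],
      mandated = decisions$mandated[i],
      insufficient_data = decisions$insufficient_data[i],
      fired_rules = I(decisions$fired_rules[[i]])
    )
  })
  jsonl_write(rows, path)
}

#' @rdname write_decisions
#' @export
read_decisions <- function(path) {
  rows <- jsonl_read(path)
  tibble(
    record_id = vapply(rows, function(r) as.character(r$record_id), character(1)),
    plan = vapply(rows, function(r) r$plan, character(1)),
    coarse_plan = vapply(rows, function(r) r$coarse_plan, character(1)),
    weighted_score = vapply(rows, function(r) as.double(r$weighted_score), double(1)),
    mandated = vapply(rows, function(r) as.logical(r$mandated), logical(1)),
    insufficient_data = vapply(rows, function(r) as.logical(r$insufficient_data %||% NA), logical(1)),
    fired_rules = lapply(rows, function(r) as.character(unlist(r$fired_rules)))
  )
}

#' Write / read the gold-standard file
#'
#' One line per case: record_id, gold_plan, true_facts (nested object with
#' unknowns as null).
#'
#' @param gold Tibble with `record_id`, `gold_plan` and the case-facts columns.
#' @param path File path.
#' @export
write_gold_standard <- function(gold, path) {
  fact_cols <- intersect(names(case_facts_schema()), names(gold))
  rows <- lapply(seq_len(nrow(gold)), function(i) {
    list(
      record_id = gold$record_id[i],
      gold_plan = gold$gold_plan[i],
      true_facts = as.list(gold[i, fact_cols, drop = FALSE])
    )
  })
  jsonl_write(rows, path)
}

#' @rdname write_gold_standard
#' @export
read_gold_standard <- function(path) {
  rows <- jsonl_read(path)
  recs <- lapply(rows, function(r) {
    tf <- lapply(r$true_facts, function(v) if (is.null(v)) NA else v)
    facts <- do.call(case_facts, tf[intersect(names(tf), names(case_facts_schema()))])
    dplyr::bind_cols(
      tibble(record_id = as.character(r$record_id), gold_plan = r$gold_plan),
      facts
    )
  })
  bind_rows(recs)
}
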