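# Reference entity recognizer: dictionary + regex matching over preprocessed
# section text, with longest-match-first overlap resolution per label and a
# minimal clause-scope negation rule for tri-state fields.

negation_cue_pattern <- "\\b(?:no|denies|denied|without|not|absent)\\b"

normalize_value <- function(entry, value, unit) {
  if (!is.null(entry$map)) {
    mapped <- entry$map[[value]]
    if (is.null(mapped)) return(NA_character_)
    return(as.character(mapped))
  }
  switch(entry$normalizer,
    number = value,
    volume_ml = value, # ml and cc are both milliliters
    length_mm = {
      num <- as.numeric(value)
      if (identical(unit, "cm")) num <- round(num * 10, 6)
      format(num, trim = TRUE, scientific = FALSE)
    },
    value
  )
}

# TRUE when a negation cue occurs earlier in the same clause (clauses are
# delimited by '.' and ';') as the span starting at `start`.
is_negated <- function(text, start) {
  prefix <- substr(text, 1L, start - 1L)
  delims <- gregexpr("[.;]", prefix)[[1]]
  clause_start <- if (delims[1] == -1L) 1L else max(as.integer(delims)) + 1L
  clause <- substr(text, clause_start, start - 1L)
  grepl(negation_cue_pattern, clause, perl = TRUE)
}

# Returns parallel vectors (label, field, start, end, value) for all
# occurrences of one entry in one preprocessed section. Plain vectors keep
# the scan fast over large corpora.
match_entry <- function(entry, text) {
  m <- gregexpr(entry$pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cap_start <- attr(m, "capture.start")
  cap_len <- attr(m, "capture.length")
  if (length(entry$field_groups) > 0 && is.null(entry$field)) {
    # one mention per named capture group, spanning the group
    gs <- as.vector(cap_start[, entry$field_groups, drop = FALSE])
    gl <- as.vector(cap_len[, entry$field_groups, drop = FALSE])
    keep <- gs > 0
    gs <- gs[keep]
    gl <- gl[keep]
    fields <- rep(entry$field_groups, each = length(starts))[keep]
    raw <- substring(text, gs, gs + gl - 1L)
    list(label = fields, field = fields, start = gs, end = gs + gl - 1L, value = raw)
  } else {
    value <- if (!is.null(entry$value)) {
      rep(as.character(entry$value), length(starts))
    } else {
      vs <- cap_start[, "value"]
      vl <- cap_len[, "value"]
      raw_val <- substring(text, vs, vs + vl - 1L)
      units <- if ("unit" %in% colnames(cap_start)) {
        us <- cap_start[, "unit"]
        ifelse(us > 0, substring(text, us, us + cap_len[, "unit"] - 1L), NA_character_)
      } else {
        rep(NA_character_, length(starts))
      }
      mapply(function(v, u) {
        normalize_value(entry, v, if (is.na(u)) NULL else u)
      }, raw_val, units, USE.NAMES = FALSE)
    }
    list(
      label = rep(entry$label, length(starts)),
      field = rep(entry$field, length(starts)),
      start = starts, end = starts + lens - 1L, value = value
    )
  }
}

# per label: keep longest first, then leftmost, discarding overlaps
drop_overlaps <- function(df) {
  keep_all <- logical(nrow(df))
  for (lab in unique(df$label)) {
    idx <- which(df$label == lab)
    if (length(idx) == 1L) {
      keep_all[idx] <- TRUE
      next
    }
    ord <- idx[order(-(df$end[idx] - df$start[idx]), df$start[idx])]
    occ_s <- integer(0)
    occ_e <- integer(0)
    for (i in ord) {
      s <- df$start[i]
      e <- df$end[i]
      if (!any(s <= occ_e & e >= occ_s)) {
        keep_all[i] <- TRUE
        occ_s <- c(occ_s, s)
        occ_e <- c(occ_e, e)
      }
    }
  }
  df[keep_all, , drop = FALSE]
}

#' Extract entity mentions from an eEMR record
#'
#' Preprocesses each narrative section and scans it with every lexicon entry.
#' Overlapping occurrences of the same label are resolved longest-match-first,
#' scanning left to right. Tri-state (logical) fields are set to `"false"`
#' when a negation cue ("no", "denies", "without", ...) precedes the mention
#' in the same clause. Offsets are 0-based, half-open, into the preprocessed
#' section text.
#'
#' @param records An eEMR tibble (one or more rows, see [emr_record()]).
#' @param lexicon An `ich_lexicon`.
#' @return A mentions tibble: `record_id`, `label`, `field`, `section`,
#'   `start`, `end`, `raw_text`, `value`, sorted by record, section, start.
#' @export
extract_entities <- function(records, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(records))
  schema <- case_facts_schema()
  negatable <- setNames(
    vapply(lexicon$entries, function(e) isTRUE(e$negatable), logical(1)),
    vapply(lexicon$entries, function(e) e$label, character(1))
  )
  logical_field <- names(schema)[schema == "logical"]
  acc <- vector("list", nrow(records) * length(emr_sections))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    for (section in emr_sections) {
      pp <- preprocess_text(records[[section]][i], lexicon)
      if (nchar(pp$text) == 0L) next
      hits <- lapply(lexicon$entries, match_entry, text = pp$text)
      hits <- hits[!vapply(hits, is.null, logical(1))]
      if (length(hits) == 0L) next
      found <- list(
        label = unlist(lapply(hits, `[[`, "label")),
        field = unlist(lapply(hits, `[[`, "field")),
        start = unlist(lapply(hits, `[[`, "start")),
        end = unlist(lapply(hits, `[[`, "end")),
        value = unlist(lapply(hits, `[[`, "value"))
      )
      found <- as.data.frame(found, stringsAsFactors = FALSE)
      found <- drop_overlaps(found)
      # clause-scope negation for tri-state fields
      cand <- found$field %in% logical_field & (negatable[found$label] %||% TRUE)
      if (any(cand)) {
        neg <- vapply(found$start[cand], function(s) is_negated(pp$text, s), logical(1))
        found$value[cand][neg] <- "false"
      }
      found$raw_text <- substring(pp$text, found$start, found$end)
      found$section <- section
      found$record_id <- records$record_id[i]
      k <- k + 1L
      acc[[k]] <- found
    }
  }
  if (k == 0L) {
    return(tibble(
      record_id = character(), label = character(), field = character(),
      section = character(), start = integer(), end = integer(),
      raw_text = character(), value = character()
    ))
  }
  out <- as_tibble(do.call(rbind, acc[seq_len(k)]))
  out <- out |>
    mutate(
      start = as.integer(.data$start - 1L), # 0-based
      end = as.integer(.data$end), # half-open
      section = factor(.data$section, levels = emr_sections)
    ) |>
    arrange(.data$record_id, .data$section, .data$start) |>
    mutate(section = as.character(.data$section)) |>
    select(
      "record_id", "label", "field", "section",
      "start", "end", "raw_text", "value"
    )
  out
}

section_precedence <- c(
  chief_complaint = 1L, history = 2L, physical_exam = 3L, ct_report = 4L
)

typed_value <- function(value, type) {
  switch(type,
    integer = as.integer(as.numeric(value)),
    double = as.numeric(value),
    logical = identical(value, "true"),
    character = value
  )
}

#' Assemble case facts from extracted mentions
#'
#' Fills each case-facts field from the mentions that target it. When two
#' mentions disagree, the section precedence ct_report > physical_exam >
#' history > chief_complaint applies, then the later offset wins; every
#' conflict is recorded. Fields with no mention stay unknown.
#'
#' @param mentions Mentions tibble from [extract_entities()].
#' @param records The eEMR tibble the mentions came from (supplies the full
#'   record_id set so mention-free records still yield all-unknown rows).
#' @return A list: `facts` (tibble `record_id` + case-facts columns) and
#'   `conflicts` (tibble `record_id`, `field`, `kept`, `discarded`).
#' @export
assemble_case_facts <- function(mentions, records) {
  schema <- case_facts_schema()
  n <- nrow(records)
  cols <- lapply(schema, function(type) rep(na_of_type(type), n))
  conflict_rows <- list()
  ment_by_record <- split(
    mentions[c("field", "section", "start", "value")],
    factor(mentions$record_id, levels = records$record_id)
  )
  for (i in seq_len(n)) {
    ment <- ment_by_record[[i]]
    if (is.null(ment) || nrow(ment) == 0L) next
    rid <- records$record_id[i]
    for (f in unique(ment$field)) {
      sel <- ment$field == f
      prec <- section_precedence[ment$section[sel]]
      starts <- ment$start[sel]
      vals <- ment$value[sel]
      winner <- which.max(prec * 1e9 + starts) # precedence, then later offset
      distinct_vals <- unique(vals)
      if (length(distinct_vals) > 1) {
        conflict_rows[[length(conflict_rows) + 1L]] <- tibble(
          record_id = rid, field = f, kept = vals[winner],
          discarded = paste(setdiff(distinct_vals, vals[winner]), collapse = "; ")
        )
      }
      cols[[f]][i] <- typed_value(vals[winner], schema[[f]])
    }
  }
  list(
    facts = dplyr::bind_cols(tibble(record_id = records$record_id), as_tibble(cols)),
    conflicts = if (length(conflict_rows) > 0) {
      bind_rows(conflict_rows)
    } else {
      tibble(
        record_id = character(), field = character(),
        kept = character(), discarded = character()
      )
    }
  )
}

#' Extract case facts straight from records
#'
#' Convenience wrapper: [extract_entities()] then [assemble_case_facts()].
#'
#' @inheritParams extract_entities
#' @return The list returned by [assemble_case_facts()].
#' @export
extract_case_facts <- function(records, lexicon = default_lexicon()) {
  assemble_case_facts(extract_entities(records, lexicon), records)
}
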