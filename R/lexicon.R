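# Lexicon: dictionary + regex inventory driving the reference entity
# recognizer. A learned tagger can replace the matcher (records in, mentions
# out) without touching the rest of the pipeline; the lexicon file is the
# reference backend's configuration.

#' Read an extraction lexicon
#'
#' Loads a YAML lexicon with sections `abbreviations`, `misspellings` and
#' `entries`. Every entry must target existing case-facts fields and its
#' pattern must compile; violations raise a configuration error naming the
#' entry.
#'
#' @param path Path to a lexicon YAML file.
#' @return A `ich_lexicon` object.
#' @seealso [default_lexicon()]
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  raw <- yaml::yaml.load_file(path)
  schema <- case_facts_schema()
  entries <- lapply(raw$entries, function(e) {
    lab <- e$label %||% "<unnamed>"
    if (is.null(e$pattern)) abort(paste0("lexicon entry '", lab, "': missing pattern"))
    bad_pattern <- function(err) {
      abort(paste0(
        "lexicon entry '", lab, "': pattern does not compile: ", conditionMessage(err)
      ))
    }
    probe <- withCallingHandlers(
      tryCatch(gregexpr(e$pattern, "", perl = TRUE), error = bad_pattern),
      warning = bad_pattern
    )
    groups <- attr(probe[[1]], "capture.names") %||% character(0)
    groups <- groups[nzchar(groups)]
    field_groups <- intersect(groups, names(schema))
    targets <- if (!is.null(e$field)) e$field else field_groups
    if (length(targets) == 0) {
      abort(paste0("lexicon entry '", lab, "': no target field (field: or named groups)"))
    }
    bad <- setdiff(targets, names(schema))
    if (length(bad) > 0) {
      abort(paste0(
        "lexicon entry '", lab, "': unknown case-facts field(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    list(
      label = lab, pattern = e$pattern,
      field = if (!is.null(e$field)) e$field else NULL,
      field_groups = field_groups,
      value = e$value, map = e$map,
      normalizer = e$normalizer %||% "number",
      negatable = e$negatable %||% TRUE
    )
  })
  structure(
    list(
      abbreviations = lapply(raw$abbreviations %||% list(), as.character),
      misspellings = lapply(raw$misspellings %||% list(), as.character),
      entries = entries
    ),
    class = "ich_lexicon"
  )
}

#' The packaged default lexicon
#'
#' Covers the GCS score, vital signs (heart rate, blood pressure, oxygen
#' saturation), consciousness grading, pathological reflex, pupil state,
#' the headache/nausea/vomiting symptom triad, and the CT-report keywords
#' (bleed location, hematoma volume, ventricular cast and shape, midline
#' shift), plus abbreviation and misspelling tables.
#'
#' @return A `ich_lexicon` object.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "ichtriage"))
}

#' @export
print.ich_lexicon <- function(x, ...) {
  cat(
    "<ich_lexicon> ", length(x$entries), " entries, ",
    length(x$abbreviations), " abbreviations, ",
    length(x$misspellings), " misspelling corrections\n",
    sep = ""
  )
  invisible(x)
}
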