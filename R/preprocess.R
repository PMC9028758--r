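# Text normalization with offset tracking. Every rewrite keeps a map from
# output character positions to positions in the raw section text, so a
# mention found in normalized text can be reported against the original.

regex_escape <- function(x) {
  gsub("([.\\\\|()\\[\\]{}^$*+?/])", "\\\\\\1", x, perl = TRUE)
}

# Apply one pattern rewrite to (text, map); replacement characters inherit the
# original offset of the first character of the span they replace.
rewrite_with_map <- function(text, map, pattern, repl_fun) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(text = text, map = map))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- character(0)
  maps <- list()
  pos <- 1L
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- s + lens[k] - 1L
    if (s > pos) {
      pieces <- c(pieces, substr(text, pos, s - 1L))
      maps[[length(maps) + 1L]] <- map[pos:(s - 1L)]
    }
    repl <- repl_fun(substr(text, s, e))
    if (nchar(repl) > 0L) {
      pieces <- c(pieces, repl)
      maps[[length(maps) + 1L]] <- rep(map[s], nchar(repl))
    }
    pos <- e + 1L
  }
  if (pos <= nchar(text)) {
    pieces <- c(pieces, substr(text, pos, nchar(text)))
    maps[[length(maps) + 1L]] <- map[pos:nchar(text)]
  }
  list(
    text = paste(pieces, collapse = ""),
    map = as.integer(unlist(maps) %||% integer(0))
  )
}

# Non-text symbols replaced by a space: control characters and decorative
# punctuation runs. Clinically meaningful punctuation (.,;:()/%-) survives.
symbol_pattern <- "[\\x00-\\x1f\\x7f*#~^=+|<>@$&_`\"\\\\]+"

table_sub_pattern <- function(keys) {
  keys <- keys[order(-nchar(keys))]
  paste0("(?<![a-z0-9])(?:", paste(regex_escape(keys), collapse = "|"), ")(?![a-z0-9])")
}

#' Normalize a narrative section for extraction
#'
#' Lowercases, replaces non-text symbols (control characters, decorative
#' punctuation runs) with spaces, corrects misspellings and expands
#' abbreviations via the lexicon tables, and collapses whitespace. An offset
#' map from every output character to its position in the raw input is
#' carried along so downstream mentions can be reported against the original
#' text.
#'
#' @param text A single string (possibly empty).
#' @param lexicon An `ich_lexicon` (default: the packaged lexicon).
#' @return A list with `text` (normalized string) and `map` (integer vector;
#'   `map[i]` is the 1-based raw-text offset behind output character `i`).
#' @examples
#' preprocess_text("pt c/o headache", default_lexicon())$text
#' @export
preprocess_text <- function(text, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || nchar(text) == 0L) {
    return(list(text = "", map = integer(0)))
  }
  state <- list(text = tolower(text), map = seq_len(nchar(text)))
  state <- rewrite_with_map(state$text, state$map, symbol_pattern, function(m) " ")
  subs <- c(lexicon$misspellings, lexicon$abbreviations)
  if (length(subs) > 0) {
    lookup <- unlist(subs)
    state <- rewrite_with_map(
      state$text, state$map, table_sub_pattern(names(subs)),
      function(m) lookup[[m]]
    )
  }
  state <- rewrite_with_map(state$text, state$map, "\\s+", function(m) " ")
  state <- rewrite_with_map(state$text, state$map, "^ | $", function(m) "")
  state
}
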