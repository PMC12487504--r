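#' Read sessions from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{jsonl}{the native format: one JSON object per line, `{"session_id":
#'     ..., "quality": ..., "utterances": [...]}`. Nulls are preserved as
#'     `NA`.}
#'   \item{csv}{one utterance per row with columns `session_id, quality,
#'     index, speaker, text, category, score`. Missing values are empty
#'     fields; this dialect cannot distinguish a missing text from an empty
#'     string (use jsonl when that matters).}
#'   \item{annomi_csv}{transcript CSVs in the style of public MI corpora:
#'     utterance rows carrying a transcript id, a session-level quality
#'     label, an interlocutor column and a client talk-type annotation, but
#'     no numeric strength scores. Column names are supplied via
#'     `column_map` because corpus schemas vary.}
#' }
#'
#' @param path file path.
#' @param format one of "jsonl", "csv", "annomi_csv".
#' @param column_map named list mapping the annomi_csv roles
#'   `session_id`, `quality`, `speaker`, `text`, `category` to column names;
#'   see [annomi_column_map()] for the defaults.
#' @param category_map named character vector translating raw talk-type
#'   values to "change"/"neutral"/"sustain".
#' @return an `mi_session_set` with `provenance = "file"`.
#' @export
read_sessions <- function(path, format = c("jsonl", "csv", "annomi_csv"),
                          column_map = annomi_column_map(),
                          category_map = c(change = "change",
                                           neutral = "neutral",
                                           sustain = "sustain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  switch(format,
         jsonl = read_sessions_jsonl(path),
         csv = read_sessions_csv(path),
         annomi_csv = read_sessions_annomi(path, column_map, category_map))
}

#' Default column mapping for annomi_csv transcripts
#'
#' @return named list of column names.
#' @export
annomi_column_map <- function() {
  list(session_id = "transcript_id", quality = "mi_quality",
       speaker = "interlocutor", text = "utterance_text",
       category = "client_talk_type")
}

scalar_or_na <- function(x, as = as.character) {
  if (is.null(x) || length(x) == 0L || (length(x) == 1L && is.na(x))) {
    as(NA)
  } else {
    as(x)
  }
}

read_sessions_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sessions <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    if (is.null(obj$session_id)) {
      stop_validation("jsonl record lacks required field 'session_id'")
    }
    utt <- do.call(rbind, lapply(obj$utterances, function(u) {
      data.frame(speaker = scalar_or_na(u$speaker),
                 text = scalar_or_na(u$text),
                 category = scalar_or_na(u$category),
                 score = scalar_or_na(u$score, as.integer),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(utt)) utt <- empty_utterances()
    session(obj$session_id, obj$quality %||% "unknown", utt,
            hidden_states = if (!is.null(obj$hidden_states)) {
              as.integer(unlist(obj$hidden_states))
            })
  })
  session_set(sessions, provenance = "file")
}

read_sessions_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = "character")
  need <- c("session_id", "quality", "index", "speaker", "text",
            "category", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_validation("csv lacks required column(s): %s",
                    paste(miss, collapse = ", "))
  }
  df$score <- suppressWarnings(as.integer(df$score))
  df$index <- as.integer(df$index)
  if (nrow(df) == 0L) return(session_set(list(), provenance = "file"))
  df <- df[order(match(df$session_id, unique(df$session_id)), df$index), ]
  sessions <- lapply(split(df, factor(df$session_id,
                                      levels = unique(df$session_id))),
                     function(d) {
                       session(d$session_id[1], d$quality[1] %||% "unknown",
                               d[, c("speaker", "text", "category", "score")])
                     })
  session_set(unname(sessions), provenance = "file")
}

read_sessions_annomi <- function(path, column_map, category_map) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = "character")
  roles <- c("session_id", "quality", "speaker", "text", "category")
  for (r in roles) {
    col <- column_map[[r]]
    if (is.null(col) || !col %in% names(df)) {
      stop_validation("annomi_csv lacks required column '%s' (role '%s')",
                      col %||% "<unmapped>", r)
    }
  }
  out <- data.frame(session_id = df[[column_map$session_id]],
                    quality = tolower(df[[column_map$quality]]),
                    speaker = tolower(df[[column_map$speaker]]),
                    text = df[[column_map$text]],
                    category = df[[column_map$category]],
                    stringsAsFactors = FALSE)
  out$quality[!out$quality %in% c("high", "low")] <- "unknown"
  known <- out$category %in% names(category_map)
  out$category[known] <- unname(category_map[out$category[known]])
  out$category[!known] <- NA_character_
  out$score <- NA_integer_
  sessions <- lapply(split(out, factor(out$session_id,
                                       levels = unique(out$session_id))),
                     function(d) {
                       session(d$session_id[1], d$quality[1],
                               d[, c("speaker", "text", "category", "score")])
                     })
  session_set(unname(sessions), provenance = "file")
}

#' Write sessions to a file
#'
#' `read_sessions(write_sessions(x))` reproduces `x` field-for-field for both
#' formats (with the CSV caveat on empty-string texts documented in
#' [read_sessions()]).
#'
#' @param set an `mi_session_set`.
#' @param path output file path.
#' @param format "jsonl" or "csv".
#' @return `path`, invisibly.
#' @export
write_sessions <- function(set, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "mi_session_set"))
  if (format == "jsonl") {
    lines <- vapply(set$sessions, function(s) {
      utt <- s$utterances
      ul <- lapply(seq_len(nrow(utt)), function(i) {
        list(speaker = utt$speaker[i],
             text = if (is.na(utt$text[i])) NULL else utt$text[i],
             category = if (is.na(utt$category[i])) NULL else utt$category[i],
             score = if (is.na(utt$score[i])) NULL else utt$score[i])
      })
      obj <- list(session_id = s$session_id, quality = s$quality,
                  utterances = ul)
      if (!is.null(s$hidden_states)) obj$hidden_states <- s$hidden_states
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                    digits = NA))
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- lapply(set$sessions, function(s) {
      if (nrow(s$utterances) == 0L) return(NULL)
      cbind(data.frame(session_id = s$session_id, quality = s$quality,
                       stringsAsFactors = FALSE),
            s$utterances)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      df <- data.frame(session_id = character(0), quality = character(0),
                       index = integer(0), speaker = character(0),
                       text = character(0), category = character(0),
                       score = integer(0))
    }
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
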