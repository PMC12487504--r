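#' Construct a single utterance record
#'
#' @param speaker "client" or "therapist".
#' @param text utterance text, or `NA` when unavailable (synthetic sessions
#'   carry scores only).
#' @param category talk-type category: "change", "neutral", "sustain", or
#'   `NA`.
#' @param score integer motivational strength score in -5..+5, or `NA`. When
#'   both score and category are present they must agree with the sign
#'   convention (score > 0 is change talk, score = 0 neutral, score < 0
#'   sustain talk).
#' @return a one-row `data.frame` with columns `speaker`, `text`, `category`,
#'   `score`.
#' @export
utterance <- function(speaker, text = NA_character_, category = NA_character_,
                      score = NA_integer_) {
  speaker <- match.arg(speaker, c("client", "therapist"))
  if (!is.na(category)) {
    category <- match.arg(category, c("change", "neutral", "sustain"))
  }
  if (!is.na(score)) {
    check_score(score)
    if (!is.na(category) && category != category_from_score(score)) {
      stop_validation(
        "category '%s' contradicts the sign of score %d", category, score)
    }
  }
  data.frame(speaker = speaker, text = as.character(text),
             category = as.character(category), score = as.integer(score),
             stringsAsFactors = FALSE)
}

check_score <- function(score, session_id = NULL, index = NULL) {
  bad <- !is.na(score) & (score < -5 | score > 5 | score != round(score))
  if (any(bad)) {
    where <- if (!is.null(session_id)) {
      sprintf(" (session '%s', index %s)", session_id,
              paste(which(bad) - 1L, collapse = ","))
    } else ""
    stop_validation(
      "score must be an integer in [-5, 5]; got %s%s",
      paste(score[bad], collapse = ","), where)
  }
  invisible(TRUE)
}

#' Construct a session
#'
#' A session is an ordered list of utterances with a quality label. The
#' utterance table carries a 0-based `index` column that is always strictly
#' increasing; readers and writers preserve order.
#'
#' @param session_id unique session identifier.
#' @param quality "high", "low", or "unknown".
#' @param utterances a `data.frame` with columns `speaker`, `text`,
#'   `category`, `score` (e.g. from rbind-ing [utterance()] rows); an `index`
#'   column is added/overwritten as 0-based positions.
#' @param hidden_states optional integer vector of ground-truth latent states
#'   (1-based), used by the synthetic generator.
#' @return an object of class `mi_session`.
#' @export
session <- function(session_id, quality = c("unknown", "high", "low"),
                    utterances = empty_utterances(), hidden_states = NULL) {
  quality <- match.arg(quality)
  stopifnot(is.character(session_id), length(session_id) == 1L)
  utterances <- validate_utterances(utterances, session_id)
  out <- list(session_id = session_id, quality = quality,
              utterances = utterances, hidden_states = hidden_states)
  class(out) <- "mi_session"
  out
}

empty_utterances <- function() {
  data.frame(index = integer(0), speaker = character(0), text = character(0),
             category = character(0), score = integer(0),
             stringsAsFactors = FALSE)
}

validate_utterances <- function(utt, session_id) {
  need <- c("speaker", "text", "category", "score")
  miss <- setdiff(need, names(utt))
  if (length(miss)) {
    stop_validation("utterance table for session '%s' lacks column(s): %s",
                    session_id, paste(miss, collapse = ", "))
  }
  utt$index <- seq_len(nrow(utt)) - 1L
  utt <- utt[, c("index", need)]
  utt$speaker <- as.character(utt$speaker)
  utt$text <- as.character(utt$text)
  utt$category <- as.character(utt$category)
  utt$score <- as.integer(utt$score)
  bad_sp <- !utt$speaker %in% c("client", "therapist")
  if (any(bad_sp)) {
    stop_validation("session '%s': invalid speaker value(s) %s", session_id,
                    paste(unique(utt$speaker[bad_sp]), collapse = ","))
  }
  bad_cat <- !is.na(utt$category) &
    !utt$category %in% c("change", "neutral", "sustain")
  if (any(bad_cat)) {
    stop_validation("session '%s': invalid category value(s) %s", session_id,
                    paste(unique(utt$category[bad_cat]), collapse = ","))
  }
  check_score(utt$score, session_id)
  both <- !is.na(utt$score) & !is.na(utt$category)
  if (any(both)) {
    expect <- vapply(utt$score[both], category_from_score, character(1))
    off <- utt$category[both] != expect
    if (any(off)) {
      stop_validation(
        "session '%s': category contradicts score sign at index %s",
        session_id, paste(utt$index[both][off], collapse = ","))
    }
  }
  rownames(utt) <- NULL
  utt
}

#' Bundle sessions into a session set
#'
#' @param sessions list of [session()] objects with unique `session_id`s.
#' @param provenance "file" or "synthetic".
#' @param metadata free-form named list.
#' @return an object of class `mi_session_set`.
#' @export
session_set <- function(sessions, provenance = c("file", "synthetic"),
                        metadata = list()) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(sessions))
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  if (anyDuplicated(ids)) {
    stop_validation("duplicate session_id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- list(sessions = sessions, provenance = provenance,
              metadata = metadata)
  class(out) <- "mi_session_set"
  out
}

#' @export
print.mi_session_set <- function(x, ...) {
  q <- session_qualities(x)
  cat(sprintf("<mi_session_set> %d sessions (%s): %d high, %d low, %d unknown\n",
              length(x$sessions), x$provenance, sum(q == "high"),
              sum(q == "low"), sum(q == "unknown")))
  invisible(x)
}

#' @export
print.mi_session <- function(x, ...) {
  cat(sprintf("<mi_session> '%s' (%s quality): %d utterances (%d client)\n",
              x$session_id, x$quality, nrow(x$utterances),
              sum(x$utterances$speaker == "client")))
  invisible(x)
}

session_qualities <- function(set) {
  vapply(set$sessions, function(s) s$quality, character(1))
}

session_ids <- function(set) {
  vapply(set$sessions, function(s) s$session_id, character(1))
}

#' Extract a session's client score sequence
#'
#' Only client utterances feed the modeling stages; therapist utterances are
#' retained in the data model but dropped here. Utterances with missing
#' scores are dropped with a warning.
#'
#' @param s an `mi_session`.
#' @return numeric vector of scores in session order.
#' @export
client_scores <- function(s) {
  stopifnot(inherits(s, "mi_session"))
  cl <- s$utterances[s$utterances$speaker == "client", , drop = FALSE]
  if (anyNA(cl$score)) {
    warning(sprintf("session '%s': dropping %d client utterance(s) without scores",
                    s$session_id, sum(is.na(cl$score))), call. = FALSE)
    cl <- cl[!is.na(cl$score), , drop = FALSE]
  }
  as.numeric(cl$score)
}

# list of client score sequences for every session in a set, named by id
score_sequences <- function(set, min_len = 1L) {
  seqs <- lapply(set$sessions, client_scores)
  names(seqs) <- session_ids(set)
  keep <- vapply(seqs, length, integer(1)) >= min_len
  seqs[keep]
}

#' Subset a session set by quality label
#'
#' @param set an `mi_session_set`.
#' @param quality "high" or "low".
#' @return an `mi_session_set` containing only matching sessions.
#' @export
filter_quality <- function(set, quality) {
  stopifnot(inherits(set, "mi_session_set"))
  quality <- match.arg(quality, c("high", "low", "unknown"))
  keep <- session_qualities(set) == quality
  session_set(set$sessions[keep], provenance = set$provenance,
              metadata = set$metadata)
}
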