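#' Transcript-cleaning rules
#'
#' Two mechanical rules are applied to raw transcripts before modeling:
#' utterances whose text is a repetitive "n/a" filler pattern are removed,
#' and an exact duplicate of the immediately preceding utterance is removed
#' when the duplicate lacks a talk-type annotation (such lines are transcript
#' artifacts, not client speech).
#'
#' @param noise_pattern regular expression matched (case-insensitively)
#'   against the whitespace-stripped text; matching utterances are removed.
#'   The default captures two or more consecutive "n/a" tokens and nothing
#'   else.
#' @param drop_duplicates remove an utterance identical (speaker and text) to
#'   its predecessor when it carries no category annotation.
#' @return a list of class `mi_cleaning_rules`.
#' @export
cleaning_rules <- function(noise_pattern = "^(n/a){2,}$",
                           drop_duplicates = TRUE) {
  out <- list(noise_pattern = noise_pattern,
              drop_duplicates = isTRUE(drop_duplicates))
  class(out) <- "mi_cleaning_rules"
  out
}

#' Clean a session's transcript
#'
#' Applies [cleaning_rules()] to one session: noise-pattern utterances are
#' removed, un-annotated exact consecutive duplicates are removed, and the
#' survivors are re-indexed from 0. The removals are recorded in the
#' `"cleaning_log"` attribute of the result (a data.frame with the original
#' index, text and reason). Cleaning is idempotent and never reorders
#' surviving utterances.
#'
#' @param raw an `mi_session`.
#' @param rules a [cleaning_rules()] object.
#' @return the cleaned `mi_session`, with attribute `cleaning_log`.
#' @export
clean_session <- function(raw, rules = cleaning_rules()) {
  stopifnot(inherits(raw, "mi_session"))
  utt <- raw$utterances
  n <- nrow(utt)
  drop <- logical(n)
  reason <- character(n)

  stripped <- gsub("[[:space:]]+", "", ifelse(is.na(utt$text), "", utt$text))
  noisy <- grepl(rules$noise_pattern, stripped, ignore.case = TRUE) &
    nzchar(stripped)
  drop[noisy] <- TRUE
  reason[noisy] <- "noise_pattern"

  if (rules$drop_duplicates && n > 1L) {
    # compare each survivor-so-far against its surviving predecessor
    prev <- NA_integer_
    for (i in seq_len(n)) {
      if (drop[i]) next
      if (!is.na(prev)) {
        same <- identical(utt$speaker[i], utt$speaker[prev]) &&
          identical(utt$text[i], utt$text[prev]) && !is.na(utt$text[i])
        if (same && is.na(utt$category[i])) {
          drop[i] <- TRUE
          reason[i] <- "duplicate_unannotated"
          next
        }
      }
      prev <- i
    }
  }

  log <- data.frame(index = utt$index[drop],
                    text = utt$text[drop],
                    reason = reason[drop],
                    stringsAsFactors = FALSE)
  kept <- utt[!drop, c("speaker", "text", "category", "score"), drop = FALSE]
  out <- session(raw$session_id, raw$quality, kept,
                 hidden_states = raw$hidden_states)
  if (nrow(out$utterances) == 0L && n > 0L) {
    warning(sprintf("session '%s': cleaning removed every utterance",
                    raw$session_id), call. = FALSE)
  }
  attr(out, "cleaning_log") <- log
  out
}

#' Clean every session in a set
#'
#' @param set an `mi_session_set`.
#' @param rules a [cleaning_rules()] object.
#' @return the cleaned `mi_session_set`; per-session logs are concatenated in
#'   the `cleaning_log` attribute.
#' @export
clean_sessions <- function(set, rules = cleaning_rules()) {
  stopifnot(inherits(set, "mi_session_set"))
  cleaned <- lapply(set$sessions, clean_session, rules = rules)
  logs <- do.call(rbind, lapply(cleaned, function(s) {
    lg <- attr(s, "cleaning_log")
    if (nrow(lg)) cbind(session_id = s$session_id, lg) else NULL
  }))
  out <- session_set(cleaned, provenance = set$provenance,
                     metadata = set$metadata)
  attr(out, "cleaning_log") <- logs
  out
}
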