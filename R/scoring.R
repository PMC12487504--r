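#' Map a strength score to its talk-type category
#'
#' Positive scores indicate movement toward change (change talk), negative
#' scores resistance (sustain talk), and zero is neutral.
#'
#' @param score integer in -5..+5 (vectorized).
#' @return character vector of "change"/"neutral"/"sustain".
#' @export
#' @examples
#' category_from_score(c(3, 0, -5))
category_from_score <- function(score) {
  check_score(score)
  ifelse(is.na(score), NA_character_,
         ifelse(score > 0, "change", ifelse(score < 0, "sustain", "neutral")))
}

#' Default keyword lexicon for the mock scorer
#'
#' Signed weights for words commonly signalling commitment to change
#' (positive) or defence of the status quo (negative). Purely a deterministic
#' testing device; not a validated clinical instrument.
#'
#' @return named integer vector of keyword weights.
#' @export
default_lexicon <- function() {
  c(want = 2L, quit = 1L, ready = 2L, will = 2L, change = 1L, try = 1L,
    can = 1L, should = 1L, better = 1L, help = 1L,
    "can't" = -2L, cant = -2L, never = -2L, "won't" = -2L, wont = -2L,
    keep = -1L, stay = -1L, fine = -1L, "don't" = -1L, dont = -1L,
    pointless = -2L, impossible = -2L)
}

#' Deterministic lexicon scorer for an utterance
#'
#' Stand-in for a model-based utterance scorer: tokenizes the text, sums the
#' signed weights of lexicon hits and clips the total to -5..+5. Stateless
#' given `(text, context)` — the `context` argument exists so real scorers
#' honouring the sequential-context contract (only information available up
#' to the current utterance may be used) share the same signature; the mock
#' ignores it.
#'
#' @param text utterance text (may be empty).
#' @param context prior utterances (unused by the mock).
#' @param lexicon named integer vector of keyword weights.
#' @return integer score in -5..+5.
#' @export
#' @examples
#' mock_score_utterance("I really want to quit")
mock_score_utterance <- function(text, context = NULL,
                                 lexicon = default_lexicon()) {
  if (is.null(text)) stop_validation("text must not be NULL")
  if (is.na(text) || !nzchar(text)) return(0L)
  tokens <- strsplit(tolower(text), "[^a-z']+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  s <- sum(lexicon[tokens], na.rm = TRUE)
  as.integer(max(-5L, min(5L, s)))
}

#' Create a scorer plug-in
#'
#' A scorer is a name plus a `score_fn(text, context)` contract returning an
#' integer in -5..+5. [mock_scorer()] wraps the lexicon rule; adapters for
#' external models implement the same contract (no network code ships here).
#'
#' @param name scorer name.
#' @param score_fn function of `(text, context)` returning an integer score.
#' @return an object of class `mi_scorer`.
#' @export
scorer <- function(name, score_fn) {
  stopifnot(is.character(name), is.function(score_fn))
  structure(list(name = name, score_fn = score_fn), class = "mi_scorer")
}

#' @rdname scorer
#' @param lexicon keyword weights for the mock rule.
#' @export
mock_scorer <- function(lexicon = default_lexicon()) {
  scorer("mock_lexicon", function(text, context = NULL) {
    mock_score_utterance(text, context, lexicon)
  })
}

#' Score every client utterance in a session set
#'
#' Applies a scorer sequentially within each session (each call receives the
#' utterances seen so far as context) and fills the `score` and `category`
#' fields of client utterances. Therapist utterances are left unscored.
#'
#' @param set an `mi_session_set` whose client utterances carry text.
#' @param scorer an `mi_scorer`, default the lexicon mock.
#' @return the scored `mi_session_set`.
#' @export
score_sessions <- function(set, scorer = mock_scorer()) {
  stopifnot(inherits(set, "mi_session_set"), inherits(scorer, "mi_scorer"))
  scored <- lapply(set$sessions, function(s) {
    utt <- s$utterances
    for (i in seq_len(nrow(utt))) {
      if (utt$speaker[i] != "client") next
      ctx <- utt[seq_len(i - 1L), , drop = FALSE]
      sc <- scorer$score_fn(utt$text[i], ctx)
      check_score(sc, s$session_id)
      utt$score[i] <- as.integer(sc)
      utt$category[i] <- category_from_score(sc)
    }
    session(s$session_id, s$quality,
            utt[, c("speaker", "text", "category", "score")],
            hidden_states = s$hidden_states)
  })
  session_set(scored, provenance = set$provenance, metadata = set$metadata)
}
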