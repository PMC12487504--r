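#' Ground-truth generator profile
#'
#' A fully specified 3-state Markov emission model in (Towards Change,
#' Non-Determined, Away From Change) order, used to simulate session score
#' sequences with known dynamics. Default numeric values throughout the
#' generator are package-invented testing conventions, not estimates from any
#' corpus.
#'
#' @param name profile name.
#' @param pi start distribution (length 3, sums to 1).
#' @param A 3x3 row-stochastic transition matrix.
#' @param emission_means per-state Gaussian means; must be strictly
#'   decreasing (gradient-valid) unless `allow_gradient_violation = TRUE`,
#'   which exists to exercise the invalid-gradient code path.
#' @param emission_sds per-state positive standard deviations.
#' @param length_range integer bounds (inclusive) on client utterances per
#'   session.
#' @param allow_gradient_violation permit non-decreasing emission means.
#' @return list of class `mi_generator_profile`.
#' @export
generator_profile <- function(name, pi, A, emission_means = c(3, 0, -3),
                              emission_sds = c(1, 1, 1),
                              length_range = c(40L, 120L),
                              allow_gradient_violation = FALSE) {
  A <- as.matrix(A)
  stopifnot(length(pi) == 3L, all(dim(A) == c(3L, 3L)),
            length(emission_means) == 3L, length(emission_sds) == 3L,
            all(emission_sds > 0), length(length_range) == 2L)
  if (any(abs(rowSums(A) - 1) > 1e-12) || abs(sum(pi) - 1) > 1e-12) {
    stop_validation("profile '%s': pi and rows of A must sum to 1", name)
  }
  if (any(A < 0) || any(pi < 0)) {
    stop_validation("profile '%s': probabilities must be non-negative", name)
  }
  if (!allow_gradient_violation && !all(diff(emission_means) < 0)) {
    stop_validation(
      "profile '%s': emission means must be strictly decreasing (set allow_gradient_violation = TRUE to override)",
      name)
  }
  structure(list(name = name, pi = as.numeric(pi), A = A,
                 emission_means = as.numeric(emission_means),
                 emission_sds = as.numeric(emission_sds),
                 length_range = as.integer(length_range)),
            class = "mi_generator_profile")
}

#' Default high- and low-quality generator profiles
#'
#' The high profile is "fluid" (every off-diagonal transition >= 0.1,
#' reflecting dynamic movement between motivational states); the low profile
#' is "sticky-Away" (Away From Change self-transition >= 0.75, reflecting
#' persistence in resistance). Emission parameters are mu = (+3, 0, -3),
#' sigma = (1, 1, 1) on the -5..+5 score scale.
#'
#' @return named list with elements `high` and `low`.
#' @export
default_profiles <- function() {
  list(
    high = generator_profile(
      "high_fluid",
      pi = c(0.40, 0.40, 0.20),
      A = matrix(c(0.55, 0.30, 0.15,
                   0.35, 0.45, 0.20,
                   0.30, 0.35, 0.35), 3, 3, byrow = TRUE)),
    low = generator_profile(
      "low_sticky_away",
      pi = c(0.15, 0.35, 0.50),
      A = matrix(c(0.25, 0.35, 0.40,
                   0.15, 0.45, 0.40,
                   0.05, 0.15, 0.80), 3, 3, byrow = TRUE)))
}

#' Synthetic dataset specification
#'
#' @param n_high,n_low session counts per quality group (defaults 30 and 10,
#'   the study design emulated by the generator).
#' @param profiles named list with `high` and `low`
#'   [generator_profile()]s.
#' @param seed integer seed.
#' @return list of class `mi_synthetic_spec`.
#' @export
synthetic_spec <- function(n_high = 30L, n_low = 10L,
                           profiles = default_profiles(), seed = 1L) {
  stopifnot(n_high >= 0L, n_low >= 0L,
            inherits(profiles$high, "mi_generator_profile"),
            inherits(profiles$low, "mi_generator_profile"))
  structure(list(n_high = as.integer(n_high), n_low = as.integer(n_low),
                 profiles = profiles, seed = as.integer(seed)),
            class = "mi_synthetic_spec")
}

#' Generate one synthetic session
#'
#' Samples a hidden path from the profile's Markov chain, then emits scores
#' `round(clip(Normal(mu_z, sigma_z), -5, +5))` (rounding after clipping
#' keeps emission means near the state means). Categories are derived from
#' the score sign; the hidden path is retained in the session as ground
#' truth.
#'
#' @param profile an [generator_profile()].
#' @param length number of client utterances (>= 1).
#' @param seed integer seed; identical profile + seed gives an identical
#'   session.
#' @param session_id id for the session.
#' @param quality quality label to attach.
#' @return an `mi_session` with `hidden_states` set.
#' @export
generate_session <- function(profile, length, seed = 1L,
                             session_id = "synthetic_1",
                             quality = "unknown") {
  stopifnot(inherits(profile, "mi_generator_profile"))
  length <- as.integer(length)
  if (length < 1L) stop_validation("length must be >= 1")
  with_local_seed(derive_seed(seed, paste0("session_", session_id)), {
    z <- integer(length)
    z[1] <- sample.int(3L, 1L, prob = profile$pi)
    if (length > 1L) {
      for (t in 2:length) {
        z[t] <- sample.int(3L, 1L, prob = profile$A[z[t - 1], ])
      }
    }
    raw <- rnorm(length, profile$emission_means[z], profile$emission_sds[z])
    scores <- as.integer(round(pmin(5, pmax(-5, raw))))
    utt <- data.frame(speaker = "client", text = NA_character_,
                      category = category_from_score(scores), score = scores,
                      stringsAsFactors = FALSE)
    session(session_id, quality, utt, hidden_states = z)
  })
}

#' Generate a labeled synthetic session set
#'
#' `n_high` sessions from the high profile and `n_low` from the low profile,
#' with per-session lengths drawn uniformly from each profile's
#' `length_range`. Fully reproducible under the spec's seed; ground-truth
#' profiles are recorded in the set's metadata and hidden paths in each
#' session.
#'
#' @param spec an [synthetic_spec()].
#' @return an `mi_session_set` with `provenance = "synthetic"`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "mi_synthetic_spec"))
  gen_group <- function(profile, n, quality) {
    if (n == 0L) return(list())
    lens <- with_local_seed(
      derive_seed(spec$seed, paste0("lengths_", quality)),
      sample(profile$length_range[1]:profile$length_range[2], n,
             replace = TRUE))
    lapply(seq_len(n), function(i) {
      generate_session(profile, lens[i],
                       seed = derive_seed(spec$seed,
                                          paste0(quality, "_", i)),
                       session_id = sprintf("%s_%02d", quality, i),
                       quality = quality)
    })
  }
  sessions <- c(gen_group(spec$profiles$high, spec$n_high, "high"),
                gen_group(spec$profiles$low, spec$n_low, "low"))
  session_set(sessions, provenance = "synthetic",
              metadata = list(seed = spec$seed,
                              n_high = spec$n_high, n_low = spec$n_low,
                              profiles = spec$profiles))
}
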