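#' Frobenius norm of the element-wise difference of two matrices
#'
#' `sqrt(sum((A - B)^2))`, the overall structural dissimilarity between two
#' transition matrices. Rows must already be aligned to the same canonical
#' state-label order (see [label_states()]). For two 3x3 row-stochastic
#' matrices the value is bounded by `sqrt(6)`.
#'
#' @param A,B numeric matrices of identical shape.
#' @return a non-negative scalar.
#' @export
#' @examples
#' transition_frobenius(diag(3), diag(3))
transition_frobenius <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) {
    stop_validation("matrix shapes differ: %s vs %s",
                    paste(dim(A), collapse = "x"),
                    paste(dim(B), collapse = "x"))
  }
  sqrt(sum((A - B)^2))
}

#' Fit one quality group's HMM
#'
#' Pools all of the group's client score sequences into one multi-sequence
#' Baum-Welch fit and canonically labels the states. A gradient-invalid fit
#' is flagged with a warning, not an error: the transition matrix can still
#' be compared even when the motivational interpretation of states is
#' blocked.
#'
#' @param set an `mi_session_set`.
#' @param quality "high" or "low"; only sessions with this label are used.
#' @param config an [hmm_config()].
#' @param min_sessions,min_scores minimum group size and per-session client
#'   score count.
#' @return object of class `mi_group_fit`: `group_label`, `sessions_used`,
#'   `labeled_hmm`.
#' @export
fit_group <- function(set, quality, config = hmm_config(),
                      min_sessions = 2L, min_scores = 3L) {
  stopifnot(inherits(set, "mi_session_set"))
  quality <- match.arg(quality, c("high", "low"))
  sub <- filter_quality(set, quality)
  seqs <- score_sequences(sub, min_len = min_scores)
  if (length(seqs) < min_sessions) {
    stop_validation(
      "group '%s' has %d usable session(s); need >= %d with >= %d client scores",
      quality, length(seqs), min_sessions, min_scores)
  }
  lab <- label_states(fit_hmm(seqs, config))
  if (!lab$gradient_valid) {
    warning(sprintf("group '%s': emission means do not follow the expected motivational gradient; state labels are not interpretable",
                    quality), call. = FALSE)
  }
  structure(list(group_label = quality, sessions_used = names(seqs),
                 labeled_hmm = lab),
            class = "mi_group_fit")
}

#' @export
print.mi_group_fit <- function(x, ...) {
  cat(sprintf("<mi_group_fit> %s-quality group, %d sessions\n",
              x$group_label, length(x$sessions_used)))
  print(x$labeled_hmm)
  invisible(x)
}

# fit + canonicalize one group's sequences; returns labeled_A plus flags
fit_sequences_canonical <- function(seqs, config) {
  lab <- label_states(fit_hmm(seqs, config))
  list(A = lab$labeled_A, gradient_valid = lab$gradient_valid,
       converged = lab$model$converged, labeled = lab)
}

#' Permutation test for a group difference in transition dynamics
#'
#' The observed statistic D is the Frobenius norm of the difference between
#' the canonically labelled transition matrices of the high- and low-quality
#' groups. Session quality labels are then shuffled (group sizes preserved),
#' both group HMMs are refitted from scratch and canonicalized, and D is
#' recomputed for each permutation. The p-value is the proportion of permuted
#' statistics greater than or equal to the observed one (`method = "basic"`);
#' `method = "smoothed"` uses the bias-corrected `(# + 1) / (N + 1)` variant.
#' Gradient-invalid or non-converged permuted fits are counted, never
#' discarded (descending-mean canonicalization with a deterministic tie-break
#' always yields a comparable matrix).
#'
#' @param set an `mi_session_set` with both high and low sessions.
#' @param n_permutations number of label shuffles (default 1000).
#' @param config [hmm_config()] used for the observed fit.
#' @param seed integer seed for the shuffles.
#' @param perm_config optional relaxed [hmm_config()] used inside the
#'   permutations (the statistic is exchangeable as long as the same settings
#'   are applied to every permutation); defaults to `config`.
#' @param method p-value convention, "basic" or "smoothed".
#' @return object of class `mi_permutation_result`: `observed_D`, `null_Ds`,
#'   `n_permutations`, `p_value`, `seed`, `degenerate_fit_count`,
#'   `high_labeled_A`, `low_labeled_A`, `method`.
#' @export
permutation_test <- function(set, n_permutations = 1000L,
                             config = hmm_config(), seed = 1L,
                             perm_config = NULL,
                             method = c("basic", "smoothed")) {
  stopifnot(inherits(set, "mi_session_set"))
  method <- match.arg(method)
  if (is.null(perm_config)) perm_config <- config
  qual <- session_qualities(set)
  n_high <- sum(qual == "high")
  n_low <- sum(qual == "low")
  if (n_high == 0L || n_low == 0L) {
    stop_validation("both groups must be non-empty (high = %d, low = %d)",
                    n_high, n_low)
  }
  keep <- qual %in% c("high", "low")
  seqs <- lapply(set$sessions[keep], client_scores)
  qual <- qual[keep]

  fit_h <- fit_sequences_canonical(seqs[qual == "high"], config)
  fit_l <- fit_sequences_canonical(seqs[qual == "low"], config)
  observed_D <- transition_frobenius(fit_h$A, fit_l$A)

  n <- length(seqs)
  null_Ds <- numeric(n_permutations)
  degenerate <- 0L
  with_local_seed(derive_seed(seed, "permutation_test"), {
    for (b in seq_len(n_permutations)) {
      idx_high <- sample.int(n, n_high)
      ph <- fit_sequences_canonical(seqs[idx_high], perm_config)
      pl <- fit_sequences_canonical(seqs[-idx_high], perm_config)
      null_Ds[b] <- transition_frobenius(ph$A, pl$A)
      if (!ph$gradient_valid || !pl$gradient_valid ||
          !ph$converged || !pl$converged) {
        degenerate <- degenerate + 1L
      }
    }
  })

  p_value <- if (method == "basic") {
    sum(null_Ds >= observed_D) / n_permutations
  } else {
    (sum(null_Ds >= observed_D) + 1) / (n_permutations + 1)
  }
  structure(list(observed_D = observed_D, null_Ds = null_Ds,
                 n_permutations = as.integer(n_permutations),
                 p_value = p_value, seed = as.integer(seed),
                 degenerate_fit_count = degenerate,
                 high_labeled_A = fit_h$A, low_labeled_A = fit_l$A,
                 high_gradient_valid = fit_h$gradient_valid,
                 low_gradient_valid = fit_l$gradient_valid,
                 method = method),
            class = "mi_permutation_result")
}

#' @export
print.mi_permutation_result <- function(x, ...) {
  cat(sprintf("<mi_permutation_result> D = %.4f, p = %.4g (%d permutations, %s)\n",
              x$observed_D, x$p_value, x$n_permutations, x$method))
  if (x$degenerate_fit_count > 0) {
    cat(sprintf("  %d permuted fit(s) were degenerate (counted, not discarded)\n",
                x$degenerate_fit_count))
  }
  invisible(x)
}
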