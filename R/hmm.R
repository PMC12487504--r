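#' HMM fitting configuration
#'
#' @param n_states number of hidden states (default 3: Towards Change,
#'   Non-Determined, Away From Change).
#' @param emission_family "gaussian" (one mean/sd per state; the default,
#'   matching the emission-mean interpretation of states) or "categorical11"
#'   (a per-state distribution over the 11 integer scores -5..+5).
#' @param max_iter maximum Baum-Welch iterations.
#' @param tol relative log-likelihood change threshold for convergence.
#' @param variance_floor lower bound on emission variances (Gaussian family);
#'   guards against variance collapse on near-constant data.
#' @param init_means deterministic initial emission means (length
#'   `n_states`); the default (+3, 0, -3) spans the score scale in the
#'   expected motivational gradient order.
#' @param init_sds initial emission standard deviations (default 1.5).
#' @param n_restarts number of additional EM runs from seeded random
#'   perturbations of `init_means`; the run with the best final
#'   log-likelihood wins. 0 = single deterministic run.
#' @param seed seed for the restart perturbations.
#' @param fix_start_from_first_score if TRUE, the start distribution is set
#'   from the empirical distribution of first-utterance score signs (positive
#'   / zero / negative mapped to the states ordered by `init_means`) and held
#'   fixed during EM, instead of being estimated.
#' @return list of class `mi_hmm_config`.
#' @export
hmm_config <- function(n_states = 3L,
                       emission_family = c("gaussian", "categorical11"),
                       max_iter = 500L, tol = 1e-6, variance_floor = 1e-2,
                       init_means = NULL, init_sds = NULL, n_restarts = 0L,
                       seed = 1L, fix_start_from_first_score = FALSE) {
  emission_family <- match.arg(emission_family)
  n_states <- as.integer(n_states)
  if (n_states < 2L) stop_validation("n_states must be >= 2")
  if (tol <= 0 || variance_floor <= 0) {
    stop_validation("tol and variance_floor must be positive")
  }
  if (is.null(init_means)) {
    init_means <- if (n_states == 3L) c(3, 0, -3) else {
      seq(4, -4, length.out = n_states)
    }
  }
  if (length(init_means) != n_states) {
    stop_validation("init_means must have length n_states = %d", n_states)
  }
  if (is.null(init_sds)) init_sds <- rep(1.5, n_states)
  if (length(init_sds) == 1L) init_sds <- rep(init_sds, n_states)
  structure(list(n_states = n_states, emission_family = emission_family,
                 max_iter = as.integer(max_iter), tol = tol,
                 variance_floor = variance_floor, init_means = init_means,
                 init_sds = init_sds, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed),
                 fix_start_from_first_score =
                   isTRUE(fix_start_from_first_score)),
            class = "mi_hmm_config")
}

validate_sequences <- function(sequences, config) {
  if (inherits(sequences, "mi_session_set")) {
    sequences <- score_sequences(sequences)
  }
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (!is.list(sequences) || length(sequences) == 0L) {
    stop_validation("need at least one score sequence")
  }
  sequences <- lapply(sequences, as.numeric)
  lens <- vapply(sequences, length, integer(1))
  if (any(lens == 0L)) stop_validation("empty score sequence supplied")
  all_obs <- unlist(sequences)
  if (any(all_obs < -5 | all_obs > 5)) {
    stop_validation("scores must lie in [-5, 5]")
  }
  if (sum(lens) < 3L * config$n_states) {
    stop_validation(
      "insufficient data: %d observations for %d states (need >= %d)",
      sum(lens), config$n_states, 3L * config$n_states)
  }
  sequences
}

init_categorical_B <- function(config) {
  # soften a discretized gaussian around each init mean
  K <- config$n_states
  B <- matrix(0, K, 11)
  support <- -5:5
  for (k in seq_len(K)) {
    w <- dnorm(support, config$init_means[k], config$init_sds[k]) + 0.02
    B[k, ] <- w / sum(w)
  }
  B
}

run_em_once <- function(sequences, config, init_means, pi0 = NULL,
                        fix_pi = FALSE) {
  K <- config$n_states
  obs <- unlist(sequences)
  lengths <- vapply(sequences, length, integer(1))
  family <- if (config$emission_family == "gaussian") 0L else 1L
  if (family == 1L) obs <- round(obs) + 5  # map scores to 0..10 bins
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  A0 <- matrix(1 / K, K, K)
  B0 <- init_categorical_B(config)
  fit <- .hmm_em_cpp(obs, lengths, family, pi0, A0, init_means,
                     config$init_sds, B0, config$max_iter, config$tol,
                     config$variance_floor, fix_pi)
  fit
}

#' Fit a hidden Markov model to score sequences
#'
#' Baum-Welch (EM) over a pooled set of independent sequences: sufficient
#' statistics are summed across sequences and each sequence restarts from the
#' start distribution. Per-session sequence boundaries are always respected
#' (sequences are never concatenated). Initialization is deterministic
#' (see [hmm_config()]); optional seeded random restarts keep the best
#' log-likelihood.
#'
#' @param sequences a list of numeric score vectors, a single numeric vector,
#'   or an `mi_session_set` (client score sequences are extracted).
#' @param config an [hmm_config()].
#' @return object of class `mi_hmm`: `pi`, `A` (row-stochastic), `mu`,
#'   `sigma` (Gaussian family) or `B` (categorical family, states x 11),
#'   `log_likelihood_trace`, `converged`, `n_iter`, `degenerate`, `config`.
#' @export
fit_hmm <- function(sequences, config = hmm_config()) {
  stopifnot(inherits(config, "mi_hmm_config"))
  sequences <- validate_sequences(sequences, config)
  all_obs <- unlist(sequences)
  degenerate <- FALSE
  if (length(unique(all_obs)) == 1L &&
      config$emission_family == "categorical11") {
    warning("all observations identical: categorical emission fit is degenerate",
            call. = FALSE)
    degenerate <- TRUE
  }

  pi0 <- NULL
  fix_pi <- FALSE
  if (config$fix_start_from_first_score) {
    firsts <- vapply(sequences, function(s) s[1], numeric(1))
    ord <- order(-config$init_means, seq_along(config$init_means))
    # proportions of positive / zero / negative first scores, mapped onto the
    # states ranked by initial mean (descending)
    p <- c(mean(firsts > 0), mean(firsts == 0), mean(firsts < 0))
    if (config$n_states != 3L) {
      stop_validation("fix_start_from_first_score requires n_states = 3")
    }
    pi0 <- numeric(3)
    pi0[ord] <- pmax(p, 1e-6)
    pi0 <- pi0 / sum(pi0)
    fix_pi <- TRUE
  }

  best <- run_em_once(sequences, config, config$init_means, pi0, fix_pi)
  if (config$n_restarts > 0L) {
    for (r in seq_len(config$n_restarts)) {
      means_r <- with_local_seed(
        derive_seed(config$seed, paste0("hmm_restart_", r)),
        config$init_means + rnorm(config$n_states, 0, 1))
      cand <- run_em_once(sequences, config, means_r, pi0, fix_pi)
      if (max(cand$log_likelihood_trace) > max(best$log_likelihood_trace)) {
        best <- cand
      }
    }
  }

  out <- list(pi = as.numeric(best$pi), A = best$A,
              mu = as.numeric(best$mu), sigma = as.numeric(best$sigma),
              B = best$B, n_states = config$n_states,
              emission_family = config$emission_family,
              log_likelihood_trace = as.numeric(best$log_likelihood_trace),
              converged = isTRUE(best$converged),
              n_iter = best$n_iter, degenerate = degenerate, config = config)
  class(out) <- "mi_hmm"
  out
}

#' @export
print.mi_hmm <- function(x, ...) {
  cat(sprintf("<mi_hmm> %d states, %s emissions, %s after %d iterations\n",
              x$n_states, x$emission_family,
              if (x$converged) "converged" else "max_iter reached", x$n_iter))
  if (x$emission_family == "gaussian") {
    cat("  emission means:", paste(sprintf("%.3f", x$mu), collapse = ", "),
        "\n")
  }
  cat("  transition matrix:\n")
  print(round(x$A, 3))
  invisible(x)
}

check_model_sequence <- function(model, sequence) {
  stopifnot(inherits(model, "mi_hmm"))
  sequence <- as.numeric(sequence)
  if (length(sequence) == 0L) stop_validation("sequence must be non-empty")
  sequence
}

#' Log-likelihood of a score sequence under a fitted model
#'
#' Scaled (per-step normalized) forward algorithm, numerically safe at
#' session lengths of hundreds of utterances.
#'
#' @param model an `mi_hmm`.
#' @param sequence numeric score vector (non-empty).
#' @return log P(sequence | model).
#' @export
log_likelihood <- function(model, sequence) {
  sequence <- check_model_sequence(model, sequence)
  obs <- if (model$emission_family == "gaussian") sequence else {
    round(sequence) + 5
  }
  .hmm_loglik_cpp(obs, model$pi, model$A,
                  if (model$emission_family == "gaussian") 0L else 1L,
                  model$mu, model$sigma, model$B)
}

#' Most likely hidden-state path (Viterbi)
#'
#' Dynamic-programming decoder in log space. Ties are broken toward the lower
#' state index at each backtrack step, so fully uninformative models yield
#' the all-1 path.
#'
#' @param model an `mi_hmm`.
#' @param sequence numeric score vector (non-empty).
#' @return list with `path` (integer states, 1-based) and `log_prob` (joint
#'   log-probability of the path and the observations).
#' @export
viterbi_decode <- function(model, sequence) {
  sequence <- check_model_sequence(model, sequence)
  obs <- if (model$emission_family == "gaussian") sequence else {
    round(sequence) + 5
  }
  res <- .hmm_viterbi_cpp(obs, model$pi, model$A,
                          if (model$emission_family == "gaussian") 0L else 1L,
                          model$mu, model$sigma, model$B)
  list(path = as.integer(res$path) + 1L, log_prob = res$log_prob)
}

state_emission_means <- function(model) {
  if (model$emission_family == "gaussian") model$mu
  else as.numeric(model$B %*% (-5:5))
}

#' Label HMM states by descending emission mean
#'
#' States are interpreted through the central tendency of their emission
#' distributions: the state with the highest emission mean is labelled
#' "Towards Change", the middle one "Non-Determined", and the lowest "Away
#' From Change". `gradient_valid` is TRUE only when the ordering is strict
#' (ties make the motivational gradient uninterpretable — a flag, never an
#' error, since matrix comparison remains possible). Ties are broken toward
#' the lower raw state index so canonicalization is deterministic.
#'
#' @param model a fitted `mi_hmm` (3 states for the named labels; other state
#'   counts get rank labels).
#' @return object of class `mi_labeled_hmm`: `model`, `state_order`
#'   (permutation raw index -> rank), `labels`, `gradient_valid`, `labeled_A`,
#'   `labeled_pi`, `emission_means` (in label order).
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "mi_hmm"))
  means <- state_emission_means(model)
  ord <- order(-means, seq_along(means))
  labels <- if (model$n_states == 3L) {
    c("Towards Change", "Non-Determined", "Away From Change")
  } else {
    sprintf("state_rank_%d", seq_len(model$n_states))
  }
  sorted <- means[ord]
  gradient_valid <- all(diff(sorted) < 0)
  out <- list(model = model, state_order = ord, labels = labels,
              gradient_valid = gradient_valid,
              labeled_A = model$A[ord, ord, drop = FALSE],
              labeled_pi = model$pi[ord],
              emission_means = sorted)
  dimnames(out$labeled_A) <- list(labels, labels)
  names(out$labeled_pi) <- labels
  class(out) <- "mi_labeled_hmm"
  out
}

#' @export
print.mi_labeled_hmm <- function(x, ...) {
  cat(sprintf("<mi_labeled_hmm> gradient %s; emission means: %s\n",
              if (x$gradient_valid) "valid" else "INVALID",
              paste(sprintf("%.2f", x$emission_means), collapse = ", ")))
  print(round(x$labeled_A, 3))
  invisible(x)
}

#' Serialize a fitted HMM to JSON
#'
#' Writes all parameters at full double precision (17 significant digits) so
#' a round trip is bit-stable across platforms.
#'
#' @param model an `mi_hmm`.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
hmm_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mi_hmm"))
  # render doubles at 17 significant digits so parsing reproduces the exact
  # bits (jsonlite's own numeric rendering tops out at ~15 digits)
  vec17 <- function(v) {
    paste0("[", paste(sprintf("%.17g", v), collapse = ","), "]")
  }
  mat17 <- function(m) {
    rows <- apply(m, 1, function(r) {
      paste0("[", paste(sprintf("%.17g", r), collapse = ","), "]")
    })
    paste0("[", paste(rows, collapse = ","), "]")
  }
  scalar <- function(x) {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
  }
  fields <- c(
    sprintf('"pi":%s', vec17(model$pi)),
    sprintf('"A":%s', mat17(model$A)),
    sprintf('"mu":%s', vec17(model$mu)),
    sprintf('"sigma":%s', vec17(model$sigma)),
    sprintf('"B":%s', mat17(model$B)),
    sprintf('"n_states":%d', model$n_states),
    sprintf('"emission_family":%s', scalar(model$emission_family)),
    sprintf('"log_likelihood_trace":%s', vec17(model$log_likelihood_trace)),
    sprintf('"converged":%s', tolower(model$converged)),
    sprintf('"n_iter":%d', model$n_iter),
    sprintf('"degenerate":%s', tolower(model$degenerate)),
    sprintf('"config":%s',
            jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE,
                             digits = NA)))
  js <- paste0("{", paste(fields, collapse = ","), "}")
  if (!is.null(path)) {
    writeLines(as.character(js), path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Deserialize a fitted HMM from JSON
#'
#' @param x a JSON string or a path to a JSON file written by
#'   [hmm_to_json()].
#' @return an `mi_hmm`.
#' @export
hmm_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  cfg <- do.call(hmm_config, obj$config[names(obj$config) %in%
                                          names(formals(hmm_config))])
  out <- list(pi = as.numeric(obj$pi), A = as.matrix(obj$A),
              mu = as.numeric(obj$mu), sigma = as.numeric(obj$sigma),
              B = as.matrix(obj$B), n_states = as.integer(obj$n_states),
              emission_family = obj$emission_family,
              log_likelihood_trace = as.numeric(obj$log_likelihood_trace),
              converged = isTRUE(obj$converged),
              n_iter = as.integer(obj$n_iter),
              degenerate = isTRUE(obj$degenerate), config = cfg)
  class(out) <- "mi_hmm"
  out
}
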