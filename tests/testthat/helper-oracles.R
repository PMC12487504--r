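# Independent oracles and fixture builders used across tests. These are
# deliberately brute-force / direct-formula implementations, kept separate
# from the package's algorithms.

# brute-force log-likelihood: sum over all K^T hidden paths
enum_loglik <- function(pi, A, mu, sigma, obs) {
  K <- length(pi)
  T_ <- length(obs)
  paths <- expand.grid(rep(list(seq_len(K)), T_))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    z <- as.integer(paths[r, ])
    p <- pi[z[1]] * dnorm(obs[1], mu[z[1]], sigma[z[1]])
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p * A[z[t - 1], z[t]] * dnorm(obs[t], mu[z[t]], sigma[z[t]])
      }
    }
    total <- total + p
  }
  log(total)
}

# brute-force Viterbi: maximum joint log-probability over all paths
enum_viterbi_logprob <- function(pi, A, mu, sigma, obs) {
  K <- length(pi)
  T_ <- length(obs)
  paths <- expand.grid(rep(list(seq_len(K)), T_))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    z <- as.integer(paths[r, ])
    lp <- log(pi[z[1]]) + dnorm(obs[1], mu[z[1]], sigma[z[1]], log = TRUE)
    if (T_ > 1) {
      for (t in 2:T_) {
        lp <- lp + log(A[z[t - 1], z[t]]) +
          dnorm(obs[t], mu[z[t]], sigma[z[t]], log = TRUE)
      }
    }
    if (lp > best) best <- lp
  }
  best
}

# random row-stochastic matrix
random_stochastic <- function(K) {
  m <- matrix(rexp(K * K), K, K)
  m / rowSums(m)
}

# random Gaussian-emission HMM packaged as an mi_hmm for the decoders
random_hmm <- function(K = 3) {
  pi <- as.numeric(random_stochastic(K)[1, ])
  A <- random_stochastic(K)
  mu <- sort(runif(K, -4, 4), decreasing = TRUE)
  sigma <- runif(K, 0.5, 2)
  make_hmm(pi, A, mu, sigma)
}

# assemble an mi_hmm object from raw parameters (bypasses fitting)
make_hmm <- function(pi, A, mu, sigma,
                     family = "gaussian", B = NULL) {
  K <- length(pi)
  if (is.null(B)) B <- matrix(1 / 11, K, 11)
  structure(list(pi = pi, A = A, mu = mu, sigma = sigma, B = B,
                 n_states = K, emission_family = family,
                 log_likelihood_trace = numeric(0), converged = TRUE,
                 n_iter = 0L, degenerate = FALSE,
                 config = hmm_config(n_states = K)),
            class = "mi_hmm")
}

# direct-formula Cohen's kappa on two label vectors
cohen_kappa_direct <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pe <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), numeric(1)))
  (po - pe) / (1 - pe)
}

# direct-formula Fleiss kappa on an items x categories count table
fleiss_kappa_direct <- function(counts, n_raters) {
  N <- nrow(counts)
  Pi <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  pj <- colSums(counts) / (N * n_raters)
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# trapezoidal ROC AUC over all thresholds
trapezoid_auc <- function(truth, prob, positive = "low") {
  thr <- sort(unique(c(-Inf, prob, Inf)), decreasing = TRUE)
  pos <- truth == positive
  tpr <- vapply(thr, function(th) mean(prob[pos] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(prob[!pos] >= th), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small text-bearing session for IO / cleaning / scoring tests
text_session <- function(id = "s1", quality = "unknown",
                         texts = c("I want to change", "mm-hmm",
                                   "I can't do this"),
                         speakers = c("client", "therapist", "client")) {
  utt <- data.frame(speaker = speakers, text = texts,
                    category = NA_character_, score = NA_integer_,
                    stringsAsFactors = FALSE)
  session(id, quality, utt)
}

# compare two session sets field-for-field (utterance tables and labels)
expect_sets_equal <- function(x, y) {
  expect_equal(length(x$sessions), length(y$sessions))
  for (i in seq_along(x$sessions)) {
    a <- x$sessions[[i]]; b <- y$sessions[[i]]
    expect_identical(a$session_id, b$session_id)
    expect_identical(a$quality, b$quality)
    expect_equal(a$utterances, b$utterances)
  }
}
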