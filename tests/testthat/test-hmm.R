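test_that("forward likelihood has the closed form at T = 1", {
  m <- make_hmm(pi = c(0.5, 0.3, 0.2), A = random_stochastic(3),
                mu = c(3, 0, -3), sigma = c(1, 1.5, 0.8))
  x <- 1.7
  expect_equal(log_likelihood(m, x),
               log(sum(m$pi * dnorm(x, m$mu, m$sigma))), tolerance = 1e-12)
})

test_that("forward and Viterbi match exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:100) {
    m <- random_hmm(3)
    T_ <- sample(2:6, 1)
    obs <- round(pmin(5, pmax(-5, rnorm(T_, 0, 2.5))))
    expect_equal(log_likelihood(m, obs),
                 enum_loglik(m$pi, m$A, m$mu, m$sigma, obs),
                 tolerance = 1e-9)
    vit <- viterbi_decode(m, obs)
    expect_equal(vit$log_prob,
                 enum_viterbi_logprob(m$pi, m$A, m$mu, m$sigma, obs),
                 tolerance = 1e-9)
  }
})

test_that("Viterbi follows emissions when they dominate and breaks ties low", {
  m <- make_hmm(pi = rep(1 / 3, 3),
                A = matrix(1 / 3, 3, 3),
                mu = c(3, 0, -3), sigma = c(0.3, 0.3, 0.3))
  expect_identical(viterbi_decode(m, c(3, 3, -3))$path, c(1L, 1L, 3L))
  # fully uniform model: every path is equally likely -> lowest-index path
  u <- make_hmm(pi = rep(1 / 3, 3), A = matrix(1 / 3, 3, 3),
                mu = c(0, 0, 0), sigma = c(1, 1, 1))
  expect_identical(viterbi_decode(u, c(1, -1, 0, 2))$path, rep(1L, 4))
})

test_that("empty sequences and insufficient data are rejected", {
  m <- random_hmm(3)
  expect_error(log_likelihood(m, numeric(0)), "non-empty")
  expect_error(viterbi_decode(m, numeric(0)), "non-empty")
  expect_error(fit_hmm(list(c(1), c(2))), "insufficient")
  expect_error(fit_hmm(list()), "at least one")
  expect_error(fit_hmm(list(c(1, 2, 9, 0, 1, 2, 3, 1, 2))), "\\[-5, 5\\]")
})

test_that("EM log-likelihood is non-decreasing and converges", {
  set.seed(42)
  seqs <- lapply(1:5, function(i) round(pmin(5, pmax(-5, rnorm(40, 0, 2)))))
  fit <- fit_hmm(seqs, hmm_config(max_iter = 200))
  tr <- fit$log_likelihood_trace
  expect_true(all(diff(tr) > -1e-8))
  # well-separated data converges quickly under the default tolerance
  sep <- generate_dataset(synthetic_spec(n_high = 8, n_low = 0, seed = 3))
  expect_true(fit_hmm(sep)$converged)
  # trace under the categorical family is monotone too
  fitc <- fit_hmm(seqs, hmm_config(emission_family = "categorical11",
                                   max_iter = 200))
  expect_true(all(diff(fitc$log_likelihood_trace) > -1e-8))
})

test_that("constant data drives the occupied state's mean to the constant", {
  fit <- fit_hmm(list(rep(3, 60)))
  occupied <- which.max(fit$pi)
  expect_lt(abs(fit$mu[occupied] - 3), 0.01)
  # all-constant categorical data flags a degenerate fit
  expect_warning(
    fit_hmm(list(rep(3, 60)), hmm_config(emission_family = "categorical11")),
    "degenerate")
})

test_that("fitted models satisfy the stochasticity invariants", {
  set.seed(42)
  set <- generate_dataset(synthetic_spec(n_high = 6, n_low = 3, seed = 11))
  fit <- fit_hmm(set)
  expect_equal(rowSums(fit$A), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  expect_true(all(fit$sigma >= sqrt(fit$config$variance_floor) - 1e-12))
})

test_that("state labels follow descending emission means with a validity flag", {
  m <- make_hmm(pi = c(0.2, 0.5, 0.3), A = random_stochastic(3),
                mu = c(3.1, -2.8, 0.2), sigma = c(1, 1, 1))
  lab <- label_states(m)
  expect_identical(lab$state_order, c(1L, 3L, 2L))
  expect_true(lab$gradient_valid)
  expect_identical(rownames(lab$labeled_A),
                   c("Towards Change", "Non-Determined", "Away From Change"))
  # a tie violates the strict gradient
  tied <- make_hmm(pi = rep(1 / 3, 3), A = random_stochastic(3),
                   mu = c(0.2, 0.2, -1), sigma = c(1, 1, 1))
  expect_false(label_states(tied)$gradient_valid)
})

test_that("canonicalization is invariant to raw state permutation and idempotent", {
  set.seed(42)
  m <- random_hmm(3)
  perm <- c(3L, 1L, 2L)
  mp <- make_hmm(m$pi[perm], m$A[perm, perm], m$mu[perm], m$sigma[perm])
  expect_equal(label_states(m)$labeled_A, label_states(mp)$labeled_A,
               tolerance = 1e-12)
  # relabeling an already-canonical model is the identity permutation
  lab <- label_states(m)
  canon <- make_hmm(lab$labeled_pi, lab$labeled_A, lab$emission_means,
                    m$sigma[lab$state_order])
  expect_identical(label_states(canon)$state_order, 1:3)
})

test_that("JSON serialization round-trips a fitted model exactly", {
  set.seed(42)
  fit <- fit_hmm(lapply(1:3, function(i) rnorm(30)))
  path <- withr::local_tempfile(fileext = ".json")
  hmm_to_json(fit, path)
  back <- hmm_from_json(path)
  expect_identical(back$pi, fit$pi)
  expect_identical(as.numeric(back$A), as.numeric(fit$A))
  expect_identical(back$mu, fit$mu)
  expect_identical(back$sigma, fit$sigma)
  expect_identical(back$converged, fit$converged)
  # sequence likelihoods agree bit-for-bit
  x <- rnorm(10)
  expect_identical(log_likelihood(fit, x), log_likelihood(back, x))
})

test_that("fix_start_from_first_score pins the start distribution", {
  seqs <- list(c(4, 3, 2), c(3, 2, 1), c(-3, -2, -4), c(0, 0, 1))
  fit <- fit_hmm(seqs, hmm_config(fix_start_from_first_score = TRUE,
                                  max_iter = 50))
  # 2/4 positive, 1/4 zero, 1/4 negative first scores, in init-mean order
  expect_equal(fit$pi, c(0.5, 0.25, 0.25), tolerance = 1e-6)
})
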