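#' Relaxed EM settings for permutation-scale refitting
#'
#' The permutation test refits two group HMMs for every label shuffle, so
#' simulation studies use a shallower EM (tol 1e-3, at most 50 iterations)
#' than the single-fit default. The permutation p-value remains exactly valid
#' under exchangeability because the observed and permuted statistics are
#' computed with identical settings.
#'
#' @return an [hmm_config()].
#' @export
relaxed_hmm_config <- function() {
  hmm_config(max_iter = 50L, tol = 1e-3)
}

# sup-distance between the empirical CDF of x and the uniform CDF on [0,1]
ks_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(pmax(abs(seq_len(n) / n - x), abs((seq_len(n) - 1) / n - x)))
}

#' Type-I calibration study for the permutation test
#'
#' Simulates `n_sims` datasets in which both "groups" are drawn from the SAME
#' generator profile (so the null of no group difference holds by
#' construction), runs the label-shuffling permutation test on each, and
#' summarizes the null p-value distribution: the rejection rate at `alpha`
#' and the Kolmogorov-Smirnov distance to the uniform distribution. A
#' calibrated test rejects at close to `alpha` and produces near-uniform
#' p-values.
#'
#' @param n_sims number of simulated datasets (default 200).
#' @param n_permutations label shuffles per dataset (default 99; scaled down
#'   from a production run of 1000 because the study multiplies it by
#'   `n_sims`).
#' @param n_high,n_low group sizes (default 30 and 10).
#' @param profile the single [generator_profile()] both groups share.
#' @param config [hmm_config()] used for every fit (observed and permuted).
#' @param alpha nominal test level.
#' @param seed integer seed.
#' @return list: `p_values`, `rejection_rate`, `ks_distance`, `alpha`,
#'   `n_sims`, `n_permutations`, `degenerate_fits`.
#' @export
permutation_calibration <- function(n_sims = 200L, n_permutations = 99L,
                                    n_high = 30L, n_low = 10L,
                                    profile = default_profiles()$high,
                                    config = relaxed_hmm_config(),
                                    alpha = 0.05, seed = 1L) {
  p_values <- numeric(n_sims)
  degenerate <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    sim_seed <- derive_seed(seed, paste0("calibration_sim_", i))
    set <- generate_dataset(synthetic_spec(
      n_high = n_high, n_low = n_low,
      profiles = list(high = profile, low = profile), seed = sim_seed))
    res <- permutation_test(set, n_permutations = n_permutations,
                            config = config, perm_config = config,
                            seed = sim_seed)
    p_values[i] <- res$p_value
    degenerate[i] <- res$degenerate_fit_count
  }
  list(p_values = p_values,
       rejection_rate = mean(p_values <= alpha),
       ks_distance = ks_uniform(p_values),
       alpha = alpha, n_sims = as.integer(n_sims),
       n_permutations = as.integer(n_permutations),
       degenerate_fits = sum(degenerate))
}

#' Power study for the permutation test
#'
#' Repeatedly simulates the default study design (separated high/low
#' generator profiles, 30 + 10 sessions) and records the permutation p-value
#' of each replicate.
#'
#' @param n_replicates number of simulated datasets (default 20).
#' @param n_permutations label shuffles per dataset (default 99).
#' @param n_high,n_low group sizes.
#' @param profiles named list of high/low [generator_profile()]s.
#' @param config [hmm_config()] for every fit.
#' @param alpha nominal level for the power summary.
#' @param seed integer seed.
#' @return list: `p_values`, `power` (share of replicates with p < alpha),
#'   `observed_Ds`.
#' @export
permutation_power <- function(n_replicates = 20L, n_permutations = 99L,
                              n_high = 30L, n_low = 10L,
                              profiles = default_profiles(),
                              config = relaxed_hmm_config(),
                              alpha = 0.05, seed = 1L) {
  p_values <- numeric(n_replicates)
  ds <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, paste0("power_rep_", i))
    set <- generate_dataset(synthetic_spec(n_high = n_high, n_low = n_low,
                                           profiles = profiles,
                                           seed = rep_seed))
    res <- permutation_test(set, n_permutations = n_permutations,
                            config = config, perm_config = config,
                            seed = rep_seed)
    p_values[i] <- res$p_value
    ds[i] <- res$observed_D
  }
  list(p_values = p_values, power = mean(p_values < alpha),
       observed_Ds = ds)
}
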