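# Small fixtures and independent oracles shared across tests.

# deterministic toy panel: I subjects, J loci, HWE at p_a
toy_panel <- function(I = 50, J = 4, p_a = 0.8, seed = 42) {
  sim_hwe_panel(rep(p_a, J), I, seed = seed)
}

# hand-solved least squares via explicit normal equations (independent of
# the package's QR path)
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force enumeration of the dosage-chain HMM posterior: sums over all
# 3^J hidden paths; independent oracle for forward-backward
enumerate_hmm_posterior <- function(genos_i, freqs, map_cM, mu, g) {
  J <- length(genos_i)
  E <- gleam:::emission_probs(genos_i, freqs)
  Tm <- gleam:::dosage_transitions(diff(map_cM), g, mu)
  prior <- exp(gleam:::log_hwe_prior(mu))
  paths <- as.matrix(expand.grid(rep(list(0:2), J)))
  w <- apply(paths, 1, function(s) {
    pr <- prior[s[1] + 1] * E[1, s[1] + 1]
    if (J > 1) {
      for (j in 2:J) {
        pr <- pr * Tm[[j - 1]][s[j - 1] + 1, s[j] + 1] * E[j, s[j] + 1]
      }
    }
    pr
  })
  post <- matrix(0, J, 3)
  for (j in seq_len(J)) {
    for (s in 0:2) post[j, s + 1] <- sum(w[paths[, j] == s])
  }
  list(posterior = post / sum(w), loglik = log(sum(w)))
}

# numeric CDF of the univariate QNM prior by trapezoid integration of the
# package density on a fine grid (used to check the sampler against the
# density without sharing the sampler's polar identity)
qnm_numeric_cdf <- function(grid, params) {
  dens <- exp(qnm_logdensity(matrix(grid, ncol = 1), params))
  dx <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  cdf / cdf[length(cdf)]
}
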