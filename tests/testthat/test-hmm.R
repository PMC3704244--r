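test_that("forward-backward equals exhaustive path enumeration on short chains", {
  set.seed(1)
  for (r in 1:4) {
    J <- sample(3:6, 1)
    map <- cumsum(runif(J, 0.5, 8))
    fr <- ancestral_freqs(runif(J, 0.6, 0.95), runif(J, 0.05, 0.4))
    mu <- runif(1, 0.4, 0.9)
    g <- runif(1, 2, 10)
    truth <- sim_chromosome(map, mu, g, I = 3, seed = 100 + r)
    genos <- sim_aim_genotypes(truth$S, fr, seed = 200 + r)
    post <- hmm_posteriors(genos, fr, map, hmm_params(mu = mu, g = g))
    for (i in 1:3) {
      oracle <- enumerate_hmm_posterior(genos[i, ], fr, map, mu, g)
      expect_lt(max(abs(post[i, , ] - oracle$posterior)), 1e-10)
      expect_equal(attr(post, "loglik")[i], oracle$loglik, tolerance = 1e-10)
    }
  }
})

test_that("posteriors respect the information limits", {
  J <- 12
  map <- seq(0, 55, by = 5)
  # fully informative markers: decode recovers the simulated dosage
  fr_info <- ancestral_freqs(rep(0.999, J), rep(0.001, J))
  truth <- sim_chromosome(map, 0.8, 6, I = 40, seed = 31)
  genos <- sim_aim_genotypes(truth$S, fr_info, seed = 32)
  post <- hmm_posteriors(genos, fr_info, map, hmm_params(mu = 0.8, g = 6))
  picked <- vapply(1:40, function(i) {
    post[cbind(i, seq_len(J), truth$S[i, ] + 1)]
  }, numeric(J))
  # near-certain decoding everywhere except the rare emission flips
  # (frequency ~1e-3 per haplotype under Bernoulli genotype sampling)
  expect_gt(mean(picked > 0.99), 0.98)
  expect_gt(min(picked), 1e-4)
  # uninformative markers: posterior falls back to the HWE prior in mu
  fr_none <- ancestral_freqs(rep(0.5, J), rep(0.5, J))
  post0 <- hmm_posteriors(genos[1:5, ], fr_none, map, hmm_params(mu = 0.7, g = 6))
  prior <- c(0.09, 0.42, 0.49)
  expect_lt(max(abs(sweep(post0, 3, prior)[, , ])), 1e-10)
  # posteriors always sum to one
  expect_equal(apply(post, c(1, 2), sum), matrix(1, 40, J), tolerance = 1e-12)
})

test_that("joint backward sampling matches marginals and preserves LD", {
  J <- 5
  map <- c(0, 1, 2, 3, 4)   # tight linkage
  fr <- ancestral_freqs(c(0.9, 0.8, 0.85, 0.9, 0.8), c(0.2, 0.1, 0.15, 0.2, 0.1))
  truth <- sim_chromosome(map, 0.75, 6, I = 4, seed = 41)
  genos <- sim_aim_genotypes(truth$S, fr, seed = 42)
  prm <- hmm_params(mu = 0.75, g = 6)
  post <- hmm_posteriors(genos, fr, map, prm)
  imp <- sample_imputations(genos, fr, map, prm, M = 4000, seed = 43)
  # sampled marginal frequencies match forward-backward posteriors
  for (i in 1:4) {
    for (j in 1:J) {
      freq <- tabulate(1 + vapply(imp$draws, function(D) D[i, j], 0L), 3) / 4000
      se <- sqrt(pmax(post[i, j, ] * (1 - post[i, j, ]), 1e-4) / 4000)
      expect_true(all(abs(freq - post[i, j, ]) < 4 * se + 0.01))
    }
  }
  # adjacent loci stay correlated within a draw (admixture LD preserved)
  wide <- sim_chromosome(seq(0, 8, by = 2), 0.75, 6, I = 300, seed = 44)
  fr2 <- ancestral_freqs(rep(0.8, 5), rep(0.2, 5))
  g2 <- sim_aim_genotypes(wide$S, fr2, seed = 45)
  one <- sample_imputations(g2, fr2, seq(0, 8, by = 2), prm, M = 1, seed = 46)
  expect_gt(cor(one$draws[[1]][, 1], one$draws[[1]][, 2]), 0.2)
  # determinism
  again <- sample_imputations(genos, fr, map, prm, M = 2, seed = 47)
  again2 <- sample_imputations(genos, fr, map, prm, M = 2, seed = 47)
  expect_identical(again$draws, again2$draws)
})

test_that("global ancestry is recovered and order-invariant", {
  J <- 800
  fr <- ancestral_freqs(rep(0.9, J), rep(0.1, J))
  set.seed(51)
  S <- matrix(rbinom(5 * J, 2, 0.8), 5, J)
  genos <- sim_aim_genotypes(S, fr, seed = 52)
  mu <- estimate_global_ancestry(genos, fr)
  expect_true(all(abs(mu - 0.8) < 0.05))
  # permuting the loci leaves the estimate unchanged
  perm <- sample(J)
  fr_p <- ancestral_freqs(fr$f1[perm], fr$f2[perm])
  expect_equal(estimate_global_ancestry(genos[, perm], fr_p), mu,
               tolerance = 1e-8)
  # all-population-1 genotypes push the estimate to the boundary clamp
  hi <- matrix(2L, 2, J)
  mu_hi <- estimate_global_ancestry(hi, fr)
  expect_true(all(mu_hi > 0.99))
  expect_error(estimate_global_ancestry(genos[, 1:5], fr), "at least 10")
  expect_error(estimate_global_ancestry(genos, ancestral_freqs(rep(0.5, J), rep(0.5, J))),
               "uninformative")
})

test_that("log-space recursions survive long chains", {
  J <- 10000
  fr <- ancestral_freqs(rep(0.85, J), rep(0.15, J))
  truth <- sim_chromosome(seq(0, by = 0.05, length.out = J), 0.8, 6, I = 1,
                          seed = 61)
  genos <- sim_aim_genotypes(truth$S, fr, seed = 62)
  post <- hmm_posteriors(genos, fr, seq(0, by = 0.05, length.out = J),
                         hmm_params(mu = 0.8, g = 6))
  expect_true(is.finite(attr(post, "loglik")[1]))
  expect_false(anyNA(post))
})

test_that("imputation-averaged mapping tracks the known-ancestry scan", {
  # end to end: simulate ancestries, emit AIM genotypes, impute with M = 10,
  # scan with Bayes-factor averaging; compare detections against scanning
  # the true ancestries on the same replicates
  J <- 25
  map <- seq(0, 96, by = 4)
  fr <- ancestral_freqs(rep(0.9, J), rep(0.1, J))
  d <- sim_design("single_locus", "gaussian", I = 300, J = J, c_mult = 1.2)
  hits_true <- hits_imp <- 0
  R <- 10
  for (r in seq_len(R)) {
    truth <- sim_chromosome(map, 0.8, 6, I = 300, seed = 700 + r)
    causal <- truth$loci$locus_id[13]
    tr <- sim_traits(truth, d, causal = causal, seed = 800 + r)
    genos <- sim_aim_genotypes(truth$S, fr, seed = 900 + r)
    imp <- sample_imputations(genos, fr, map, hmm_params(mu = 0.8, g = 6),
                              M = 10, seed = 1000 + r)
    imp_panel <- ancestry_panel(truth$S, truth$loci, imputations = imp$draws)
    cfg <- scan_config(family = "gaussian")
    s_true <- stage1_scan(truth, tr$y, NULL, cfg)
    s_imp <- stage1_scan(imp_panel, tr$y, NULL, cfg)
    hits_true <- hits_true + s_true$results$selected[s_true$results$locus_id == causal]
    hits_imp <- hits_imp + s_imp$results$selected[s_imp$results$locus_id == causal]
  }
  expect_lte(abs(hits_true - hits_imp) / R, 0.1)
})
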