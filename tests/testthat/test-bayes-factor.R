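test_that("shrunken Wald statistic follows the closed form", {
  # z^2 = 16, I tau = 1 -> shrinkage 1/2 -> T = 8
  expect_equal(shrunken_wald_T(4, Sigma = 1, sigma2 = 1, tau = 1 / 100, n = 100), 8)
  expect_equal(shrunken_wald_T(0, 1, 1, 0.5, 100), 0)
  expect_equal(shrunken_wald_T(rep(0, 2), diag(2), 1, 0.5, 100), 0)
  # tau -> infinity recovers the raw Wald statistic
  expect_equal(shrunken_wald_T(4, 1, 1, 1e9, 100), 16, tolerance = 1e-6)
  # tau = 0 kills it
  expect_equal(shrunken_wald_T(4, 1, 1, 0, 100), 0)
  expect_error(shrunken_wald_T(1, matrix(0, 1, 1), 1, 1, 10), "singular")
})

test_that("closed-form Bayes factor reproduces hand-evaluated cases", {
  blk0 <- list(beta = 0, Sigma = matrix(1), sigma2 = 1)
  bf0 <- qnm_bayes_factor(blk0, tau = 1 / 200, n = 200)  # I tau = 1, T = 0
  expect_equal(bf0$bf, 2^(-3 / 2), tolerance = 1e-12)
  expect_lt(bf0$bf, 1)  # evidence favors the null at beta-hat = 0

  # z^2 = 16, I tau = 1: T = 8, BF = 9 * 2^(-3/2) * e^4
  blk <- list(beta = 4, Sigma = matrix(1), sigma2 = 1)
  bf <- qnm_bayes_factor(blk, tau = 1 / 100, n = 100)
  expect_equal(bf$T, 8)
  expect_equal(bf$bf, 9 * 2^(-3 / 2) * exp(4), tolerance = 1e-12)
  expect_equal(bf$log10_bf, log10(bf$bf))
})

test_that("closed form equals the quadrature oracle on random instances", {
  set.seed(101)
  # 50 gaussian p = 1 instances
  worst1 <- 0
  for (r in 1:50) {
    n <- sample(40:120, 1)
    S <- matrix(rbinom(n, 2, runif(1, 0.6, 0.9)), n, 1)
    if (max(S) == min(S)) next
    E <- if (r %% 2) matrix(rnorm(n), n, 1) else NULL
    y <- rnorm(n, runif(1, -0.5, 0.8) * S[, 1])
    d <- build_design(S, E)
    tau <- runif(1, 1e-4, 5 / n)
    blk <- extract_ancestry_block(fit_glm(y, d))
    closed <- qnm_bayes_factor(blk, tau, n)
    oracle <- bf_numeric_oracle(y, d, tau)
    worst1 <- max(worst1, abs(log(closed$bf) - log(oracle)))
  }
  expect_lt(worst1, 1e-5)

  # 20 gaussian p = 2 instances (correlated dosage pairs)
  worst2 <- 0
  for (r in 1:20) {
    n <- sample(60:150, 1)
    S <- sim_correlated_pair(0.8, runif(1, 0, 0.7), n)
    if (any(apply(S, 2, function(s) max(s) == min(s)))) next
    y <- rnorm(n, S %*% runif(2, -0.3, 0.5))
    d <- build_design(S)
    tau <- runif(1, 1e-4, 5 / n)
    blk <- extract_ancestry_block(fit_glm(y, d))
    closed <- qnm_bayes_factor(blk, tau, n)
    oracle <- bf_numeric_oracle(y, d, tau)
    worst2 <- max(worst2, abs(log(closed$bf) - log(oracle)))
  }
  expect_lt(worst2, 1e-3)
})

test_that("oracle limits: tau to zero gives BF 1; binomial Laplace regime", {
  set.seed(33)
  n <- 150
  S <- matrix(rbinom(n, 2, 0.8), n, 1)
  y <- rnorm(n, 0.4 * S[, 1])
  d <- build_design(S)
  bfs <- vapply(c(1e-3, 1e-5, 1e-7), function(tau) bf_numeric_oracle(y, d, tau), 0)
  expect_lt(abs(bfs[3] - 1), abs(bfs[1] - 1))
  expect_equal(bfs[3], 1, tolerance = 0.05)
  expect_identical(bf_numeric_oracle(y, d, 0), 1)

  yb <- rbinom(n, 1, plogis(0.8 * (S[, 1] - mean(S[, 1]))))
  fb <- fit_glm(yb, d, family = "binomial")
  closed <- qnm_bayes_factor(extract_ancestry_block(fb), 0.02, n)
  oracle <- bf_numeric_oracle(yb, d, 0.02, family = "binomial")
  expect_equal(closed$bf, oracle, tolerance = 5e-2)
})

test_that("BF is strictly increasing in the Wald statistic", {
  W <- seq(0, 50, by = 0.5)
  lbf <- gleam:::log_bf_from_wald(W, tau = 0.002, n = 1000, p = 1)
  expect_true(all(diff(lbf) > 0))
  lbf2 <- gleam:::log_bf_from_wald(W, tau = 0.002, n = 1000, p = 2)
  expect_true(all(diff(lbf2) > 0))
})

test_that("empirical-Bayes tau behaves at boundaries and under planted effects", {
  # all beta-hat = 0 -> tau-hat = 0 and all BFs = 1
  blocks <- replicate(5, list(beta = 0, Sigma = matrix(1), sigma2 = 1),
                      simplify = FALSE)
  eb <- estimate_tau(blocks, n = 1000, mode = "genomewide")
  expect_equal(eb$tau_hat, 0)
  ebl <- estimate_tau(blocks, n = 1000, mode = "per_locus")
  expect_equal(ebl$per_locus_tau, rep(0, 5))

  # single locus, per-locus mode: Wald below p pins tau at 0
  expect_equal(gleam:::per_locus_tau(0.8, 1L, 1000, 0.01), 0)
  # the closed-form stationary point agrees with direct optimization
  for (W in c(2, 7, 19, 60)) {
    t_cf <- gleam:::per_locus_tau(W, 1L, 1000, 0.01)
    opt <- optimize(function(lt) gleam:::log_bf_from_wald(W, exp(lt), 1000, 1),
                    c(log(1e-12), log(0.01)), maximum = TRUE, tol = 1e-12)
    expect_equal(t_cf, exp(opt$maximum), tolerance = 1e-5)
  }

  # genome-wide tau-hat grows with planted effect size
  set.seed(77)
  tau_at <- function(c_mult) {
    n <- 600
    S <- matrix(rbinom(n * 30, 2, 0.8), n, 30)
    y <- rnorm(n, S[, 1:3] %*% rep(c_mult * 0.85, 3))
    blocks <- lapply(1:30, function(j) {
      extract_ancestry_block(fit_glm(y, build_design(S[, j, drop = FALSE])))
    })
    estimate_tau(blocks, n, mode = "genomewide")$tau_hat
  }
  taus <- vapply(c(0, 0.3, 0.7), tau_at, 0)
  expect_true(all(diff(taus) >= 0))
  expect_gt(taus[3], 0)
})

test_that("imputation averaging is an arithmetic mean on the BF scale", {
  expect_equal(average_bf(c(10, 1000))$bf, 505)
  expect_equal(average_bf(c(10, 1000))$log10_bf, log10(505))
  one <- qnm_bayes_factor(list(beta = 2, Sigma = matrix(1), sigma2 = 1),
                          0.01, 100)
  expect_equal(average_bf(list(one))$bf, one$bf)
  dup <- average_bf(list(one, one, one))
  expect_equal(dup$bf, one$bf)
  expect_equal(dup$n_imputations_averaged, 3L)
  expect_error(average_bf(list()), "empty")
  expect_error(average_bf(c(1, 2), weights = c(0.7, 0.7)), "sum to 1")
  expect_equal(average_bf(c(10, 1000), weights = c(0.9, 0.1))$bf, 109)
})
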