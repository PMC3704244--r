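test_that("stage 1 matches a direct single-locus computation and finds a planted effect", {
  set.seed(1)
  d <- sim_design("single_locus", "gaussian", I = 800, J = 60, c_mult = 0.4)
  panel <- sim_panel(d, seed = 21)
  tr <- sim_traits(panel, d, seed = 22)
  causal <- attr(panel, "causal")
  cfg <- scan_config(family = "gaussian")
  scan <- stage1_scan(panel, tr$y, tr$E, cfg)
  res <- scan$results
  expect_equal(nrow(res), 60)
  expect_equal(res$locus_id[which.max(res$log10_bf)], causal)

  # the vectorized gaussian path equals the generic per-locus GLM route
  j <- 7
  blk <- extract_ancestry_block(
    fit_glm(tr$y, build_design(panel$S[, j, drop = FALSE], tr$E)))
  W <- gleam:::wald_stat(blk$beta, blk$Sigma, blk$sigma2)
  tau_j <- gleam:::per_locus_tau(W, 1L, 800, 10 / 800)
  expect_equal(res$beta_hat[j], unname(blk$beta), tolerance = 1e-10)
  expect_equal(res$log10_bf[j],
               gleam:::log_bf_from_wald(W, tau_j, 800, 1) / log(10),
               tolerance = 1e-8)
  # selection is the threshold rule
  expect_equal(res$selected, !is.na(res$log10_bf) & res$log10_bf > 2)
})

test_that("planted single-locus effect attains the genome-wide maximum", {
  d <- sim_design("single_locus", "gaussian", I = 1000, J = 200, c_mult = 0.4)
  hits <- 0
  for (r in 1:20) {
    panel <- sim_panel(d, seed = 300 + r)
    tr <- sim_traits(panel, d, seed = 600 + r)
    scan <- stage1_scan(panel, tr$y, tr$E, scan_config(family = "gaussian"))
    best <- scan$results$locus_id[which.max(scan$results$log10_bf)]
    hits <- hits + (best == attr(panel, "causal"))
  }
  expect_gte(hits, 18)  # >= 95% nominal, 20-replicate binomial slack
})

test_that("pure-noise scans select almost nothing at the default threshold", {
  panel <- sim_hwe_panel(runif(1000, 0.7, 0.9), 1000, seed = 31)
  n_sel <- 0
  for (t in 1:6) {
    set.seed(40 + t)
    y <- rnorm(1000)
    scan <- stage1_scan(panel, y, NULL, scan_config(family = "gaussian"))
    n_sel <- n_sel + sum(scan$results$selected)
  }
  expect_lt(n_sel / 6, 2)  # expected ~0.6 per 1000-locus trait set
})

test_that("degenerate imputation (truth duplicated M times) changes nothing", {
  d <- sim_design("single_locus", "gaussian", I = 300, J = 20, c_mult = 0.4)
  panel <- sim_panel(d, seed = 51)
  tr <- sim_traits(panel, d, seed = 52)
  dup <- ancestry_panel(panel$S, panel$loci,
                        imputations = list(panel$S, panel$S, panel$S))
  s1 <- stage1_scan(panel, tr$y, NULL, scan_config(family = "gaussian"))
  s2 <- stage1_scan(dup, tr$y, NULL, scan_config(family = "gaussian"))
  expect_equal(s1$results$log10_bf, s2$results$log10_bf, tolerance = 1e-12)
  expect_equal(s2$n_imputations, 3L)
})

test_that("skipped loci are reported, never silently dropped", {
  d <- sim_design("single_locus", "gaussian", I = 100, J = 5, c_mult = 0.4)
  panel <- sim_panel(d, seed = 61)
  S <- panel$S
  S[, 3] <- 2L  # constant dosage column
  panel2 <- ancestry_panel(S, transform(panel$loci, p_a = colMeans(S) / 2))
  tr <- sim_traits(panel2, d, causal = panel2$loci$locus_id[1], seed = 62)
  scan <- stage1_scan(panel2, tr$y, NULL, scan_config(family = "gaussian"))
  expect_equal(nrow(scan$results), 5)
  expect_equal(scan$results$skipped_reason[3], "degenerate")
  expect_false(scan$results$selected[3])
})

test_that("stage 2 enumerates, ranks, and identifies subsets correctly", {
  # two independent causal loci: the joint pair should beat the marginals
  set.seed(71)
  S <- cbind(rbinom(1000, 2, 0.85), rbinom(1000, 2, 0.85),
             rbinom(1000, 2, 0.85))
  panel <- ancestry_panel(S)
  y <- 0.5 * S[, 1] + 0.5 * S[, 2] + rnorm(1000)
  cfg <- scan_config(family = "gaussian")
  report <- gleam_map(panel, y, NULL, cfg)
  expect_setequal(report$selected, c("locus1", "locus2"))
  s2 <- report$stage2
  expect_equal(nrow(s2), 3)  # {1}, {2}, {1,2}
  pair <- s2$log10_bf[s2$subset == "locus1+locus2"]
  singles <- s2$log10_bf[s2$size == 1]
  expect_gt(pair, max(singles))
  expect_setequal(report$identified, c("locus1", "locus2"))
  expect_equal(s2$rank, seq_len(nrow(s2)))
  expect_true(all(diff(s2$log10_bf) <= 0))

  # single selected locus: stage 2 unnecessary, identified = that locus
  y1 <- 0.5 * S[, 1] + rnorm(1000)
  rep1 <- gleam_map(panel, y1, NULL, cfg)
  if (length(rep1$selected) == 1) {
    expect_equal(nrow(rep1$stage2), 0)
    expect_equal(rep1$identified, rep1$selected)
  }

  # no subset passing the threshold -> empty identified set
  fake <- structure(list(selected = c("a", "b"),
                         stage2 = data.frame(subset = c("a", "b", "a+b"),
                                             size = c(1, 1, 2),
                                             log10_bf = c(1.2, 0.8, 1.9),
                                             rank = 1:3),
                         delta = 2), class = "mapping_report")
  expect_equal(identify_loci(fake), character())
  fake$stage2$log10_bf <- c(1.2, 0.8, 5.1)
  fake$stage2 <- fake$stage2[order(-fake$stage2$log10_bf), ]
  expect_setequal(identify_loci(fake), c("a", "b"))
  expect_setequal(identify_loci(fake, "all_passing"), c("a", "b"))
})

test_that("scan output is invariant to locus ordering", {
  d <- sim_design("single_locus", "gaussian", I = 300, J = 12, c_mult = 0.4)
  panel <- sim_panel(d, seed = 81)
  tr <- sim_traits(panel, d, seed = 82)
  perm <- sample(12)
  loci_p <- panel$loci[perm, ]
  o <- order(loci_p$chrom, loci_p$pos_bp)
  panel_p <- ancestry_panel(panel$S[, perm][, o], loci_p[o, ])
  s1 <- stage1_scan(panel, tr$y, NULL, scan_config(family = "gaussian"))
  s2 <- stage1_scan(panel_p, tr$y, NULL, scan_config(family = "gaussian"))
  m <- match(s1$results$locus_id, s2$results$locus_id)
  expect_equal(s1$results$log10_bf, s2$results$log10_bf[m], tolerance = 1e-12)
})

test_that("stage-2 cap errors by default and truncates on request", {
  sel <- paste0("l", 1:20)
  panel <- toy_panel(I = 30, J = 4)
  expect_error(stage2_joint(panel, rnorm(30), NULL, sel, scan_config()),
               "raise delta")
})

test_that("two-stage pruning does not increase flanking false positives", {
  d <- sim_design("two_locus", "binomial", n_replicates = 15)
  res <- run_experiment(d, methods = c("gleam1", "gleam2"), seed = 7)
  tab <- res$table
  g1 <- tab[tab$method == "gleam1", ]
  g2 <- tab[tab$method == "gleam2", ]
  expect_lte(g2$REG1, g1$REG1)
  expect_lte(g2$REG2, g1$REG2)
  expect_lte(g2$REG3, g1$REG3)
})
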