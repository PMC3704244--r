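#' Scan configuration
#'
#' @param delta log10 Bayes-factor selection threshold (default 2: a locus is
#'   a susceptibility candidate when log10 BF > delta).
#' @param family GLM family for the trait.
#' @param tau_mode empirical-Bayes mode for the prior dispersion: "per_locus"
#'   (default; each locus/subset maximizes its own marginal evidence) or
#'   "genomewide" (one shared tau maximizing the pooled evidence, reused in
#'   stage 2).
#' @param max_selected cap on the number of stage-1 selections carried to
#'   stage 2.
#' @param max_subset_size cap on the cardinality of enumerated stage-2
#'   subsets.
#' @param overflow what to do when stage 1 selects more than `max_selected`
#'   loci: "error" (default) or "truncate" (keep the top `max_selected` by
#'   log10 BF).
#' @param sigma2_source dispersion plugged into the Bayes factor:
#'   "alternative" (default, from the alternative-model fit) or "null".
#' @param tau_max upper bound for tau as a multiple of 1/I (default 10).
#' @param seed optional integer seed.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(delta = 2, family = c("gaussian", "binomial", "poisson"),
                        tau_mode = c("per_locus", "genomewide"),
                        max_selected = 15L, max_subset_size = 10L,
                        overflow = c("error", "truncate"),
                        sigma2_source = c("alternative", "null"),
                        tau_max = 10, seed = NULL) {
  stopifnot(max_selected >= 1, max_subset_size >= 1)
  structure(list(delta = delta, family = match.arg(family),
                 tau_mode = match.arg(tau_mode),
                 max_selected = as.integer(max_selected),
                 max_subset_size = as.integer(max_subset_size),
                 overflow = match.arg(overflow),
                 sigma2_source = match.arg(sigma2_source),
                 tau_max = tau_max, seed = seed),
            class = "scan_config")
}

# Per-locus ancestry blocks for one dosage matrix.
# Gaussian: vectorized exact least squares by residualizing trait and every
# dosage column against [intercept, covariates] (Frisch-Waugh; identical to
# the joint fit). Other families: one IRLS fit per locus.
# Returns data.frame(beta, Sss (= 1/Sigma), sigma2, W, skipped_reason).
scan_blocks <- function(S, y, E, family, sigma2_estimator = "ml") {
  I <- nrow(S)
  J <- ncol(S)
  skipped <- rep(NA_character_, J)
  const <- apply(S, 2, function(s) max(s) == min(s))
  skipped[const] <- "degenerate"
  beta <- Sss <- sigma2 <- W <- rep(NA_real_, J)

  if (family == "gaussian") {
    Z <- if (is.null(E)) matrix(1, I, 1) else cbind(1, E)
    qz <- qr(Z)
    k <- ncol(Z) + 1L
    yt <- qr.resid(qz, y)
    St <- qr.resid(qz, sweep(S, 2, colMeans(S)))
    ss <- colSums(St^2)
    ok <- !const & ss > 1e-10
    skipped[!ok & !const] <- "degenerate"
    b <- colSums(St * yt)[ok] / ss[ok]
    rss <- sum(yt^2) - b^2 * ss[ok]
    s2 <- if (sigma2_estimator == "ml") rss / I else rss / (I - k)
    s2 <- pmax(s2, 1e-12)
    beta[ok] <- b
    Sss[ok] <- ss[ok]
    sigma2[ok] <- s2
    W[ok] <- b^2 * ss[ok] / s2
  } else {
    for (j in which(!const)) {
      des <- build_design(S[, j, drop = FALSE], E)
      fit <- tryCatch(fit_glm(y, des, family = family),
                      gleam_separation = function(e) e,
                      error = function(e) e)
      if (inherits(fit, "gleam_separation")) { skipped[j] <- "separation"; next }
      if (inherits(fit, "error")) { skipped[j] <- conditionMessage(fit); next }
      blk <- extract_ancestry_block(fit)
      beta[j] <- blk$beta
      Sss[j] <- 1 / blk$Sigma[1, 1]
      sigma2[j] <- blk$sigma2
      W[j] <- blk$beta^2 * Sss[j] / blk$sigma2
    }
  }
  data.frame(beta = beta, Sss = Sss, sigma2 = sigma2, W = W,
             skipped_reason = skipped, stringsAsFactors = FALSE)
}

#' Stage 1: single-locus screen
#'
#' Fits the trait on each locus separately (plus covariates), computes the QNM
#' Bayes factor with the empirical-Bayes tau, and averages Bayes factors over
#' imputation draws when the panel carries them. Loci with constant dosage or
#' separated binomial fits are reported as skipped, never silently dropped.
#'
#' @param panel an [ancestry_panel].
#' @param y trait vector aligned with the panel's subjects.
#' @param E optional covariate matrix.
#' @param cfg a [scan_config()].
#' @return object of class `gleam_scan`: `results` data.frame (locus_id,
#'   beta_hat, se, log10_bf, selected, skipped_reason), `tau` (the
#'   empirical-Bayes estimates of the last draw), `delta`, `family`.
#' @export
stage1_scan <- function(panel, y, E = NULL, cfg = scan_config()) {
  stopifnot(inherits(panel, "ancestry_panel"))
  if (length(y) != panel$n_subjects) {
    stop("trait has ", length(y), " subjects, panel has ", panel$n_subjects)
  }
  draws <- panel_draws(panel)
  M <- length(draws)
  J <- panel$n_loci
  I <- panel$n_subjects
  bf_mat <- matrix(NA_real_, J, M)
  beta_mat <- se_mat <- matrix(NA_real_, J, M)
  skipped <- rep(NA_character_, J)
  tau_last <- NULL
  for (m in seq_len(M)) {
    bl <- scan_blocks(draws[[m]], y, E, cfg$family)
    ok <- is.na(bl$skipped_reason)
    skipped[!is.na(bl$skipped_reason)] <- bl$skipped_reason[!is.na(bl$skipped_reason)]
    eb <- estimate_tau(bl$W[ok], I, mode = cfg$tau_mode,
                       tau_max = cfg$tau_max / I, p = 1L)
    tau_vec <- if (cfg$tau_mode == "per_locus") eb$per_locus_tau else
      rep(eb$tau_hat, sum(ok))
    bf_mat[ok, m] <- exp(log_bf_from_wald(bl$W[ok], tau_vec, I, 1L))
    beta_mat[, m] <- bl$beta
    se_mat[, m] <- sqrt(bl$sigma2 / bl$Sss)
    tau_last <- eb
  }
  if (all(!is.na(skipped))) stop("all loci were skipped")
  bf_avg <- rowMeans(bf_mat)
  results <- data.frame(
    locus_id = panel$loci$locus_id,
    beta_hat = rowMeans(beta_mat),
    se = rowMeans(se_mat),
    log10_bf = log10(bf_avg),
    selected = !is.na(bf_avg) & log10(bf_avg) > cfg$delta,
    skipped_reason = skipped,
    stringsAsFactors = FALSE
  )
  results$selected[!is.na(skipped)] <- FALSE
  structure(list(results = results, tau = tau_last, delta = cfg$delta,
                 family = cfg$family, n_imputations = M),
            class = "gleam_scan")
}

#' @export
print.gleam_scan <- function(x, ...) {
  cat("gleam_scan (", x$family, "): ", nrow(x$results), " loci, ",
      sum(x$results$selected), " selected at log10 BF > ", x$delta,
      " (M = ", x$n_imputations, ")\n", sep = "")
  top <- x$results[order(-x$results$log10_bf), ][seq_len(min(5, nrow(x$results))), ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stage 2: joint Bayes factors over subsets of selected loci
#'
#' Enumerates every non-empty subset (up to `max_subset_size`) of the stage-1
#' selected loci, fits the joint GLM with all subset loci plus covariates, and
#' scores each subset with the joint QNM Bayes factor (p = subset size),
#' averaged over imputation draws. Subsets are ranked by log10 BF descending;
#' ties broken by smaller subset, then lexicographic locus order.
#'
#' @param panel an [ancestry_panel].
#' @param y trait vector.
#' @param E optional covariates.
#' @param selected character vector of selected locus ids (>= 2 for a
#'   non-empty result).
#' @param cfg a [scan_config()].
#' @param tau_genomewide stage-1 genome-wide tau to reuse when
#'   `cfg$tau_mode == "genomewide"`.
#' @return data.frame (subset, size, log10_bf, rank); empty when fewer than
#'   two loci are selected.
#' @export
stage2_joint <- function(panel, y, E = NULL, selected, cfg = scan_config(),
                         tau_genomewide = NULL) {
  empty <- data.frame(subset = character(), size = integer(),
                      log10_bf = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (length(selected) < 2) return(empty)
  if (length(selected) > cfg$max_selected) {
    stop("stage 2 would enumerate subsets of ", length(selected),
         " loci (cap ", cfg$max_selected, "); raise delta or max_selected, ",
         "or use overflow = 'truncate'")
  }
  selected <- sort(selected)
  idx <- match(selected, panel$loci$locus_id)
  if (anyNA(idx)) stop("selected loci not on panel: ",
                       paste(selected[is.na(idx)], collapse = ","))
  draws <- panel_draws(panel)
  I <- panel$n_subjects
  sizes <- seq_len(min(length(selected), cfg$max_subset_size))
  subsets <- unlist(lapply(sizes, function(k) {
    utils::combn(seq_along(selected), k, simplify = FALSE)
  }), recursive = FALSE)
  bf <- vapply(subsets, function(sub) {
    vals <- vapply(draws, function(S) {
      des <- build_design(S[, idx[sub], drop = FALSE], E)
      fit <- tryCatch(fit_glm(y, des, family = cfg$family),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      blk <- extract_ancestry_block(fit)
      p <- length(sub)
      W <- wald_stat(blk$beta, blk$Sigma, blk$sigma2)
      tau <- if (cfg$tau_mode == "genomewide") {
        if (is.null(tau_genomewide)) stop("genomewide mode needs stage-1 tau")
        tau_genomewide
      } else {
        per_locus_tau(W, p, I, cfg$tau_max / I)
      }
      exp(log_bf_from_wald(W, tau, I, p))
    }, 0)
    mean(vals)
  }, 0)
  labels <- vapply(subsets, function(sub) paste(selected[sub], collapse = "+"), "")
  out <- data.frame(subset = labels,
                    size = lengths(subsets),
                    log10_bf = log10(bf),
                    stringsAsFactors = FALSE)
  ord <- order(-out$log10_bf, out$size, out$subset)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Final locus identification rule
#'
#' Turns a mapping report into the identified locus set. `top_subset`
#' (default): members of the highest-ranked stage-2 subset whose log10 BF
#' exceeds delta (with at most one selected locus, that locus itself when it
#' passed stage 1). `all_passing`: the union over all stage-2 subsets passing
#' delta.
#'
#' @param report a [gleam_map()] result.
#' @param rule "top_subset" or "all_passing".
#' @return character vector of locus ids (possibly empty).
#' @export
identify_loci <- function(report, rule = c("top_subset", "all_passing")) {
  rule <- match.arg(rule)
  sel <- report$selected
  s2 <- report$stage2
  if (length(sel) <= 1) return(sel)
  if (!nrow(s2)) return(character())
  passing <- s2[s2$log10_bf > report$delta, , drop = FALSE]
  if (!nrow(passing)) return(character())
  if (rule == "top_subset") {
    strsplit(passing$subset[1], "+", fixed = TRUE)[[1]]
  } else {
    unique(unlist(strsplit(passing$subset, "+", fixed = TRUE)))
  }
}

#' Run the full two-stage admixture mapping procedure
#'
#' Stage-1 single-locus screen at log10 BF > delta, stage-2 joint subset
#' evaluation over the selected loci, and the final identification rule.
#'
#' @inheritParams stage1_scan
#' @param rule identification rule passed to [identify_loci()].
#' @return object of class `mapping_report` with `stage1` (scan results),
#'   `selected`, `stage2` (subset table), `identified`, `tau`, `delta`,
#'   `config`, `truncated` (TRUE when the selected set was capped).
#' @export
gleam_map <- function(panel, y, E = NULL, cfg = scan_config(),
                      rule = c("top_subset", "all_passing")) {
  rule <- match.arg(rule)
  scan <- stage1_scan(panel, y, E, cfg)
  res <- scan$results
  sel <- res$locus_id[res$selected]
  truncated <- FALSE
  if (length(sel) > cfg$max_selected) {
    if (cfg$overflow == "error") {
      stop("stage 1 selected ", length(sel), " loci (cap ", cfg$max_selected,
           "); raise delta or max_selected, or use overflow = 'truncate'")
    }
    keep <- order(-res$log10_bf[res$selected])[seq_len(cfg$max_selected)]
    sel <- sel[keep]
    truncated <- TRUE
  }
  tau_gw <- if (cfg$tau_mode == "genomewide") scan$tau$tau_hat else NULL
  s2 <- stage2_joint(panel, y, E, sel, cfg, tau_genomewide = tau_gw)
  report <- structure(list(stage1 = res, selected = sel, stage2 = s2,
                           identified = character(), tau = scan$tau,
                           delta = cfg$delta, config = cfg,
                           truncated = truncated),
                      class = "mapping_report")
  report$identified <- identify_loci(report, rule)
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("mapping_report: ", sum(x$stage1$selected), " loci selected in stage 1",
      if (x$truncated) " (truncated)", "; identified: ",
      if (length(x$identified)) paste(x$identified, collapse = ", ") else "none",
      "\n", sep = "")
  if (nrow(x$stage2)) {
    cat("top stage-2 subsets:\n")
    print(utils::head(x$stage2, 5), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
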