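#' Penalized-regression scan (lasso / elastic net)
#'
#' Fits all loci jointly with a penalized GLM (coordinate descent via glmnet),
#' leaving covariates unpenalized, and selects the loci with nonzero ancestry
#' coefficients at the regularization value minimizing k-fold
#' cross-validation error. Dosage columns are standardized internally by
#' glmnet; coefficients are reported on the original scale.
#'
#' @param panel an [ancestry_panel] (a single dosage matrix; when imputation
#'   draws are present, the first draw is used).
#' @param y trait vector.
#' @param E optional covariates (unpenalized).
#' @param method "lasso" (alpha = 1) or "enet" (alpha = 0.5).
#' @param family "gaussian" or "binomial".
#' @param k_folds cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param standardize standardize predictor columns before penalization.
#' @param lambda optional fixed penalty overriding cross-validation (0 gives
#'   the unpenalized joint fit; values at or above lambda_max select
#'   nothing).
#' @return object of class `penalized_scan`: `method`, `selected` (locus
#'   ids with nonzero coefficients), `coef` (named ancestry coefficients),
#'   `lambda`, `k_folds`, `seed`.
#' @export
penalized_scan <- function(panel, y, E = NULL, method = c("lasso", "enet"),
                           family = c("gaussian", "binomial"), k_folds = 10L,
                           seed = NULL, standardize = TRUE, lambda = NULL) {
  method <- match.arg(method)
  family <- match.arg(family)
  if (max(y) == min(y)) stop("constant trait: cross-validation is degenerate")
  S <- panel_draws(panel)[[1]]
  J <- ncol(S)
  x <- if (is.null(E)) S else cbind(S, E)
  penalty <- c(rep(1, J), rep(0, if (is.null(E)) 0 else ncol(E)))
  alpha <- if (method == "lasso") 1 else 0.5
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) {
    foldid <- sample(rep_len(seq_len(k_folds), length(y)))
    cv <- glmnet::cv.glmnet(x, y, family = family, alpha = alpha,
                            penalty.factor = penalty, foldid = foldid,
                            standardize = standardize)
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))[1 + seq_len(J)]
    lambda <- cv$lambda.min
  } else {
    fit <- glmnet::glmnet(x, y, family = family, alpha = alpha,
                          penalty.factor = penalty, standardize = standardize,
                          thresh = 1e-12)
    co <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                                 family = family, alpha = alpha,
                                 penalty.factor = penalty,
                                 standardize = standardize,
                                 thresh = 1e-12))[1 + seq_len(J)]
  }
  names(co) <- panel$loci$locus_id
  structure(list(method = method,
                 selected = panel$loci$locus_id[abs(co) > 0],
                 coef = co, lambda = lambda,
                 k_folds = k_folds, seed = seed),
            class = "penalized_scan")
}

#' @export
print.penalized_scan <- function(x, ...) {
  cat("penalized_scan (", x$method, "): ", length(x$selected),
      " loci selected at lambda.min = ", format(x$lambda, digits = 4), "\n",
      sep = "")
  invisible(x)
}
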