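#' Build a scan design matrix
#'
#' Assembles intercept, local-ancestry block and covariate block into a single
#' design. Ancestry columns are centered to mean zero (the scale on which the
#' Bayes factor's prior covariance is defined); covariates enter as given.
#'
#' @param S_block numeric matrix (I x p) of local-ancestry dosages.
#' @param E optional numeric matrix or vector (I x q) of covariates.
#' @param center center the ancestry columns (default TRUE).
#' @return list of class `gleam_design`: `X` (I x (1+p+q) matrix), `roles`
#'   (per-column role: intercept/ancestry/covariate), `p`, `q`, `degenerate`
#'   (logical per ancestry column: TRUE when the column is constant).
#' @export
build_design <- function(S_block, E = NULL, center = TRUE) {
  S_block <- as.matrix(S_block)
  I <- nrow(S_block)
  p <- ncol(S_block)
  if (p < 1) stop("ancestry block must have at least one column")
  if (anyNA(S_block)) stop("missing values in ancestry block")
  if (!is.null(E)) {
    E <- as.matrix(E)
    if (nrow(E) != I) stop("dimension mismatch: ancestry block has ", I,
                           " rows, covariates have ", nrow(E))
    if (anyNA(E)) stop("missing values in covariates")
  }
  q <- if (is.null(E)) 0L else ncol(E)
  degenerate <- apply(S_block, 2, function(s) max(s) == min(s))
  Sc <- if (center) sweep(S_block, 2, colMeans(S_block)) else S_block
  X <- cbind(`(Intercept)` = 1, Sc)
  if (q > 0) {
    if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(q))
    X <- cbind(X, E)
  }
  if (is.null(colnames(S_block))) {
    colnames(X)[1 + seq_len(p)] <- paste0("S", seq_len(p))
  }
  roles <- c("intercept", rep("ancestry", p), rep("covariate", q))
  structure(list(X = X, roles = roles, p = p, q = q, degenerate = degenerate),
            class = "gleam_design")
}

#' Fit a generalized linear model for a trait on ancestry and covariates
#'
#' Gaussian traits are fit by closed-form least squares; binomial and poisson
#' traits by iteratively reweighted least squares (canonical links). The fit
#' exposes exactly the pieces the Bayes factor consumes: the ancestry
#' coefficient subvector, its unit-dispersion covariance factor, and the
#' dispersion.
#'
#' @param y numeric response; 0/1 for binomial, non-negative integers for
#'   poisson.
#' @param design a [build_design()] result.
#' @param family one of "gaussian", "binomial", "poisson".
#' @param sigma2_estimator for gaussian fits, "ml" (residual sum of squares
#'   over I; the scale under which the closed-form Bayes factor is the exact
#'   marginal-likelihood ratio) or "reml" (RSS/(I - k)).
#' @return object of class `gleam_fit` with elements `coef`, `beta_S`,
#'   `Sigma_hat` (p x p; covariance of beta_S is sigma2_hat * Sigma_hat),
#'   `sigma2_hat`, `loglik`, `n_obs`, `family`, `converged`, `fitted`.
#' @export
fit_glm <- function(y, design, family = c("gaussian", "binomial", "poisson"),
                    sigma2_estimator = c("ml", "reml")) {
  family <- match.arg(family)
  sigma2_estimator <- match.arg(sigma2_estimator)
  X <- design$X
  I <- nrow(X)
  if (length(y) != I) stop("response length ", length(y), " != design rows ", I)
  if (anyNA(y)) stop("missing values in response")
  if (any(design$degenerate)) {
    stop("degenerate (constant) ancestry column in design: ",
         paste(which(design$degenerate), collapse = ","))
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial traits must be coded 0/1")
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    stop("poisson traits must be non-negative integers")
  }
  k <- ncol(X)
  idx_S <- which(design$roles == "ancestry")

  if (family == "gaussian") {
    qrx <- qr(X)
    if (qrx$rank < k) stop("rank-deficient design (rank ", qrx$rank, " < ", k, ")")
    coef <- qr.coef(qrx, y)
    res <- y - X %*% coef
    rss <- sum(res^2)
    XtX_inv <- chol2inv(qr.R(qrx))
    dimnames(XtX_inv) <- list(colnames(X), colnames(X))
    sigma2 <- if (sigma2_estimator == "ml") rss / I else rss / (I - k)
    sigma2 <- max(sigma2, 1e-12)  # guard exact fits
    loglik <- -I / 2 * (log(2 * pi * rss / I) + 1)
    fit <- list(coef = coef, Sigma_full = XtX_inv, sigma2_hat = sigma2,
                loglik = loglik, converged = TRUE, fitted = drop(X %*% coef))
  } else {
    fam <- if (family == "binomial") stats::binomial() else stats::poisson()
    g <- stats::glm.fit(X, y, family = fam,
                        control = list(epsilon = 1e-12, maxit = 100))
    eta <- g$linear.predictors
    mu <- g$fitted.values
    if (family == "binomial" && max(abs(eta)) > 30) {
      stop(structure(
        list(message = "complete or quasi-complete separation in binomial fit",
             call = sys.call(-1)),
        class = c("gleam_separation", "error", "condition")))
    }
    score <- drop(crossprod(X, y - mu))
    converged <- g$converged && max(abs(score)) < 1e-6
    if (!converged) stop("IRLS did not converge (max |score| = ",
                         format(max(abs(score))), ")")
    w <- fam$mu.eta(eta)  # canonical link: variance function = mu.eta
    R <- qr.R(qr(sqrt(w) * X))
    info_inv <- chol2inv(R)
    dimnames(info_inv) <- list(colnames(X), colnames(X))
    loglik <- if (family == "binomial") {
      sum(stats::dbinom(y, 1, mu, log = TRUE))
    } else {
      sum(stats::dpois(y, mu, log = TRUE))
    }
    fit <- list(coef = g$coefficients, Sigma_full = info_inv, sigma2_hat = 1,
                loglik = loglik, converged = TRUE, fitted = mu)
  }

  structure(list(
    coef = fit$coef,
    beta_S = fit$coef[idx_S],
    Sigma_hat = fit$Sigma_full[idx_S, idx_S, drop = FALSE],
    Sigma_full = fit$Sigma_full,
    sigma2_hat = fit$sigma2_hat,
    loglik = fit$loglik,
    n_obs = I,
    family = family,
    converged = fit$converged,
    fitted = fit$fitted,
    design = design
  ), class = "gleam_fit")
}

#' Extract the ancestry block of a fit
#'
#' Returns the ancestry coefficient estimate, the matching sub-block of the
#' unit-dispersion covariance factor (covariate adjustment happens through the
#' joint fit), and the dispersion estimate.
#'
#' @param fit a [fit_glm()] result.
#' @return list with `beta`, `Sigma`, `sigma2`, `n`.
#' @export
extract_ancestry_block <- function(fit) {
  if (!inherits(fit, "gleam_fit")) stop("not a gleam_fit")
  if (!isTRUE(fit$converged)) stop("fit did not converge; no ancestry block available")
  list(beta = fit$beta_S, Sigma = fit$Sigma_hat, sigma2 = fit$sigma2_hat,
       n = fit$n_obs)
}

#' @export
print.gleam_fit <- function(x, ...) {
  cat("gleam_fit (", x$family, "), I = ", x$n_obs, "\n", sep = "")
  cat("  beta_S:", format(x$beta_S, digits = 4), "\n")
  cat("  sigma2_hat:", format(x$sigma2_hat, digits = 4),
      " loglik:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}
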