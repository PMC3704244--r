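#' Quadratic normal moment (QNM) prior parameters
#'
#' The QNM prior is the non-local prior used for the ancestry effect vector
#' under the alternative hypothesis. Its density is
#' \deqn{f(\beta) = \frac{\beta' \Sigma^{-1} \beta}{I \tau \sigma^2 p}\,
#'       N_p(\beta;\, 0,\, I \tau \sigma^2 \Sigma),}
#' i.e. a normal density tilted by the quadratic form, so that it vanishes at
#' \eqn{\beta = 0}. \eqn{\sigma^2 \Sigma} is the covariance of the (weighted)
#' least-squares estimator of \eqn{\beta}, and \eqn{\tau} a dispersion
#' multiplier estimated empirically.
#'
#' @param tau dispersion multiplier, > 0.
#' @param sigma2 dispersion, > 0.
#' @param Sigma p x p positive-definite scale matrix.
#' @param n number of subjects I.
#' @return list of class `qnm_params`.
#' @export
qnm_params <- function(tau, sigma2, Sigma, n) {
  Sigma <- as.matrix(Sigma)
  stopifnot(tau > 0, sigma2 > 0, n > 0)
  if (!isSymmetric(unname(Sigma), tol = 1e-8)) stop("Sigma must be symmetric")
  L <- tryCatch(chol(Sigma), error = function(e) stop("Sigma is not positive definite"))
  structure(list(tau = tau, sigma2 = sigma2, Sigma = Sigma, n = n,
                 p = ncol(Sigma), chol_Sigma = L),
            class = "qnm_params")
}

#' QNM prior log-density
#'
#' @param beta numeric p-vector (or n x p matrix of points).
#' @param params a [qnm_params()] object.
#' @return log density (vector when `beta` is a matrix); `-Inf` at the origin.
#' @export
qnm_logdensity <- function(beta, params) {
  stopifnot(inherits(params, "qnm_params"))
  p <- params$p
  B <- if (is.matrix(beta)) beta else matrix(beta, ncol = p)
  if (ncol(B) != p) stop("beta has ", ncol(B), " columns; expected ", p)
  v <- params$n * params$tau * params$sigma2
  L <- params$chol_Sigma
  # z = L'^{-1} beta so that quad = beta' Sigma^{-1} beta = |z|^2
  z <- backsolve(L, t(B), transpose = TRUE)
  quad <- colSums(z^2)
  logdet <- 2 * sum(log(diag(L)))
  lognorm <- -0.5 * (p * log(2 * pi * v) + logdet) - quad / (2 * v)
  out <- ifelse(quad == 0, -Inf, log(quad) - log(v * p) + lognorm)
  if (is.matrix(beta)) out else out[1]
}

#' Sample from the QNM prior
#'
#' Uses the exact polar mixture representation: writing
#' \eqn{\beta = \sqrt{v}\, A z} with \eqn{A A' = \Sigma} and
#' \eqn{v = I\tau\sigma^2}, the tilted density in \eqn{z} is isotropic with
#' squared radius distributed as \eqn{\chi^2_{p+2}}; the direction is uniform
#' on the sphere.
#'
#' @param n number of draws.
#' @param params a [qnm_params()] object.
#' @param seed optional integer seed for reproducibility.
#' @return n x p matrix of draws.
#' @export
qnm_sample <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "qnm_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- params$p
  v <- params$n * params$tau * params$sigma2
  r <- sqrt(stats::rchisq(n, df = p + 2))
  u <- matrix(stats::rnorm(n * p), n, p)
  u <- u / sqrt(rowSums(u^2))
  z <- r * u
  sqrt(v) * z %*% params$chol_Sigma  # z %*% chol = (t(chol) %*% t(z))', A = t(chol)
}
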