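#' HMM parameters for two-ancestry local-ancestry inference
#'
#' Standard admixture HMM: per haplotype, ancestry switches between markers
#' at map distance d cM with probability 1 - exp(-g d / 100), and after a
#' switch the ancestry is drawn from (mu, 1 - mu). The hidden state at a
#' locus is the ancestry dosage (0/1/2 high-risk haplotypes); emissions are
#' binomial mixtures of the two ancestral allele frequencies under
#' within-ancestry Hardy-Weinberg equilibrium.
#'
#' @param mu admixture proportion (high-risk ancestry), scalar or per
#'   subject; must lie in (0, 1).
#' @param g generations since admixture (> 0), default 6.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(mu = 0.8, g = 6) {
  stopifnot(all(mu > 0 & mu < 1), g > 0)
  structure(list(mu = mu, g = g), class = "hmm_params")
}

#' Ancestral allele frequencies
#'
#' @param f1 reference-allele frequency at each AIM in the high-risk
#'   ancestral population.
#' @param f2 same in the other ancestral population.
#' @param clamp frequencies are clamped to [clamp, 1 - clamp] to avoid
#'   zero-probability emissions.
#' @return list of class `ancestral_freqs`.
#' @export
ancestral_freqs <- function(f1, f2, clamp = 1e-3) {
  stopifnot(length(f1) == length(f2))
  structure(list(f1 = pmin(pmax(f1, clamp), 1 - clamp),
                 f2 = pmin(pmax(f2, clamp), 1 - clamp)),
            class = "ancestral_freqs")
}

# emission matrix for one subject: J x 3, P(genotype g_j | dosage s)
# s high-risk haplotypes carry Bern(f1) alleles, 2-s carry Bern(f2)
emission_probs <- function(genos, freqs) {
  J <- length(genos)
  E <- matrix(0, J, 3)
  f1 <- freqs$f1
  f2 <- freqs$f2
  for (s in 0:2) {
    # allele count = sum of s Bern(f1) and (2 - s) Bern(f2)
    p0 <- if (s >= 1) f1 else f2          # first haplotype freq
    p1 <- if (s == 2) f1 else f2          # second haplotype freq
    pr_g <- cbind((1 - p0) * (1 - p1),
                  p0 * (1 - p1) + (1 - p0) * p1,
                  p0 * p1)
    E[, s + 1] <- pr_g[cbind(seq_len(J), genos + 1L)]
  }
  E
}

# dosage transition matrices along the chain: list over intervals of 3 x 3
# matrices; haploid switch prob r, post-switch ancestry Bern(mu)
dosage_transitions <- function(d_cM, g, mu) {
  r <- 1 - exp(-g * d_cM / 100)
  a <- (1 - r) + r * mu   # P(high -> high) per haplotype
  b <- r * mu             # P(low  -> high) per haplotype
  lapply(seq_along(r), function(i) {
    ai <- a[i]; bi <- b[i]
    rbind(
      c((1 - bi)^2, 2 * bi * (1 - bi), bi^2),                       # from s = 0
      c((1 - ai) * (1 - bi), ai * (1 - bi) + (1 - ai) * bi, ai * bi), # s = 1
      c((1 - ai)^2, 2 * ai * (1 - ai), ai^2)                         # s = 2
    )
  })
}

log_hwe_prior <- function(mu) {
  log(c((1 - mu)^2, 2 * mu * (1 - mu), mu^2))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# forward pass in log space for one subject; returns J x 3 log-alpha and loglik
hmm_forward <- function(logE, logT, logpi) {
  J <- nrow(logE)
  la <- matrix(-Inf, J, 3)
  la[1, ] <- logpi + logE[1, ]
  if (J > 1) {
    for (j in 2:J) {
      lt <- logT[[j - 1]]
      for (s in 1:3) {
        la[j, s] <- logsumexp(la[j - 1, ] + lt[, s]) + logE[j, s]
      }
    }
  }
  list(log_alpha = la, loglik = logsumexp(la[J, ]))
}

#' Posterior local-ancestry dosage probabilities
#'
#' Forward-backward in log space over the dosage chain, per subject.
#'
#' @param genos integer matrix (subjects x AIMs) of reference-allele dosages
#'   0/1/2.
#' @param freqs an [ancestral_freqs()] object aligned with the AIM columns.
#' @param map_cM increasing genetic positions of the AIMs.
#' @param params an [hmm_params()] object.
#' @return array I x J x 3 of posterior probabilities P(dosage = 0/1/2),
#'   with attribute `loglik` (per-subject log-likelihood vector).
#' @export
hmm_posteriors <- function(genos, freqs, map_cM, params = hmm_params()) {
  genos <- as.matrix(genos)
  I <- nrow(genos)
  J <- ncol(genos)
  stopifnot(length(map_cM) == J, length(freqs$f1) == J)
  if (is.unsorted(map_cM)) stop("map_cM must be non-decreasing")
  mu <- rep_len(params$mu, I)
  post <- array(NA_real_, c(I, J, 3))
  ll <- numeric(I)
  for (i in seq_len(I)) {
    logE <- log(emission_probs(genos[i, ], freqs))
    Tm <- dosage_transitions(diff(map_cM), params$g, mu[i])
    logT <- lapply(Tm, log)
    logpi <- log_hwe_prior(mu[i])
    fw <- hmm_forward(logE, logT, logpi)
    lb <- matrix(0, J, 3)  # log-beta
    if (J > 1) {
      for (j in (J - 1):1) {
        lt <- logT[[j]]
        for (s in 1:3) {
          lb[j, s] <- logsumexp(lt[s, ] + logE[j + 1, ] + lb[j + 1, ])
        }
      }
    }
    lp <- fw$log_alpha + lb
    lp <- lp - apply(lp, 1, logsumexp)
    post[i, , ] <- exp(lp)
    ll[i] <- fw$loglik
  }
  attr(post, "loglik") <- ll
  post
}

#' Sample local-ancestry imputations by joint backward sampling
#'
#' Draws whole dosage paths from the posterior of the hidden chain (forward
#' filtering, backward sampling), so the draws preserve the
#' along-chromosome admixture linkage disequilibrium rather than being
#' independent per-locus draws.
#'
#' @inheritParams hmm_posteriors
#' @param M number of imputation draws.
#' @param seed optional integer seed.
#' @param loci optional locus metadata passed to the resulting panels.
#' @return list of class `imputation_set`: `draws` (list of M I x J dosage
#'   matrices), `posterior_mean` (I x J).
#' @export
sample_imputations <- function(genos, freqs, map_cM, params = hmm_params(),
                               M = 10L, seed = NULL) {
  stopifnot(M >= 1)
  if (!is.null(seed)) set.seed(seed)
  genos <- as.matrix(genos)
  I <- nrow(genos)
  J <- ncol(genos)
  mu <- rep_len(params$mu, I)
  draws <- replicate(M, matrix(0L, I, J), simplify = FALSE)
  pmean <- matrix(0, I, J)
  for (i in seq_len(I)) {
    logE <- log(emission_probs(genos[i, ], freqs))
    Tm <- dosage_transitions(diff(map_cM), params$g, mu[i])
    logT <- lapply(Tm, log)
    fw <- hmm_forward(logE, logT, log_hwe_prior(mu[i]))
    la <- fw$log_alpha
    for (m in seq_len(M)) {
      s <- integer(J)
      pr <- exp(la[J, ] - logsumexp(la[J, ]))
      s[J] <- sample.int(3L, 1L, prob = pr)
      if (J > 1) {
        for (j in (J - 1):1) {
          lw <- la[j, ] + logT[[j]][, s[j + 1]]
          pr <- exp(lw - logsumexp(lw))
          s[j] <- sample.int(3L, 1L, prob = pr)
        }
      }
      draws[[m]][i, ] <- s - 1L
    }
  }
  for (m in seq_len(M)) pmean <- pmean + draws[[m]] / M
  structure(list(draws = draws, posterior_mean = pmean),
            class = "imputation_set")
}

#' Per-subject global ancestry estimate
#'
#' Maximum-likelihood admixture proportion under the locus-independence
#' approximation (each AIM contributes a Hardy-Weinberg mixture likelihood),
#' optimized per subject on (0.001, 0.999).
#'
#' @inheritParams hmm_posteriors
#' @return numeric vector of mu-hat per subject.
#' @export
estimate_global_ancestry <- function(genos, freqs) {
  genos <- as.matrix(genos)
  if (ncol(genos) < 10) stop("need at least 10 AIMs")
  if (max(abs(freqs$f1 - freqs$f2)) < 1e-6) {
    stop("panel is uninformative: ancestral frequencies coincide at every AIM")
  }
  vapply(seq_len(nrow(genos)), function(i) {
    E <- emission_probs(genos[i, ], freqs)
    nll <- function(mu) -sum(log(E %*% exp(log_hwe_prior(mu))))
    stats::optimize(nll, c(0.001, 0.999))$minimum
  }, 0)
}

#' Simulate AIM genotypes given true local-ancestry dosages
#'
#' Each of the s high-risk haplotypes carries a Bernoulli(f1) allele and the
#' 2 - s others Bernoulli(f2); used to exercise the HMM end to end.
#'
#' @param S true dosage matrix (subjects x loci).
#' @param freqs an [ancestral_freqs()].
#' @param seed optional integer seed.
#' @return integer genotype matrix of reference-allele dosages.
#' @export
sim_aim_genotypes <- function(S, freqs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- as.matrix(S)
  I <- nrow(S)
  J <- ncol(S)
  F1 <- matrix(freqs$f1, I, J, byrow = TRUE)
  F2 <- matrix(freqs$f2, I, J, byrow = TRUE)
  # allele from haplotype 1: high-risk when S >= 1; from haplotype 2: when S == 2
  a1 <- stats::rbinom(I * J, 1L, ifelse(S >= 1, F1, F2))
  a2 <- stats::rbinom(I * J, 1L, ifelse(S == 2, F1, F2))
  matrix(a1 + a2, I, J, dimnames = dimnames(S))
}
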