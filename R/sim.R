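#' MAP ancestry-proportion estimates under Hardy-Weinberg equilibrium
#'
#' Posterior-mode estimate of the high-risk allele (ancestry) frequency under
#' a Beta(a, b) prior: (count + a - 1) / (2I + a + b - 2). The default
#' uniform prior reduces to the sample frequency.
#'
#' @param counts per-locus counts of high-risk allele copies (0..2I).
#' @param I number of subjects.
#' @param prior_a,prior_b Beta prior parameters.
#' @return vector of frequency estimates.
#' @export
map_allele_freq <- function(counts, I, prior_a = 1, prior_b = 1) {
  if (any(counts < 0) || any(counts > 2 * I)) stop("counts must lie in [0, 2I]")
  if ((prior_a < 1 && any(counts == 0)) || (prior_b < 1 && any(counts == 2 * I))) {
    stop("Beta prior with a or b < 1 has no interior mode at a boundary count")
  }
  (counts + prior_a - 1) / (2 * I + prior_a + prior_b - 2)
}

#' Simulate a linkage-equilibrium panel under Hardy-Weinberg equilibrium
#'
#' Dosages at each locus are Binomial(2, p_a) draws (two independent allele
#' copies), independent across loci: the null configuration in which any
#' identified locus is a genuine false positive.
#'
#' @param p_a vector of per-locus high-risk ancestry proportions.
#' @param I number of subjects.
#' @param seed optional integer seed.
#' @return an [ancestry_panel].
#' @export
sim_hwe_panel <- function(p_a, I, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(p_a < 0 | p_a > 1)) stop("p_a must lie in [0, 1]")
  J <- length(p_a)
  S <- matrix(stats::rbinom(I * J, 2L, rep(p_a, each = I)), I, J)
  loci <- data.frame(locus_id = sprintf("l%04d", seq_len(J)), chrom = 1L,
                     pos_bp = seq_len(J) * 1000000L,
                     cM = as.numeric(seq_len(J)), p_a = p_a,
                     stringsAsFactors = FALSE)
  colnames(S) <- loci$locus_id
  ancestry_panel(S, loci)
}

#' Simulate a correlated dosage pair via a latent-Gaussian threshold model
#'
#' Each subject carries a standard bivariate normal latent pair with
#' correlation rho; dosages are cut at C0 = qnorm((1-p_a)^2) and
#' C1 = qnorm(1 - p_a^2), so both marginals are exactly Hardy-Weinberg while
#' the latent correlation induces admixture linkage disequilibrium between
#' the two loci.
#'
#' @param p_a ancestry proportion shared by the two loci.
#' @param rho latent correlation in [-1, 1].
#' @param I number of subjects.
#' @param seed optional integer seed.
#' @return I x 2 integer matrix of dosages.
#' @export
sim_correlated_pair <- function(p_a, rho, I, seed = NULL) {
  stopifnot(rho >= -1, rho <= 1, p_a >= 0, p_a <= 1)
  if (!is.null(seed)) set.seed(seed)
  C0 <- stats::qnorm((1 - p_a)^2)
  C1 <- stats::qnorm(1 - p_a^2)
  Z1 <- stats::rnorm(I)
  Z2 <- rho * Z1 + sqrt(1 - rho^2) * stats::rnorm(I)
  cut_one <- function(z) ifelse(z <= C0, 0L, ifelse(z > C1, 2L, 1L))
  cbind(S1 = cut_one(Z1), S2 = cut_one(Z2))
}

#' Simulate an admixed chromosome with Markov ancestry blocks
#'
#' Per haplotype, ancestry follows a two-state Markov process along the
#' genetic map: between adjacent loci at map distance d cM the ancestry is
#' redrawn from the stationary law with probability 1 - exp(-g d / 100)
#' (g = generations since admixture) and copied otherwise. Dosage is the sum
#' of two independent haplotypes, so the dosage correlation between loci at
#' distance d is exp(-g d / 100) when the ancestry proportion is locally
#' constant, decaying monotonically with distance.
#'
#' @param loci_cM increasing vector of genetic positions (cM).
#' @param p_a per-locus ancestry proportion (scalar or J-vector); the
#'   stationary law of the redraws.
#' @param g generations since admixture (larger g = faster LD decay).
#' @param I number of subjects.
#' @param seed optional integer seed.
#' @param chrom chromosome label for the metadata.
#' @return an [ancestry_panel].
#' @export
sim_chromosome <- function(loci_cM, p_a, g, I, seed = NULL, chrom = 1L) {
  if (is.unsorted(loci_cM, strictly = FALSE)) stop("loci_cM must be non-decreasing")
  if (!is.null(seed)) set.seed(seed)
  J <- length(loci_cM)
  p_a <- rep_len(p_a, J)
  r <- 1 - exp(-g * diff(loci_cM) / 100)
  hap <- function() {
    H <- matrix(0L, I, J)
    H[, 1] <- stats::rbinom(I, 1L, p_a[1])
    for (j in 2:J) {
      redraw <- stats::runif(I) < r[j - 1]
      H[, j] <- ifelse(redraw, stats::rbinom(I, 1L, p_a[j]), H[, j - 1])
    }
    H
  }
  S <- hap() + hap()
  loci <- data.frame(locus_id = sprintf("c%s_l%03d", chrom, seq_len(J)),
                     chrom = as.integer(chrom),
                     pos_bp = as.integer(round(loci_cM * 1e6)) + 1L,
                     cM = loci_cM, p_a = p_a, stringsAsFactors = FALSE)
  colnames(S) <- loci$locus_id
  ancestry_panel(S, loci)
}

#' Simulation design
#'
#' Full specification of a simulation experiment. Three kinds are built in:
#' `null` (linkage-equilibrium panel, trait independent of all loci),
#' `single_locus` (one causal locus with effect beta = c * p_a), and
#' `two_locus` (artificial chromosome of two pieces with a causal locus
#' mid-piece and Markov admixture LD).
#'
#' @param kind one of "null", "single_locus", "two_locus".
#' @param family trait family ("gaussian" or "binomial").
#' @param I subjects per replicate.
#' @param J loci (null / single-locus designs).
#' @param c_mult effect-size multiplier c (beta_j = c * p_a_j at causal
#'   loci). Defaults to the study conditions of each design: 0 (null),
#'   0.4 gaussian / 0.8 binomial (single-locus, the top of the studied
#'   ranges), 0.7 gaussian / 0.35 binomial (two-locus).
#' @param alpha covariate effect (0 = absent, 1 = present).
#' @param n_trait_sets trait sets simulated per panel (null design).
#' @param n_replicates number of replicates.
#' @param p_a_range range for null/background ancestry proportions.
#' @param causal_pa_range range the causal-locus ancestry proportion is drawn
#'   from (the top-20% band of the reference panel).
#' @param pieces_Mb lengths of the two chromosome pieces (two-locus design);
#'   the genetic map is 1 cM/Mb.
#' @param loci_per_piece loci per piece, equally spaced (causal mid-piece).
#' @param reg_target_loci number of flanking loci whose dosage correlation
#'   with the causal locus should exceed `r_threshold` on each piece; the
#'   Markov generation parameter g of each piece is calibrated in closed form
#'   to this (g = 100 log(1/r) / d*, d* the half-window width).
#' @param r_threshold admixture-LD correlation threshold defining the
#'   flanking regions (default 0.12).
#' @return list of class `sim_design`.
#' @export
sim_design <- function(kind = c("null", "single_locus", "two_locus"),
                       family = c("gaussian", "binomial"),
                       I = 1000L, J = 1000L, c_mult = NULL, alpha = 0,
                       n_trait_sets = 1L, n_replicates = 100L,
                       p_a_range = c(0.70, 0.90),
                       causal_pa_range = c(0.8321, 0.8817),
                       pieces_Mb = c(139.50, 114.88),
                       loci_per_piece = 51L,
                       reg_target_loci = c(42L, 35L),
                       r_threshold = 0.12) {
  kind <- match.arg(kind)
  family <- match.arg(family)
  if (is.null(c_mult)) {
    # study defaults: single-locus designs use the top of the printed c
    # ranges (continuous 0.2-0.4, binary 0.4-0.8); the two-locus design
    # uses the printed pairings (0.7 continuous, 0.35 binary)
    c_mult <- switch(kind,
                     null = 0,
                     single_locus = if (family == "gaussian") 0.4 else 0.8,
                     two_locus = if (family == "gaussian") 0.7 else 0.35)
  }
  if (kind == "null") n_trait_sets <- max(n_trait_sets, 1L)
  structure(list(kind = kind, family = family, I = as.integer(I),
                 J = as.integer(J), c_mult = c_mult, alpha = alpha,
                 n_trait_sets = as.integer(n_trait_sets),
                 n_replicates = as.integer(n_replicates),
                 p_a_range = p_a_range, causal_pa_range = causal_pa_range,
                 pieces_Mb = pieces_Mb,
                 loci_per_piece = as.integer(loci_per_piece),
                 reg_target_loci = as.integer(reg_target_loci),
                 r_threshold = r_threshold),
            class = "sim_design")
}

# closed-form Markov calibration: exp(-g d*/100) = r at the half-window edge
calibrate_g <- function(spacing_cM, target_loci, r_threshold = 0.12) {
  d_star <- (target_loci + 1) / 2 * spacing_cM
  100 * log(1 / r_threshold) / d_star
}

#' Build one replicate panel for a design
#'
#' @param design a [sim_design()].
#' @param seed integer seed for this replicate.
#' @return an [ancestry_panel]; for the two-locus design the causal locus ids
#'   are attached as attribute `causal`.
#' @export
sim_panel <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (design$kind %in% c("null", "single_locus")) {
    p_a <- stats::runif(design$J, design$p_a_range[1], design$p_a_range[2])
    causal <- integer(0)
    if (design$kind == "single_locus") {
      causal <- sample.int(design$J, 1L)
      p_a[causal] <- stats::runif(1, design$causal_pa_range[1],
                                  design$causal_pa_range[2])
    }
    panel <- sim_hwe_panel(p_a, design$I)
    attr(panel, "causal") <- panel$loci$locus_id[causal]
    panel
  } else {
    Jp <- design$loci_per_piece
    mid <- (Jp + 1L) %/% 2L
    pieces <- vector("list", 2)
    for (k in 1:2) {
      spacing <- design$pieces_Mb[k] / (Jp - 1)        # 1 cM/Mb map
      g <- calibrate_g(spacing, design$reg_target_loci[k], design$r_threshold)
      p_piece <- stats::runif(1, design$causal_pa_range[1],
                              design$causal_pa_range[2])
      pieces[[k]] <- sim_chromosome(seq(0, by = spacing, length.out = Jp),
                                    p_piece, g, design$I, chrom = k)
    }
    S <- cbind(pieces[[1]]$S, pieces[[2]]$S)
    loci <- rbind(pieces[[1]]$loci, pieces[[2]]$loci)
    panel <- ancestry_panel(S, loci)
    attr(panel, "causal") <- c(pieces[[1]]$loci$locus_id[mid],
                               pieces[[2]]$loci$locus_id[mid])
    panel
  }
}

#' Simulate traits for a panel
#'
#' Continuous traits: y = alpha E + sum_j beta_j S_j + eps with E and eps
#' standard normal; binary traits: logit P(y = 1) = alpha E + sum_j beta_j
#' S_j. Effects are beta_j = c * p_a_j at the causal loci (uncentered
#' dosages, no intercept, exactly as the generating models are written).
#'
#' @param panel an [ancestry_panel].
#' @param design a [sim_design()].
#' @param causal character vector of causal locus ids (default: the panel's
#'   `causal` attribute).
#' @param seed optional integer seed.
#' @return list with `y`, `E` (NULL when alpha = 0), `beta` (named effect
#'   vector at causal loci).
#' @export
sim_traits <- function(panel, design, causal = attr(panel, "causal"),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- panel$n_subjects
  idx <- match(causal, panel$loci$locus_id)
  if (anyNA(idx)) stop("causal loci not on panel")
  beta <- design$c_mult * panel$loci$p_a[idx]
  lin <- if (length(idx)) drop(panel$S[, idx, drop = FALSE] %*% beta) else rep(0, I)
  E <- NULL
  if (design$alpha != 0) {
    E <- matrix(stats::rnorm(I), I, 1, dimnames = list(NULL, "E1"))
    lin <- lin + design$alpha * drop(E)
  }
  y <- if (design$family == "gaussian") {
    lin + stats::rnorm(I)
  } else {
    stats::rbinom(I, 1L, stats::plogis(lin))
  }
  list(y = y, E = E, beta = stats::setNames(beta, causal))
}

#' Dichotomize a continuous trait at its extremes
#'
#' Labels the top q fraction as cases (1) and the bottom q fraction as
#' controls (0); the middle is excluded via the inclusion mask. Ties are
#' broken by stable sort order.
#'
#' @param y continuous trait.
#' @param q tail fraction in (0, 0.5).
#' @return list with `labels` (0/1/NA), `mask` (TRUE for retained subjects).
#' @export
dichotomize_extremes <- function(y, q = 0.2) {
  stopifnot(q > 0, q < 0.5)
  n <- length(y)
  if (max(y) == min(y)) stop("constant trait cannot be dichotomized")
  nq <- floor(q * n)
  ord <- order(y)  # stable
  labels <- rep(NA_integer_, n)
  labels[ord[seq_len(nq)]] <- 0L
  labels[ord[seq(n - nq + 1, n)]] <- 1L
  list(labels = labels, mask = !is.na(labels))
}

#' Classify loci into causal flanking regions by realized admixture LD
#'
#' Given the two causal loci, labels every other locus REG1 or REG2 when its
#' realized dosage correlation with causal Locus 1 or Locus 2 exceeds the
#' threshold (ties to the stronger correlation), and REG3 otherwise.
#'
#' @param panel an [ancestry_panel].
#' @param causal character vector of exactly two causal locus ids.
#' @param r_threshold correlation threshold (default 0.12).
#' @return list of class `region_labels`: `labels` (factor per locus with
#'   levels LOCUS1, LOCUS2, REG1, REG2, REG3), `r_threshold`.
#' @export
classify_regions <- function(panel, causal, r_threshold = 0.12) {
  if (length(causal) != 2 || causal[1] == causal[2]) {
    stop("exactly two distinct causal loci required")
  }
  idx <- match(causal, panel$loci$locus_id)
  if (anyNA(idx)) stop("causal loci not on panel")
  r1 <- suppressWarnings(as.numeric(stats::cor(panel$S[, idx[1]], panel$S)))
  r2 <- suppressWarnings(as.numeric(stats::cor(panel$S[, idx[2]], panel$S)))
  lab <- rep("REG3", panel$n_loci)
  in1 <- !is.na(r1) & r1 > r_threshold
  in2 <- !is.na(r2) & r2 > r_threshold
  lab[in1] <- "REG1"
  lab[in2 & (!in1 | abs(r2) > abs(r1))] <- "REG2"
  lab[idx[1]] <- "LOCUS1"
  lab[idx[2]] <- "LOCUS2"
  structure(list(labels = factor(lab, c("LOCUS1", "LOCUS2", "REG1", "REG2", "REG3")),
                 r_threshold = r_threshold),
            class = "region_labels")
}
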