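---
title: "Generalized admixture mapping with QNM-prior Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized admixture mapping with QNM-prior Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gleam)
```

## The problem

In a recently admixed population (e.g. African Americans), each chromosome
is a mosaic of ancestry blocks. When a trait differs in prevalence between
the ancestral populations, loci carrying risk variants sit in blocks that
are enriched for the high-risk ancestry, so regressing the trait on *local
ancestry* — the number of allele copies $S_{ij} \in \{0,1,2\}$ subject $i$
inherits from the high-risk population at marker $j$ — localizes
susceptibility regions with far fewer markers than a SNP association scan.
`gleam` implements this as a generalized linear model with a Bayes-factor
test, handling continuous, binary and count traits, covariate adjustment,
multi-locus models, and averaging over multiply-imputed ancestries.

## Model and Bayes factor

For $p$ loci considered jointly, with centered ancestry dosages $S_i$ and
covariates $E_i$:

$$y_i = \beta_0 + \beta' S_i + \alpha' E_i + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2)$$

for continuous traits, and the logistic analogue
$\mathrm{logit}\,P(y_i = 1) = \beta_0 + \beta' S_i + \alpha' E_i$ for
binary traits (Poisson regression for counts). Evidence for
$H_1: \beta \ne 0$ against $H_0: \beta = 0$ is a Bayes factor whose prior
under $H_1$ is the *quadratic normal moment* (QNM) prior

$$f_{\mathrm{QNM}}(\beta) =
  \frac{\beta' \Sigma^{-1} \beta}{I \tau \sigma^2 p}\,
  N_p(\beta;\, 0,\, I \tau \sigma^2 \Sigma),$$

with $\sigma^2 \Sigma$ the covariance of the (iteratively reweighted)
least-squares estimator $\hat\beta$ and $\tau$ a dispersion multiplier.
Two properties make this non-local prior attractive here. First, it
vanishes at $\beta = 0$, so evidence accumulates for a true null as well as
for a true alternative — ordinary local priors cannot do both. Second,
scaling by $\Sigma$ encodes admixture-specific structure: loci with higher
high-risk ancestry proportion get larger prior effect scale, and correlated
loci (admixture LD) get correlated prior effects.

With this prior the Bayes factor is closed-form:

$$T = \frac{I\hat\tau}{1 + I\hat\tau}\,
      \frac{\hat\beta' \hat\Sigma^{-1} \hat\beta}{\hat\sigma^2},
\qquad
BF = \frac{p + T}{p}\,(1 + I\hat\tau)^{-(p/2+1)}\, e^{T/2}.$$

The printed form of this expression is ambiguous about the grouping of the
normalizing terms; the grouping used here was derived as the unique reading
that equals the exact gaussian marginal-likelihood ratio (the posterior-mean
identity $E[\beta'\Sigma^{-1}\beta \mid \hat\beta]$ under the conjugate
update gives $(p+T)/(p(1+I\tau))$, and the normal-ratio term contributes
$(1+I\tau)^{-p/2} e^{T/2}$). `bf_numeric_oracle()` verifies it by direct
quadrature of the profile likelihood against the prior: agreement is at
machine precision for gaussian traits ($p = 1, 2$) and within the expected
Laplace error (a few percent) for binomial traits, where the closed form is
an asymptotic-normal plug-in with $\hat\sigma^2 = 1$ and $\hat\Sigma$ the
inverse observed information.

### Empirical-Bayes dispersion $\hat\tau$

$\tau$ is estimated from the data by maximizing marginal evidence on
$[0, \tau_{max}]$ with $\tau_{max} = 10/I$; the boundary $\hat\tau = 0$
(BF $= 1$) is the maximizer whenever the Wald statistic does not exceed
$p$. Two modes are provided:

* `per_locus` (default): each locus (or stage-2 subset) maximizes its own
  BF. The stationary condition reduces to a quadratic in
  $I\tau/(1+I\tau)$, solved in closed form.
* `genomewide`: one shared $\hat\tau$ maximizes the summed log BF across
  loci, re-used unchanged in stage 2.

The default is `per_locus` because it is the mode consistent with the
method's published operating characteristics: at the $\log_{10} BF > 2$
threshold it implies a per-locus null selection rate of
$P(\chi^2_1 > 11.7) \approx 6\times10^{-4}$ — the "conservative"
few-in-ten-thousand null behavior the procedure is known for — whereas a
genome-wide pooled $\hat\tau$ collapses to the $\hat\tau = 0$ boundary
under a pure null scan and selects nothing at all, which makes its null
error rate degenerate rather than conservative. Pooling remains available
and is sensible when many loci carry small effects.

## The two-stage procedure

1. **Stage 1** (`stage1_scan()`): single-locus GLM fits ($p = 1$) for each
   of the $J$ markers, covariates adjusted by joint fitting (exact in a
   GLM, unlike residualization). Loci with $\log_{10} BF > \delta$
   (default $\delta = 2$) are selected. Constant-dosage loci and separated
   logistic fits are reported as `skipped`, never silently dropped.
2. **Stage 2** (`stage2_joint()`): every non-empty subset of the selected
   loci (up to `max_subset_size`) is fit jointly and scored with the
   $p = |{\rm subset}|$ Bayes factor. Subsets are ranked by
   $\log_{10} BF$, ties broken toward smaller subsets then lexicographic
   order.
3. **Identification** (`identify_loci()`): the default rule reports the
   members of the top-ranked subset passing $\delta$; with at most one
   selected locus stage 2 is unnecessary and the selection stands.

Stage 2 exists because admixture LD extends over tens of centimorgans: a
marginal scan flags the high-LD neighborhood of a causal locus wholesale,
and the joint model lets the causal loci explain away their correlated
flankers. Subset enumeration is capped (`max_selected = 15`,
`max_subset_size = 10`); exceeding the cap is an error by default, while
the simulation harness truncates to the top selections so one extreme
replicate cannot abort an experiment.

When local ancestries are imputed rather than observed, every Bayes factor
is computed per imputation draw and combined by an (equal-weight)
arithmetic mean on the BF scale before thresholding — posterior draws are
exchangeable, so equal weights are the natural choice absent stated
weights.

## What the simulation engine emulates

`sim_design()` encodes three experiment families; their defaults are the
study conditions, not tuning knobs.

* **Null**: $J = 1000$ linkage-equilibrium loci, dosages
  Binomial$(2, p_a)$ under Hardy–Weinberg equilibrium with
  $p_a \sim U(0.70, 0.90)$; 10 trait sets per panel;
  $y_i = \alpha E_i + \varepsilon_i$ with $E_i, \varepsilon_i \sim N(0,1)$
  and $\alpha \in \{0, 1\}$.
* **Single locus**: one causal locus with
  $\beta = c \times p_a$ and $p_a \sim U(0.8321, 0.8817)$ (the top-20%
  ancestry band of a 1296-AIM African-American reference panel);
  $c \in \{0.2,\dots,0.4\}$ for continuous traits (largest effect
  $0.4 \times 0.8817 = 0.3527$) and $\{0.4,\dots,0.8\}$ for binary.
* **Two locus**: an artificial chromosome of two pieces (139.50 and
  114.88 Mb at 1 cM/Mb, 51 equally spaced loci each, causal locus
  mid-piece). Per haplotype, ancestry is a two-state Markov chain with
  switch probability $1 - e^{-g d / 100}$ per $d$ cM, so dosage
  correlation decays as $e^{-g d / 100}$. $g$ is calibrated in closed form
  so that 42 and 35 flanking loci exceed dosage correlation $0.12$ with
  their causal locus ($g_1 \approx 3.53$, $g_2 \approx 5.13$) — the
  printed definition of the high-LD regions REG1/REG2; the remainder is
  REG3. Effects use $c = 0.7$ (continuous) and $c = 0.35$ (binary), as
  printed, although the binary pairing is internally surprising (it gives
  marginal Wald $z \approx 2$ at the causal loci, hence little power) —
  it is reproduced rather than corrected. Panels and traits are
  regenerated per replicate with seeds derived from the master seed.

A latent-Gaussian threshold construction (`sim_correlated_pair()`) is also
provided: bivariate normal latents cut at $\Phi^{-1}((1-p_a)^2)$ and
$\Phi^{-1}(1-p_a^2)$ give exactly Hardy–Weinberg marginals with tunable
admixture LD; it is the construction behind the correlated-prior
illustrations and several tests.

### What the generator does not emulate

The reference study resampled *empirical* local ancestries; this package
substitutes the Markov process above. The substitution preserves the
stated statistical features (HWE marginals, the 42/35-locus region
definitions, LD decay with distance) but not the empirical LD *profile*:
an exponential decay calibrated to span 42 loci above $r = 0.12$ makes the
immediate neighbors of a causal locus very highly correlated
($r \approx 0.9$), almost certainly more than in the empirical panel
(where inter-individual variation in global ancestry contributes a flat,
low-level correlation). Consequences observed in this package's own
experiments: with strong continuous effects the stage-1 scan flags wide
flanking windows (REG1 rates near 0.5 where the study reports 0.021), and
cross-validated lasso false selection in the remainder region runs at
0.06–0.08 against the reported 0.023. The binary-trait region rates and
the power/selection frequencies of the causal loci themselves are
insensitive to this and reproduce the reported values. Passing tests
therefore validate the method's operating characteristics under the
synthetic LD model, not the empirical LD profile of any particular panel.

## Local-ancestry HMM

The HMM the reference method defines in unavailable appendices is replaced
by a conventional two-ancestry model, documented as such: hidden dosage
chain with per-haplotype switch probability $1 - e^{-gd/100}$ mixed by the
subject's admixture proportion $\mu$ (estimated per subject by 1-D maximum
likelihood under locus independence), emissions binomial mixtures of the
ancestral allele frequencies (clamped to $[10^{-3}, 1-10^{-3}]$ to avoid
zero-probability observations) under within-ancestry HWE. Forward–backward
runs in log space (finite likelihood verified at $J = 10^4$); imputation
draws are *joint* backward samples of whole paths, preserving
along-chromosome ancestry correlation, which is what makes multi-locus
Bayes factors on imputed data meaningful. Exactness is tested against
brute-force enumeration over all $3^J$ paths for short chains. All
reproduction experiments use known simulated ancestries, so this
substitution does not enter them.

## Numerical choices

* Gaussian dispersion plugs in the ML estimate RSS$/I$ (a `reml` option
  gives RSS$/(I-k)$): the BF derives from marginal likelihoods, where the
  ML scale is the natural plug-in; $\hat\sigma^2$ comes from the
  alternative-model fit (a `null` option exists).
* IRLS via `stats::glm.fit` (deviance tolerance $10^{-12}$, 100
  iterations) with a post-hoc score check $\|X'(y-\hat\mu)\|_\infty <
  10^{-6}$; logistic separation (any $|\hat\eta| > 30$) raises a typed
  error and the locus is recorded as skipped.
* Perfect fits guard $\hat\sigma^2$ at $10^{-12}$.
* The quadrature oracle integrates in prior-standardized coordinates over
  a union of prior-scale and likelihood-scale intervals, so it stays exact
  when $\tau \to 0$ separates the two scales.
* Penalized comparators use `glmnet` with unpenalized covariates,
  10-fold CV at `lambda.min`, elastic-net mixing fixed at 0.5 (the study
  does not state one), standardization on.
* Experiment problem sizes used by the package's own checks: 100
  replicates for the two-locus designs, 30 panels × 10 trait sets ×
  1000 loci × 1000 subjects for the null design — large enough that the
  rare-event null median (a few $10^{-4}$) is measurable while a full run
  stays in the minutes range.

## Known limitations

Two-ancestry populations only; no ancestry-by-covariate interactions; no
recombination-hotspot inference; the identification rule reports subset
membership, not effect estimates with model-averaged uncertainty. The
synthetic LD caveat above is the main one to keep in mind when comparing
numbers against studies built on empirical ancestry panels.
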