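---
title: "Variance-component heritability and QTL linkage for urine arsenic composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component heritability and QTL linkage for urine arsenic composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

Ingested inorganic arsenic (iAs) is methylated stepwise to monomethylarsonate
(MMA) and dimethylarsinate (DMA), and the three species are excreted in
urine. The *relative* composition — %iAs, %MMA, %DMA of the summed species —
measures a person's methylation capacity, which varies between people and
aggregates in families. `arsqtl` implements the full quantitative-genetic
analysis of such compositions on extended pedigrees:

1. phenotype preparation (detection-limit filtering, percentages, a
   two-stage trait transformation),
2. heritability estimation by variance-component maximum likelihood,
3. exact multipoint identity-by-descent (IBD) computation from short tandem
   repeat (STR) genotypes,
4. a genome-wide variance-component QTL linkage scan with empirically
   calibrated LOD scores, and
5. a synthetic-data generator whose defaults mirror the family-study
   conditions the package targets.

## The variance-component model

For a trait vector $y$ on $n$ pedigree members the model is multivariate
normal,

$$ y \sim \mathcal{N}\!\left(X\beta,\; \Omega\right), \qquad
   \Omega = \sigma^2_g\, 2\Phi \;+\; \sigma^2_q\, \hat\Pi(x) \;+\;
            \sigma^2_c\, H \;+\; \sigma^2_e\, I, $$

where $\Phi$ is the kinship matrix computed by the standard recursion
($\phi_{ij} = \tfrac12[\phi_{f(i)j} + \phi_{m(i)j}]$ over a parent-first
ordering, $\phi_{ii} = \tfrac12(1 + \phi_{f(i)m(i)})$), $\hat\Pi(x)$ is the
matrix of expected proportions of alleles shared identical by descent at
genomic position $x$, $H$ is an optional household indicator, and $I$ the
residual identity. Heritability is $h^2 = \sigma^2_g / \sum_k \sigma^2_k$.

Fixed effects are profiled out by generalised least squares inside the
likelihood, which is equivalent to joint maximisation. Because families are
independent, $\Omega$ is block diagonal; `vc_model()` finds the blocks once
(connected components of the combined component sparsity pattern) and all
likelihood evaluations factor per family, so cost grows linearly in the
number of families.

### Numerical choices

* **Optimisation on the variance scale.** `fit_ml()` maximises over
  $\sigma^2_k \ge 0$ directly with box-constrained L-BFGS-B from three
  deterministic starts (equal split, 90/10, 10/90 of the phenotypic
  variance), rather than over log-variances. Log-parameterisation cannot
  represent the boundary $\sigma^2 = 0$, which this application *needs*:
  the null hypothesis of every test sits on that boundary. Components that
  converge below `boundary_tol * var(y)` are pinned to exactly zero in a
  profile refit, so null fits are exact rather than "small".
* **Convergence tolerance.** The optimiser stops at a relative
  log-likelihood change of about $10^{-8}$ (`factr = 4.5e7`). Likelihood
  ratios built from two such fits are stable to roughly $10^{-6}$, far
  below any decision threshold used here (the smallest is the 2-decimal
  LOD rounding).
* **Standard errors** come from the numerically observed information
  (central-difference Hessian) with a delta-method transformation to
  $h^2$; they are reported as `NA` when any component sits on the
  boundary, where the quadratic approximation is invalid.

### Boundary likelihood-ratio test

Testing $\sigma^2_g = 0$ (or $\sigma^2_q = 0$) places the parameter on the
boundary of its space, so the LRT is not $\chi^2_1$: its null distribution
is the ½:½ mixture of a point mass at zero and $\chi^2_1$.
`heritability_test()` therefore reports $p = \tfrac12 P(\chi^2_1 \ge
\mathrm{LRT})$ for positive statistics and $p = \tfrac12$ at zero. LOD
scores are $\mathrm{LRT} / (2\ln 10)$.

## Two-stage trait transformation

Percentages are bounded and left- or right-skewed, so raw compositions
violate the normality the variance-component likelihood assumes.
`transform_trait()` applies:

1. **Logit**: $\mathrm{logit}(p/100)$ maps $(0,100)$ to the real line.
2. **Covariate adjustment under the polygenic model**: fixed effects (age,
   age², sex and their interactions, smoking, education, obesity, alcohol,
   region, log total arsenic) are estimated jointly with a polygenic
   component, and *marginal* residuals $y - X\hat\beta$ are taken. Fitting
   $\beta$ by GLS under the polygenic model (not OLS) avoids biasing the
   covariate effects in correlated family data; taking marginal rather
   than conditional residuals keeps the genetic signal in the residual for
   the second stage. The fraction of logit-scale variance explained by the
   covariates, $1 - \mathrm{var}(r)/\mathrm{var}(y)$, is reported.
3. **Rank-based inverse normal**: Blom scores
   $\Phi^{-1}\!\big[(\mathrm{rank} - 3/8)/(n + 1/4)\big]$, with average
   ranks for ties, control residual kurtosis (high kurtosis inflates
   variance-component LODs). The scores are then rescaled to unit sample
   variance — a rank-preserving affine step — so the final trait has mean
   0 and variance 1 exactly and enters the second stage with an intercept
   only.

## Multipoint IBD: inheritance-vector hidden Markov model

For each family the hidden state at a locus is the *inheritance vector*:
one bit per meiosis (2 per non-founder) saying whether the grandpaternal or
grandmaternal allele was transmitted. `inheritance_hmm()` runs an exact
forward–backward pass over this state space along each chromosome:

* **Transitions** between markers $d$ cM apart flip each bit independently
  with the Haldane recombination fraction
  $\theta = \tfrac12(1 - e^{-2d/100})$ (no interference). The transition
  operator is applied bit by bit in $O(m 2^m)$ rather than $O(4^m)$.
* **Emissions** sum genotype probabilities over founder allele assignments
  (genotypes are unphased; founder allele frequencies are counted from
  typed founders with a half pseudo-count). When all family founders are
  typed, a fast path enumerates only the heterozygous-founder phase
  configurations and checks all vectors at once.
* **Posterior IBD**: at any position the posterior over vectors gives
  $\hat\pi_{ij}$, the expected proportion of alleles shared IBD, via the
  per-vector founder-slot sharing counts. With no marker information the
  posterior is uniform and $\hat\Pi$ reduces exactly to $2\Phi$, so the
  QTL component is confounded with the polygenic one and the scan LOD is
  zero — uninformative regions cannot generate signal.

State space size is $2^{\text{meioses}}$ per family, so the computation is
exponential in family size; families above `bit_limit` (default 16 meioses,
i.e. 8 non-founders) raise a capability error suggesting pedigree
splitting. This is the standard trade-off of exact Lander–Green-style
multipoint analysis: desk-scale linkage fixtures here use nuclear families,
while heritability (which needs only $\Phi$) runs on extended pedigrees of
any size.

## Linkage scan and empirical LOD calibration

`qtl_scan()` fits the QTL model on a cM grid per chromosome and reports
$\mathrm{LOD}(x)$ against the polygenic null (fitted once per trait).
Pedigree members without a usable phenotype (below a detection limit, or
with missing covariates) are marked `NA` in the trait vector: they still
contribute marker information to the IBD computation, and the
variance-component fits use the phenotyped subset. `call_peaks()` applies
the conventional thresholds: suggestive 1.9, significant 3.3.

Variance-component LOD scores can be miscalibrated when trait normality
fails. `estimate_correction_constant()` calibrates them empirically: it
simulates a fully informative marker unlinked to the trait (every founder
carries unique alleles, transmissions independent of the phenotype),
computes the *exact* IBD matrix from the realised descent, fits the QTL
model, and repeats $R$ times (desk default $R = 1000$; at least 100). The
constant $c$ is a least-squares line through the origin relating
theoretical ½:½-mixture quantiles to empirical quantiles of the positive
null LODs at probabilities 0.50–0.95. Adjusted LOD $= c \times$ LOD,
rounded half-up to two decimals as in published LOD tables. Well-behaved
inverse-normal traits give $c \approx 1$ (the `near_unity` diagnostic flags
$c \in [0.95, 1.05]$); heavy-tailed untransformed traits inflate null LODs
and get $c < 1$.

## Synthetic-data generator

`sim_dataset(sim_config(seed = ...))` produces a complete study:

* **Pedigrees** (default 40 extended three-generation families of 18,
  about 720 individuals): a founder couple, five adult children with
  married-in spouses, grandchildren, and one half-sibship, yielding
  parent–offspring, sibling, half-sibling, avuncular and first-cousin
  pairs. A nuclear template serves linkage fixtures.
* **Genetic map and STR genotypes**: marker spacings uniform in
  2.4–17.6 cM (mean 10), 4 equifrequent alleles per marker (expected
  heterozygosity 0.75), gene-dropped with Haldane recombination; founder
  descent labels are retained so realised IBD is known exactly. An
  optional error injector creates Mendelian inconsistencies for testing
  `mendelian_check()`.
* **Phenotypes**: two latent log-ratio traits (iAs vs DMA, MMA vs DMA)
  each decompose into covariate effects (20% of variance), an additive
  polygenic part (default heritabilities 0.53 and 0.50), an optional
  planted QTL, and environmental noise; polygenic and environmental
  deviations of the two latents are correlated (each blend preserves the
  marginal variance and the $2\Phi$ covariance, so per-trait heritability
  is unchanged). The multinomial-logistic transform maps the latents to a
  three-part composition, which *guarantees* the percentages sum to 100
  and induces the negative %DMA correlations characteristic of such data.
  Concentrations in µg/L are the composition times lognormal total
  arsenic and creatinine.

### Realism limits

The generator aims at structural realism (family covariance, composition
closure, marker information content), not at reproducing any particular
cohort: covariates are drawn from marginal distributions without joint
structure beyond age-by-generation; total arsenic is independent of the
composition; all pedigrees are outbred and completely genotyped/phenotyped
by default; the QTL model is strictly additive. Headline numbers from any
real study are therefore not reproduction targets — estimates on synthetic
data should recover the *configured* truth, and the test suite checks
exactly that.

## Problem sizes

Defaults are chosen so every analysis runs on a laptop in seconds to a few
minutes: heritability on ~700 individuals in extended families (a fit takes
about a second), linkage on a few hundred individuals in nuclear families
with two chromosomes of a dozen STRs, and $R = 1000$ replicates for the LOD
correction. All are package choices, configurable through `sim_config()`
and function arguments.

## Limitations

* Exact multipoint IBD is exponential in family meioses (`bit_limit`);
  no approximate (MCMC or composite-likelihood) fallback is provided.
* ML variance components are downward-biased relative to REML in small
  samples; the package follows the ML convention because the LRT and LOD
  machinery requires comparable likelihoods.
* The ½:½ mixture null is asymptotic; at small sample sizes the zero-LRT
  mass deviates slightly from one half (the test suite quantifies this on
  30-family fixtures).
* Haldane's map function (no interference) is assumed throughout, matching
  the generator and the HMM transitions.
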