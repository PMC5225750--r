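---
title: "Genomic selection for clonally replicated trials: models and methods"
author: "clonalGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for clonally replicated trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalGS)
```

## Scope

`clonalGS` implements the full analysis chain used to evaluate genomic
selection (GS) in a clonally propagated crop such as strawberry: marker
quality control, pedigree and genomic relationship matrices, REML
estimation of genetic parameters from clonally replicated field trials,
six whole-genome prediction methods, cross- and true-validation metrics,
selection efficiency, and relatedness-corrected linkage disequilibrium
(LD). Because raw breeding-program data are rarely public, the package
also ships a breeding-population simulator so every stage can be
exercised and tested end to end.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the places where a genuinely open
design decision had to be made.

## The clonal trial mixed models

A clonal field trial tests each genotype as several vegetatively
propagated copies, laid out in replicate blocks subdivided into raised
beds and subplots. The single-trial model for a plot-level observation
is

$$
y = 1\mu + w\beta + Xr + Z_1 b(r) + Z_2 p(br) + Z_3 a + Z_4 f +
Z_5 c(f) + e,
$$

with fixed intercept, transplant-weight covariate $w$ (seedling-derived
trials only) and replicate $r$; random bed-within-replicate
$b(r)\sim N(0,\sigma_b^2 I)$, subplot-within-bed
$p(br)\sim N(0,\sigma_p^2 I)$, additive genotype
$a\sim N(0,\sigma_a^2 A)$ with $A$ the pedigree numerator (or genomic)
relationship matrix, family $f\sim N(0,\sigma_f^2 I)$, clone-within-family
$c(f)\sim N(0,\sigma_c^2 I)$ and residual $e\sim N(0,\sigma_e^2 I)$.
The family and clone terms absorb non-additive genetic variance at the
resolution the design can see (full-sib family deviations and total
genotype-specific deviations); no locus-level dominance is modelled.

Derived parameters, with $\sigma_t^2 = \sigma_b^2+\sigma_p^2+\sigma_a^2+
\sigma_f^2+\sigma_c^2+\sigma_e^2$:

* narrow-sense heritability $h^2 = \sigma_a^2/\sigma_t^2$;
* broad-sense heritability
  $H^2 = (\sigma_a^2+\sigma_f^2+\sigma_c^2)/\sigma_t^2$;
* ad-hoc clonal-mean heritability
  $h_{\bar c}^2 = \sigma_a^2 / \bar\sigma_c^2$ with
  $\bar\sigma_c^2 = \sigma_b^2+\sigma_p^2+\sigma_a^2+\sigma_f^2+
  \sigma_c^2+\sigma_e^2/\bar r$ and $\bar r$ the harmonic mean of
  per-genotype replicate counts.

The $h_{\bar c}^2$ denominator is typeset ambiguously in the field's
literature: it is unclear whether only the residual, or all plot-level
nuisance variances, are divided by $\bar r$. The default here is the
literal reading (only $\sigma_e^2/\bar r$); `hc2_mode = "clone_mean"`
divides $\sigma_b^2$, $\sigma_p^2$ and $\sigma_e^2$ all by $\bar r$.
The mode in effect is printed with every report.

Standard errors of all three ratios are delta-method approximations
using the average-information matrix as the asymptotic covariance of
the variance components. This is one defensible choice among several
(profile-likelihood intervals being the main alternative); it matches
what most REML software reports.

### Paired-trial model and Type-B correlation

Genotype-by-environment interaction between two trials is estimated by
a combined model with trial-specific ("heterogeneous") bed, subplot and
residual variances and interaction terms for genotype, family and
clone. The Type-B additive correlation is

$$ r_B = \frac{\sigma_a^2}{\sigma_a^2 + \sigma_{ta}^2}, $$

near 1 when genotype rankings are stable across trials.

One structural decision was forced: if both the genotype-by-trial term
and the clone-by-trial term carry iid identity covariance, the two are
exactly aliased (identical design and covariance structure) and
$r_B$ is not estimable. Since the genotype-by-trial deviation is an
*additive* deviation, this package gives it the additive covariance
within each trial (block-diagonal $A$), which separates it from the
clone-by-trial term. The simulator draws the matching quantity — a
pedigree-polygenic trial-specific deviation — so recovery of $r_B$ is a
genuine end-to-end test.

### Adjusted clonal means

Genomic prediction methods take one phenotypic value per genotype: the
generalized-least-squares genotype mean from a model with genotype
fixed and the design strata (replicate, bed, subplot) random, with the
covariate evaluated at its mean. Replicate is treated as random here by
default (`replicate_random = FALSE` switches it), matching the
all-terms-random description of this model in the field; an
estimability check reports genotypes confounded with design strata.

## The REML engine

`reml_fit()` maximises the REML log-likelihood with
average-information (AI) updates and an expectation-maximisation (EM)
fallback: the first iteration is EM, an AI step that leaves the
parameter space or decreases the likelihood is replaced by an EM step,
and components are kept above $10^{-8}\times\mathrm{var}(y)$ by
projection (components pinned there are flagged as boundary).
Convergence requires a relative log-likelihood change below $10^{-8}$
and relative component change below $10^{-6}$; in addition, five
consecutive iterations with a numerically stationary log-likelihood are
accepted as converged, because on near-flat ridges (see below) the
components can drift indefinitely at constant likelihood.

The log-likelihood includes the $\log\det(X'X)$ correction so that it
is invariant to the fixed-effect parameterisation (reference-level and
sum-to-zero codings give identical likelihoods and components). On
balanced one-way designs the estimates agree with the closed-form
ANOVA decomposition to $10^{-8}$, which is one of the package's oracle
tests.

This is a dense-matrix engine: every iteration factorises an
$n \times n$ covariance, which is the right trade-off for trial-sized
data (hundreds to a few thousand plots) and keeps the code auditable.

**A note on identifiability.** With pedigree $A$, family and clone
terms in one model, the additive variance is identified by
*between-family* relationship structure. If all crosses are between
unrelated founders, $A$ is nearly $0.5\cdot(\text{family blocks}) +
0.5 I$ and the likelihood has a flat ridge between $\sigma_a^2$ and
$\sigma_f^2+\sigma_c^2$; estimates can hit the boundary with very large
(honest) standard errors. Real breeding populations are deeply
pedigreed, which is why the simulator's default pedigree has two
generations (tested families are linked through shared grandparents).

## Whole-genome regression samplers

`fit_wgr()` implements single-site Gibbs samplers for
$y = 1\mu + X\beta + e$ on dosages centred by twice the training allele
frequency:

* **BRR** — common Gaussian effect variance (homogeneous shrinkage);
* **BL** — Bayesian LASSO with Park–Casella per-marker exponential
  mixing variances and a gamma hyperprior on $\lambda^2$;
* **Bayes B** — point mass at zero plus a per-marker
  scaled-inverse-$\chi^2$ variance (a scaled-t slab);
* **Bayes C** — point mass at zero plus a common Gaussian slab.

Method descriptions in parts of the literature swap the Bayes B/C slab
families; this package follows the convention of the widely used
Bayesian regression software (B = scaled-t, C = Gaussian) and provides
`slab_swap = TRUE` to exchange them for sensitivity checks.

Default chains are 12 000 iterations, 2 000 burn-in, thinning 5 —
desk-scale settings; an effective sample size of the residual variance
below 100 raises a warning, not an error. Priors are auto-scaled by the
usual partition rule with $R^2 = 0.5$: the prior modes attribute half
of $\mathrm{var}(y)$ to the markers and half to the residual. The prior
inclusion probability for the mixture models defaults to a sampled
$\pi$ with Beta prior mean 0.5 and weight 10. Preliminary-work reports
in the field indicate the defaults are not critical, and the samplers
expose every hyperparameter for those who want to check.

All draws use R's RNG, so a chain is bit-reproducible given its seed.
Two oracle tests pin the samplers down: BRR with fixed variances
reproduces the ridge-regression closed form to better than 0.01, and
Bayes C with $\pi = 1$ agrees with BRR.

## Kernel methods

GBLUP fits $y = 1\mu + Za + e$, $a \sim N(0, \sigma_a^2 A_g)$ with the
marker-based relationship matrix of Yang et al. (off-diagonals averaged
over pairwise-complete markers — no imputation — and the
heterozygosity-corrected diagonal). PBLUP replaces $A_g$ by the
pedigree numerator matrix; RKHS replaces it by a Gaussian kernel
$K_{jk} = \exp(-h\, d^2_{jk} / \overline{d^2})$ on squared Euclidean
distances between dosage rows. Normalising by the mean off-diagonal
squared distance makes the bandwidth unit-free; $h = 0.5$ is the
default and both constants are recorded in the kernel's metadata. The
distance normalisation constant is not standardised in the field, so it
is an explicit, documented choice here; sensitivity to $h$ should be
reported rather than assumed. Kernel averaging (multi-kernel RKHS) is
deliberately out of scope.

Non-PSD kernels are repaired by **bending**: eigenvalues below
$\varepsilon = 10^{-6}$ are raised to $\varepsilon$ and the matrix is
reconstructed. Eigenvalue clipping is simple, deterministic and
idempotent; the flag `bend_applied` makes the repair auditable. Solves
use Cholesky factorisation; an inverse is never formed explicitly.

Unphenotyped individuals are carried inside the kernel and predicted
jointly from the mixed-model equations — this is exactly how
marker-only candidates are predicted in the incomplete-information
scenario, and how true validation works for the kernel methods.

## Validation and selection efficiency

* **Predictive ability (PA)** — Pearson correlation between adjusted
  clonal means and GEBVs.
* **Prediction accuracy (PACC)** — PA rescaled by the ad-hoc
  heritability. The default is $\mathrm{PA}/\sqrt{h_{\bar c}^2}$ (the
  classical rescaling, and the only one consistent with published
  accuracy magnitudes at low heritability); the literal division by
  $h_{\bar c}^2$ is available behind `sqrt_scaling = FALSE`. Values
  above 1 are flagged, never truncated.
* **Cross-validation** — k-fold (default $k = 5$; descriptions in the
  field vary between four- and five-fold, so it is configurable) with
  one pooled correlation over out-of-fold predictions as the primary
  statistic; per-fold correlations are also returned.
* **True validation** — train on one trial, predict a different trial
  from markers only, score against the test trial's adjusted means;
  PACC uses the test trial's $h_{\bar c}^2$ by default (passing the
  training trial's value is the documented alternative).
* **Selection efficiency** — the realised fraction of the genetic gain
  achievable with complete information when the top 5% or 10% is
  selected on marker-only predictions. Gain is measured as the mean
  complete-information GEBV of the selected set minus the population
  mean, so identical rankings give exactly 100% and a random ranking
  gives 0 in expectation. The complete-information reference is a GBLUP
  fit on the test trial's own phenotypes and markers. Ties are broken
  by id order, deterministically.

## Linkage disequilibrium

Within-linkage-group LD is the squared Pearson correlation $r^2$
between dosage vectors (composite LD; the markers are unphased).
Relatedness-corrected LD ($r_v^2$) GLS-centres each dosage vector with
the generalized mean under $V$ and whitens by the Cholesky factor of
$V$, where $V$ is the bent genomic relationship matrix built from the
markers of that same linkage group (LG-specific by default, per the
correction's standard usage). When $V$ is any positive multiple of the
identity, $r_v^2 = r^2$ exactly — a tested invariant. Decay profiles
bin pairs by map distance (1 cM default bins); spline smoothing is a
plotting nicety and intentionally not part of the statistics.

## The simulator

`simulate_breeding_trials()` generates the structures the analysis
assumes, with defaults chosen to emulate a strawberry-like program:

* **Genome** — 28 linkage groups of 60 cM (a ~1 700 cM map), markers
  placed uniformly at random; 2 000 markers by default (a desk-scale
  stand-in for panels of 5k–17k).
* **Founder LD** — a copy chain along each chromosome: a marker's
  allele copies its left neighbour with probability
  $\exp(-d/\text{block length})$ (default block 10 cM), otherwise it is
  a fresh Bernoulli draw at that marker's target frequency
  (uniform on [0.1, 0.9]). This produces LD decaying over roughly
  10 cM, which is the qualitative target; it is a generating stand-in,
  not a coalescent model.
* **Pedigree** — circular mating (parent $i$ crossed to parent $i+1$,
  closing the circle), 22 parents and 10 progeny per cross by default;
  two generations by default so families share grandparents (see the
  identifiability note above).
* **Meiosis** — gene dropping with Haldane recombination
  ($c = \tfrac12(1-e^{-2d/100})$ per adjacent interval), diploid.
  The octoploid crop's array genotypes are delivered as disomic
  dosages and every method treats them as such, so diploid meiosis is
  the faithful level of abstraction — this is stated prominently
  because it is the simulator's largest simplification.
* **Trait** — 100 genotyped QTL by default (traits of interest show at
  most minor-effect QTL), additive values rescaled to hit the target
  $h^2$ exactly in the empirical variance; family and clone deviations,
  bed and subplot effects and plot residuals iid at configured
  fractions of a unit total variance. Default fractions
  ($h^2 = 0.25$, family 0.10, clone 0.10, bed 0.05, plot 0.05) sit in
  the middle of the reported ranges for such trials (narrow-sense
  0.03–0.46, broad-sense up to ~0.66).
* **Two trials** — the marker-determined additive part is shared; a
  pedigree-polygenic genotype-by-trial deviation is added to hit the
  target $r_B$; 20% of genotypes appear in both trials and the rest are
  split, mirroring paired trials that share checks but consist mostly
  of different individuals.

What the simulator does **not** emulate: selection between generations,
epistasis or locus-level dominance, spatial residual correlation beyond
the bed/subplot strata, genotyping error, and subgenome behaviour of an
octoploid. Passing tests therefore demonstrate internal correctness and
qualitative behaviour (orderings, recoveries), not field performance on
real data.

## Problem sizes used in the tests

The packaged checks run at deliberately modest sizes chosen as the
smallest that leave the statistical checks meaningful: trials of
200–450 genotypes with 2–3 clonal replicates, 600–2 000 markers,
recovery checks asserted within two standard errors, orderings asserted
as majorities over 10–20 seeds, and Monte Carlo chains of 6 000–50 000
iterations depending on the precision the oracle needs. The acceptance
script reports recovery estimates as means over three simulation
replicates because a single fit at these sizes has a standard error of
roughly 0.15 on a heritability scale.

## Known limitations

* The AI covariance underlying all standard errors is asymptotic;
  near boundaries it can be indefinite (it is PSD-projected for the
  delta method) and the SEs are then approximate.
* Genotype-by-trial variance is estimable only through shared
  genotypes and pedigree links; with neither, the combined model is
  flagged as unreliable rather than refused.
* The Gaussian-kernel bandwidth default is a convention, not an
  optimum; no bandwidth sampling is implemented.
* Selection efficiency depends on the complete-information reference
  being a sensible benchmark; it is fixed to GBLUP-on-test-trial by
  construction.
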