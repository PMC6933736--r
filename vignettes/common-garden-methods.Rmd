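---
title: "Methods: quantitative genetics of clonal common-garden trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of clonal common-garden trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardenQG)
```

# Scope

gardenQG analyses multi-year clonal common-garden trials of the kind used in
forest-tree provenance research: hundreds of genotypes collected across a
wide latitudinal range, grouped into provenances within populations (river
drainages) within genetic demes, clonally replicated by ramets, and measured
for many traits in two or more years. Because every genotype grows in one
environment, among-population trait differences reflect genetics, and
between-year differences within a genotype reflect phenotypic plasticity.

The package implements five connected analyses — variance partitioning with
REML mixed models, plasticity quantification, Qst-Fst divergence testing,
Lande-Arnold phenotypic selection analysis, and trait-climate correlated
evolution under Brownian motion — plus a synthetic-data generator with known
ground truth against which every stage is tested.

# The synthetic-data generator

`simulate_dataset()` draws each trait as

$$y_{ijkr} = \mu + b\,(\mathrm{lat}_i - \overline{\mathrm{lat}})
  + P_i + V_{j(i)} + Y_t + (PY)_{it} + G_{k(ij)} + e_{ijkr},$$

with independent Gaussian layers for population (around a linear latitudinal
cline), provenance-in-population, year, population-by-year, genotype, and
ramet-level residual. Default design: 29 populations in 3 demes spanning
45.6-59.6 degrees N, about 14 genotypes per population in 5 provenance
groups, 4-20 ramets per genotype, two measurement years. Missing values are
deleted completely at random at a per-trait rate (default 30% for the
ecophysiology-style traits, which in real trials are measured on subsets);
the real missingness mechanism in field data is unlikely to be this benign,
which is one reason passing recovery tests here does not certify behaviour
on real data.

Per-trait variance magnitudes are not identifiable from published summary
tables, so the defaults were chosen once for statistical power and realism:
phenology-style traits get strong clines and population variance well above
the drift expectation, ecophysiology-style traits weak clines and lower
heritability. Demes add no extra variance layer by default: they enter as
labels derived from latitude order, matching their descriptive role in
provenance studies. The two years are exchangeable labels with i.i.d. year
effects.

The recorded ground-truth Qst per trait is
$\sigma^2_b / (\sigma^2_b + 2\sigma^2_w)$ computed from the generating
components, where $\sigma^2_b$ includes the cline-induced among-population
variance (using the population variance of the realized latitudes) and
$\sigma^2_w = \sigma^2_{prov} + \sigma^2_{geno}$ is the genetic variance
within populations.

## The fitness surface

`simulate_fitness()` inverts a phenotypic selection analysis: given
standardized genotype means $z$, fitness is
$W = w_0 + \sum_k \beta_k z_k + \sum_k (\gamma_k / 2) z_k^2 + \varepsilon$
with $w_0 = 1 - \sum_k \gamma_k / 2$, so mean fitness is 1 and regressions
of relative fitness $w = W/\bar W$ on $z$ recover $\beta_k$ and $\gamma_k$
on their configured scales ($\gamma$ is the doubled quadratic coefficient
throughout, the usual selection-differential convention).

A deliberately concave surface (e.g. $\gamma = -0.4$) is negative in the
deep trait tail (about 3% of genotypes at $|z| > 1.9$). Flooring those
values at a positive constant would attenuate the realized curvature by
roughly 20% and silently bias every downstream recovery check, so the
default keeps them and records the negative fraction as an attribute; an
optional `floor` argument clips at a fraction of mean fitness for users who
need strictly positive fitness (as a height-gain proxy is in real data,
where the quadratic form is only a local approximation). This is the one
place where the generator chooses faithfulness of the surface over strict
positivity.

# REML mixed models

`fit_reml()` fits a single-random-intercept Gaussian mixed model. The
variance ratio $\lambda = \sigma^2_u/\sigma^2_e$ is profiled: for grouped
random effects the matrices $V_0^{-1} = (I + \lambda ZZ')^{-1}$,
$\log|V_0|$ and $X'V_0^{-1}X$ all have closed Woodbury forms in the group
sizes, so one evaluation costs $O(np + qp^2 + p^3)$ and no $n \times n$
matrix is ever built. The profile criterion is minimized by a coarse grid
on $\log\lambda$, golden-section refinement, and a final root-polish of the
analytic profile score (golden-section alone is limited to about
$\sqrt{\epsilon} \approx 10^{-8}$ relative accuracy, which is not enough to
reproduce balanced-design closed forms to $10^{-8}$). The $\lambda = 0$
boundary is always compared explicitly and flagged when active.

Choices that matter:

* Factors are coded with sum-to-zero contrasts; term-wise Wald F statistics
  are then type-III tests. Denominator df use the Satterthwaite
  approximation: the covariance of each independent contrast is
  differentiated numerically with respect to $(\sigma^2_u, \sigma^2_e)$ and
  combined with the inverse observed REML information; multi-df terms pool
  per-contrast df Fai-Cornelius style. At a boundary fit ($\hat\sigma^2_u =
  0$) the information matrix is singular and the residual df $n - p$ is
  used instead.
* The random-effect likelihood-ratio test refers $2\Delta\ell$ (clipped at
  zero) to $\chi^2_1$. The null value lies on the boundary of the parameter
  space, so this is conservative by construction; the conservatism is
  accepted rather than mixture-corrected, and the calibration test checks
  rejection $\le$ 5%, not = 5%.
* The genetic random term is the genotype identity (an i.i.d. intercept per
  clone). A marker-derived genotype covariance would be the natural
  structured alternative; with clonally replicated genotypes the identity
  covariance already captures the clone-mean structure that the downstream
  chi-square tests rely on.
* The variance-partitioning model for a two-year trial is
  `value ~ year + population + year:population` with the genotype random
  intercept. Populations are crossed with years in a common garden;
  a population-nested-in-year coding would alias the interaction.
* Least-squares means average model predictions over a reference grid with
  equal weight per level of the other factors; cells never observed under
  the nesting are reported with `estimable = FALSE`.
* AIC is reported as the REML criterion plus twice the parameter count
  (fixed coefficients + variance components), so AIC minus the criterion is
  a constant per model structure.

# Plasticity

Genotype plasticity is the difference of a genotype's mean trait value
between the two years, second minus first by sorted label (the order is
recorded); it is antisymmetric under relabeling, and the signed version is
primary since direction matters for reaction norms. Population-level
plasticity is the difference of population-by-year LS means with
error-propagated intervals. Fitness-plasticity and trait-climate
associations use Spearman rank correlations (the latter keyed by the garden
climate value of each observation's measurement year — with two years this
is a coarse two-point contrast, and the package deliberately exposes the
climate table as data rather than hard-coding an index). Garden-versus-
origin climate comparisons use a two-sided Wilcoxon rank-sum test for
unpaired series and a paired t-test for paired ones; degenerate inputs
(all-tied samples) return p = 1 with a warning rather than an error.

# Qst-Fst

`mcmc_variance_components()` is a conjugate Gibbs sampler for the nested
model population / provenance-in-population / genotype with inverse-gamma
(univariate inverse-Wishart) priors on all four variances and a flat prior
on the mean. Defaults follow common practice for weakly-informative
variance priors: shape = rate = 0.001, 50,000 iterations, 10% burn-in,
thinning by 10; a sensitivity fit at shape = rate = 1 is part of the test
suite, and effective sample sizes are reported with a warning below 200.
Optional log or square-root response transforms improve homoscedasticity
for skewed traits.

Qst is computed per posterior draw as
$\sigma^2_{pop} / (\sigma^2_{pop} + 2\sigma^2_{within})$ with
$\sigma^2_{within} = \sigma^2_{prov} + \sigma^2_{geno}$ by default: in a
clonal design the within-population *genetic* variance is the clone-mean
variance, and the ramet-level residual is non-genetic and excluded (the
components included are configurable). The point estimate is the posterior
median, the interval equal-tailed 95%.

Fst is the multi-locus ratio-of-averages Weir-Cockerham theta with a
percentile bootstrap over loci. The divergence rule is conservative:
divergent selection is called only when the Qst point estimate and the
entire Qst interval lie above the upper bound of the neutral interval.

# Selection analysis

Fitness is relativized and traits z-scored within year across all genotypes
(no population stratification — the comparison group is the whole garden in
each year). The linear differential is the coefficient of $z$ in a
regression of $w$ on $z$ (optionally with a genetic-group random intercept
via the package's own REML engine); the quadratic differential doubles the
$z^2$ coefficient from $w \sim z + z^2$. Significance uses label
permutations of $w$ across genotypes — genotype means are the exchangeable
unit, ramet-level resampling would fake replication — with the add-one
estimator $p = (1 + \#\{|s^*| \ge |s|\})/(B + 1)$, which cannot return
zero. Gradients come from the multiple regression of $w$ on all traits with
listwise deletion (the dropped count is reported, since ecophysiology-style
missingness degrades the multivariate analysis first). Temporal
heterogeneity is the year-by-trait interaction test in the pooled model
$w \sim z \times year$. Classification: significant $\gamma < 0$ with the
fitted peak $z^* = -b_z/(2 b_{z^2})$ inside the observed standardized range
is stabilizing; significant $\gamma > 0$ disruptive; otherwise a
significant $\beta$ gives directional selection by sign. Holm's step-down
correction is applied across traits within an analysis family.

The fitness-residual variant regresses $w$ on a covariate set (default:
genetic-group intercepts) and reruns the differentials on the residuals;
with no covariates it reproduces the main analysis exactly, which is the
tested reduction.

# Correlated evolution on a phylogeny

Trees come from neighbor joining on Euclidean genetic distances (negative
branches clamped to zero), midpoint-rooted and height-normalized to 1; the
construction is deliberately swappable since distance-tree choice is a
convention, not an inference. The default analysis grain is
population-mean tips (climate is constant within a population); an
individual-tip mode is simply a larger distance matrix.

The bivariate Brownian log-likelihood uses the matrix-normal identity with
covariance $R \otimes C$: one Cholesky factor of the $n \times n$
shared-branch-length matrix $C$ whitens both trait vectors, after which
every likelihood evaluation is arithmetic on a 3x3 Gram matrix. Duplicate
or zero-length tips make $C$ singular; a relative jitter of $10^{-8}$ is
applied and recorded. Posterior sampling is Metropolis-within-Gibbs over
$(\mu_x, \mu_y, \log\sigma^2_x, \log\sigma^2_y, \rho)$ on internally
standardized data (the chain is mapped back to the data scale; both models
in a Bayes-factor comparison receive the identical affine transform, which
cancels in the log Bayes factor).

Marginal likelihoods use stepping-stone sampling along the power posterior
path with $\beta_k = (k/K)^{1/0.3}$ (Beta(0.3, 1) quantile spacing, which
concentrates stones near the prior where the integrand varies fastest);
the conventional full schedule is 100 stones of 1000 iterations. Stepping
stone needs proper priors, so the model uses N(0, 5^2) on the standardized
means, log-uniform rates on [0.01, 100], and uniform(-1, 1) on $\rho$ —
a vague-but-proper prescription rather than improper flats, with the box
documented and configurable. MCMC kernels mix random walks with
independence draws from the prior; without the latter, chains at
prior-dominated stones mix far too slowly and the marginal-likelihood
estimates are unstable by tens of log units (this failure mode is exactly
what the conjugate-toy accuracy test guards against). The reported MC
standard error treats per-stone samples as independent and is therefore an
optimistic diagnostic, not a confidence interval.

The log Bayes factor is **twice** the difference of log marginal
likelihoods — the doubled convention, kept because the support ladder
(weak > 2, moderate > 5, strong > 10) and the family-wise threshold 9.8 are
defined on that scale. The threshold 9.8 is taken as configuration; its
derivation is not reproduced here.

# Problem sizes used in the tests

The test suite exercises every stage at reduced but statistically faithful
sizes, chosen as the smallest designs where the checked properties have
adequate power: REML oracles at 50 observations; selection recovery at 400
genotypes with 300-500 permutations; permutation and type-III calibration
at 500 replicates; Qst recovery at the full 29 x 14 x 4 design with 10,000
Gibbs iterations; Fst at 500 loci; stepping stone at 30-50 stones of
250-500 iterations (the coevolution power surface runs 200-tip trees).
`scripts/acceptance.R` recomputes the same quantities from scratch at these
sizes.

# Known limitations

* One random intercept: no crossed random effects, spatial field effects,
  or marker-structured genotype covariance in the REML engine.
* The Gibbs sampler assumes Gaussian layers after an optional marginal
  transform; heavy-tailed traits need a transform, not a different
  likelihood.
* The Brownian model has no Ornstein-Uhlenbeck or rate-shift alternatives;
  logBF contrasts correlation against independence only.
* The generator's missingness is MCAR and its years are exchangeable;
  real trials have structured missingness and year-specific climates.
* Satterthwaite df are fragile near variance boundaries; the boundary
  fallback (residual df) is anti-conservative when shrinkage is strong.
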