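# gardenQG

Quantitative genetics of multi-year clonal common-garden trials, for forest
geneticists and evolutionary ecologists who work with provenance trials:
hundreds of clonally replicated genotypes collected across a species range,
grown in one garden, and measured for many traits over several years.
Because the environment is shared, among-population differences are
genetic; because years differ, within-genotype differences are plastic.
The package asks, in order: how is trait variance partitioned; how plastic
are genotypes and populations; is among-population divergence stronger
than neutral drift; which traits are under selection and of what form; and
do traits co-evolve with the climate of their source niches.

## Methods at a glance

* **Variance partitioning** — REML linear mixed models
  `value ~ Year + Population + Year:Population` with a genotype random
  intercept; type-III F tests with Satterthwaite denominator df,
  likelihood-ratio tests for the random term, LS-means, BLUPs.
* **Plasticity** — genotype plasticity as the between-year difference in
  mean trait value; population reaction norms from Population x Year
  LS-means; Spearman correlations with fitness and garden climate;
  Wilcoxon / paired-t garden-vs-origin climate comparisons.
* **Q_ST-F_ST** — Gibbs sampling of the nested variance components
  (population / provenance / genotype) with inverse-gamma priors;
  Q_ST = s2_between / (s2_between + 2 s2_within) per posterior draw with
  95% credible intervals; multi-locus Weir-Cockerham theta with a locus
  bootstrap; divergent selection called only when the whole Q_ST interval
  clears the neutral interval.
* **Selection analysis** — Lande-Arnold differentials: beta from
  w ~ z, gamma as twice the quadratic coefficient of w ~ z + z^2, with
  seeded permutation p-values (add-one estimator), multivariate gradients,
  a year-by-trait heterogeneity test, and classification into
  directional / stabilizing / disruptive with the peak-in-range rule.
* **Correlated evolution** — bivariate Brownian motion on a
  neighbor-joining genotype tree; stepping-stone log marginal likelihoods
  (Beta(0.3, 1) stone spacing); logBF = 2 (logML_dep - logML_indep) with
  support bands at 2 / 5 / 10 and a family-wise threshold flag at 9.8.
* **Synthetic data** — `simulate_dataset()` and friends generate the whole
  design (variance layers, latitudinal clines, missingness, a known
  fitness surface, Balding-Nichols markers, correlated Brownian tip data)
  with ground truth recorded, so every stage has a parameter-recovery test.

See `vignettes/common-garden-methods.Rmd` for models, priors, numerical
choices and limitations.

## Worked example

```r
library(gardenQG)

cfg <- simulation_config(
  n_populations = 12, genotypes_per_population = 10,
  ramets_per_genotype = c(3, 5),
  trait_specs = list(bud_set = trait_spec(grand_mean = 200, cline_slope = -3,
                                          sd_population = 5, sd_year = 4,
                                          sd_pop_x_year = 1, sd_genotype = 3,
                                          sd_residual = 5)),
  fitness_surface = list(bud_set = list(beta_true = 0.3, gamma_true = -0.2)),
  seed = 42)
sim <- simulate_dataset(cfg)

fit <- fit_reml(value ~ year + population + year:population,
                sim$observations, random = ~ genotype)
anova(fit)
#> Type-III tests of fixed effects (Satterthwaite df)
#>             term       F df_num df_den        p
#>             year  69.590      1  811.5 3.13e-16
#>       population 191.600     11  106.5  < 2e-16
#>  year:population   2.274     11  811.5  0.00983

q <- compute_qst(mcmc_variance_components(sim$observations, "bud_set",
                                          n_iter = 10000, seed = 1))
q
#> Qst [bud_set] = 0.939, 95% CI (0.867, 0.977), ESS 520

fst <- weir_cockerham_fst(simulate_markers(cfg, seed = 43), seed = 44)
fst
#> Weir-Cockerham theta = 0.1015, 95% bootstrap CI (0.0965, 0.1068)
#>   500 loci (500 polymorphic)

classify_divergence(q, fst)
#> [1] "divergent_selection"
```

Reading the output: the year row says the trait shifted between years
(plasticity), the population row that populations differ genetically, and
the interaction row that plasticity varies moderately among populations.
The Q_ST posterior (0.94) sits far above the neutral Weir-Cockerham band
(~0.10), so the divergence classifier reports selection rather than drift —
as it should here, since the generator built this trait with a strong
latitudinal cline.

`run_pipeline(cfg, outdir = "out")` chains all stages (variance,
plasticity, Q_ST-F_ST, selection, coevolution) and writes one tidy CSV per
stage plus ground-truth and provenance JSON files; identical configurations
reproduce outputs byte for byte. A thin command-line wrapper lives in
`inst/scripts/garden-pipeline.R`.

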