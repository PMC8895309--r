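# tractmaturity

Multivariate analysis of white-matter tract microstructure, age, and
episodic-memory recall in developing cohorts.

Developmental studies ask how the maturation of prefrontal–limbic tracts
(uncinate fasciculus, dorsal and ventral cingulum, fornix) relates to the
growth of episodic memory in childhood. Per tract and hemisphere, three
diffusion-tensor parameters — fractional anisotropy (FA), radial
diffusivity (RD) and axial diffusivity (AD) — describe microstructure,
and the children's verbal learning task provides three recall scores
(short-delay free, long-delay free, long-delay cued). Testing every
metric against every score inflates the test count and ignores that the
parameters are collinear descriptions of one structure. `tractmaturity`
implements the multivariate alternative for researchers running such
brain–behavior analyses.

## The method

**Partial least squares correlation (PLS-SVD).** For one tract, let
`X` (n × 6) hold the z-scored diffusion metrics of both hemispheres and
`Y` the z-scored recall scores (or age). The cross-correlation matrix

    R = YᵀX / (n − 1),   R = U S Vᵀ

is decomposed by SVD. Columns of `V` (predictor saliences) and `U`
(behavior saliences) are paired latent variables; `Lx = XV`, `Ly = YU`
are subject-level latent scores. Significance of a latent variable is
assessed by permuting rows of `Y` (5,000 permutations, add-one p-value);
the reliability of each metric's salience by bootstrap ratios
(salience / bootstrap SE over 5,000 sign-aligned resamples, |ratio| >
1.96 = reliable).

**Tract maturity scores.** With `Y` = age the first latent variable has
a closed form (salience ∝ the metric–age correlation vector), and each
subject's projection on it — sign-aligned to correlate positively with
age — is a *tract maturity score*: how much a child's tract
microstructure resembles that of older children. Maturity scores of
tracts whose age latent variable passes the permutation test are
correlated with each recall score under Benjamini–Hochberg FDR, with
evidence quantified by the default two-sided Bayes factor for a Pearson
correlation (stretched-beta prior of width 1), and probed for age-group
differences with `em ~ maturity × group` interaction models (cutoff 7
years).

**Synthetic cohorts.** A calibrated generator
(`generate_cohort()`) produces cohorts with the statistical structure
the analyses assume — a per-tract latent maturation factor partially
explained by age, metric–age loadings, recall-on-age R², and a
configurable coupling between maturation residuals and memory — with
full ground truth recorded, so every stage is testable without clinical
data.

## Worked example

```r
library(tractmaturity)

sim <- generate_cohort(sim_config(seed = 42))      # 37 children, ages 4-12
am  <- build_analysis_matrix(sim$cohort, sim$metrics,
                             "dorsal_cingulum", "age")
ms  <- maturity_scores(am, n_perm = 5000, n_boot = 5000, seed = 7)
ms
#> Tract maturity scores for 'dorsal_cingulum' - n = 37
#> LV1 permutation p = 0.0002 (significant at alpha = 0.05)
#> Correlation with age: 0.649
ms$bootstrap
#>   variable   salience         se bootstrap_ratio reliable
#> 1  left_fa  0.5689472 0.06702244       8.4889067     TRUE
#> 2  left_rd -0.4586418 0.06322432      -7.2541996     TRUE
#> 3  left_ad -0.2652296 0.13841301      -1.9162187    FALSE
#> 4 right_fa  0.1339637 0.14439493       0.9277591    FALSE
#> 5 right_rd -0.5509282 0.05234469     -10.5250063     TRUE
#> 6 right_ad -0.2722717 0.13274307      -2.0511176     TRUE
```

The age latent variable of this simulated dorsal cingulum is significant
(permutation p = 0.0002); FA loads positively and RD negatively, with
both RD saliences and left FA highly reliable — maturity here means
higher anisotropy and lower radial diffusivity. The maturity score
correlates 0.65 with age. Relating it to memory:

```r
maturity_em_association(ms, sim$cohort)
#>             tract       behavior       panel  n     r    p_raw   p_fdr  bf10
#> 1 dorsal_cingulum           sdfr          em 37 0.539 0.000583 0.00175 60.48
#> 2 dorsal_cingulum           ldfr          em 37 0.335 0.042827 0.04283  1.47
#> 3 dorsal_cingulum           ldcr          em 37 0.376 0.021886 0.03283  2.57
#> 4 dorsal_cingulum discrimination specificity 37 0.409 0.011936 0.01194  4.28
```

Short-delay free recall survives FDR decisively (r = 0.54, BF₁₀ ≈ 60:
strong evidence; this cohort was generated with the dorsal cingulum
coupled to that score), while the long-delay scores carry only weak
evidence. `run_pipeline(run_config(...))` chains all stages — univariate
age effects, memory-PLSC, age-PLSC/maturity, FDR + Bayes-factor
associations, interactions — and serializes a schema-validated
`report.json` plus TSV tables, byte-identical under a fixed seed.

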