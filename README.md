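# twinherit

Heritability estimation for batteries of behavioral measures in classical
twin designs — with every estimator validated by parameter recovery on a
built-in twin-cohort simulator.

`twinherit` is aimed at researchers who have (or want to reason about)
phenotype tables with MZ/DZ twin structure: M numeric measures per subject,
family ids, zygosity, optional retest occasions. It implements, end to end:

1. **Twin-cohort simulation** with known ground truth. Each measure's
   variance is split into additive genetic (A), common-environment (C),
   dominance (D) and unique-environment (E) fractions with the classical
   sharing pattern — A correlates 1.0 within MZ and 0.5 within DZ pairs,
   D 1.0 and 0.25, C 1.0 for both, E not at all — plus cross-measure
   genetic correlation and reliability-calibrated retest occasions.
2. **Behavioral fingerprinting**: nearest-neighbour re-identification of a
   subject from their retest profile (or of their MZ co-twin) by Euclidean
   distance over z-scored measures, with a permutation null for the number
   of correct identifications.
3. **Classical heritability** from double-entry twin correlations via
   Falconer's formula, h² = 2(r_MZ − r_DZ), with the standard model
   selection: ACE when r_MZ ≤ 2 r_DZ, ADE (headline h² = r_MZ) when
   r_MZ > 2 r_DZ, flagged "NONE" when r_MZ < r_DZ; optional disattenuation
   by test-retest reliability.
4. **Bivariate genetic correlation** via the cross-twin cross-trait moment
   contrast, decomposing the phenotypic correlation as
   ρ_P = √(h²_a h²_b) ρ_G + √((1−h²_a)(1−h²_b)) ρ_E.
5. **Classifier-weight heritability proxies**: MZ-vs-DZ classification of
   per-pair absolute z-scored difference vectors with a univariate OLS
   model, a ridge classifier (CV-selected penalty, majority vote) and a
   random forest (100 trees, depth 5, √M features per split), 1000
   bootstrap iterations of oversample / 70-30 split / fit; absolute
   coefficients and impurity importances as qualitative per-measure
   heritability, plus the Haufe forward-model transform.
6. **Exploratory factor analysis**: principal axis factoring, Kaiser
   retention, Promax rotation, regression and Bartlett factor scores, and
   a factor-level rerun of the whole heritability battery.
7. **Statistical testing**: Spearman agreement matrices across the four
   heritability profiles and a Monte Carlo permutation test for the
   task-vs-questionnaire domain difference in mean heritability.

The central container, `TwinCohort`, extends Bioconductor's
`SummarizedExperiment`: a measures × subjects assay, subject metadata in
`colData`, per-measure variance fractions in `rowData`.

## Worked example

Simulate a cohort at a typical study scale (149 MZ + 90 DZ pairs, 46
retest subjects) with known per-measure heritabilities, then estimate them
back three ways:

```r
library(twinherit)

a2 <- c(0.2, 0.35, 0.5, 0.65, 0.8, 0)
specs <- varianceSpecs(sprintf("m%d", 1:6), a2 = a2, e2 = 1 - a2,
                       reliability = 0.9,
                       domain = rep(c("task", "questionnaire"), 3))
design <- cohortDesign(6, nMZPairs = 149, nDZPairs = 90, nUnrelated = 200,
                       nRetest = 46, seed = 42)
cohort <- simulateCohort(design, specs)
cohort
#> TwinCohort: 6 measures x 678 subjects
#>   MZ pairs: 149  DZ pairs: 90  singletons: 200
#>   retest subjects: 46

falconerProfile(cohort)[, c("measure_id", "rMZ", "rDZ", "model", "h2")]
#>   measure_id    rMZ   rDZ model      h2
#> 1         m1 0.0867 0.032   ADE  0.0867
#> 2         m2 0.2632 0.265  NONE -0.0040
#> 3         m3 0.4181 0.191   ADE  0.4181
#> 4         m4 0.5930 0.506   ACE  0.1733
#> 5         m5 0.7494 0.467   ACE  0.5655
#> 6         m6 0.0076 0.012  NONE -0.0093

fingerprintSelf(cohort, nPerm = 1000, seed = 1)
#> IdentificationResult: 18/46 correct (39.1%)
#>   median rank 2.5, mean rank 6.5
#>   permutation p < 0.001 (1000 permutations)

ps  <- buildPairFeatures(cohort)
res <- ridgeClassify(ps, runConfig(nIterations = 200,
                                   nAlphaIterations = 50, seed = 1))
#> ridge: alpha = 10, mean accuracy = 64.0% (95% CI 54.4-73.4%)
cor(a2, res$weights$mean, method = "spearman")
#> [1] 0.83
```

Reading the output: at ~100 pairs per zygosity the twin correlations are
noisy — the true a² of measure m4 is 0.65, but a high sampled r_DZ pushed
its Falconer estimate down to 0.17, and the two near-zero-heritability
measures drew slightly inverted correlations ("NONE"). The ridge weight
profile nevertheless ranks the measures close to the planted truth
(Spearman 0.83), which is exactly the qualitative use these weights are
meant for. Self-identification succeeds for 39% of retest subjects against
678 candidates (chance would be ~1 correct in total), with a permutation
p below 1/1000.

`runPipeline(pipelineConfig(...))` chains all stages — fingerprinting,
Falconer profile, genetic-correlation matrix, the three classifiers,
factor extraction with a factor-level rerun, and the domain permutation
tests — into one reproducible, seed-derived report bundle; see the
methods vignette (`vignettes/twin-heritability.Rmd`).

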