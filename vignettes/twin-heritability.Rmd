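---
title: "Methods: twin-study heritability estimation in twinherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-study heritability estimation in twinherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `twinherit`, the
design decisions taken where the methodology was genuinely open, the
numerical conventions, and what the simulator-based validation does and
does not establish.

# The variance-components model

For each measure, the phenotype of subject $i$ is modelled as

$$ y_i = \sqrt{a^2}\,A_i + \sqrt{c^2}\,C_i + \sqrt{d^2}\,D_i +
         \sqrt{e^2}\,E_i, $$

with standard-normal components and $a^2+c^2+d^2+e^2 = 1$: additive
genetics ($A$), common (family) environment ($C$), non-additive/dominance
genetics ($D$) and unique environment ($E$). The classical twin design
identifies these through the sharing pattern within twin pairs: $A$
correlates 1.0 within monozygotic (MZ) and 0.5 within dizygotic (DZ)
pairs, $D$ 1.0 and 0.25, $C$ 1.0 for both, and $E$ is subject-specific.
Hence the expected within-pair correlations are

$$ r_{MZ} = a^2 + d^2 + c^2, \qquad
   r_{DZ} = \tfrac12 a^2 + \tfrac14 d^2 + c^2 . $$

Only three of the four components are identifiable from two correlations,
so each measure is modelled as ACE *or* ADE, never both
(`varianceSpecs()` enforces $c^2 d^2 = 0$). The estimators assume the
equal-environment assumption (MZ and DZ pairs experience equally similar
shared environments), random mating, and no gene-environment interaction
— the standard, and debated, premises of Falconer-style estimation.

## What the simulator emulates, and what it does not

`simulateCohort()` draws the components directly with the sharing pattern
above. Cross-measure structure is imposed on the $A$ components through a
genetic correlation matrix (optionally built from a factor-loading recipe
via `factorCorrMatrix()`); an analogous hook exists for the $E$
components (`envCorr`), while $C$ and $D$ are independent across measures
by default. Retest occasions are generated as

$$ y^{retest} = \rho\, y + \sqrt{1-\rho^2}\,\varepsilon $$

so that the expected test-retest correlation equals the target
reliability $\rho$ exactly, with occasion noise independent of $E$ —
reliability and $e^2$ are separately tunable. Age and sex are generated
independent of the phenotypes (twins share both); an optional linear
covariate-effect recipe exists solely to exercise residualization, since
a cohort's true covariate structure is study-specific and no default
claim about it is warranted.

The simulator deliberately does **not** model: pedigrees beyond twin
pairs and singletons, assortative mating, gene-environment interaction,
floor/ceiling effects, skewed or ordinal measure distributions, missing
data, or age trends in heritability. Passing recovery tests on this
generator therefore shows that the estimators are *correct under the
classical model's own assumptions* — not that those assumptions hold for
any particular real battery.

All randomness flows from a single integer seed. The pipeline derives
per-stage seeds from the global seed by a fixed draw
(`sample.int(2^31 - 2, ...)` under the global seed), so stages are
independently reproducible and the whole report bundle is bit-identical
across reruns.

# Classical estimation

Twin correlations use **double entry** (each pair contributes both
orderings), making the estimate invariant to within-pair order and close
to the intraclass correlation; the method was chosen because pair
ordering is arbitrary in real tables. Falconer's formula
$h^2 = 2(r_{MZ} - r_{DZ})$ applies under ACE; when $r_{MZ} > 2 r_{DZ}$
the ADE reading takes $r_{MZ}$ itself as the headline estimate (it
absorbs additive plus non-additive variance). Both forms are always
stored (`h2`, `h2_falconer`) because published figures are ambiguous
about which convention populates them for ADE-pattern measures; no guess
is committed. The boundary $r_{MZ} = 2 r_{DZ}$ is classified ACE
(dominance assumed negligible there). $r_{MZ} < r_{DZ}$ yields a flagged
negative estimate ("NONE") rather than an error: negative point estimates
are a real, informative outcome of the moment estimator at finite n.
Disattenuation divides by test-retest reliability and flags corrected
values above 1, which poor reliability can produce artificially.

# Bivariate genetic correlation

The phenotypic correlation of two traits decomposes as
$\rho_P = \sqrt{h_a^2 h_b^2}\,\rho_G +
\sqrt{(1-h_a^2)(1-h_b^2)}\,\rho_E$. `twinherit` estimates the genetic
covariance by the cross-twin cross-trait contrast
$2(\mathrm{ctct}_{MZ} - \mathrm{ctct}_{DZ})$ — a moment estimator
assumption-matched to Falconer's formula — rather than pedigree maximum
likelihood (as in SOLAR-style software). This is a deliberate method
substitution: it needs only twin pairs, has a closed form, and recovers
planted $\rho_G$ within $\pm 0.1$ at 5000+5000 pairs in the package's
tests; it does not provide likelihood-ratio tests or standard errors.
Before decomposition the measures are standardized, residualized on
$[1, \mathrm{age}, \mathrm{sex}, \mathrm{age\times sex}, \mathrm{age}^2,
\mathrm{age}^2\times\mathrm{sex}]$, and rank-transformed to normality.
Heritability inputs are the Falconer estimates truncated into
$[0.01, 0.99]$ (logged); cells where either trait's $h^2$ falls outside
$(0,1)$ are masked with a reason rather than propagating nonsense, and
$\rho_G$ beyond $[-1,1]$ is clamped and logged. For unmasked, unclamped
cells the recomposition reproduces $\rho_P$ to machine precision.

The rank-based inverse normal transform uses the Blom offset,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with average ranks for ties — a
documented constant choice among the standard offsets, which differ
negligibly at cohort sizes.

# Classifier weights as heritability proxies

If phenotypic differences between MZ and DZ pairs arise from genetics
alone, a classifier separating MZ from DZ pair-difference vectors should
weight measures in proportion to their heritability. Features are the
absolute z-scored within-pair differences (one row per pair, +1 = MZ,
−1 = DZ); informative raw regression slopes are expected to be negative,
since MZ differences are smaller, and absolute magnitudes are reported.

The protocol, per iteration: re-balance the smaller DZ class by
resampling with replacement, split 70/30, fit, score the held-out side;
1000 iterations by default. Three models are run:

* **Univariate OLS** per feature — the maximal contribution of each
  measure in isolation.
* **Ridge** on $\pm 1$ labels with an unpenalized intercept, solved in
  closed form. The penalty is chosen in a separate phase: per-iteration
  5-fold cross-validation over the grid
  (200, 100, 10, 1, 0.1, 0.01, 0.001), then the modal winner is fixed for
  the scoring phase. The fold count is this package's choice (the
  protocol source leaves it unstated); ties keep grid order. The Haufe
  forward-model transform (`haufeTransform()`, pattern
  $= \Sigma_x w$) is provided because raw multivariate weights can load
  on noise-suppressor features.
* **Random forest** with 100 trees, depth 5 and $\sqrt M$ features per
  split ("auto"/sqrt pinned explicitly; Gini impurity, also unstated in
  the source and documented here as a choice). Importances are
  mean-decrease-impurity, normalized to sum to 1 per iteration; ROC AUC
  accompanies accuracy. `rfTune()` reproduces the out-of-bag sweeps
  (trees 20–160, depth 1–10 or unlimited, sqrt/log2/all features) that
  justify those defaults.

Splits are stratified by class (unstated in the source; stratification
avoids degenerate single-class splits, and any residual degenerate draw
is redrawn and counted).

## The oversampling leak, and where each variant is used

The faithful protocol balances *before* splitting, so duplicated DZ rows
can appear on both sides of the split. On signal-bearing data this
inflates test accuracy mildly; on a *null* cohort it alone pushes
measured accuracy to ~55% (ridge) and ~70% (random forest) — pure
memorization. `RunConfig(strictSplit = TRUE)` splits the original pairs
first and then balances each side separately, a leakage-free evaluation
whose chance level is exactly 50%. The package keeps the faithful
ordering as the default for comparability, and uses the strict split
wherever a chance-level claim is being measured (the null-cohort checks
in the test suite and the acceptance script). Bootstrap summaries report
the mean accuracy, the 2.5th–97.5th percentile interval, and the
bootstrap p-value: the fraction of iterations at or below 50%, reported
as "< 1/n" (never 0) when no iteration reaches it.

A related caveat found while validating the null pipeline: a single
simulated cohort of 150+90 pairs has finite-sample differences between
its MZ and DZ empirical distributions that generalize within the cohort,
moving the cohort's chance level by about ±3 accuracy points. The
acceptance script therefore averages the null accuracy over 20
independent cohorts (50 iterations each) to measure the *expected*
chance level; single-cohort runs quote wider uncertainty.

# Factor analysis

Principal axis factoring iterates the eigendecomposition of the
communality-reduced correlation matrix from squared-multiple-correlation
starts until the largest communality change is below $10^{-4}$ (cap 100
iterations; the tolerance is a documented stand-in for legacy software
whose exact criterion is unpublished). Heywood communalities are clipped
to 0.999 with a warning. The Kaiser rule is applied to the eigenvalues of
the *unreduced* correlation matrix, strictly $> 1$ — the convention of
the mainstream SPSS-style workflow — so an identity matrix retains zero
factors; a fixed `nFactors` override supports scree-based choices, and
the eigenvalue vector is always exposed for scree inspection. Promax uses
$\kappa = 4$ (the common default; the choice matters little at clean
simple structure): varimax with Kaiser normalization, the power target
$\Lambda|\Lambda|^{\kappa-1}$, an oblique Procrustes fit, and the implied
factor correlation matrix. Regression (Thurstone) scores use
$R^{-1}\Lambda\Phi$; Bartlett scores use
$\Psi^{-1}\Lambda(\Lambda^{\top}\Psi^{-1}\Lambda)^{-1}$. Bartlett scores
are conditionally unbiased with variance $1 + (\Lambda^{\top}
\Psi^{-1}\Lambda)^{-1}$, near 1 only for high-communality designs — the
package's tests check the closed form, not a blanket "variance 1".

The factor-level rerun repeats Falconer estimation, the three
classifiers and the Spearman agreement matrix on regression factor
scores, and additionally fits ridge and random forest on the
concatenated regression + Bartlett score sets — eighteen highly
correlated features — as a robustness probe: models that handle
correlated features should split weight evenly across the two nearly
identical copies of each factor.

# Permutation and agreement statistics

Domain differences (task vs questionnaire mean heritability) are tested
with the absolute difference of domain means against a Monte Carlo null
that reassigns domain labels preserving group sizes (default 100,000
draws; the exact label-space size, e.g. $\binom{37}{15} \approx 9.4
\times 10^9$, is reported alongside). "More extreme" is $\geq$, two-sided
through the absolute statistic, and a zero count is reported as the
$1/n_{perm}$ upper bound — permutation p-values are never 0. The
four-profile family is reported both uncorrected and
Bonferroni-adjusted, labelled as such. Method agreement uses Spearman
rank correlation with average-rank ties; constant profiles are masked.

# Fingerprinting conventions

Identification ranks candidates by ascending Euclidean distance with
strict competition ranking and *pessimistic* ties: a candidate tied with
the true match pushes it to the worst tied rank, so ties at the minimum
count as failures — conservative and reproducible, and measure-zero for
continuous data anyway. Self-identification keeps the target's own
original profile among the candidates; co-twin identification removes
only the target itself. Retest profiles are standardized with the
original cohort's means and SDs so the two occasions share a scale. The
permutation null shuffles the truth mapping and recounts exact (rank-1)
identifications; with a bijective truth map the null expectation is one
correct match regardless of cohort size (the classic matching-problem
result). Mean rank is reported over *all* targets, successes and
failures alike.

# Problem sizes and reproducibility of the validation

The test suite validates parameter recovery at sizes chosen to make
sampling error small relative to the tolerances: 5,000–10,000 twin pairs
for correlation targets (Monte Carlo SE below 0.01), 1,000 retest
subjects for reliability, n = 1189 with 37 measures for the nine-factor
retention check, and 2,000+2,000 pairs with 50 bootstrap iterations per
model for the weight-profile agreement checks (mean weight profiles are
stable well below the default 1000 iterations, which remain the analysis
default). Falconer recovery at 5000+5000 pairs has per-measure SE ≈ 0.03,
so the ±0.05 per-measure recovery check is asserted on estimates averaged
over three seeded replicates, whose SE ≈ 0.017. Every stochastic test
fixes its seed.

# Known limitations

* Moment estimators only: no maximum-likelihood SEM variance components,
  no confidence intervals on $h^2$ beyond bootstrap-over-pairs hooks.
* The genetic-correlation decomposition inherits all Falconer
  assumptions and masks rather than models out-of-range heritabilities.
* Classifier-weight profiles are *qualitative* rankings; their scale is
  not an estimate of $h^2$.
* The simulator's Gaussian, complete-case world understates the
  difficulties of real batteries (ordinal scales, missingness, outliers).
* Identification assumes one true match per target; household/sibling
  structure beyond twins is out of scope.
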