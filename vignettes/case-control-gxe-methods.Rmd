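---
title: "Methods: case-control SNP association and gene-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP association and gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgxe)
```

This vignette documents the statistical machinery of `snpgxe`: the models
and their assumptions, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the numerical
and design choices made where the methodology left them open.

## The setting

The package serves candidate-SNP case-control studies: a few biallelic
variants genotyped in unrelated cases and controls, binary lifestyle and
serological covariates, and a continuous age used only for adjustment. Its
reference application is a study of three regulatory variants of *ARID1B*
in hepatocellular carcinoma (611 cases / 614 controls), whose published
summary tables ship with the package (`hcc_genotype_counts()` and
friends). Individual-level data for that study were never deposited, which
shapes the package in two ways: every crude statistic is computable from
the bundled counts, and everything that needs subject-level covariates
(adjusted ORs, adjusted interaction p-values) is validated by simulation
against known generating truth instead of against printed values.

## Genotype orientation and contrasts

Genotype calls are stored as copies of the alternate allele (0/1/2, `NA`
for failed calls). The odds-ratio baseline is an *explicitly declared*
homozygote (`variant_def(..., reference_genotype =)`), never the major or
minor homozygote inferred from frequency: in the reference study the
baseline for rs73013281 is CC although T is the majority allele, so
frequency-based inference would silently invert the reported contrasts.
The dominant model pools carriers of any non-baseline allele against the
baseline homozygote; the recessive model isolates the opposite
homozygote; the additive model uses the 0/1/2 dose of the non-baseline
allele; the codominant model fits both non-baseline genotype classes as
separate indicators.

Missing calls are handled complete-case *per test*: a subject missing one
variant's call still contributes to every other variant's table. This
mirrors how call rates below 100% give per-variant totals slightly under
the cohort totals.

## Contingency statistics

`pearson_chi2()` is the plain Pearson statistic on the product-of-margins
expectation with df = (r−1)(c−1) and **no continuity correction at any
table size**. The policy is pinned by a fixture: the study's gender table
prints χ² = 0.15, which is the uncorrected value (Yates would give ≈
0.10), and mixing corrected 2×2 with uncorrected 2×3 statistics would make
the permutation reference distributions inconsistent across codings. A
zero row/column margin is a hard error naming the degenerate margin.

`hwe_test()` estimates the allele frequency p̂ = (2n₂+n₁)/2N and compares
observed genotype counts with (q̂², 2p̂q̂, p̂²)·N by χ² on 1 df (one
parameter estimated). A monomorphic sample returns statistic 0 with a
flag rather than an error. The asymptotic test is the default because it
is the classical goodness-of-fit formulation; `exact = TRUE` switches to
the conditional exact test (heterozygote-count distribution given allele
counts), preferable when a genotype class is sparse. Note the bundled
control counts for rs73013281 give χ² ≈ 4.58 (p ≈ 0.032): the package
reports what the counts imply.

## Odds ratios

Crude ORs use the cross-product with the Woolf log-scale standard error
√(1/a+1/b+1/c+1/d), z = 1.959964 for 95% intervals, and a two-sided Wald
p. Any zero cell triggers the Haldane–Anscombe correction (+0.5 to all
four cells) and flags the result — this keeps the Woolf machinery defined
while making the approximation visible downstream.

`fit_logistic()` is a Newton–Raphson/IRLS maximum-likelihood fit:
convergence when the largest coefficient update < 1e-8 or the
log-likelihood change < 1e-10, capped at 100 iterations; the covariance is
the inverse observed information. Separation is detected as any
standardized coefficient beyond ±15 — such fits are returned flagged
non-converged, never silently. The test suite cross-checks coefficients,
standard errors and log-likelihood against `glm()` to 1e-6 and verifies
the saturated-model identity (a single binary predictor reproduces the 2×2
cross-product OR) on every bundled table.

`select_genetic_model()` fits all four codings and ranks converged fits by
AIC. The ranking criterion is a package choice: the model-selection recipe
used by the reference study is not described in its text, and AIC is
standard, penalises the extra codominant parameter, and is fully auditable
because all fits are returned.

## Permutation empirical p-values

`permutation_pvalues()` permutes case/control labels uniformly; genotypes
and covariates travel with the subject, preserving their joint
distribution, so exchangeability holds under the global null of no
phenotype association. All tests share one permutation stream, which is
what lets the correction account for correlation among linked variants.
The empirical p is (r+1)/(B+1) with r the number of permutations at least
as extreme as observed — the add-one rule keeps p off zero. B defaults to
10,000. Ties are counted with a 1e-9 relative tolerance: label-swapped
tables produce the same |z| only up to the last floating-point ulp, and an
exact comparison would systematically miss those ties and inflate the
empirical p.

Two discreteness facts matter when checking uniformity of the null
empirical p. With a single binary contrast the permutation distribution
lives on the hypergeometric support of one cell, so small cohorts have
large atoms; and with *exactly equal* case and control counts, mirrored
tables collapse to identical |z|, merging the two central atoms into one
carrying ~10–15% of the mass. The calibration checks therefore use
study-sized cohorts with unequal group sizes (as in the reference study's
611/614), where the empirical p is uniform to within atoms of ≤ 5% mass.

## Gene-environment interaction

The interaction module works on the dominant collapse of the genetic
factor (matching the reference study's stratified table) crossed with a
binary exposure whose reference level is configurable, so the baseline
cell is always (baseline homozygote, favourable exposure).

*Multiplicative*: a logistic model with G, E and G×E; the two-sided Wald p
of the product term. Without covariates this is the saturated 2×2×2 model,
and the product-term OR equals the ratio of stratum cross-product ORs
exactly (asserted to 1e-6 in tests).

*Additive*: RERI = OR₁₁ − OR₁₀ − OR₀₁ + 1 from the joint-exposure
indicator fit; zero under exact additivity of OR-scale excess risks. The
test is a nonparametric bootstrap resampling subjects with replacement
**within** phenotype groups — the case/control margins are fixed by the
retrospective design, so unstratified resampling would add spurious
margin variance. Percentile intervals (not BCa) are used for determinism
and simplicity; the two-sided p is 2·min(fraction ≤ 0, fraction > 0)
clipped to [2/n_boot, 1]; n_boot defaults to 10,000. AP (RERI/OR₁₁) and
the synergy index S are reported alongside but RERI drives the p-value.
With no adjustment covariates the per-resample RERI is computed in closed
form from the 2×4 cell counts (a multinomial draw per phenotype group),
which is exactly the saturated logistic fit at a fraction of the cost;
with covariates every resample is refit and >1% non-convergence aborts
with a diagnostic. The bootstrap construction behind the reference
study's printed additive p-value is not described in its text, so printed
interaction p-values are treated as non-reproducible; the implementation
is instead validated by its type-I error under RERI = 0 simulation.

## Haplotype EM

`em_haplotypes()` implements the classical EM for unphased diplotypes:
E-step weights each subject's compatible haplotype pairs by 2f_i f_j
(f_i² for homozygous pairs) normalised within subject; M-step re-estimates
frequencies from expected haplotype counts; iteration stops when the
largest frequency change < 1e-8 (cap 10,000). The observed-data
log-likelihood is asserted non-decreasing at every iteration, and
frequencies remain on the simplex by construction. Because the likelihood
can be multi-modal at three or more loci, five starts are used by default
(uniform plus four seeded Dirichlet draws) and the best final likelihood
wins. EM replaces the external Bayesian phasing tool used by the
reference study: downstream analyses need only frequencies, not
individual phases, and a deterministic in-package estimator is testable
against an exhaustive oracle. The oracle (in the test suite) grids the
4-haplotype simplex at step 0.01 — about 1.8e5 points, the finest grid
that enumerates in reasonable time — refines the best point with a
softmax-parameterised Nelder–Mead, and requires the EM likelihood to be
at least the oracle's minus 1e-6.

Subjects missing any call in the haplotype block are excluded; no
imputation is attempted inside EM. Haplotype-level ORs are computed from
*expected* haplotype counts, so their Woolf CIs understate uncertainty;
every such result carries an `em_based` flag. D′ is reported as |D|/Dmax
in [0,1] and r² as D²/(p_A p_a p_B p_b); both are invariant to allele
labelling, and a monomorphic locus is an explicit error.

## The synthetic cohort generator

`simulate_cohort()` draws a prospective population — HWE genotypes at
configured allele frequencies (or diplotypes from multi-locus haplotype
frequencies, which induces LD), Bernoulli covariates (independent by
default, optionally coupled pairwise at a configured odds ratio via the
Plackett construction), Gaussian age — assigns disease by a logistic
model, and rejection-samples to exact case/control quotas. This makes
every configured OR directly interpretable: it is the prospective
disease OR, and the case-control estimators are tested for recovering it.
Interactions can be configured on the multiplicative scale (a product-term
log-OR) or the additive scale, where the joint-cell log-odds is solved so
that the model's RERI at baseline covariates equals the target.

Defaults are the reference study's conditions: 611/614 subjects, the three
variants at their control-group alternate-allele frequencies (0.698,
0.919, 0.932), covariate prevalences from the published control column,
age ~ N(55.9, 12.1) years. A draw cap (default 2000× the target size)
turns a hopeless baseline risk into an informative error.

What the generator does *not* emulate: the age/gender frequency-matching
algorithm (matching is emulated by drawing both groups from one
population, not re-implemented), population stratification/admixture, and
the real cohort's unknown covariate correlation structure (the coupling
option exists but defaults to independence). Passing simulation tests
therefore demonstrates estimator correctness under the stated generating
model — not robustness to confounding structures the generator cannot
produce.

`estimate_power()` is the simulation analogue of a power calculation:
the rejection fraction of the crude Wald test at level α over `n_sims`
generated cohorts, with the binomial Monte-Carlo standard error. The
reference study's printed power figures are not comparison targets: their
α, genetic model and computing method are unstated.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to give informative Monte-Carlo
precision while keeping the suite quick: null-permutation uniformity uses
200 replicates × 500 permutations at 611/614 (KS at α = 0.01); the
additive-bootstrap type-I check uses 500 replicates of 600/600 cohorts
with 1,000 resamples each (tolerance ±2% around α = 0.05); OR recovery
averages 200 replicates; Woolf coverage uses 2,000 tables at 600/600; the
EM oracle runs on ≤20-subject two-locus instances where exhaustive search
is exact. Production analyses should keep the 10,000-permutation /
10,000-bootstrap defaults.

## Known limitations

- Adjusted ORs for the reference study cannot be reproduced to printed
  precision — the joint covariate distribution is not recoverable from
  published margins; the adjusted machinery is validated by parameter
  recovery instead.
- Haplotype ORs from EM expected counts understate uncertainty (no
  phase-uncertainty propagation into the CI).
- The permutation correction is per-test empirical p, not a max-T
  family-wise procedure.
- Tabular input only (a handful of candidate SNPs); no VCF/PLINK parsing,
  no relatedness handling — all subjects are assumed unrelated.
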