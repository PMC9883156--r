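---
title: "Estimating assortative mating from chromosome-set polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating assortative mating from chromosome-set polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistic

Assortative mating (AM) — the tendency of phenotypically similar people to
pair — leaves a genomic footprint: trait-increasing alleles become
positively correlated *across* physically unlinked loci in the offspring
generation. This cross-locus correlation is gametic phase disequilibrium
(GPD). Because it spans chromosomes, it can be measured without any
partner data by splitting the genome into two disjoint chromosome sets,
building a polygenic score (PGS) on each, and regressing one on the
other:

$$\mathrm{PGS}_{odd} \approx \theta_{even\_to\_odd}\,\mathrm{PGS}_{even} + \mathrm{PCs}_{even},
\qquad
\mathrm{PGS}_{even} \approx \theta_{odd\_to\_even}\,\mathrm{PGS}_{odd} + \mathrm{PCs}_{odd}.$$

Both scores are z-standardized, so $\theta$ is a (PC-adjusted)
correlation. Under random mating and well-controlled stratification
$\theta$ is null; under AM it is positive. `estimate_gpd()` is the core
fit, returning a classed estimate with the coefficient, its standard
error, a two-sided Wald P value and a collinearity diagnostic.

Population stratification also correlates unlinked loci, so each
regression adjusts for principal components computed from *the
predictor-side chromosome set only*, mirroring the displayed equations
(adjusting both sides was deliberately rejected as a departure from the
estimator being reproduced). The default is 20 PCs per set;
`sweep_pc_adjustment()` re-fits across a 0–30 grid, because an AM signal
is stable in the number of PCs whereas a stratification artifact
collapses as PCs are added.

The two directional estimates differ only through which variants enter
each score; `select_conservative()` adopts the direction with the larger
variance (ties to even-to-odd). Per-trait differences
$\theta_{eo}-\theta_{oe}$ across traits are screened for a single
outlier with `grubbs_test()` (transchromosomal imbalance, e.g. when a few
strong-effect loci concentrate on one chromosome set and collide with
stratification; the VIF flag on each estimate reports the same risk at
the fit level).

## Out-of-sample orchestration

Scores must be built from effect sizes estimated in individuals disjoint
from those being scored, otherwise overfitting masquerades as GPD.
`run_logo()` implements the leave-one-group-out design: individuals are
split into ten random folds (sizes differing by at most one); per-variant
effects are estimated in nine folds (`run_gwas()`: per-variant OLS with
covariates; binary traits on the linear-probability scale), shrunk
(`shrink_effects()`), and used to score and fit both directional
regressions in the held-out fold, whose own genotypes also provide the
chromosome-set PCs. Fold estimates are pooled by inverse-variance
fixed-effect meta-analysis (`fixed_effect_meta()`), with Cochran's Q for
heterogeneity. Random-effects pooling is deliberately not offered.

`run_loro()` is the leave-one-region-out analogue over geographic
labels, to absorb geography-driven homogamy: effects are trained on all
other regions and the GPD is estimated within the held-out region, then
pooled. The exact original mechanics of the regional scheme are not
fully specified in public material; training-out-of-region with
in-region estimation is this package's documented interpretation, and
regions below a minimum size (default 100) are dropped with a warning.

Significance across a trait panel uses `bonferroni_threshold()`; for an
81-trait panel this is $0.05/81 = 6.2\times10^{-4}$.

## Stand-ins for biobank-scale components

Two production components are replaced by desk-scale equivalents behind
the same interfaces, so real outputs can be slotted in:

* Mixed-model association (sparse-GRM MLM) is replaced by OLS with
  covariates. Simulated samples are unrelated by design, so the GRM
  correction would be inert; `run_logo()` accepts precomputed summary
  statistics via `compute_pgs()` for pipelines that ran a real MLM.
* Bayesian continuous-shrinkage posterior effects are replaced by
  pluggable shrinkage: `empirical_bayes` (default) multiplies each
  estimate by $\hat\tau^2/(\hat\tau^2+se_i^2)$ with $\hat\tau^2$ from
  moment matching, `pt` applies P-value thresholding, `none` is the
  identity. The GPD statistic needs an unbiased-direction score, not an
  optimal one; empirical-Bayes shrinkage is always a contraction.

## Phenotype curation

`rint()` is the rank-based inverse normal transform
$\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with Blom offset
$c = 3/8$ (the prior literature this follows does not print the
constant; Blom's is the common default and the offset is configurable).
Ties get average ranks; missing values propagate. Questionnaire
encoders map dietary frequency to days/week (7 / 3.5 / 1.5 / 0) and
physical-activity categories to minutes/week
(210 / 140 / 105 / 70 / 45 / 30 / 0), with gymnastics counted at
half-length sessions, hence exactly half the value per category. Labels
are normalized case-insensitively with a small alias table.

## The forward simulator

`simulate_founders()` draws phased genotypes at Hardy–Weinberg
equilibrium; `sample_architecture()` picks M causal variants uniformly
with standard-normal effects on the standardized-genotype scale;
`simulate_phenotype()` builds $y_j = g_j + e_j$ with
$g_j = \sum_i W_{ij}\beta_i$,
$W_{ij} = (x_{ij}-2p_i)\,[2p_i(1-p_i)]^{-1/2}$, and
$e_j \sim N\!\big(0, \mathrm{Var}(g)(1-h^2)/h^2\big)$. Standardization
frequencies stay frozen at founder values across generations so genetic
values are comparable between generations; residual variance is
recalibrated each generation, which makes the realized (equilibrium)
heritability equal the nominal $h^2$.

Mate pairing targets a spousal phenotype correlation $r$ by noisy-rank
matching: each individual gets a matching score
$s = a\,z + \sqrt{1-a^2}\,\varepsilon$ with $z$ the standardized
phenotype, and partners are paired rank-adjacent on $s$ (male–female by
rank when sexes are used; sexes alternate at birth). The calibration is
$a(r) = \sqrt{|r|}$: under rank matching the partners share the score
$s$, and $E[z\,|\,s] = a s$ gives $\mathrm{Cov}(z, z') = a^2 = r$.
$r=0$ is uniform random pairing, $r=1$ exact rank matching; negative
$r$ pairs opposite-sorted halves. Iterative-swapping matching was
rejected as slower with no accuracy gain.

`reproduce()` transmits one recombinant gamete per parent: chromosomes
assort independently; within a chromosome, crossovers follow a Poisson
process along the physical map (default 1 expected crossover per
chromosome, uniformly placed). Because GPD is a cross-chromosome
statistic, within-chromosome map realism is secondary. The
implementation draws the Poisson increments of the crossover process
between adjacent variants and takes the parental-haplotype source as
(start + cumulative count) mod 2, which vectorizes over all gametes.

`simulate_stratified()` adds discrete structure: subpopulation
frequencies are Balding–Nichols draws around shared ancestral
frequencies (between-subpopulation variance `divergence * p(1-p)`),
truncated to (0.01, 0.99) to match a MAF ≥ 1% variant universe, with
per-subpopulation phenotype offsets and endogamous mating. A purely
environmental trait (`simulate_phenotype(pop, arch = NULL)`, giving
$y = \mathrm{offset} + N(0,1)$) combined with a nonzero trait shift is
the canonical stratification-confounded null: the score becomes an
ancestry proxy and the unadjusted $\theta$ is strongly positive with no
AM at all. With a literal zero-effect architecture the residual-variance
formula is kept as written (Var(g)=0 gives e=0), so the environmental
trait is a separate, explicit construction rather than a special case.

The simulator deliberately omits selection, mutation, migration between
subpopulations, realistic human linkage maps and the X chromosome.
Passing tests therefore demonstrate the estimator's behaviour under
clean Mendelian transmission with known AM — not robustness to
real-data complications such as linkage structure, relatedness,
genotyping error or phenotype measurement artifacts.

## Theory: the expected GPD at equilibrium

`expected_gpd()` evaluates the closed form

$$\theta = \frac{\rho f_0}{2-\rho(2-f_0)}
\left[1+\frac{M(1-\rho)}{n\,h_{eq}^2}
\left\{1+\frac{\rho f_0}{2(1-\rho)}\right\}^{-3}\right]^{-1},$$

with $\rho = r\,h_{eq}^2$, $f_{eq} = h_{snp}^2/h_{eq}^2$ and
$f_0 \approx f_{eq}/(1-\rho)$, exactly as printed in the source
derivation, with no higher-order correction. The first factor is the
infinite-GWAS limit (returned as an attribute); the finite-$n$ bracket
accounts for noise in estimated effects, so the value rises with $n$ and
falls with $M$.

One property of this closed form matters for simulator validation: the
$f_0 \approx f_{eq}/(1-\rho)$ step converts the equilibrium-measured
variance fraction to its base-generation counterpart under the implicit
assumption that the score's own captured variance does not inflate under
AM — accurate for sparse tagging scores and small $\rho$. For a score
built from the *complete* causal set with true effects, the correct
fraction is $f_0 = 1$, and the gametic variance-component recursions
give the exact equilibrium cross-half-genome correlation

$$\theta_\infty = \frac{\rho}{2-\rho},$$

implemented as `equilibrium_gpd_exact()`. At small $\rho$ the two
expressions agree to first order; at $\rho = 0.48$ (e.g. $r = 0.6$,
$h_{eq}^2 = 0.8$) the printed approximation gives 0.470 while the exact
complete-score limit is 0.316. The forward simulator converges to the
exact limit (a property test verifies this), which is the appropriate
benchmark in the complete-score regime; the printed approximation
remains the reported theory value, as in the source, and the
acceptance suite records the discrepancy rather than papering over it.

## Numerical choices

* HWE exact test: conditional test on allele counts, probabilities by
  the standard recurrence over same-parity heterozygote counts,
  accumulated in log space so biobank-scale counts stay finite;
  outcomes no more probable than observed (with a $1+10^{-9}$ relative
  tolerance) are summed.
* QC rules use strict inequalities exactly as printed (call rate
  < 0.99, MAF < 0.01, HWE P < 1e−6 exclude); a variant exactly at a
  threshold is retained.
* PCA: column-standardized dosages, monomorphic variants dropped,
  missing dosages mean-imputed; deterministic sign convention (the
  largest-magnitude loading of each component is positive) so runs are
  bit-reproducible. Estimates are invariant to PC sign flips regardless.
* Wald P values use the normal approximation (the intended large-n
  regime); the per-variant GWAS reports t-based P values.
* Missing dosages in scoring are mean-imputed per variant, matching
  common scoring-tool defaults.
* VIF of the score term against the PCs is reported on every estimate;
  VIF > 10 sets the collinearity flag.
* All randomness flows from a single seed; fixed seed implies
  bit-identical populations, fold assignments and estimates.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks run at sizes chosen to keep the default suite
fast while leaving the statistical conclusions unambiguous: equilibrium
AM runs use n = 4000 per generation, M = 500 causal variants over 22
chromosomes and 10 generations (20 replicate seeds); null calibration
uses 200 replicates of one generation of random mating from 4000
founders, estimated in an unrelated subset of n = 2000 (one offspring
per family — the Wald standard error assumes unrelated individuals,
which is also the pipeline's design premise, and sibships would
otherwise inflate the type-I error); stratification checks use two
subpopulations of
2000 with a 1000-variant panel; the LOGO negative control uses 20 seeds
of a 10,000-causal-variant trait (h² = 0.5) at n = 2000 with ten folds.
The acceptance script (`scripts/acceptance.R`) re-runs the same
computations from scratch at these sizes.

## Known limitations

* Predictor-side-only PC adjustment leaves a small residual when the
  score itself is an almost pure ancestry proxy: sample PCs recover
  ancestry with accuracy limited by n·Fst, and the unadjusted target
  score keeps its full ancestry loading. In fully confounded null
  simulations the adjusted estimate is attenuated by an order of
  magnitude but can remain marginally nonzero — the same mechanism the
  collinearity flag is there to surface.
* The empirical-Bayes stand-in shares only the direction-preserving
  property with continuous-shrinkage posteriors; absolute θ magnitudes
  from estimated-effect scores are not comparable across shrinkage
  methods.
* The closed-form theory value inherits the printed $f_0$
  approximation's bias outside the sparse-tag/small-ρ regime (above).
* One to ten generations of AM need not be at equilibrium; the
  simulator exposes `generations` rather than assuming equilibrium, and
  how many generations a real cohort's signal reflects is not
  identifiable from GPD alone.
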