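---
title: "Methods: climate-association scans for mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-association scans for mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human mitochondrial DNA is a small, maternally inherited, effectively
non-recombining genome: every site shares a single genealogy. Allele
frequencies therefore covary strongly with ancestry, and any attempt to
detect genotype-environment associations (GEA) — alleles whose frequencies
track climate beyond what shared ancestry explains — must model that
ancestry explicitly. `mtclimscan` implements such a scan: per-SNP binomial
generalized linear mixed models (GLMMs) with ancestry principal components
as fixed effects and a per-country random intercept, compared by
likelihood-ratio tests (LRTs) under family-wise Bonferroni control, with a
tree-based subsequent test as an independent line of evidence. A coalescent
simulator with known injected effects provides the ground truth on which
the whole pipeline is calibrated.

## Curation model

Input is a gapped multi-FASTA alignment containing a designated reference
row (for real mtDNA, the rCRS). Curation follows three rules, each with a
fixed convention:

* **Iterative gap curation** (`gap_threshold = 0.9997`): a column where the
  reference carries a gap and more than 99.97% of sequences carry a gap is
  treated as a spurious private insertion; every non-reference sequence with
  a non-gap character in such a column is removed, all-gap columns are
  deleted, and the procedure repeats until stable. Deleting the emptied
  columns stands in for re-alignment: removing a private insertion's carrier
  leaves all other sequences' coordinates unchanged, so for
  substitution-only data re-alignment is a no-op. The procedure terminates
  (every iteration removes at least one sequence or stops) and is
  idempotent.
* **Variant extraction**: gaps are non-variants and `N` is missing; a site
  is emitted only where the reference base is A/C/G/T and at least one
  sequence carries a different base. Multi-allelic columns collapse to a
  binary reference/alternative coding because the scan models genotype as a
  binary response; the VCF writer still records every observed alternative
  allele. Genotypes are haploid (`GT` of `0`, `1` or `.`), the mtDNA
  convention.
* **Frequency and sampling filters**: minor allele frequency at least
  `5e-5` (the literal 0.005%; retained at the boundary), countries with at
  least 20 individuals retained, countries above 1,000 individuals reduced
  to a seeded uniform subsample of exactly 1,000. A configurable
  country-exclusion list supports robustness re-runs.

The MAF cutoff is configurable because 0.005% is unusually permissive
(at ~24k sequences it removes only singletons); we apply it literally.

## The mixed-model engine

For one SNP with binary genotype $y_i$, fixed design $x_i$ (intercept,
ancestry PCs 1-4, and 0-2 climate predictors) and country $g(i)$:

$$\operatorname{logit} P(y_i = 1) = x_i^\top \beta + u_{g(i)},
  \qquad u_g \sim \mathcal N(0, \sigma^2).$$

The marginal likelihood integrates each $u_g$ out; we maximise its Laplace
approximation. Implementation choices:

* **Inner loop**: penalised iteratively reweighted least squares (PIRLS)
  for $(\beta, u)$ jointly at fixed $\sigma$, with the random effects
  profiled out per group by a Schur complement; step-halving guards the
  penalised deviance. Conditional modes for the final objective are
  refreshed by a damped per-group Newton iteration — the per-group
  objective is strictly concave, so backtracking makes this globally
  convergent even at quasi-separated sites.
* **Outer loop**: derivative-free golden-section search over
  $\log\sigma \in [-4.5, 1.8]$ of the profiled Laplace objective
  (a grid pass brackets the optimum first). The $\sigma = 0$ boundary is
  always evaluated — there the model is an ordinary logistic regression,
  solved exactly by IRLS — and returned whenever it attains the larger
  objective, so boundary fits equal the logistic MLE to machine precision.
  An optional `method = "bobyqa"` refinement runs a joint
  bound-constrained quadratic-approximation polish over
  $(\beta, \log\sigma)$; on calibration studies it changes LRT p-values
  only marginally (see *Calibration*, below) at roughly ten times the
  cost, so the profiled search is the default.
* **Convergence and separation**: tolerance `1e-8` on the objective; up to
  3 restarts from perturbed starts; coefficient divergence (|β| > 40, the
  signature of separation at rare or perfectly clade-aligned sites) is
  reported as non-convergence, never silently accepted.
* **Oracle**: `loglik_quadrature()` evaluates the same marginal likelihood
  by 30-node adaptive Gauss-Hermite quadrature (recentred at the
  conditional mode, rescaled by the local curvature). It is exact to
  machine precision against direct numerical integration and is used only
  in tests. The Laplace error grows like $\sigma^2$ and shrinks with
  per-group size; on the package's toy fixtures (3-5 groups, 12-20
  observations each, $\sigma \le 0.3$) the two objectives agree within
  5e-3, and the tests probe exactly that regime.
* **Dispersion**: Pearson residual sum at the conditional modes divided by
  $n - p_{\text{fixed}}$. We chose not to count the random effect in the
  denominator; at scan sample sizes the difference is far below the 0.8
  filter threshold. Fitted probabilities at exactly 0/1 are capped with a
  warning.

## The scans

The **null model** per SNP is intercept + PC1-4 + country random intercept.
The **LatPrecip alternative** adds country-standardized latitude and annual
precipitation (LRT df = 2); the **PaleoBio alternatives** add one of 12
predictors each (df = 1): ten paleo-bioclimatic summaries (annual and
quarterly temperature and precipitation measures, temperature seasonality,
leaf-area index) plus endemic plant species and disease-outbreak counts.
SNPs whose null model fails to converge or has dispersion below 0.8 are
filtered before correction; the Bonferroni threshold is
$\alpha / n_{\text{tested}}$ (joint scan) or
$\alpha / (n_{\text{tested}} \times 12)$ (paleo scan) with $\alpha = 0.01$,
so `threshold × tests = alpha` exactly. Degrees of freedom equal the number
of fixed effects added, the natural default when nothing else
is specified.

Candidates are clustered by pairwise squared Pearson correlation of
genotype vectors: edges where $r^2 > 0.2$, clusters = connected components,
representative = smallest p (ties to the smaller site index). Connected
components are the single-threshold equivalent of hierarchical clustering
at a fixed cut, which keeps the rule order-free and deterministic. The
paleo scan assigns each candidate the predictor with the smallest p-value;
ties break by the declared predictor order. The overlap report
distinguishes shared candidates, linked candidates ($r^2 > 0.5$ with a
joint-scan candidate), and unshared ones.

Sequential PC-drop tests refit the alternative with each PC removed
(df = 1). Raw p-values are reported; the multiplicity correction for "at
least one PC significant" is left to the caller because the appropriate
test count depends on how many SNPs and PCs are in play. The environmental-
PC robustness check needs no special code: `environmental_pca()` scores can
be appended as one more predictor column and run through the same LRT
machinery.

## The tree test

A deliberately simplified subsequent test, not a port of any existing
tool: it preserves the logic — reconstruct genotype and phenotype over the
tree, score their co-distribution across branches, and compare against a
homoplasy-matched null — while fixing each ingredient to a standard,
testable primitive:

* genotypes: Fitch parsimony (bottom-up state-sets, top-down resolution,
  ties to state 0), verified against brute-force minima;
* phenotype (latitude, the single testable variable): squared-change
  parsimony, equivalently Brownian-motion ML states, by the standard
  two-pass linear scheme, verified against a direct weighted-least-squares
  solve; zero-length branches are jittered to 1e-9;
* score: absolute difference of branch-length-weighted mean phenotype
  between genotype-1 and genotype-0 branches, each branch carrying its
  child-end genotype and the mean of its endpoint phenotypes; undefined
  when every branch carries one genotype;
* null: the site's own parsimony event count re-placed on branches with
  probability proportional to branch length, toggling the subtended
  clades; empirical p with +1 smoothing,
  $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_{\text{sims}})$,
  so p is never 0.

The end product is a one-sided Wilcoxon rank-sum
test of whether p-values of SNPs linked to scan candidates ($r^2 > 0.5$)
are skewed low relative to unlinked SNPs.

## The generator and what it does (not) emulate

The generator produces: a Kingman coalescent genealogy (constant population
size — the simplest model that yields realistic shared-ancestry PCs);
per-site Poisson mutation on branches with toggling 0/1 states, so
designated sites (default: 10 of 200 at 20x rate) are strongly homoplasic;
country assignment that interpolates between monophyletic clades
(`mixing = 0`, obtained by cutting the ultrametric tree where exactly K
lineages exist) and uniform multinomial (`mixing = 1`), with
Dirichlet-skewed country sizes; climate predictors drawn from a
two-latent-factor correlation model in which latitude *is* the leading
(thermal) factor; and selection injected as independent per-individual
Bernoulli redraws around a logistic cline in one predictor — deliberately
breaking the site's linkage with the genealogy, mirroring the observation
that climate-associated mtDNA alleles recur on multiple branches.

Standard study conditions (the package defaults, used by the tests): 2,000
individuals, 40 countries, 200 sites, mutation rate 0.2 per site per
coalescent time unit, `mixing = 0.5` (the real data's degree of
clade-country concordance is not quantified; half-mixing is a deliberate
middle ground), skew 0.5, reference length 2,000, 5 private-insertion
sequences. Injected effects use common variants (MAF ≥ 0.1), matching the
observation that real candidates are not rare, with baseline frequency
clamped to [0.05, 0.95] so the logit is finite.

What the generator does **not** emulate: realistic human demography or
migration, empirical haplogroup frequencies, sequencing error beyond
private insertions, heteroplasmy, indel polymorphism, or raster-derived
climate (climate enters as a table by construction). Passing tests
therefore demonstrate statistical correctness and calibration of the
machinery under a faithful null of shared ancestry + recurrent mutation,
not that real mtDNA climate candidates would be recovered.

## Calibration, and one honest caveat

On fully null data at the standard conditions, roughly half the sites
survive the convergence and dispersion filters (real mtDNA data sets show
similar attrition), the scan produces no Bonferroni candidates in ~99% of
replicates, and the LRT p-value distribution is close to uniform — but the
tail is measurably inflated: the empirical rate of p < 0.05 sits around
0.07-0.08 rather than 0.05. The inflation is not an optimisation artifact:
the joint BOBYQA polish moves it only from ~0.086 to ~0.079 on matched
replicates, and refitting the same sites with `lme4::glmer` reproduces the
ours almost exactly. It is the expected small-sample behaviour of a
chi-square-referenced LRT for *country-level* predictors when the
effective replication is the number of countries (~37 after filtering),
not the number of individuals. The family-wise Bonferroni control — the
inference the scan actually uses — is unaffected in our studies. We report
this as measured rather than recalibrating (e.g. by a country-level
parametric bootstrap), which would depart from the method being
implemented.

## Numerical conventions

* PCA: mean-imputation of missing genotypes, plain covariance PCA (no
  allele-frequency scaling; unit-variance scaling available by flag), signs
  fixed by making each component's largest-magnitude loading positive.
* Predictors are z-scored over countries and broadcast to individuals;
  coefficients are reported on that standardized scale.
* LRT statistics are clamped at 0; an alternative below the null by more
  than 1e-6 triggers a warning after the engine's restarts.
* All randomness flows from explicit seeds through a deterministic
  sub-seed derivation; identical configuration and seed give byte-identical
  outputs, which the pipeline tests assert literally.

## Problem sizes used by the studies

Unit tests run toy fixtures (tens to hundreds of observations). The
acceptance studies use the standard conditions above: 100 null-scan
replicates for type-I calibration, 50 replicates each for detection power
(effect 2.0 log-odds per predictor SD) and predictor assignment (under
identity predictor correlation, the condition under which "the generating
predictor" is identifiable), 200 null re-placements for tree-test
uniformity, and one seeded end-to-end pipeline run with three injected
effects for the recall / false-positive / reproducibility check. The
`analysis/` scripts run the same machinery at the same scale as a
narrative workflow.

## Known limitations

* Single scalar random intercept; no crossed or nested effects.
* Binary response only; tri-allelic sites are collapsed.
* The tree test is a simplified subsequent test; equivalence with existing
  implementations is not claimed, and terminal/simultaneous test variants
  are out of scope.
* Chi-square LRT reference is anticonservative in the far tail at
  country-level replication (quantified above).
* The curation stage assumes substitution-dominated alignments; it does
  not genotype indels or handle circular-coordinate wrap-around.
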