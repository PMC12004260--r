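---
title: "Clumping-and-thresholding PRS with stratified case-control association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clumping-and-thresholding PRS with stratified case-control association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`prsct` implements a complete clumping-and-thresholding (C+T) polygenic risk
score workflow for testing genetic overlap between a base trait (summary
statistics from a GWAS, e.g. idiopathic pulmonary fibrosis) and a target
case-control trait measured at the individual level (e.g. COVID-19 severity
grades): allele harmonisation and QC, greedy LD clumping, p-value threshold
scanning for the best-fit score, age- and sex-stratified logistic association
with principal-component adjustment and liability-scale variance conversion,
sentinel/locus-exclusion sensitivity analyses, regulatory-domain gene
assignment with hypergeometric enrichment, pathway-restricted scores, and a
replication stage with frozen models. A liability-threshold simulator
generates every input with known ground truth so the whole pipeline is
testable without any external download.

# The score and its selection

The raw score of individual $j$ is
$$\mathrm{PRS}_j = \sum_{i=1}^{n} \beta_i \, G_{ij},$$
where $\beta_i$ is the base-GWAS log odds ratio of the effect allele of
variant $i$ and $G_{ij} \in [0,2]$ its dosage. Missing dosages are replaced
by the variant's sample mean at scoring time, never at read time. All scores
are standardised to z-scores with the sample ($n-1$) standard deviation, so
association effect sizes are odds ratios per standard deviation of the
score.

Variants enter the score in two steps:

* **Clumping.** Variants are visited by ascending base p-value (ties broken
  by position, then effect allele, so the result is independent of input row
  order). Each retained index variant removes all not-yet-processed variants
  on its chromosome within an inclusive 250-kb window whose dosage
  $r^2 \ge 0.1$. LD is measured as the squared Pearson correlation of target
  dosages (the target cohort is the LD reference; no external panel is
  used). A zero-variance dosage pair has $r^2$ defined as 0 — such variants
  are in any case removed by the MAF filter.
* **Thresholding.** For a grid of p-value cutoffs $P_T$, the model at $P_T$
  contains exactly the clumped variants with base $p \le P_T$. The scan
  fits each model's standardized score in the stratum's logistic model and
  keeps the model with the smallest Wald p-value; ties prefer fewer variants
  and then the smaller threshold. Thresholds that select the same variant
  subset share one fit.

Before either step, base records are harmonised against the target:
matching is on (chromosome, position, unordered allele pair), first with the
reported alleles, then with their strand complement; swapped orientations
negate the effect size; A/T and C/G pairs are dropped as strand-ambiguous
(their orientation cannot be inferred from the alleles); unmatched and
duplicated records are dropped. Every drop is logged with a reason code.
QC removes variants with minor allele frequency below 1% or imputation
quality below 0.3; both comparisons are strict, so values exactly at the
boundary are retained.

The default threshold grid is $\{5\times10^{-8}, 10^{-6}, 10^{-4}\}$ plus an
arithmetic grid with $5\times10^{-5}$ spacing up to 0.5, plus 1. The fine
spacing matters: best-fit thresholds of C+T analyses are often
interior values such as $2\times10^{-3}$ that a log-spaced grid would skip.
Examples in this vignette and the package tests use much coarser explicit
grids to keep runtimes in seconds.

# Stratified association

The discovery grid crosses three nested outcomes (hospitalisation, severe
illness, critical illness) with nine strata: the full sample, the two sexes,
the two age bands split at 60 years, and the four age-by-sex cells — 27
tests, flagged at the Bonferroni threshold $0.05/27$. Covariates follow the
stratification: the full sample adjusts for age, sex and 10 PCs; sex strata
for age and PCs; age strata for sex and PCs; age-by-sex cells for PCs only —
a stratified-on variable never reappears as a covariate.

Two design points were genuinely open and are resolved as follows:

* **Standardisation cohort.** z-scores are computed once on the outcome's
  full analysis sample and reused inside strata, so per-SD effects are
  comparable across strata that share a model. Standardising within each
  stratum instead is a one-line change (`standardize_idx`) and is exposed
  for sensitivity checks.
* **Scan granularity.** The threshold scan runs per stratum, not per
  outcome: different strata may legitimately select different thresholds,
  which is what per-stratum best-fit reporting implies.

Principal components are the top left singular directions of the
column-standardised dosage matrix restricted to an LD-pruned
($r^2 < 0.1$, 250 kb, position order, first-of-pair wins) variant subset;
the sign convention makes the largest-magnitude loading positive. Logistic
models are maximum-likelihood fits via iteratively reweighted least squares
(`stats::glm`); confidence intervals are Wald intervals
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$ (the CI construction is not
specified by typical C+T reports; Wald is the standard choice), and
non-convergence or separation is flagged in a `status` field rather than
returned as numbers.

Observed-scale variance explained is the incremental Nagelkerke pseudo-$R^2$
of the score (full model minus covariates-only model). It is converted to
the liability scale with the standard ascertainment correction
$$R^2_{liab} = R^2_{obs}\cdot
  \frac{K(1-K)}{\varphi(z_K)^2}\cdot\frac{K(1-K)}{P(1-P)},$$
with population prevalence $K$, sample case fraction $P$, and $z_K$ the
normal quantile at $1-K$. Default prevalences are 0.5% for hospitalisation
and, multiplying by the severe (59%) and critical (19%) shares of
hospitalised cases, 0.295% and 0.095%.

Sensitivity re-analyses reuse the same engine under modified masks:
excluding samples with chronic respiratory disease; restricting controls to
at-risk (non-hospitalised, phenotyped) individuals so population controls
contribute nothing; and the 90-day mortality outcome, flagged at the
nine-test threshold $0.05/9$. Locus exclusion removes a sentinel variant and
everything within an inclusive ±1 Mb flank on its chromosome, which also
removes LD proxies of the sentinel; sentinel-only models take exactly a
supplied list of published risk variants, optionally minus a designated
promoter variant.

# Pathway stage

Variants of the best whole-genome model map to genes through a simplified
basal-plus-extension regulatory rule: each gene owns a basal interval 5 kb
upstream to 1 kb downstream of its TSS (strand-aware), extended up to 1 Mb
per side but truncated at the nearest neighbouring basal domain. This is a
deliberate, configurable stand-in for web-tool regulatory annotations, which
cannot be redistributed; extended domains of adjacent genes may overlap, and
a variant maps to every gene whose extended domain contains it. Enrichment
of the mapped gene list is a one-sided hypergeometric test per gene set with
Benjamini–Hochberg control; the background universe is all genes of the
supplied annotation (not the genome), which is the defensible choice when
the annotation itself defines which genes could ever be hit. The top five
sets (by FDR, then p, then size — a deterministic order) get
pathway-restricted scores: the whole-genome model cut down to variants
mapping to the set's genes, refit in the same stratum model, reported at
nominal $p < 0.05$.

# What the simulator emulates

The generator produces the statistical structure the analysis assumes:

* **Genotypes.** A Gaussian copula: per LD block, a latent AR(1) normal
  vector (parameter $\rho$, so latent correlation decays as $\rho^{|i-j|}$)
  is thresholded at each variant's allele frequency to one haplotype; two
  haplotypes sum to a dosage. Blocks are laid end to end on one or more
  synthetic chromosomes, positions 1-based. This gives cheap, controllable
  $r^2$ decay — not a human LD spectrum.
* **Base GWAS.** Point-normal true effects (a `causal_fraction` of variants,
  rescaled so causal effects explain `h2_base` of a unit liability),
  reported with estimation noise of standard error
  $1/\sqrt{n_{base}\cdot 2p(1-p)}$ and two-sided Wald p-values. A fraction
  of records is emitted in swapped allele orientation to exercise
  harmonisation. True effects are returned alongside, so parameter-recovery
  tests can compare against truth.
* **Target cohort.** Target per-variant effects are a
  `rho_overlap`-correlated transform of the base true effects; the liability
  adds age and sex terms and Gaussian noise. Severity scales 0–4 are cut
  from the liability at empirical quantiles calibrated so case fractions of
  the phenotyped cohort match the scenario (defaults keep the observed
  composition: half of phenotyped patients hospitalised, of whom 59% severe
  and 19% critical — the same ratios that give the 0.295%/0.095% population
  prevalences). Critical = scale 4; severe = scales 3–4; hospitalised =
  scales 3–4 plus a configurable fraction (default one half) of scale-2
  patients, since no admission rule for moderate disease can be asserted
  from severity definitions alone. Unphenotyped population controls are
  appended as controls for every outcome with no severity scale. 90-day
  mortality is Bernoulli among critical cases and independent of the genetic
  score unless a coupling knob is set — matching the null mortality
  behaviour the analysis is expected to show — and is `excluded` for
  population controls.
* **Sentinel.** When requested, one common, well-imputed variant gets a
  large base effect (at least 5 standard errors, reported at genome-wide
  significance by construction) and a target effect of the *opposite*
  direction — a MUC5B-promoter-like configuration. Its imputation quality is
  pinned high deliberately: a designated sensitivity locus that randomly
  vanished at QC would make the locus-exclusion analysis meaningless.
* **Annotation.** Gene bodies and TSSs placed along the simulated
  coordinates, and gene sets of which the first preferentially contains the
  genes nearest to causal variants, so enrichment recovery has a known
  answer.

What passing tests on this simulator do **not** show: behaviour under
realistic human MAF/LD spectra, imputation error, cryptic relatedness,
ancestry admixture, or sex-chromosome variants. The simulator's population
is homogeneous, so principal components absorb noise rather than real
structure; the structure-recovery test for PCs uses a dedicated
two-subpopulation construction instead.

# Numerical and degenerate-input choices

* Variant identity is (chromosome, position, unordered allele pair) — never
  the rsID — making base/target matching robust to ID drift.
* Boundary semantics are inclusive where a window is involved
  ($|pos - pos_{index}| \le 250\,000$; locus flank $\le 1$ Mb) and strict
  for the QC filters (MAF $< 0.01$, info $< 0.3$ are dropped).
* Empty models raise a classed error that the scanner treats as "skip this
  threshold"; a scan in which no threshold fits raises its own error.
* Zero-variance scores (degenerate models) and quartile binning with heavy
  ties are errors, not silent `NaN`s.
* Every generator takes an explicit seed and is bit-reproducible; the
  genotype map, base-GWAS truth and target effects can be pinned separately
  from the individual-level draws, which is how a replication cohort shares
  the discovery genome and trait architecture while containing new
  individuals.

# Validation experiments and their scale

The package's acceptance experiments (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) use these problem sizes, chosen to
give stable Monte-Carlo estimates in a few minutes on one core:

* Type-I error: 40 cohorts of n = 5000 (1000 of them population controls),
  120 variants, fixed single-threshold model, 27 tests each. The null here
  is *exact*: no shared effects and no target-trait genetic variance. With a
  finite causal set, merely decorrelating base and target effects
  (`rho_overlap = 0`) leaves per-cohort chance alignment between score
  weights and redrawn target effects — a realized alternative, i.e. power,
  not test size. The complementary calibration check keeps target genetics
  and verifies the mean OR across cohorts is 1. For the same reason the
  type-I experiment fixes a single threshold: taking the best p over a
  scanned grid is a selection procedure, and its minimum is not a nominal
  test.
* Effect recovery: a per-SD log-OR of 0.1 planted through the
  package-computed standardized score on 20 cohorts of n = 20 000; the mean
  estimate must land within ±10% of truth.
* Quartile monotonicity (20 cohorts, n = 5000, planted log-OR 0.35),
  sentinel locus exclusion (20 cohorts, n = 4000, flipped sentinel), and
  causal-pathway recovery (10 cohorts, n = 2500, 20 random same-size gene
  sets each) check the qualitative behaviours the analysis relies on.

# Known limitations

Reference-panel LD, haplotype-phase-aware $r^2$, multi-ancestry LD,
penalised or Bayesian PRS weighting, survival modelling of mortality, and
meta-analysis across cohorts are out of scope. The regulatory-domain rule is
a simplification of curated annotation tools, and the enrichment background
is annotation-wide rather than genome-wide. Multi-allelic variant records
must be split upstream.
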