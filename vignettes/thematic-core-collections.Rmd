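---
title: "Thematic core collections: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thematic core collections: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coretheme` builds trait-directed core collections from a germplasm bank and
validates them against the entire collection. This vignette is the package's
account of the science behind each stage: the models fitted, the parameters
that matter, what the synthetic-germplasm generator does and does not
emulate, and the decisions taken where the procedure admitted more than one
reasonable design.

## 1. The mixed model and EM-REML

Quantitative traits from germplasm evaluations are observed in incomplete,
unbalanced multi-environment trials: an accession appears in some
location-years ("environments") and not others, inside blocks nested within
the trial. Per trait we fit

$$y = \mu + Zg + Wb + Ti + e,$$

with all effects random: $g \sim N(0, \sigma^2_g I)$ per accession,
$b \sim N(0, \sigma^2_b I)$ per block within environment,
$i \sim N(0, \sigma^2_{ge} I)$ per accession-by-environment cell, and
$e \sim N(0, \sigma^2_e I)$. The only fixed effect is the grand mean. The
model assumes independent, homoscedastic effects — no spatial field trend,
no pedigree or genomic relationship structure among the genotype effects,
and no fixed covariates; those are out of scope by design.

Variance components are REML estimates from EM iterations on Henderson's
mixed-model equations:

* per iteration the equations are assembled at the current variance ratios
  $\lambda_k = \sigma^2_e/\sigma^2_k$ and solved; the factor with the most
  levels (in practice the genotype-by-environment interaction) has a
  diagonal cross-product block and is absorbed via its Schur complement, so
  the dense solve is only as large as accessions + blocks + 1,
* EM updates $\sigma^2_k \leftarrow (\hat u_k'\hat u_k +
  \sigma^2_e\,\mathrm{tr}(C_{kk}))/q_k$ and
  $\sigma^2_e \leftarrow (y'y - \hat s'r)/(n-1)$ use exact block traces of
  the inverse coefficient matrix, computed through the same absorption,
* convergence is declared when the change in $-2\log L_R$ falls below
  `tol = 1e-6`, with a cap of 200 iterations; estimates are clamped at a
  floor of `1e-8` so a collapsing component cannot produce a singular
  system. Both constants are arguments of `fit_reml()` and are recorded in
  the fitted object together with the full likelihood trace (the test suite
  asserts the trace is non-decreasing, the EM guarantee).

EM-REML was chosen over average-information updates for robustness on the
sparse, unbalanced incidence structures germplasm data produce: EM steps
cannot overshoot into negative variances, at the cost of more (cheap)
iterations. Degenerate designs are handled by structure, not failure: a
single environment drops the interaction term, a single block level drops
the block term, and a factor whose incidence is confounded with the
residual (one record per level) is dropped with a logged warning;
zero-variance data returns every component at the floor.

BLUPs are the solutions of the same equations at the REML estimates
(`predict_blups()`), with a pseudo-inverse fallback (condition number
logged) for ill-conditioned systems. Accessions with no records for a trait
are absent from that trait's table rather than zero-filled. On any small
instance the solutions equal a dense, hand-assembled solve of the equations
to 1e-8 — this is enforced in the tests.

**Heritability.** The source procedure reports broad-sense $h^2$ without a
formula, so the package documents its own choice: the entry-mean form
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/n_{env} +
\sigma^2_e/(n_{env} n_{rep}))$, with $n_{env}$ and $n_{rep}$ defaulting to
the mean environment count per accession and mean records per
accession-environment cell observed in the data. It is exposed as
`heritability(vc, n_env, n_rep)` so any other convention can be computed.

## 2. Selection: ranking, eligibility, truncation

A theme is a named set of traits with directions (`"higher"`/`"lower"`),
optional hard filters, and a target size. The procedure never states how
multiple BLUPs are combined into one ordering, so the package uses an
equal-weight mean of per-trait ranks: it is scale-free, insensitive to
unequal BLUP variances across traits, and invariant under monotone
transforms of any single trait (a tested property). Per-theme weights are
exposed in `theme_config()` for users who want unequal emphasis.

Numerical conventions, all deterministic:

* per-trait ties receive average ranks; composite ties are broken by
  accession id, so repeated runs order identically,
* an accession with BLUPs for fewer than 50% of a theme's traits is
  excluded with a logged reason rather than imputed (`min_coverage`
  argument),
* hard filters (`<`, `<=`, `>`, `>=` on numeric values; `in` on class sets)
  remove accessions before truncation, each removal logged with the violated
  filter; an accession with no value for a filtered trait fails the filter,
  since it cannot demonstrate eligibility,
* truncation takes the top `n_target`; if fewer candidates remain, all are
  taken with a warning. Top-$k$ sets are nested in top-$(k+1)$ sets by
  construction.

## 3. Redundancy: IBS and pruning

Identity-by-state between accessions $a, b$ is the mean over loci called in
both of $1 - |d_a - d_b|/2$ — the average proportion of shared alleles on
dosage codes. Pairs above the threshold (default 0.95, the conventional
clone-detection cut) are duplicates. The computation uses indicator-matrix
cross-products with complete-case locus handling per pair; pairs sharing no
called locus are flagged missing. Diversity and kinship statistics refuse
mean-imputed matrices: imputation fabricates fractional heterozygotes and
would bias Ho and IBS.

Which member of a duplicate pair to drop is unspecified in the source
procedure; the package keeps the better-ranked member (preserving the
selection intent), breaking ties toward the lower accession id. Pruning is
a greedy pass over pairs in descending-IBS order; after the pass no
surviving within-collection pair exceeds the threshold, and no pair loses
both members to each other. Pruning is per collection, after truncation;
cross-collection duplicates are allowed, as the overlap analysis implies.
No backfilling to the target size happens by default (the source counts
show none); `backfill = TRUE` re-truncates from the ranked list and
re-checks the additions.

## 4. Diversity accounting

**Shannon–Weaver.** For each trait, $H' = -\sum_i p_i \ln p_i$ over class
frequencies, normalized by $\ln k$. For qualitative traits $k$ is the
descriptor's class count; quantitative traits are cut into $k = 6$
equal-width classes spanning the *entire collection's* range, and a
sub-collection is always binned against that scheme. Class $j$ covers
$(\min + (j{-}1)\,\mathrm{Amp}/6,\ \min + j\,\mathrm{Amp}/6]$ with class 1
closed at the minimum, so a value sitting exactly on a boundary belongs to
the lower class. The normalizing constant uses the number of *defined*
classes, not the classes realized in a subset — a collection that lost
classes is thereby penalized, which is what "monomorphism to maximum
diversity" should mean. A zero-range trait yields class 1 for everyone and
$H' = 0$, flagged monomorphic.

**Gene diversity.** Per locus with $\tilde n$ called individuals:
$H_o$ is the observed heterozygote fraction and
$H_s = \frac{\tilde n}{\tilde n - 1}\left(1 - \sum_i \tilde p_i^2 -
\frac{H_o}{2\tilde n}\right)$, the within-population gene diversity with
the Nei–Chesser small-sample correction (single-population setting), with
$F_{is} = 1 - H_o/H_s$ wherever $H_s > 0$. Loci with $\tilde n < 2$ are
excluded from $H_s/F_{is}$. Means are taken over loci with defined values;
because "mean Fis" has two conventions in the literature, both
$\overline{F_{is}}$ and $1 - \bar H_o / \bar H_s$ are reported.

**Allele retention.** The package counts distinct observed alleles summed
over loci (ref seen if any called dosage < 2, alt if any > 0) and reports
$100\cdot$ subset/reference, rounded to 2 decimals, via
`retention_percent()` — the percentage is well defined whatever the
counting unit of a published allele total may have been.

**Kappa.** Selection coincidence between collections is Cohen's kappa on
binary selected/unselected vectors over a common universe. The universe
defaults to all phenotyped accessions but is configurable, because
published kappa values are sensitive to that denominator and the
convention is often left unstated. Degenerate vectors (all or none
selected) give `NA`.

## 5. Ordination validation

PCA is an eigen-decomposition of the covariance (or correlation) structure,
with two reproducibility conventions: zero-variance features are dropped
when scaling, and each component is sign-fixed so its largest-magnitude
loading is positive. Genotype matrices are mean-imputed before ordination
(the only place imputed data is accepted); the phenotypic matrix is the
accession-by-trait BLUP table, standardized.

DAPC retains the minimal leading PCs reaching the variance fraction
(default 0.80), capped at $n - g - 1$ to avoid a saturated discriminant
(warned), then fits a linear discriminant with collections as a-priori
groups; discriminant axes number $\min(g-1, \text{PCs})$. Posteriors come
from the discriminant's Gaussian model. Accessions in several collections
get one label by theme priority order. `dapc_permutation_test()` provides a
label-permutation null for the reassignment accuracy with the add-one
p-value correction.

## 6. The synthetic-germplasm generator

The generator exists so that every downstream stage can be tested against
known truth. Its defaults are the package's study conditions: 300
accessions in 3 sub-populations at $F_{st} = 0.1$, 2,000 SNPs over 18
chromosomes with ancestral frequencies uniform on
$[\text{maf}, 1-\text{maf}]$ (maf 0.05), 5 planted clone pairs at 1%
per-locus discordance, trials in 4 environments with 2 blocks and variance
components $(\sigma^2_g, \sigma^2_b, \sigma^2_{ge}, \sigma^2_e) =
(1.0, 0.3, 0.5, 1.0)$, 10% missing phenotypes.

* **Genotypes** follow two-level Balding–Nichols sampling: population
  frequency $\sim \mathrm{Beta}(p(1{-}F_{st})/F_{st},
  (1{-}p)(1{-}F_{st})/F_{st})$ around the ancestral $p$, dosages
  $\sim \mathrm{Binomial}(2, \cdot)$. The source data are real accessions;
  this structure is the generator's own choice of a standard, analytically
  tractable model of substructure. A two-population run at $F_{st} = 0.2$
  reproduces its parameter under an independent Hudson estimator (tested).
* **Clones** copy a progenitor's row and flip each locus with probability
  $e$, a flip replacing the dosage by a uniform draw from the other two
  values. Under the dosage IBS metric the expected clone-pair similarity is
  $1 - e\,(3-h)/4$ for heterozygote fraction $h$ — about $1 - 2e/3$ —
  comfortably above 0.95 for $e \le 0.03$, which is the detection regime
  the redundancy stage assumes. A planted clone also inherits its
  progenitor's genetic value and interaction profile in the trial
  generator: duplicates in a bank are the same genotype under two names,
  and only with that coupling do duplicates co-select and exercise the
  pruning stage the way real selections do.
* **Trials** draw every effect from the generating mixed model; unbalance
  enrols each accession in each environment independently with probability
  0.7 (redrawn if an accession would appear nowhere), and records are then
  deleted completely at random at one global rate, keeping at least one
  record per accession. The source states its trials were unbalanced but
  not how; independent enrolment is configuration, not inference.
* **Qualitative scores** give each accession a latent class and perturb
  each year's observation away from it with probability 0.1 (uniform over
  the other classes), emulating the minor year-to-year fluctuations that
  data-mode aggregation absorbs. Mode ties are broken by most recent year,
  then lowest class code — an invented, documented convention.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: linkage disequilibrium between loci (loci are
independent), any genotype-phenotype linkage (genetic values are drawn
independently of the SNPs, except for the clone coupling), pedigree
structure, selection response across generations, missingness that is
informative rather than completely at random, and shared latent classes
between clones in the qualitative generator.

## 7. Problem sizes and determinism

Every generator and the pipeline thread a single integer seed; identical
seeds give byte-identical outputs, and the pipeline manifest records the
seed, parameters, input hashes and per-stage counts (initial − removed =
final per collection, a tested identity). The test suite runs at deliberate
scales — parameter recovery at 300 accessions × 4 environments × 2 blocks
over 10 seeds, oracle equality on 100 random panels up to 20 × 50,
clone detection at 300 × 2,000 — chosen to keep Monte-Carlo error well
inside the asserted tolerances while the whole suite stays fast.

## 8. Known limitations

* QC exposes `maf_min` (default 0.05) and `max_missing` (default 0.20); the
  source workflow's exact cut-offs are not recoverable from its description,
  so these defaults are the common reading of such filters, not a
  reproduction.
* Mean-dosage imputation is a deliberate simplification restricted to
  ordination; haplotype-aware imputation is out of scope, and diversity
  statistics always use raw calls.
* Univariate REML per trait; no multivariate shrinkage across correlated
  traits.
* Greedy duplicate pruning is not guaranteed to be a minimum removal set on
  pathological duplicate graphs (it is on chains, which is what clone
  clusters look like in practice; tested).
* Published kappa and allele-count totals depend on conventions (universe,
  counting unit) that the package parameterises rather than guesses.
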