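---
title: "Family-aware evaluation of polygenic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-aware evaluation of polygenic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprs)
```

## The problem famprs addresses

Polygenic risk scores (PRS) for breast cancer are usually validated in
population case–control designs, where confounding by ancestry and shared
environment is hard to exclude. A complementary design compares each
affected woman with her own unaffected female relatives: relatives share
ancestry and much of their environment, so a systematic PRS excess in
cases over their relatives is more directly attributable to the score
itself. famprs implements both arms — the population-level logistic/ROC
analysis and the within-family paired analysis — together with the
plumbing they need (weight-file scoring, allele harmonization, pedigree
relationship classification) and a fully synthetic cohort generator, so
the entire pipeline is testable without access to any restricted cohort.

## Scoring model

The raw score of individual $i$ is

$$\mathrm{PRS}_i = \sum_j d_{ij}\,\ln(\mathrm{OR}_j),$$

where $d_{ij} \in \{0,1,2\}$ is the dosage of the effect allele of
variant $j$ and the weight is the natural-log per-allele odds ratio from
the weight file. Scores are standardized to z-scores,
$z = (\mathrm{PRS} - \bar{\mathrm{PRS}})/s$, with mean and SD
(denominator $n-1$) taken over a reference set — all scored samples by
default, controls-only by option. All downstream inference uses
z-scores, so the choice of reference shifts and scales but never reorders
individuals.

### Allele harmonization

A weight file and a genotype panel rarely agree on allele labels.
`harmonize()` classifies each score variant as `matched` (panel counts
the effect allele), `allele_swapped` (panel counts the other allele;
dosage complemented as $2-d$ at scoring time), `strand_flipped` (labels
agree only after reverse complement, with the orientation recorded),
`ambiguous_dropped`, or `absent_from_panel`. A/T and C/G variants are
palindromic under reverse complement, so strand cannot be resolved from
labels alone; they are dropped by default (with a warning) rather than
guessed, because frequency-based resolution is out of scope and a wrong
guess flips the sign of the variant's contribution. Variants whose
alleles are irreconcilable even after flipping are also dropped, with a
distinguishing `note`.

### Missing dosages

The default `missing_policy = "skip"` omits a missing variant from that
sample's sum and reports `n_variants_used` per sample; this mirrors the
common practice of scoring with the subset of markers actually available
in a panel rather than imputing the absent ones. `"mean_dosage"`
(substituting the variant's mean dosage over non-missing samples) is
available when a fixed number of contributing variants is preferred.
The two agree exactly when nothing is missing, which the test suite
checks.

## Pedigree machinery

Kinship is computed by the standard recursion on the family graph:
founders are treated as unrelated and non-inbred
($\varphi(a,a) = 1/2$), and for $a$ with parents $f,m$,
$\varphi(a,b) = \tfrac12[\varphi(f,b) + \varphi(m,b)]$ whenever $b$ is
not a descendant of $a$, with unknown parents contributing zero. Degree
of relationship, however, is classified from the *path type* (parent,
full sibling, grandparent, half sibling, aunt/niece, ...), not from the
raw kinship value: inbreeding inflates kinship but should not promote,
say, a half-sister to first degree, because the analysis groups are
named relationship classes.

`enumerate_pairs()` builds the five within-family groups: full sisters,
mothers, daughters, first-plus-second-degree relatives, and all female
blood relatives. Each affected woman is paired once with every eligible
unaffected female relative in the group, so a case appears as many times
as she has relatives — deliberate repetition that mirrors the paired
design this package reproduces. Relatives by marriage (zero kinship)
never pair; individuals with unknown affection are excluded from both
sides. A `dedup_relatives` flag restricts each relative to her first
pair for sensitivity analyses of the over-representation this repetition
induces.

## Within-family inference

For each group, the paired differences $z_{\text{case}} -
z_{\text{relative}}$ enter a Wilcoxon signed-rank test: zeros are
dropped, absolute differences are ranked with midranks, and
$W = \min(W^+, W^-)$. The normal approximation uses

$$\mu_W = \frac{n(n+1)}{4}, \qquad
\sigma_W = \sqrt{\frac{n(n+1)(2n+1)}{24}}, \qquad
Z = \frac{W - \mu_W}{\sigma_W},$$

with $p = 2\Phi(Z)$, and the level-$\alpha$ acceptance region for $W$ is
$\mu_W \pm z_{1-\alpha/2}\,\sigma_W$ rounded half-away-from-zero to
integers (`critical_interval()`). Design choices worth stating:

* **Smaller-rank-sum convention.** $W$ is the smaller of the two rank
  sums, so $Z \le 0$ always; the separate `direction` field records which
  side dominated. This matches the convention of the widely used online
  calculators that report uniformly negative Z for two-sided tests.
* **No tie correction by default.** PRS are continuous, so exact ties
  among $|{\rm differences}|$ have probability zero; the uncorrected
  $\sigma_W$ is also what the reference arithmetic this package
  reproduces uses. A `tie_correction` flag subtracts
  $\sum_g (t_g^3 - t_g)/48$ for data with genuine ties.
* **Normal approximation at all $n$.** The analysis groups of interest
  have $n \ge 17$, where the approximation is adequate;
  `exact_permutation_p()` enumerates all $2^n$ sign assignments (for
  $n \le 20$) and serves as the oracle in the test suite, not as an
  analysis path.
* **Dependence caveat.** Pairs that share a case are not independent, so
  the nominal signed-rank level strictly applies only to designs with
  one pair per family; with repetition the test is best read
  descriptively. The type-I-error calibration experiment in the test
  suite therefore uses one sibling pair per independent family, the
  design under which the 0.05 nominal level is the correct reference.

## Population-level arm

Case/control selection applies the exclusion rules in a fixed order —
males; incomplete genetic or phenotypic records; controls with any
personal or family history; at most one control per family — and
reports a per-criterion removal tally. The one-per-family tie-break is
deterministic by default (oldest eligible woman, then lexicographic id):
an older unaffected control has survived more risk-years and is the more
informative single representative. A seeded random tie-break is
available; note that the oldest-first rule deliberately shifts the
control age distribution upward, which matters when age is itself a
predictor of interest.

Association is a maximum-likelihood logistic fit (`stats::glm`) of
status on the z-scored PRS, reported as the odds ratio per SD with a
Wald 95% interval $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Perfect
separation is detected and reported as an error rather than returning a
divergent estimate. Discrimination is the rank-based (Mann–Whitney) AUC
— the fraction of case–control pairs in which the case scores higher,
ties counted half — computed from midranks; the joint model adds age
linearly and evaluates the AUC of its fitted probabilities.

## Monogenic arm

`build_pathogenic_set()` merges two evidence sources over a candidate
gene list: predicted loss-of-function consequence (stop gained,
frameshift, essential splice, start lost) in a candidate gene, and a
pathogenic/likely-pathogenic ClinVar-style label. The default
`"shared"` mode requires both — the stricter reading of "compared and
merged; shared variants coded as pathogenic" — while `"union"` accepts
either source, since the looser reading is also defensible; both
behaviors are first-class and tested. `flag_carriers()` labels
heterozygous (dosage 1) and homozygous (dosage 2) carriers from hard
genotype calls only and recomputes each variant's allele frequency from
the panel as $(n_{het} + 2 n_{hom}) / (2 n_{called})$.

## The synthetic cohort generator

The generator is the stand-in for a family cohort this package cannot
ship: three-generation families (founder couple; their children with
founder spouses; grandchildren), unlinked variants gene-dropped from
Hardy–Weinberg founders (each non-founder inherits one allele drawn
uniformly from each parent's two), and a liability-threshold phenotype

$$L = \beta_1 z_{\mathrm{PRS}} + \beta_2 z_{\mathrm{age}} +
\sqrt{1 - \beta_1^2 - \beta_2^2}\,\varepsilon,
\qquad \text{affected} \iff L > \Phi^{-1}(1-K),$$

with $\mathrm{Var}(L) = 1$ so the prevalence $K$ maps to a fixed
threshold. Only women can be affected. Defaults are chosen to emulate
the cohort conditions this pipeline targets: $K = 0.0122$ (a 1.22%
prevalence among women), 313 score variants with centered-normal
weights of SD 0.05 (typical GWAS per-allele log-OR magnitudes), founder
allele frequencies uniform on (0.01, 0.5), 21 rare LOF variants with
frequencies log-uniform in [0.00037, 0.026] (rare-variant frequency
spectra are closer to log-uniform than uniform; both endpoints are
honored), and generation age bands of 70 ± 8, 47 ± 6 and 25 ± 5 years so
the case/relative mean ages land near the high-40s range typical of the
within-family groups. `liability_slope_for_or()` converts a target
per-SD odds ratio (e.g. 1.24) into $\beta_1$ by a deterministic
numerical search against logistic fits on a fixed simulated draw.

Everything is reproducible bit-for-bit from `sim_config(seed = )`: one
seed is set at the start of `simulate_cohort()` and all stages consume
the stream in a fixed order.

What the generator does **not** emulate — and hence what passing tests
do and do not show: there is no linkage disequilibrium (the unit of
analysis is the aggregate score, which does not require haplotype
structure), no ascertainment through clinical referral, no age-of-onset
hazard model (onset age is set to current age at simulation), and no
shared-environment variance component beyond what the shared genotypes
induce. Tests passing on this generator demonstrate the *arithmetic and
calibration* of the pipeline under a clean polygenic liability model,
not the field performance of any particular score in any particular
population.

## Numerical choices and degenerate inputs

* Critical bounds round half-away-from-zero (base `round()` would go
  half-to-even and disagree with the reference integer bounds).
* Zero paired differences are dropped before ranking; a group whose
  differences are all zero is an error, an empty pair group is a
  skipped row with a message, not a failure.
* Standardization requires at least two reference samples and nonzero
  variance; zero-variance predictors, single-class AUC inputs, and
  collinear joint-model designs are explicit errors.
* `gene_drop()` refuses individuals with exactly one known parent (the
  templates never produce them; external pedigrees may).
* Pedigree parsing rejects cycles, duplicate ids within a family, and
  parents of inconsistent sex; dangling parent references are demoted
  to founders with a warning rather than rejected, since truncated
  real-world pedigree extracts are common.

## Problem sizes used in the shipped experiments

The prevalence calibration uses a 200,000-draw liability sample; the
estimator-recovery experiment uses 500 replicate cohorts of 72 cases and
2,603 controls; the type-I-error calibration uses 2,000 replicate groups
of 25 independent sibling pairs (50,000 nuclear families gene-dropped in
one pass). These sizes give binomial/Monte-Carlo error bands a few times
narrower than the effects of interest while keeping the default test run
fast on a single core.

## Known limitations

* Degree classification recognizes named classes through grandparents,
  aunts/nieces and half-siblings; anything more distant is reported as
  degree `3+`/`other` without a finer label (great-grandmother, cousin,
  half-aunt, ...), which is sufficient for the five analysis groups.
* The harmonization report cannot rescue strand-ambiguous variants; on
  panels with many A/T–C/G markers a frequency-aware harmonizer would
  retain more of the score.
* The within-family test with repeated cases has no exact nominal level
  (see above); confidence in group-level conclusions should lean on the
  independent-pairs calibration plus the descriptive critical bounds.
* VCF input uses hard GT calls only; dosage-field (imputed) VCFs should
  be converted to the dosage-TSV dialect first.
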