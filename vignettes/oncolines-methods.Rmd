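---
title: "Models and methods behind oncolines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oncolines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolines)
```

`oncolines` characterizes cancer cell-line panels transcriptome-wide and
scores how faithfully each line models its disease-matched tumor cohort.
This vignette explains the models, the tunable constants, what the
synthetic-data generator does and does not emulate, and the design choices
made where a convention had to be fixed.

## Expression normalization: from TPM to nTPM

Between-sample comparability is obtained in two steps.

**pTPM.** Transcript-per-million values are restricted to protein-coding
genes and each sample is rescaled to sum to one million
(`to_ptpm()`). This removes differences caused by non-coding content.

**TMM.** A trimmed mean of M-values (`tmm_factors()`) rescales samples
against a reference column. For sample $k$ versus reference $r$, over
genes positive in both,

$$M_g = \log_2 \frac{x_{gk}}{x_{gr}}, \qquad
  A_g = \tfrac12 \log_2 \frac{x_{gk}\, x_{gr}}{10^{12}},$$

the most extreme 30% of $M$ on each side and 5% of $A$ on each side are
discarded, and the factor is $2^{\bar M_w}$ with $\bar M_w$ the
inverse-variance weighted mean of the surviving $M_g$ (delta-method
binomial weights; weighting on by default, `logratio_trim = 0.3`).
Dividing pTPM by these factors yields nTPM (`apply_tmm()`,
`normalize_ntpm()`).

Three conventions had to be fixed where the procedure is usually left to
an implementation:

* **Reference column.** The "median column" is interpreted as the sample
  whose upper-quartile expression over its detected genes is the median
  of those statistics across samples; ties go to the smallest sample ID
  (`select_tmm_reference()`). This is deterministic and matches the
  common implementation family.
* **Factor rescaling.** Factors are divided by their geometric mean so
  they multiply to one, making nTPM invariant (up to a global constant)
  to the reference choice.
* **Weight scale.** The delta-method weights are computed from each
  gene's within-sample proportion at a nominal depth of $10^6$. On pTPM
  input this is identical to the classic count formulation (and to
  `edgeR::calcNormFactors`, which a test verifies at $10^{-8}$), but it
  is invariant to per-sample rescaling, so TMM is an exact fixed point:
  recomputing factors on nTPM returns exactly one.

For the activity-inference branch the package uses median-of-ratios size
factors (`size_factors_median_of_ratios()`) followed by
$\log_2(x/s_j + 1)$ and per-gene centering (`log_center()`). The
$\log_2(x + 1)$ transform stands in for a variance-stabilizing
transform; it preserves the centered-linear-model contract that the
activity methods rely on and is documented as an approximation. The
median is the plain (arithmetic) median of ratios; this differs from a
log-space median only when the usable gene count is even.

## Gene classification

Detection is `nTPM >= 1` throughout — the boundary value counts as
detected, which is the only assignment that covers the cutoff
consistently in both taxonomies.

**Distribution** (`classify_distribution()`): *not detected* (no line),
*single* (one line), *some* (more than one but strictly fewer than a
third of lines), *many* (at least a third but not all), *all*. The
one-third boundary compares counts against $n/3$ as a real number. A
one-sample matrix with a detected gene reports *single*, following the
listed evaluation order.

**Specificity** (`classify_specificity()`), evaluated on per-disease
averaged profiles (CLDs, `aggregate_cld()`) in strict precedence order
with fold threshold 4 (inclusive) and ratio denominators clamped below
at 0.01 nTPM:

1. *enriched* — one detected group at least 4-fold above every other;
2. *group-enriched* — 2–10 detected groups whose **mean** is at least
   4-fold above the outside maximum;
3. *enhanced* — one or more detected groups at least 4-fold above the
   **mean** of the others;
4. *low-specificity* — detected somewhere;
5. *not detected*.

Two genuinely open readings were resolved as follows. The
group-enriched rule uses the group **mean** against the outside maximum
(the per-member reading is available via `group_rule = "all"`). The
greedy search — grow the candidate set from the highest-expressed groups,
accept the smallest qualifying size — is provably equivalent to an
exhaustive subset search for this rule: the top-$k$ set has the largest
mean and the smallest outside maximum of all $k$-sets, so it qualifies
whenever any $k$-set does. A test checks this equivalence against a
literal exhaustive oracle on random matrices. Note the precedence
consequence: a vector like $(10, 4, 1)$ is group-enriched (top-2 mean 7
$\geq 4 \times 1$), not enhanced; the enhanced branch requires that no
single group and no group set qualifies, as in $(10, 2.6, 2)$.

The union of enriched, group-enriched and enhanced genes of a group is
its **elevated set** (`elevated_set()`) — the group's expression
signature. Stage-level signatures use the same fourfold rule on stage
means within a cohort (`stage_signature()`).

## Cell-line prioritization

Each cancer cell line is scored against its disease-matched tumor cohort
by two metrics:

* **Correlation**: Spearman's $\rho$ between the line's nTPM profile and
  the cohort's per-gene mean, over the common genes (at least 100).
* **Enrichment**: the cohort's elevated-gene set is tested by preranked
  GSEA (`gsea_preranked()`) against the line's genes ranked by
  $\log_2\!\big((x_g + 1)/(b_g + 1)\big)$, where $b$ is the *disease
  baseline* — the unweighted mean over CLD mean profiles, so every
  disease contributes equally regardless of panel size. The pseudocount
  of 1 nTPM guards zeros and is config-exposed.

The enrichment score is the signed maximal deviation of the classic
running sum (hit increments proportional to $|s_g|$, miss decrements
$1/(n-m)$). Because a single ranked list admits no sample permutation,
the null is built from random same-size gene sets (1000 by default,
seeded); NES divides ES by the mean absolute null ES of matching sign,
and the one-sided p-value uses the matching-sign exceedance frequency
with +1 smoothing. Ties in the ranking are broken by gene ID so results
are bit-reproducible.

Ranks by descending $\rho$ and by descending NES are averaged
(`integrate_ranks()`); the final ordering breaks ties by higher $\rho$,
then ID, and the top 5 lines — plus anything tied with the fifth
combined score — are flagged selected. Stage- and subtype-level variants
(`prioritize_stage_or_subtype()`) repeat the procedure against stage
mean profiles and stage signatures, falling back to correlation-only
ranking (with a warning) when a stage has an empty signature.

One caveat worth knowing: permutation NES is only comparable across
lines whose ranking-statistic distributions are similar. On a noiseless
synthetic panel the unperturbed best line has near-zero statistics
outside the planted genes, which inflates its null and deflates its NES
even at ES = 1; under realistic noise the nulls align and the planted
best line wins the combined rank. This is why rank-recovery claims are
made in the noisy regime.

## Pathway and cytokine activity

Given centered log expression $x$ and a gene-by-signature weight matrix
$W$, three linear scores are computed per sample and signature: the
slope t-statistic of $x$ on one signature (`ulm_scores()`), the partial
t-statistics of a joint regression on all signatures (`mlm_scores()`,
$df = \text{genes} - \text{signatures} - 1$), and a weighted sum
standardized against a gene-label permutation null (`wsum_scores()`).
Each method's scores are standardized per signature across samples and
averaged into a consensus z (`consensus_scores()`); $|z| > 1$ flags
significance. The consensus construction (standardize, then unweighted
mean) is the simplest convention that satisfies the z-scale contract;
the aggregation formula was otherwise unspecified.

Cytokine-style scoring (`permutation_activity()`) fits a
ridge-penalised multivariate model per sample (default
$\lambda = 10^4$, config-exposed; tests assert rank stability across a
10-fold $\lambda$ range rather than a particular value) with a
10,000-permutation gene-label null; $p < 0.05$ flags significance.
Under gene exchangeability each permutation z is a standard-normal-scale
draw — "null" means centered at zero on average, not uniformly tiny.

Activity profiles are matched by mean squared error over shared
signatures (`activity_mse()`), and pathway- and cytokine-MSE ranks are
combined exactly like the two fidelity metrics
(`prioritize_by_mse()`).

## The synthetic-data generator

`generate_panel()` builds a multi-disease panel in which every
downstream claim has a planted truth. Expected expression is designed
per disease on a relative scale and converted to counts; counts are
negative binomial with $\mathrm{var} = \mu + \phi\mu^2$ ($\phi = 0$
degenerates to Poisson; `exact_library = TRUE` returns exact expected
counts for noiseless checks). Defaults: 4 diseases × 5 lines, 600
genes, baseline 20, library size $2\times10^7$, dispersion 0.1.

Planted structure, chosen to exercise every classifier branch:

* *enriched*: 15 genes per disease at 8× baseline (planted fold 8 —
  twice the classification threshold, so moderate noise cannot erase
  it);
* *group-enriched*: 5 genes per disease pair at 8× in both members;
* *enhanced*: 5 genes per disease at $4.5\times$ the mean of the other
  diseases while one other disease is raised to $1.5\times$ baseline.
  The raise factor matters: with the outside maximum at baseline the
  top-2 group would qualify as group-enriched and the planted label
  would be wrong; $1.5\times$ keeps the gene below both the enriched
  bound ($4.5\mu < 4 \times 1.5b$) and the group bound
  ($(x + 1.5b)/2 < 4b$) for every panel width of at least three
  diseases;
* *housekeeping* (20% of genes) and a low-expressed background, both
  uniform across diseases (low-specificity truth), and a not-detected
  block planted near 0.3 nTPM.

Column sums of the design are equalised by a small multiplicative
filler on the background block (far below the fold-4 threshold), so
per-sample rescaling to one million does not distort planted folds.

Cell-line identity is modelled as per-gene lognormal perturbation of
the disease profile, sd 0.8 on the log2 scale — cell lines of one
cancer type are substantially heterogeneous, and about one log2-fold
inter-line variation is a realistic magnitude. The perturbation is
mean-preserving across the perturbed lines of a disease, so CLD-level
truth stays exact. Line 1 of each disease is unperturbed: it is the
planted best model for the disease's pseudo-tumor cohort
(`generate_cohorts()`), which samples around the same disease design.
Line 2 carries the planted stage signature (40 reserved background
genes at 5×) on top of a mild (0.16 sd) perturbation, mirroring a model
line specific to one tumor stage: the second stage of each cohort
carries the same boost. With two planted lines per disease the
generator exercises both the cohort-level invariant (best line at
combined rank 1) and the stage-level one (stage line first for its
stage) without the two interfering — the stage boost actually *lowers*
the stage line's cohort-level NES because forty non-signature genes
crowd the top of its ranking.

`generate_signature_matrix()` builds the activity world: random gene
subsets with Gaussian weights, planted activities $\sim N(0,1)$, and
expression $W A^\top + \varepsilon$ with $\sigma = 0.1$ by default.

**What the generator does not emulate:** batch effects between panels
(none were needed for the data this pipeline targets), read-level
artifacts, transcript-length bias, correlated gene modules, tumor
stromal/immune admixture (purity is planted as an annotation, not as
mixed expression), and single-cell data. Passing recovery tests
therefore shows the pipeline is correct and well-calibrated under an
idealised generative model — not that real cell-line panels meet these
assumptions.

## Problem sizes and numerical choices

Simulations run at 600 genes, 4 diseases × 5 lines and 20-sample
cohorts — large enough that rank statistics are stable, small enough
that the full suite re-runs in minutes; the classifier itself is exact
at any size. Permutation counts are 1000 for pipeline runs and 10,000
where null calibration itself is being tested. Ratio denominators are
clamped at 0.01 nTPM; fold boundaries are inclusive; all tie-breaks
(gene ID, sample ID, higher ρ) are deterministic, and every random draw
derives from one integer seed via fixed sub-streams, so identical
configurations reproduce byte-identical outputs.

## Known limitations

* The classification depends on the panel's disease composition: adding
  or removing diseases changes CLD means and hence categories — the
  taxonomy is relative, not a gene property.
* Permutation NES is not comparable across ranking lists with very
  different statistic distributions (see above); the correlation metric
  carries no such caveat.
* The consensus activity z is a convention; other aggregations
  (weighted by method benchmark performance, rank-based) are defensible
  and would shift the |z| > 1 significance tally.
* With a single perturbed line per disease the mean-preserving
  constraint collapses the perturbation to zero; at least three lines
  per disease are needed for distinct line identities.
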