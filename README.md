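# oncolines

Transcriptome-wide characterization of cancer cell-line panels and
tumor-fidelity scoring of individual lines against disease-matched tumor
cohorts.

Cancer cell lines are the workhorse models of oncology, but lines carrying
the same disease label differ widely in how well their expression programs
reflect the tumors they are meant to model. `oncolines` implements, as a
tested and reusable R pipeline, the analysis chain needed to answer "which
of my cell lines best represents this cancer type?" from gene-level
expression alone:

1. **nTPM normalization** — TPM restricted to protein-coding genes and
   rescaled to one million per sample (pTPM), then trimmed-mean-of-M-values
   (TMM) scaling against a median reference column
   (`logratio_trim = 0.3`, weighted), giving cross-sample-comparable nTPM.
2. **Gene classification** — every gene is categorized by expression
   *distribution* across cell lines (not detected / single / some / many /
   all; detection cutoff 1 nTPM) and by *specificity* across disease-level
   averaged profiles, called CLDs (enriched / group-enriched / enhanced /
   low-specificity / not detected; fold threshold 4). The union of the
   first three categories forms a group's **elevated set** — its
   expression signature.
3. **Prioritization** — each line is scored against its matched tumor
   cohort by (a) Spearman correlation to the cohort mean profile and
   (b) preranked GSEA of the cohort's elevated set against the line's
   log2 fold changes over the disease baseline (NES from a seeded
   random-set permutation null). The two rank lists are averaged; the top
   5 lines (plus fifth-place ties) are selected. Stage- and
   subtype-level variants use fourfold stage signatures.
4. **Statistical comparison** — tumor-purity filtering (> 0.7),
   hypergeometric overlap tests with Benjamini-Hochberg correction,
   CLD-to-cohort correlation matrices with one-sided signed-rank
   matched-vs-unmatched tests, complete-linkage clustering on
   1 − Spearman's ρ, and a PCA first-neighbor check at 80% variance.
5. **Activity inference** — pathway activities as a consensus z of
   univariate, multivariate and weighted-sum linear models on centered
   log expression (significant when |z| > 1), cytokine-style activities
   from ridge regression with a 10,000-permutation null (significant when
   p < 0.05), and MSE-based matching of activity profiles.

A first-class **synthetic-data generator** plants known specificity
categories, best-matching cell lines, stage signatures and pathway
activities, so every stage of the pipeline is validated against ground
truth. The methods vignette (`vignettes/oncolines-methods.Rmd`) documents
the models, conventions and limitations.

## Worked example

```r
library(oncolines)

cfg     <- panel_config(seed = 11)            # 4 diseases x 5 lines, 600 genes
panel   <- generate_panel(cfg)
cohorts <- generate_cohorts(cfg, panel$truth) # matched pseudo-tumor cohorts

ntpm  <- normalize_ntpm(panel$tpm)
clds  <- aggregate_cld(ntpm, panel$annotation)
calls <- classify_genes(clds, sample_m = ntpm)
table(calls$specificity)
#>        enhanced        enriched  group-enriched low-specificity    not-detected
#>               8              64              12             360             156
```

At the default dispersion of 0.1 the classifier recovers the planted
categories at ~98% (the narrow-margin *enhanced* category absorbs most of
the disagreements; in noiseless mode recovery is exactly 100%). Scoring
the five D01 cell lines against their matched cohort:

```r
cntpm  <- normalize_ntpm(cohorts$tpm)
kept   <- filter_by_purity(cohorts$annotation)      # purity > 0.7
cmeans <- aggregate_cld(cntpm[, kept$sample_id],
                        data.frame(sample_id = kept$sample_id,
                                   disease = kept$cohort))
sig <- elevated_set(classify_genes(cmeans), "C_D01") # 25-gene cohort signature

pr <- prioritize_lines(
  ntpm[, panel$annotation$sample_id[panel$annotation$disease == "D01"]],
  cohort_mean_profile(cntpm[, kept$sample_id[kept$cohort == "C_D01"]]),
  sig, disease_baseline(clds), params = gsea_params(seed = 11),
  min_genes = 100)
pr[, c("cell_line_id", "rho", "nes", "adj_p", "final_rank", "selected")]
#>   cell_line_id   rho  nes   adj_p final_rank selected
#> 1      D01.L01 0.851 3.13 0.00794          1     TRUE
#> 2      D01.L02 0.873 2.75 0.00794          2     TRUE
#> 3      D01.L05 0.799 2.81 0.00794          3     TRUE
#> 4      D01.L03 0.792 2.84 0.00794          4     TRUE
#> 5      D01.L04 0.794 2.78 0.00794          5     TRUE
```

`D01.L01` — the line the generator planted as the cohort's best model —
takes final rank 1: it leads the NES ranking and the combined rank even
though `D01.L02` (the planted stage-specific line) edges it on raw ρ.
`run_all(run_config(synthetic = cfg))` chains all stages and returns a
structured report with category counts, per-cohort rankings, activity
tallies and recovery-versus-truth summaries.

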