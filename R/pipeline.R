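#' Pipeline run configuration
#'
#' Aggregates every tunable constant of the pipeline in one place:
#' detection cutoff (1 nTPM), specificity fold threshold (4), purity
#' threshold (0.7), consensus significance (|z| > 1), cytokine
#' significance (p < 0.05) and selection depth (top 5). Exactly one of
#' `synthetic` (a [panel_config()]) or `inputs` (a named list of file
#' paths: `tpm`, `annotation`, `cohort_tpm`, `cohort_annotation`,
#' `signatures`, `match_map`) must be given.
#'
#' @param synthetic optional [panel_config()] for a fully synthetic run.
#' @param inputs optional named list of input file paths.
#' @param cutoff detection cutoff on the nTPM scale.
#' @param fold specificity fold threshold.
#' @param purity tumor-purity threshold (strictly-above kept).
#' @param consensus_z consensus significance threshold on |z|.
#' @param cytokine_p cytokine permutation significance threshold.
#' @param top_k prioritization selection depth.
#' @param gsea a [gsea_params()] list.
#' @param samples_per_cohort pseudo-cohort size for synthetic runs.
#' @param n_stages stage labels per synthetic cohort.
#' @param activity_signatures,activity_genes,activity_genes_per_signature
#'   shape of the synthetic signature world.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @param seed integer master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, cutoff = 1, fold = 4,
                       purity = 0.7, consensus_z = 1, cytokine_p = 0.05,
                       top_k = 5, gsea = gsea_params(),
                       samples_per_cohort = 20, n_stages = 2,
                       activity_signatures = 5, activity_genes = 400,
                       activity_genes_per_signature = 40,
                       out_dir = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of `synthetic` or `inputs` must be given")
  thresholds <- c(cutoff = cutoff, fold = fold, purity = purity,
                  consensus_z = consensus_z, cytokine_p = cytokine_p,
                  top_k = top_k)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  structure(list(synthetic = synthetic, inputs = inputs, cutoff = cutoff,
                 fold = fold, purity = purity, consensus_z = consensus_z,
                 cytokine_p = cytokine_p, top_k = top_k, gsea = gsea,
                 samples_per_cohort = samples_per_cohort,
                 n_stages = n_stages,
                 activity_signatures = activity_signatures,
                 activity_genes = activity_genes,
                 activity_genes_per_signature = activity_genes_per_signature,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks ID consistency between matrices and annotations, unit
#' declarations and threshold sanity. Violations are returned, not
#' raised.
#'
#' @param cfg a [run_config()].
#' @param tpm,annotation optional already-loaded panel matrix and
#'   annotation to check (used for synthetic dry runs and by [run_all()]).
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
validate_inputs <- function(cfg, tpm = NULL, annotation = NULL) {
  v <- character()
  if (!is.null(tpm)) {
    if (any(tpm < 0))
      v <- c(v, "negative expression value in TPM matrix")
    if (!expr_unit(tpm) %in% c("TPM", "unknown"))
      v <- c(v, paste0("expected TPM unit, got ", expr_unit(tpm)))
    if (!is.null(annotation)) {
      miss <- setdiff(colnames(tpm), annotation$sample_id)
      if (length(miss))
        v <- c(v, paste0("annotation missing sample(s): ",
                         paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(cfg$inputs)) {
    absent <- !vapply(cfg$inputs, file.exists, logical(1))
    if (any(absent))
      v <- c(v, paste0("missing input file(s): ",
                       paste(unlist(cfg$inputs[absent]), collapse = ", ")))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Run the full characterization and prioritization pipeline
#'
#' Executes normalize, classify, compare, prioritize and activity stages
#' end to end and returns a structured report: per-category gene counts
#' for the panel classification, per-cohort prioritization tables,
#' significant-activity tallies and a provenance block. With a fixed
#' configuration and seed the report is identical across runs.
#'
#' @param cfg a [run_config()]; currently the synthetic branch generates
#'   its inputs from `cfg$synthetic`, while the file branch reads the
#'   paths in `cfg$inputs`.
#' @return a report list with elements `classification` (category counts
#'   and per-gene calls), `cld_cohort` (correlation matrix and matched
#'   tests), `rankings` (per-cohort prioritization data frames),
#'   `activity` (consensus tallies), `recovery` (planted-truth agreement,
#'   synthetic runs only) and `provenance`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$synthetic)) {
    panel <- generate_panel(cfg$synthetic)
    cohorts <- generate_cohorts(cfg$synthetic, panel$truth,
                                samples_per_cohort = cfg$samples_per_cohort,
                                n_stages = cfg$n_stages)
    tpm <- panel$tpm; ann <- panel$annotation
    cohort_tpm <- cohorts$tpm; cohort_ann <- cohorts$annotation
    truth <- cohorts$truth
  } else {
    chk <- validate_inputs(cfg)
    if (!chk$ok)
      stop("stage validate: ", paste(chk$violations, collapse = "; "))
    tpm <- read_expression_tsv(cfg$inputs$tpm, unit = "TPM")
    ann <- utils::read.delim(cfg$inputs$annotation, stringsAsFactors = FALSE)
    cohort_tpm <- read_expression_tsv(cfg$inputs$cohort_tpm, unit = "TPM")
    cohort_ann <- utils::read.delim(cfg$inputs$cohort_annotation,
                                    stringsAsFactors = FALSE)
    truth <- NULL
  }
  chk <- validate_inputs(cfg, tpm, ann)
  if (!chk$ok) stop("stage validate: ", paste(chk$violations, collapse = "; "))

  # normalize
  ntpm <- normalize_ntpm(tpm)
  cohort_ntpm <- normalize_ntpm(cohort_tpm)

  # purity filter on cohort samples
  kept <- filter_by_purity(cohort_ann, cfg$purity)
  cohort_ntpm <- expr_matrix(
    unname_attr(cohort_ntpm[, kept$sample_id, drop = FALSE]), unit = "nTPM")
  cohort_ann <- kept

  # classify
  clds <- aggregate_cld(ntpm, ann)
  calls <- classify_genes(clds, sample_m = ntpm, fold = cfg$fold,
                          cutoff = cfg$cutoff)
  cohort_means <- aggregate_cld(cohort_ntpm,
    data.frame(sample_id = cohort_ann$sample_id,
               disease = cohort_ann$cohort, stringsAsFactors = FALSE))
  cohort_calls <- classify_genes(cohort_means, fold = cfg$fold,
                                 cutoff = cfg$cutoff)

  # compare
  match_map <- if (!is.null(truth))
    data.frame(disease = names(truth$disease_cohort),
               cohort = unname(truth$disease_cohort), stringsAsFactors = FALSE)
  else
    utils::read.delim(cfg$inputs$match_map, stringsAsFactors = FALSE)
  corr <- cld_cohort_correlation(clds, cohort_means, match_map)

  # prioritize per cohort
  baseline <- disease_baseline(clds)
  rankings <- lapply(seq_len(nrow(match_map)), function(i) {
    d <- match_map$disease[i]; co <- match_map$cohort[i]
    lines <- ntpm[, ann$sample_id[ann$disease == d], drop = FALSE]
    sig <- elevated_set(cohort_calls, co)
    if (!length(sig)) return(NULL)
    cm <- cohort_mean_profile(
      cohort_ntpm[, cohort_ann$sample_id[cohort_ann$cohort == co],
                  drop = FALSE])
    pr <- prioritize_lines(lines, cm, sig, baseline, params = cfg$gsea,
                           top_k = cfg$top_k,
                           min_genes = min(100, nrow(ntpm)))
    pr$cohort_id <- co
    pr
  })
  names(rankings) <- match_map$cohort
  rankings <- Filter(Negate(is.null), rankings)

  # activity (synthetic signature world; for file runs, user signatures)
  sigworld <- generate_signature_matrix(
    n_genes = cfg$activity_genes, n_signatures = cfg$activity_signatures,
    genes_per_signature = cfg$activity_genes_per_signature,
    seed = .sub_seed(cfg$seed, 9L))
  x <- sigworld$expression; w <- sigworld$weights
  cons <- consensus_scores(list(
    ulm = ulm_scores(x, w), mlm = mlm_scores(x, w),
    wsum = wsum_scores(x, w, n_perm = 500, seed = .sub_seed(cfg$seed, 10L))),
    z_threshold = cfg$consensus_z)
  activity <- list(
    n_signatures = nrow(cons$z), n_samples = ncol(cons$z),
    total_entries = length(cons$z),
    significant_entries = sum(cons$significant),
    significant_fraction = mean(cons$significant))

  recovery <- NULL
  if (!is.null(truth)) {
    agree <- calls$specificity == truth$genes[calls$gene_id, "category"]
    top1 <- vapply(rankings, function(r) {
      co <- r$cohort_id[1L]
      r$cell_line_id[r$final_rank == 1L] == truth$cohort_best_line[co]
    }, logical(1))
    recovery <- list(classification_agreement = mean(agree),
                     best_line_top1 = mean(top1))
  }

  report <- list(
    classification = list(
      specificity_counts = as.list(table(calls$specificity)),
      distribution_counts = as.list(table(calls$distribution)),
      n_genes = nrow(calls), calls = calls),
    cohort_classification = list(
      specificity_counts = as.list(table(cohort_calls$specificity))),
    cld_cohort = corr,
    rankings = rankings,
    activity = activity,
    recovery = recovery,
    provenance = list(seed = cfg$seed,
                      n_samples = ncol(tpm),
                      n_cohort_samples = ncol(cohort_ntpm),
                      package_version = as.character(utils::packageVersion("oncolines"))))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report),
                                        c("cld_cohort", "rankings"))],
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(do.call(rbind, rankings),
                       file.path(cfg$out_dir, "rankings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
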