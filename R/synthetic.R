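#' Configuration for a synthetic cell-line panel
#'
#' Describes a multi-disease cell-line panel with planted expression
#' structure: per-disease enriched genes, group-enriched genes shared by
#' small disease groups, enhanced genes (elevated against the mean of the
#' other diseases but below the enriched threshold against the best single
#' one), housekeeping genes detected everywhere, a background of
#' low-specificity genes and a block of not-detected genes. The planted
#' category of every gene is returned as ground truth so downstream
#' classification, prioritization and activity inference can be validated
#' exactly.
#'
#' Counts are drawn from a negative binomial parameterised as
#' `var = mu + dispersion * mu^2`; `dispersion = 0` degenerates to Poisson,
#' and `exact_library = TRUE` additionally replaces sampling by the exact
#' expected counts (noiseless mode). The first cell line of every disease
#' receives no per-line perturbation and is therefore the planted best
#' model for that disease's pseudo-tumor cohort; the remaining lines get
#' mean-preserving lognormal per-gene perturbation of width
#' `line_perturb_sd` (log2 scale).
#'
#' @param n_diseases number of diseases (>= 2; >= 3 when enhanced genes
#'   are planted).
#' @param lines_per_disease cell lines per disease, scalar or vector.
#' @param n_genes total number of genes.
#' @param frac_housekeeping fraction of genes planted as housekeeping.
#' @param enriched_per_disease enriched genes planted per disease.
#' @param group_enriched_per_group group-enriched genes per disease group.
#' @param group_size diseases per group-enriched group (2 to 10).
#' @param enhanced_per_disease enhanced genes planted per disease.
#' @param fold_planted planted fold for enriched and group-enriched genes
#'   (must exceed the classification threshold of 4).
#' @param baseline_expression baseline relative expression level; after
#'   per-sample rescaling to one million this maps to the nTPM scale.
#' @param dispersion negative-binomial dispersion (>= 0).
#' @param library_size expected total counts per sample.
#' @param line_perturb_sd per-line lognormal perturbation sd (log2 scale)
#'   for non-best lines.
#' @param frac_not_detected fraction of the unplanted remainder planted
#'   below the detection cutoff.
#' @param exact_library replace count sampling by exact expected counts.
#' @param stage_genes_per_disease background genes reserved per disease as
#'   its planted stage signature (used by [generate_cohorts()]; the same
#'   genes are boosted in the disease's second line — mildly perturbed
#'   elsewhere — so stage-level prioritization has a matching model line
#'   without disturbing the best line's cohort-level fidelity).
#' @param stage_fold planted fold of the stage signature (> 4).
#' @param seed integer master seed; all sub-draws derive from it.
#' @return a validated list of class `panel_config`.
#' @export
panel_config <- function(n_diseases = 4, lines_per_disease = 5, n_genes = 600,
                         frac_housekeeping = 0.2, enriched_per_disease = 15,
                         group_enriched_per_group = 5, group_size = 2,
                         enhanced_per_disease = 5, fold_planted = 8,
                         baseline_expression = 20, dispersion = 0.1,
                         library_size = 2e7, line_perturb_sd = 0.8,
                         frac_not_detected = 0.4, exact_library = FALSE,
                         stage_genes_per_disease = 40, stage_fold = 5,
                         seed = 1L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              lines_per_disease = rep_len(as.integer(lines_per_disease),
                                          n_diseases),
              n_genes = as.integer(n_genes),
              frac_housekeeping = frac_housekeeping,
              enriched_per_disease = as.integer(enriched_per_disease),
              group_enriched_per_group = as.integer(group_enriched_per_group),
              group_size = as.integer(group_size),
              enhanced_per_disease = as.integer(enhanced_per_disease),
              fold_planted = fold_planted,
              baseline_expression = baseline_expression,
              dispersion = dispersion, library_size = library_size,
              line_perturb_sd = line_perturb_sd,
              frac_not_detected = frac_not_detected,
              exact_library = isTRUE(exact_library),
              stage_genes_per_disease = as.integer(stage_genes_per_disease),
              stage_fold = stage_fold,
              seed = as.integer(seed))
  if (cfg$n_diseases < 2L) stop("configuration error: need >= 2 diseases")
  if (cfg$enhanced_per_disease > 0L && cfg$n_diseases < 3L)
    stop("configuration error: enhanced genes need >= 3 diseases")
  if (cfg$group_size < 2L || cfg$group_size > 10L)
    stop("configuration error: group_size must lie in [2, 10]")
  if (cfg$group_size >= cfg$n_diseases && cfg$group_enriched_per_group > 0L)
    stop("configuration error: group_size must be below n_diseases")
  if (cfg$fold_planted <= 4)
    stop("configuration error: fold_planted must exceed the fold threshold of 4")
  if (cfg$frac_housekeeping < 0 || cfg$frac_housekeeping > 1)
    stop("configuration error: frac_housekeeping must lie in [0, 1]")
  if (cfg$dispersion < 0) stop("configuration error: dispersion must be >= 0")
  if (cfg$stage_genes_per_disease > 0L && cfg$stage_fold <= 4)
    stop("configuration error: stage_fold must exceed the fold threshold of 4")
  n_groups <- cfg$n_diseases %/% cfg$group_size
  planted <- cfg$n_diseases * (cfg$enriched_per_disease +
                               cfg$enhanced_per_disease) +
    n_groups * cfg$group_enriched_per_group +
    round(cfg$frac_housekeeping * cfg$n_genes)
  if (planted > cfg$n_genes)
    stop("configuration error: planted gene sets exceed n_genes")
  class(cfg) <- "panel_config"
  cfg
}

# Deterministic design shared by generate_panel and generate_cohorts:
# per-disease mean profiles in relative units with equalised column sums,
# plus the planted gene bookkeeping.
.panel_design <- function(cfg) {
  D <- cfg$n_diseases
  G <- cfg$n_genes
  b <- cfg$baseline_expression
  diseases <- sprintf("D%02d", seq_len(D))
  genes <- sprintf("g%04d", seq_len(G))

  n_groups <- D %/% cfg$group_size
  groups <- lapply(seq_len(n_groups), function(i)
    diseases[seq.int((i - 1L) * cfg$group_size + 1L, i * cfg$group_size)])

  idx <- 0L
  take <- function(n) {
    out <- genes[seq_len(n) + idx]
    idx <<- idx + n
    out
  }
  enr <- lapply(diseases, function(d) take(cfg$enriched_per_disease))
  names(enr) <- diseases
  grp <- lapply(seq_len(n_groups), function(i) take(cfg$group_enriched_per_group))
  enh <- lapply(diseases, function(d) take(cfg$enhanced_per_disease))
  names(enh) <- diseases
  hk <- take(round(cfg$frac_housekeeping * G))
  rest <- if (idx < G) genes[seq.int(idx + 1L, G)] else character(0)
  n_nd <- round(cfg$frac_not_detected * length(rest))
  nd <- rest[seq_len(n_nd)]
  bg <- setdiff(rest, nd)

  design <- matrix(b, G, D, dimnames = list(genes, diseases))
  hk_levels <- withr::with_seed(.sub_seed(cfg$seed, 1L),
    stats::runif(length(hk), 0.5 * b, 2 * b))
  design[hk, ] <- hk_levels
  bg_levels <- withr::with_seed(.sub_seed(cfg$seed, 2L),
    stats::runif(length(bg), 0.5 * b, 2 * b))
  design[bg, ] <- bg_levels
  for (d in diseases)
    design[enr[[d]], d] <- cfg$fold_planted * b
  for (i in seq_along(groups))
    design[grp[[i]], groups[[i]]] <- cfg$fold_planted * b
  # enhanced: target 4.5 x mean(others) with one other disease raised to
  # 1.5 x baseline, which keeps the gene below both the enriched and the
  # group-enriched thresholds for any D >= 3
  for (di in seq_len(D)) {
    d <- diseases[di]
    raised <- diseases[di %% D + 1L]
    mu_others <- b * (D - 0.5) / (D - 1)
    design[enh[[d]], raised] <- 1.5 * b
    design[enh[[d]], d] <- 4.5 * mu_others
  }

  # equalise column sums with a per-disease multiplicative filler on the
  # background block (stays far below the fold-4 threshold)
  if (length(bg)) {
    cs <- colSums(design)
    target <- max(cs)
    bsum <- colSums(design[bg, , drop = FALSE])
    design[bg, ] <- sweep(design[bg, , drop = FALSE], 2L,
                          1 + (target - cs) / bsum, "*")
  }
  # not-detected level chosen to land near 0.3 nTPM after per-sample
  # rescaling to one million
  if (length(nd)) {
    nd_level <- 0.3 * mean(colSums(design)) / 1e6
    design[nd, ] <- nd_level
  }

  truth_genes <- data.frame(
    gene_id = genes,
    category = "low-specificity",
    groups = "",
    stringsAsFactors = FALSE)
  rownames(truth_genes) <- genes
  for (d in diseases) {
    truth_genes[enr[[d]], "category"] <- "enriched"
    truth_genes[enr[[d]], "groups"] <- d
    truth_genes[enh[[d]], "category"] <- "enhanced"
    truth_genes[enh[[d]], "groups"] <- d
  }
  for (i in seq_along(groups)) {
    truth_genes[grp[[i]], "category"] <- "group-enriched"
    truth_genes[grp[[i]], "groups"] <- paste(groups[[i]], collapse = ";")
  }
  truth_genes[nd, "category"] <- "not-detected"

  # disjoint per-disease stage-signature blocks from the background pool
  k <- min(cfg$stage_genes_per_disease, length(bg) %/% max(1L, D))
  stage_genes <- lapply(seq_len(D), function(di)
    if (k > 0L) bg[seq.int((di - 1L) * k + 1L, di * k)] else character(0))
  names(stage_genes) <- diseases

  list(design = design, diseases = diseases, genes = genes,
       truth_genes = truth_genes, background = bg, housekeeping = hk,
       not_detected = nd, stage_genes = stage_genes)
}

# NB / Poisson / exact sampling of a count column around expected counts mu
.sample_counts <- function(mu, dispersion, exact) {
  if (exact) return(mu)
  if (dispersion == 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic cell-line panel with known ground truth
#'
#' See [panel_config()] for the planted structure. Returns raw counts, the
#' derived TPM matrix (per-sample scaling to one million), a sample
#' annotation table and the ground truth. A fixed seed gives bit-identical
#' output.
#'
#' @param config a [panel_config()] object.
#' @return list with `counts`, `tpm` (expression matrices), `annotation`
#'   (data frame: `sample_id`, `rrid`, `panel`, `disease`, `primary`,
#'   `site`, `lineage`) and `truth` (list: `genes` data frame of planted
#'   categories, `best_line` disease-to-line map, `design`).
#' @export
generate_panel <- function(config) {
  cfg <- if (inherits(config, "panel_config")) config else do.call(panel_config, config)
  des <- .panel_design(cfg)
  D <- cfg$n_diseases
  G <- cfg$n_genes
  sites <- c("lung", "liver", "bone", "brain", "lymph")

  cols <- list(); ann <- list()
  for (di in seq_len(D)) {
    d <- des$diseases[di]
    L <- cfg$lines_per_disease[di]
    # mean-preserving per-line perturbation: the first line is exact (the
    # planted best model), the second — the stage-matching line — gets a
    # mild perturbation, the rest the full width; factors are rescaled so
    # the within-disease mean profile stays equal to the design
    pert <- matrix(1, G, L)
    if (L > 1L && cfg$line_perturb_sd > 0) {
      sds <- rep(cfg$line_perturb_sd, L - 1L)
      sds[1L] <- 0.2 * cfg$line_perturb_sd    # line 2
      raw <- withr::with_seed(.sub_seed(cfg$seed, 100L + di),
        matrix(2^stats::rnorm(G * (L - 1L), 0,
                              rep(sds, each = G)), G, L - 1L))
      pert[, -1L] <- raw / rowMeans(raw)
    }
    stage_line <- min(2L, L)
    for (li in seq_len(L)) {
      prof <- des$design[, d] * pert[, li]
      # the stage line additionally expresses the disease's planted stage
      # signature, so stage-level prioritization has a matching model
      if (li == stage_line && length(des$stage_genes[[d]]))
        prof[des$stage_genes[[d]]] <- prof[des$stage_genes[[d]]] * cfg$stage_fold
      mu <- prof / sum(prof) * cfg$library_size
      cnt <- withr::with_seed(.sub_seed(cfg$seed, 1000L + 100L * di + li),
        .sample_counts(mu, cfg$dispersion, cfg$exact_library))
      id <- sprintf("%s.L%02d", d, li)
      cols[[id]] <- cnt
      ann[[id]] <- data.frame(
        sample_id = id, rrid = NA_character_, panel = "synthetic",
        disease = d, primary = li <= ceiling(L / 2),
        site = sites[(li - 1L) %% length(sites) + 1L], lineage = d,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- des$genes
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  tpm <- sweep(counts, 2L, colSums(counts) / 1e6, "/")
  best <- vapply(des$diseases, function(d) sprintf("%s.L01", d), character(1))
  stage_line <- vapply(seq_along(des$diseases), function(di)
    sprintf("%s.L%02d", des$diseases[di],
            min(2L, cfg$lines_per_disease[di])), character(1))
  names(stage_line) <- des$diseases
  list(counts = expr_matrix(counts, unit = "counts"),
       tpm = expr_matrix(tpm, unit = "TPM"),
       annotation = annotation,
       truth = list(genes = des$truth_genes, best_line = best,
                    stage_line = stage_line, design = des$design,
                    background = des$background))
}

#' Generate disease-matched pseudo-tumor cohorts
#'
#' One cohort per disease of the panel configuration, sampled around the
#' same per-disease design profiles so each cohort shares its disease's
#' planted elevated genes, with per-sample purity drawn uniformly from
#' `purity_range` and cyclic stage labels. When `n_stages >= 2`, one stage
#' (the second) carries the disease's planted stage signature (the
#' background genes reserved by [panel_config()]'s
#' `stage_genes_per_disease`, upregulated `stage_fold`-fold in that
#' stage's samples and in the panel's best line). The panel's unperturbed
#' first line per disease is recorded as the cohort's planted best cell
#' line.
#'
#' @param config the [panel_config()] used for the panel.
#' @param truth the `truth` element returned by [generate_panel()].
#' @param samples_per_cohort samples per cohort (>= 2).
#' @param purity_range tumor-purity interval within `[0, 1]`.
#' @param n_stages number of stage labels (>= 1).
#' @return list with `tpm` (cohort expression matrix), `annotation`
#'   (data frame: `sample_id`, `cohort`, `disease`, `purity`, `stage`) and
#'   `truth` (the input truth extended with `disease_cohort`, `best_line`
#'   per cohort and `stage` plantings).
#' @export
generate_cohorts <- function(config, truth, samples_per_cohort = 20,
                             purity_range = c(0.75, 1), n_stages = 2) {
  cfg <- if (inherits(config, "panel_config")) config else do.call(panel_config, config)
  if (samples_per_cohort < 2L)
    stop("configuration error: samples_per_cohort must be >= 2")
  if (n_stages < 1L) stop("configuration error: n_stages must be >= 1")
  des <- .panel_design(cfg)
  G <- cfg$n_genes
  stages <- sprintf("stage%d", seq_len(n_stages))
  planted_stage <- if (n_stages >= 2L) stages[2L] else NA_character_

  cols <- list(); ann <- list(); stage_truth <- list()
  for (di in seq_along(des$diseases)) {
    d <- des$diseases[di]
    cohort <- sprintf("C_%s", d)
    sgenes <- if (is.na(planted_stage)) character() else des$stage_genes[[d]]
    purity <- withr::with_seed(.sub_seed(cfg$seed, 6000L + di),
      stats::runif(samples_per_cohort, purity_range[1L], purity_range[2L]))
    for (si in seq_len(samples_per_cohort)) {
      stage <- stages[(si - 1L) %% n_stages + 1L]
      prof <- des$design[, d]
      if (stage %in% planted_stage && length(sgenes))
        prof[sgenes] <- prof[sgenes] * cfg$stage_fold
      mu <- prof / sum(prof) * cfg$library_size
      cnt <- withr::with_seed(.sub_seed(cfg$seed, 20000L + 1000L * di + si),
        .sample_counts(mu, cfg$dispersion, cfg$exact_library))
      id <- sprintf("%s.T%03d", cohort, si)
      cols[[id]] <- cnt
      ann[[id]] <- data.frame(sample_id = id, cohort = cohort, disease = d,
                              purity = purity[si], stage = stage,
                              stringsAsFactors = FALSE)
    }
    stage_truth[[cohort]] <- list(stage = planted_stage, genes = sgenes,
                                  line = unname(truth$stage_line[d]))
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- des$genes
  tpm <- sweep(counts, 2L, colSums(counts) / 1e6, "/")
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL

  cohorts <- sprintf("C_%s", des$diseases)
  names(cohorts) <- des$diseases
  best <- truth$best_line
  names(best) <- cohorts[names(best)]
  truth$disease_cohort <- cohorts
  truth$cohort_best_line <- best
  truth$stage <- stage_truth
  list(tpm = expr_matrix(tpm, unit = "TPM"), annotation = annotation,
       truth = truth)
}

#' Generate a signature weight matrix with planted activities
#'
#' Builds a gene-by-signature weight matrix (random gene subsets with
#' Gaussian weights), planted per-sample activities, and a centered-log
#' expression matrix `expression = weights %*% t(activities) + noise`.
#'
#' @param n_genes number of genes.
#' @param n_signatures number of signatures.
#' @param genes_per_signature nonzero weights per signature (>= 3, at most
#'   `n_genes`).
#' @param seed integer seed.
#' @param n_samples number of samples (default 50).
#' @param noise_sd Gaussian noise sd on the expression (default 0.1).
#' @return list with `weights` (genes x signatures), `activities`
#'   (samples x signatures) and `expression` (centered-log genes x
#'   samples).
#' @export
generate_signature_matrix <- function(n_genes, n_signatures,
                                      genes_per_signature, seed = 1L,
                                      n_samples = 50, noise_sd = 0.1) {
  if (genes_per_signature > n_genes)
    stop("configuration error: genes_per_signature exceeds n_genes")
  if (genes_per_signature < 3L)
    stop("configuration error: signatures need >= 3 genes")
  genes <- sprintf("g%04d", seq_len(n_genes))
  sigs <- sprintf("sig%02d", seq_len(n_signatures))
  samples <- sprintf("s%03d", seq_len(n_samples))
  w <- withr::with_seed(.sub_seed(seed, 1L), {
    w <- matrix(0, n_genes, n_signatures, dimnames = list(genes, sigs))
    for (s in seq_len(n_signatures)) {
      members <- sample.int(n_genes, genes_per_signature)
      w[members, s] <- stats::rnorm(genes_per_signature)
    }
    w
  })
  act <- withr::with_seed(.sub_seed(seed, 2L),
    matrix(stats::rnorm(n_samples * n_signatures), n_samples, n_signatures,
           dimnames = list(samples, sigs)))
  noise <- withr::with_seed(.sub_seed(seed, 3L),
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples))
  x <- w %*% t(act) + noise
  dimnames(x) <- list(genes, samples)
  list(weights = signature_matrix(w), activities = act,
       expression = expr_matrix(x, unit = "centered-log"))
}
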