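#' Preranked GSEA parameters
#'
#' @param weight_exponent exponent applied to the absolute ranking
#'   statistic in the running sum (default 1).
#' @param n_permutations size of the random-gene-set null (default 1000;
#'   at least 100).
#' @param seed integer seed for the permutation null.
#' @param pseudocount pseudocount added to numerator and denominator of
#'   the fold change in [ranked_fold_changes()] (default 1 on the nTPM
#'   scale).
#' @return a list of class `gsea_params`.
#' @export
gsea_params <- function(weight_exponent = 1, n_permutations = 1000,
                        seed = 1L, pseudocount = 1) {
  if (weight_exponent < 0) stop("weight_exponent must be nonnegative")
  if (n_permutations < 100) stop("need at least 100 permutations")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), pseudocount = pseudocount),
            class = "gsea_params")
}

#' Mean expression profile of a tumor cohort
#'
#' @param cohort nTPM expression matrix of cohort samples.
#' @return named per-gene arithmetic mean vector.
#' @export
cohort_mean_profile <- function(cohort) {
  if (ncol(cohort) < 1L) stop("need at least one sample")
  rowMeans(cohort)
}

#' Spearman correlation of cell lines to a cohort mean profile
#'
#' @param lines nTPM expression matrix of cell lines.
#' @param cohort_mean named per-gene mean vector (see
#'   [cohort_mean_profile()]).
#' @param min_genes smallest acceptable gene intersection (default 100).
#' @return named vector of Spearman rho, one per cell line.
#' @export
correlation_metric <- function(lines, cohort_mean, min_genes = 100) {
  genes <- intersect(rownames(lines), names(cohort_mean))
  if (length(genes) < min_genes)
    stop("gene intersection (", length(genes), ") below the floor of ",
         min_genes)
  drop(stats::cor(lines[genes, , drop = FALSE], cohort_mean[genes],
                  method = "spearman"))
}

#' Disease baseline expression
#'
#' The unweighted mean over CLD mean profiles — each disease contributes
#' equally regardless of how many cell lines it holds. This is the
#' denominator of the per-cell-line fold changes fed to preranked GSEA.
#'
#' @param clds nTPM matrix with one column per CLD (>= 2 columns).
#' @return named per-gene baseline vector.
#' @export
disease_baseline <- function(clds) {
  if (ncol(clds) < 2L) stop("need at least two CLD profiles")
  rowMeans(clds)
}

#' Rank genes of a cell line by log2 fold change over the disease baseline
#'
#' `stat_g = log2((x_g + pseudocount) / (b_g + pseudocount))`, sorted
#' descending with ties broken by gene ID for determinism.
#'
#' @param line named per-gene nTPM vector of one cell line.
#' @param baseline named per-gene baseline vector on the same genes.
#' @param params a [gsea_params()] list (only `pseudocount` is used).
#' @return named numeric vector of statistics, sorted descending.
#' @export
ranked_fold_changes <- function(line, baseline, params = gsea_params()) {
  if (!setequal(names(line), names(baseline)))
    stop("line and baseline must cover the same genes")
  baseline <- baseline[names(line)]
  stat <- log2((line + params$pseudocount) / (baseline + params$pseudocount))
  stat[order(-stat, names(stat), method = "radix")]
}

# Signed maximal deviation of the weighted running sum, computed from hit
# positions only: between hits the sum falls linearly, so the maximum is
# attained just after a hit and the minimum just before one (or at the
# ends, where the sum is 0).
.running_es <- function(w, pos, n) {
  m <- length(pos)
  hw <- w[pos]
  tot <- sum(hw)
  hw <- if (tot > 0) hw / tot else rep(1 / m, m)
  miss <- 1 / (n - m)
  cumhit <- cumsum(hw)
  drop_before <- (pos - seq_len(m)) * miss
  after <- cumhit - drop_before
  before <- cumhit - hw - drop_before
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment with a permutation null
#'
#' Classic running-sum enrichment: walking down the ranked list, hits
#' increment the sum proportionally to `|stat|^weight_exponent`
#' (normalized to sum to one over the set) and misses decrement it by
#' `1 / (n - set size)`. The enrichment score (ES) is the signed maximal
#' deviation. The null is built from `n_permutations` random gene sets of
#' the same size; NES is the ES divided by the mean absolute null ES of
#' matching sign, and the one-sided p-value is the matching-sign null
#' exceedance frequency with +1 smoothing on numerator and denominator.
#'
#' @param stats named numeric ranking statistics (any order; sorted
#'   internally, descending, ties by gene ID).
#' @param gene_set character vector of gene IDs; its intersection with
#'   `names(stats)` must be non-empty and not the whole universe.
#' @param params a [gsea_params()] list.
#' @return list with `es`, `nes`, `p_value`, `n_hits`.
#' @export
gsea_preranked <- function(stats, gene_set, params = gsea_params()) {
  ord <- order(-stats, names(stats), method = "radix")
  s <- stats[ord]
  n <- length(s)
  pos <- which(names(s) %in% gene_set)
  m <- length(pos)
  if (m == 0L || m == n)
    stop("gene set must hit at least one and fewer than all ranked genes")
  w <- abs(s)^params$weight_exponent
  es <- .running_es(w, pos, n)
  null_es <- withr::with_seed(params$seed,
    vapply(seq_len(params$n_permutations), function(i)
      .running_es(w, sort.int(sample.int(n, m)), n), numeric(1)))
  if (es >= 0) {
    same <- null_es[null_es >= 0]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(same >= es)) / (1 + length(same))
  } else {
    same <- null_es[null_es < 0]
    nes <- if (length(same)) -(abs(es) / mean(abs(same))) else NA_real_
    p <- (1 + sum(same <= es)) / (1 + length(same))
  }
  list(es = es, nes = nes, p_value = p, n_hits = m)
}

#' Integrate correlation and GSEA ranks for one cohort
#'
#' Cell lines are ranked by descending Spearman rho and by descending NES
#' (average ranks on ties); the combined score is the mean of the two
#' ranks. The final ordering is ascending by combined score, with ties
#' broken by higher rho and then lexicographic ID. The top `top_k` lines
#' are flagged selected, along with any line tied with the `top_k`-th
#' combined score.
#'
#' @param records data frame with columns `cell_line_id`, `rho`, `nes`
#'   (and optionally the other prioritization fields, which are kept).
#' @param top_k selection depth (default 5).
#' @return `records` with `rank_corr`, `rank_gsea`, `combined_rank`,
#'   `final_rank` and `selected` columns, sorted by `final_rank`.
#' @export
integrate_ranks <- function(records, top_k = 5) {
  if (anyNA(records$rho) || anyNA(records$nes))
    stop("every record needs both metrics (rho and NES)")
  records$rank_corr <- rank(-records$rho, ties.method = "average")
  records$rank_gsea <- rank(-records$nes, ties.method = "average")
  records$combined_rank <- (records$rank_corr + records$rank_gsea) / 2
  ord <- .tie_break_order(records$combined_rank, -records$rho,
                          records$cell_line_id)
  records <- records[ord, , drop = FALSE]
  records$final_rank <- seq_len(nrow(records))
  kth <- records$combined_rank[min(top_k, nrow(records))]
  records$selected <- records$final_rank <= top_k | records$combined_rank == kth
  rownames(records) <- NULL
  records
}

#' Score all cell lines of one cohort by both fidelity metrics
#'
#' For each cell line: Spearman correlation to the cohort mean profile,
#' and preranked GSEA of the cohort's elevated gene set against the
#' line's baseline-relative log2 fold-change ranking. GSEA p-values are
#' BH-adjusted across the cohort's lines, and ranks are integrated with
#' [integrate_ranks()].
#'
#' @param lines nTPM expression matrix of the cohort-matched cell lines.
#' @param cohort_mean named per-gene cohort mean vector.
#' @param signature character vector: the cohort's elevated gene set.
#' @param baseline named per-gene disease baseline (see
#'   [disease_baseline()]).
#' @param params a [gsea_params()] list.
#' @param top_k selection depth (default 5).
#' @param min_genes floor for the correlation gene intersection.
#' @return prioritization data frame (one row per cell line) with
#'   `cell_line_id`, `rho`, `es`, `nes`, `p_value`, `adj_p`, ranks and
#'   `selected`.
#' @export
prioritize_lines <- function(lines, cohort_mean, signature, baseline,
                             params = gsea_params(), top_k = 5,
                             min_genes = 100) {
  rho <- correlation_metric(lines, cohort_mean, min_genes = min_genes)
  gsea <- lapply(colnames(lines), function(cl) {
    stat <- ranked_fold_changes(lines[, cl], baseline, params)
    gsea_preranked(stat, signature, params)
  })
  records <- data.frame(
    cell_line_id = colnames(lines),
    rho = unname(rho[colnames(lines)]),
    es = vapply(gsea, `[[`, numeric(1), "es"),
    nes = vapply(gsea, `[[`, numeric(1), "nes"),
    p_value = vapply(gsea, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  records$adj_p <- bh_adjust(records$p_value)
  integrate_ranks(records, top_k = top_k)
}

#' Stage- or subtype-level cell line prioritization
#'
#' For every stage (or molecular subtype) label: cohort samples carrying
#' the label are averaged into a stage mean profile, the fourfold stage
#' signature is computed with [stage_signature()], and the cohort's cell
#' lines are prioritized against the stage exactly as at cohort level. A
#' stage whose signature is empty falls back to correlation-only ranking
#' with a warning.
#'
#' @param lines nTPM expression matrix of cohort-matched cell lines.
#' @param cohort nTPM expression matrix of cohort samples.
#' @param labels stage or subtype label per cohort sample (column order or
#'   named by sample ID).
#' @param baseline named per-gene disease baseline.
#' @param params a [gsea_params()] list.
#' @param top_k selection depth.
#' @return named list of prioritization data frames, one per label.
#' @export
prioritize_stage_or_subtype <- function(lines, cohort, labels, baseline,
                                        params = gsea_params(), top_k = 5) {
  if (!is.null(names(labels))) labels <- labels[colnames(cohort)]
  if (length(unique(labels)) < 2L) stop("need at least two labels")
  sigs <- stage_signature(cohort, labels)
  out <- lapply(unique(labels), function(lab) {
    stage_mean <- rowMeans(cohort[, labels == lab, drop = FALSE])
    if (!length(sigs[[lab]])) {
      warning("stage '", lab, "' has an empty signature; ",
              "correlation-only ranking")
      rho <- correlation_metric(lines, stage_mean)
      rec <- data.frame(cell_line_id = colnames(lines),
                        rho = unname(rho[colnames(lines)]),
                        es = NA_real_, nes = NA_real_, p_value = NA_real_,
                        adj_p = NA_real_, stringsAsFactors = FALSE)
      rec <- rec[.tie_break_order(-rec$rho, rec$rho, rec$cell_line_id), ]
      rec$rank_corr <- seq_len(nrow(rec))
      rec$rank_gsea <- NA_real_
      rec$combined_rank <- rec$rank_corr
      rec$final_rank <- rec$rank_corr
      kth <- rec$combined_rank[min(top_k, nrow(rec))]
      rec$selected <- rec$final_rank <= top_k | rec$combined_rank == kth
      rownames(rec) <- NULL
      return(rec)
    }
    prioritize_lines(lines, stage_mean, sigs[[lab]], baseline,
                     params = params, top_k = top_k)
  })
  names(out) <- unique(labels)
  out
}
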