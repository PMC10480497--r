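#' Merge two cell-line panels, averaging common lines
#'
#' Cell lines present in both panels are collapsed to a single column whose
#' per-gene expression is the arithmetic mean of the two measurements; the
#' merged column keeps the first panel's sample ID. The number of unique
#' samples is `ncol(a) + ncol(b) - nrow(common_ids)`.
#'
#' @param a,b nTPM expression matrices over the same genes.
#' @param common_ids data frame with columns `a` and `b` mapping sample IDs
#'   of panel `a` to their counterparts in panel `b`.
#' @return merged nTPM expression matrix.
#' @export
merge_panels <- function(a, b, common_ids = data.frame(a = character(), b = character())) {
  if (!setequal(rownames(a), rownames(b)))
    stop("panels must share the same gene set")
  b <- b[rownames(a), , drop = FALSE]
  if (!all(common_ids$a %in% colnames(a)))
    stop("common ID(s) absent from panel a: ",
         paste(setdiff(common_ids$a, colnames(a)), collapse = ", "))
  if (!all(common_ids$b %in% colnames(b)))
    stop("common ID(s) absent from panel b: ",
         paste(setdiff(common_ids$b, colnames(b)), collapse = ", "))
  out <- a
  if (nrow(common_ids))
    out[, common_ids$a] <- (a[, common_ids$a, drop = FALSE] +
                            b[, common_ids$b, drop = FALSE]) / 2
  rest <- setdiff(colnames(b), common_ids$b)
  out <- cbind(out, b[, rest, drop = FALSE])
  expr_matrix(unname_attr(out), unit = "nTPM")
}

#' Aggregate cell lines into disease-level profiles (CLDs)
#'
#' A CLD ("cell line disease") profile is the per-gene arithmetic mean of
#' the nTPM expression of all cell lines sharing a primary disease. Callers
#' are expected to have excluded non-cancerous and unannotated lines.
#'
#' @param m nTPM expression matrix of cell lines.
#' @param ann data frame with columns `sample_id` and `disease` covering
#'   every column of `m`.
#' @return nTPM expression matrix with one column per disease.
#' @export
aggregate_cld <- function(m, ann) {
  if (!all(colnames(m) %in% ann$sample_id))
    stop("annotation missing sample(s): ",
         paste(setdiff(colnames(m), ann$sample_id), collapse = ", "))
  dis <- ann$disease[match(colnames(m), ann$sample_id)]
  groups <- split(colnames(m), dis)
  empty <- lengths(groups) == 0L
  if (any(empty)) stop("empty disease group: ", names(groups)[empty][1L])
  out <- vapply(groups, function(s) rowMeans(m[, s, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(m), names(groups)))
  expr_matrix(out, unit = "nTPM")
}

#' Classify a gene's expression distribution across cell lines
#'
#' Counts the cell lines in which the gene is detected (expression at or
#' above `cutoff`, 1 nTPM by default) and assigns one of: `not-detected`
#' (none), `single` (exactly one), `all` (every line), `some` (more than
#' one but fewer than a third of the lines, strict), or `many` (at least a
#' third but not all). The single-sample edge case yields `single` when
#' detected, following the listed evaluation order.
#'
#' @param row numeric vector of per-sample expression for one gene.
#' @param cutoff detection cutoff on the nTPM scale (default 1; detected
#'   means at or above the cutoff).
#' @return list with `category`, `n_detected`, `n_samples`.
#' @examples
#' classify_distribution(c(0.5, 3, 8))
#' @export
classify_distribution <- function(row, cutoff = 1) {
  n <- length(row)
  if (n < 1L) stop("need at least one sample")
  k <- sum(row >= cutoff)
  category <-
    if (k == 0L) "not-detected"
    else if (k == 1L) "single"
    else if (k == n) "all"
    else if (k < n / 3) "some"
    else "many"
  list(category = category, n_detected = k, n_samples = n)
}

#' Classify a gene's expression specificity across groups
#'
#' Applies the five-category specificity taxonomy to a vector of per-group
#' mean expression (typically CLD or tumor-cohort profiles), evaluated in
#' precedence order:
#'
#' 1. **enriched** — one group is detected (at or above `cutoff`) and at
#'    least `fold` times higher than every other group;
#' 2. **group-enriched** — a set of 2 to `group_max` groups, all detected,
#'    whose mean is at least `fold` times the maximum outside the set (the
#'    set is grown greedily from the highest-expressed groups; the smallest
#'    qualifying set is reported — for this rule the greedy top-k set
#'    qualifies whenever any size-k set does);
#' 3. **enhanced** — one or more groups detected and at least `fold` times
#'    the mean of the remaining groups;
#' 4. **low-specificity** — detected in at least one group;
#' 5. **not-detected** — below `cutoff` everywhere.
#'
#' Denominators are clamped below at `clamp` (0.01 nTPM) so ratios against
#' unexpressed groups stay finite. The boundary is inclusive: a fold of
#' exactly `fold` qualifies.
#'
#' @param x named numeric vector of per-group expression (>= 2 groups).
#' @param fold fold-change threshold (default 4).
#' @param cutoff detection cutoff (default 1 nTPM).
#' @param clamp lower clamp for ratio denominators (default 0.01 nTPM).
#' @param group_max largest allowed group-enriched set (default 10).
#' @param group_rule `"mean"` (default) requires the group mean to exceed
#'   `fold` times the outside maximum; `"all"` requires every member to.
#' @return list with `category`, `defining_groups` (character vector,
#'   ordered by descending expression) and `fold` (achieved ratio for the
#'   defining rule, `NA` for the last two categories).
#' @examples
#' classify_specificity(c(A = 40, B = 5, C = 5))
#' classify_specificity(c(A = 40, B = 39, C = 5))
#' @export
classify_specificity <- function(x, fold = 4, cutoff = 1, clamp = 0.01,
                                 group_max = 10, group_rule = c("mean", "all")) {
  group_rule <- match.arg(group_rule)
  n <- length(x)
  if (n < 2L) stop("need at least two groups")
  if (is.null(names(x))) names(x) <- paste0("g", seq_len(n))

  # enriched: only the top group can qualify
  top <- which.max(x)
  denom <- max(clamp, max(x[-top]))
  if (x[top] >= cutoff && x[top] >= fold * denom)
    return(list(category = "enriched", defining_groups = names(x)[top],
                fold = unname(x[top] / denom)))

  # group-enriched: grow the set from the top; smallest qualifying size wins
  ord <- order(-x, names(x), method = "radix")
  for (s in seq_len(min(group_max, n - 1L))[-1L]) {
    S <- ord[seq_len(s)]
    if (x[S[s]] < cutoff) break   # sets are sorted; no larger set is all-detected
    out_max <- max(clamp, max(x[ord[-seq_len(s)]]))
    stat <- if (group_rule == "mean") mean(x[S]) else min(x[S])
    if (stat >= fold * out_max)
      return(list(category = "group-enriched",
                  defining_groups = names(x)[S],
                  fold = unname(stat / out_max)))
  }

  # enhanced: against the mean of the other groups
  ratios <- vapply(seq_len(n), function(g) {
    mg <- max(clamp, mean(x[-g]))
    unname(x[g] / mg)
  }, numeric(1))
  hit <- which(x >= cutoff & ratios >= fold)
  if (length(hit)) {
    hit <- hit[order(-x[hit], names(x)[hit], method = "radix")]
    return(list(category = "enhanced", defining_groups = names(x)[hit],
                fold = max(ratios[hit])))
  }

  if (any(x >= cutoff))
    return(list(category = "low-specificity", defining_groups = character(),
                fold = NA_real_))
  list(category = "not-detected", defining_groups = character(),
       fold = NA_real_)
}

#' Classify every gene of a grouped expression matrix
#'
#' Runs [classify_specificity()] on each row of a per-group (e.g. CLD or
#' cohort) nTPM matrix, and [classify_distribution()] on each row of an
#' optional per-sample matrix.
#'
#' @param group_m nTPM matrix with one column per group.
#' @param sample_m optional nTPM matrix with one column per sample, for the
#'   distribution taxonomy.
#' @inheritParams classify_specificity
#' @return data frame with columns `gene_id`, `specificity`,
#'   `defining_groups` (semicolon-joined), `fold`, and — when `sample_m` is
#'   given — `distribution`, `n_detected`.
#' @export
classify_genes <- function(group_m, sample_m = NULL, fold = 4, cutoff = 1,
                           clamp = 0.01, group_max = 10,
                           group_rule = c("mean", "all")) {
  group_rule <- match.arg(group_rule)
  calls <- lapply(seq_len(nrow(group_m)), function(i)
    classify_specificity(group_m[i, ], fold = fold, cutoff = cutoff,
                         clamp = clamp, group_max = group_max,
                         group_rule = group_rule))
  out <- data.frame(
    gene_id = rownames(group_m),
    specificity = vapply(calls, `[[`, character(1), "category"),
    defining_groups = vapply(calls, function(c)
      paste(c$defining_groups, collapse = ";"), character(1)),
    fold = vapply(calls, `[[`, numeric(1), "fold"),
    stringsAsFactors = FALSE)
  if (!is.null(sample_m)) {
    sm <- sample_m[rownames(group_m), , drop = FALSE]
    dist <- lapply(seq_len(nrow(sm)), function(i)
      classify_distribution(sm[i, ], cutoff = cutoff))
    out$distribution <- vapply(dist, `[[`, character(1), "category")
    out$n_detected <- vapply(dist, `[[`, integer(1), "n_detected")
  }
  out
}

#' Elevated gene set of a group
#'
#' The union of genes classified enriched, group-enriched or enhanced with
#' the given group among their defining groups. This union is the group's
#' expression signature (e.g. a tumor cohort's signature for preranked
#' GSEA).
#'
#' @param calls data frame from [classify_genes()].
#' @param group group label.
#' @param known_groups optional character vector of valid group labels used
#'   to validate `group`; defaults to all labels seen in `calls`.
#' @return character vector of gene IDs.
#' @export
elevated_set <- function(calls, group, known_groups = NULL) {
  seen <- unique(unlist(strsplit(calls$defining_groups, ";", fixed = TRUE)))
  valid <- if (is.null(known_groups)) seen else known_groups
  if (!group %in% valid)
    stop("unknown group label: ", group)
  elev <- calls$specificity %in% c("enriched", "group-enriched", "enhanced")
  hit <- vapply(strsplit(calls$defining_groups, ";", fixed = TRUE),
                function(g) group %in% g, logical(1))
  calls$gene_id[elev & hit]
}

#' Stage (or subtype) signatures within a cohort
#'
#' Genes with at least `fold` (default four) times higher mean expression
#' in one stage than in any other stage, and detected (mean at or above
#' `cutoff`), form that stage's signature.
#'
#' @param cohort nTPM expression matrix of cohort samples.
#' @param stage_labels stage (or molecular subtype) label per sample, in
#'   column order or named by sample ID.
#' @inheritParams classify_specificity
#' @return named list of gene-ID vectors, one per stage.
#' @export
stage_signature <- function(cohort, stage_labels, fold = 4, cutoff = 1,
                            clamp = 0.01) {
  if (!is.null(names(stage_labels))) stage_labels <- stage_labels[colnames(cohort)]
  stages <- unique(stage_labels)
  if (length(stages) < 2L) stop("need at least two stages")
  means <- vapply(stages, function(s)
    rowMeans(cohort[, stage_labels == s, drop = FALSE]), numeric(nrow(cohort)))
  colnames(means) <- stages
  sets <- lapply(stages, function(s) {
    ms <- means[, s]
    other <- pmax(clamp, apply(means[, setdiff(stages, s), drop = FALSE], 1L, max))
    rownames(cohort)[ms >= cutoff & ms >= fold * other]
  })
  names(sets) <- stages
  sets
}
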