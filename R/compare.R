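#' Filter tumor samples by purity
#'
#' Samples whose tumor purity is at or below the threshold are considered
#' highly infiltrated by immune and stromal cells and removed; only
#' strictly-above-threshold samples are kept (a purity of exactly 0.7 is
#' excluded under the default).
#'
#' @param ann data frame of sample annotation with columns `sample_id` and
#'   `purity` (fractions in `[0, 1]`; no missing values).
#' @param threshold purity threshold (default 0.7).
#' @return the retained rows of `ann`.
#' @export
filter_by_purity <- function(ann, threshold = 0.7) {
  if (is.null(ann$purity) || anyNA(ann$purity))
    stop("missing purity for sample(s): ",
         paste(ann$sample_id[is.na(ann$purity)], collapse = ", "))
  ann[ann$purity > threshold, , drop = FALSE]
}

#' Hypergeometric overrepresentation test for two gene sets
#'
#' Upper-tail probability of observing at least the seen overlap between
#' two gene sets drawn from a common universe,
#' `P(X >= |a intersect b|)` with `X ~ Hypergeometric(N, |a|, |b|)`.
#'
#' @param a,b character vectors of gene IDs; both must be subsets of
#'   `universe`.
#' @param universe character vector, the background gene list.
#' @return list with `n_universe`, `n_a`, `n_b`, `n_overlap`, `p_value`.
#' @examples
#' hypergeom_overlap(letters[1:5], letters[2:5], letters)
#' @export
hypergeom_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("both sets must be subsets of the universe")
  N <- length(universe); K <- length(a); n <- length(b)
  k <- length(intersect(a, b))
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(n_universe = N, n_a = K, n_b = n, n_overlap = k,
       p_value = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' the mapping to the input order is preserved. Thin validated wrapper
#' around [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' CLD-to-cohort correlation matrix with matched-vs-unmatched test
#'
#' Computes the Spearman correlation over common genes between every CLD
#' profile and every tumor-cohort mean profile. For each CLD with a
#' matched cohort, a one-sided one-sample Wilcoxon signed-rank test asks
#' whether the correlations to the unmatched cohorts are significantly
#' lower than the matched correlation (the matched value is the location
#' null). The exact distribution is used for up to 25 unmatched cohorts,
#' the continuity-corrected normal approximation above that.
#'
#' @param clds nTPM matrix, one column per CLD.
#' @param cohorts nTPM matrix of cohort mean profiles, one column per
#'   cohort.
#' @param match_map data frame with columns `disease` (CLD label) and
#'   `cohort`; CLDs without a matched cohort are skipped with a message.
#' @return list with `rho` (CLD x cohort Spearman matrix) and `tests`
#'   (data frame: `disease`, `cohort`, `matched_rho`, `p_value`).
#' @export
cld_cohort_correlation <- function(clds, cohorts, match_map) {
  genes <- intersect(rownames(clds), rownames(cohorts))
  if (!length(genes)) stop("no common genes between CLDs and cohorts")
  rho <- stats::cor(clds[genes, , drop = FALSE], cohorts[genes, , drop = FALSE],
                    method = "spearman")
  tests <- lapply(colnames(clds), function(d) {
    co <- match_map$cohort[match_map$disease == d]
    if (!length(co) || !co[1L] %in% colnames(cohorts)) {
      message("CLD without matched cohort, skipped: ", d)
      return(NULL)
    }
    co <- co[1L]
    matched <- rho[d, co]
    unmatched <- rho[d, setdiff(colnames(rho), co)]
    p <- stats::wilcox.test(unmatched, mu = matched, alternative = "less",
                            exact = length(unmatched) <= 25,
                            correct = TRUE)$p.value
    data.frame(disease = d, cohort = co, matched_rho = unname(matched),
               p_value = p, stringsAsFactors = FALSE)
  })
  list(rho = rho, tests = do.call(rbind, tests))
}

#' Pooled within-group correlations under a sample grouping
#'
#' For the grouping `"primary"`, pairwise Spearman correlations between
#' primary cell lines are computed within each disease and pooled;
#' `"metastatic-by-disease"` does the same for metastatic lines;
#' `"metastatic-by-site"` groups metastatic lines by collection site
#' instead. Groups with fewer than two samples contribute no pairs.
#'
#' @param m nTPM expression matrix of cell lines.
#' @param ann data frame with columns `sample_id`, `disease`, `primary`
#'   (logical: primary tumor origin) and `site`.
#' @param grouping one of `"primary"`, `"metastatic-by-disease"`,
#'   `"metastatic-by-site"`.
#' @return numeric vector of pooled pairwise correlations.
#' @export
groupwise_correlations <- function(m, ann,
    grouping = c("primary", "metastatic-by-disease", "metastatic-by-site")) {
  grouping <- match.arg(grouping)
  ann <- ann[ann$sample_id %in% colnames(m), , drop = FALSE]
  sub <- if (grouping == "primary") ann[ann$primary, ] else ann[!ann$primary, ]
  key <- if (grouping == "metastatic-by-site") sub$site else sub$disease
  groups <- split(sub$sample_id, key)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 1L)
    stop("grouping '", grouping, "' has no group with at least two samples")
  unlist(lapply(groups, function(s) {
    r <- stats::cor(m[, s, drop = FALSE], method = "spearman")
    r[upper.tri(r)]
  }), use.names = FALSE)
}

#' Contrast pooled correlation distributions between groupings
#'
#' Runs [groupwise_correlations()] for each requested grouping and
#' compares every pair of pooled distributions with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @inheritParams groupwise_correlations
#' @param groupings character vector of grouping names to include.
#' @return list with `distributions` (named list of pooled correlation
#'   vectors) and `tests` (data frame: `grouping_a`, `grouping_b`,
#'   `p_value`).
#' @export
groupwise_correlation_contrast <- function(m, ann,
    groupings = c("primary", "metastatic-by-disease", "metastatic-by-site")) {
  dists <- lapply(groupings, function(g) groupwise_correlations(m, ann, g))
  names(dists) <- groupings
  pairs <- utils::combn(groupings, 2L, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    pv <- stats::wilcox.test(dists[[p[1L]]], dists[[p[2L]]],
                             alternative = "two.sided", exact = FALSE)$p.value
    data.frame(grouping_a = p[1L], grouping_b = p[2L], p_value = pv,
               stringsAsFactors = FALSE)
  }))
  list(distributions = dists, tests = tests)
}

#' Complete-linkage clustering of expression profiles
#'
#' Hierarchical agglomeration of the matrix columns with complete linkage
#' on the distance `1 - Spearman's rho`. Ties in the distance matrix are
#' resolved deterministically by [stats::hclust()]'s label-order
#' convention.
#'
#' @param m expression matrix; columns are the profiles to cluster.
#' @return an object of class `hclust` (merge list plus heights).
#' @export
hcluster_profiles <- function(m) {
  if (ncol(m) < 2L) stop("need at least two profiles")
  const <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  if (any(const))
    stop("constant column (correlation undefined): ",
         paste(colnames(m)[const], collapse = ", "))
  rho <- stats::cor(m, method = "spearman")
  stats::hclust(stats::as.dist(1 - rho), method = "complete")
}

#' First-neighbor agreement of paired samples in PC space
#'
#' Genes are z-scored across samples, a PCA is fitted, and the smallest
#' number of components whose cumulative variance reaches `variance_kept`
#' is retained. For each left-panel member of a pair, the Euclidean first
#' neighbor among the right-panel samples is found; the function reports
#' the fraction of pairs whose left member has its counterpart as first
#' neighbor.
#'
#' @param m expression matrix containing both panels' samples as columns.
#' @param pairs data frame with columns `left` and `right` (sample IDs).
#' @param variance_kept fraction of total variance to preserve, in
#'   `(0, 1]` (default 0.8).
#' @param right_pool candidate neighbor samples; defaults to
#'   `unique(pairs$right)`.
#' @return list with `fraction`, `n_pcs`, and `neighbors` (data frame:
#'   `left`, `right`, `first_neighbor`, `hit`).
#' @export
pc_neighbor_check <- function(m, pairs, variance_kept = 0.8,
                              right_pool = unique(pairs$right)) {
  if (variance_kept <= 0 || variance_kept > 1)
    stop("variance_kept must lie in (0, 1]")
  miss <- setdiff(c(pairs$left, pairs$right), colnames(m))
  if (length(miss)) stop("pair member(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  sds <- apply(m, 1L, stats::sd)
  z <- (m[sds > 0, , drop = FALSE] - rowMeans(m[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_kept - 1e-9)[1L]  # tolerance guards variance_kept = 1
  scores <- pc$x[, seq_len(k), drop = FALSE]
  nb <- vapply(pairs$left, function(l) {
    cand <- setdiff(right_pool, l)
    d <- sqrt(rowSums((scores[cand, , drop = FALSE] -
                       matrix(scores[l, ], length(cand), k, byrow = TRUE))^2))
    cand[which.min(d)]
  }, character(1))
  hit <- nb == pairs$right
  list(fraction = mean(hit), n_pcs = k,
       neighbors = data.frame(left = pairs$left, right = pairs$right,
                              first_neighbor = unname(nb), hit = hit,
                              stringsAsFactors = FALSE))
}
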